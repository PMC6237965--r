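test_that("temporal identity: unchanged coarse reproduces the fine scene", {
  set.seed(31)
  fine <- random_scene("2014-01-01", 8, seed = 31)
  coarse <- random_scene("2014-01-01", 8, seed = 32)
  pair <- fusion_pair(fine, coarse)
  coarse_tp <- coarse
  coarse_tp$date <- as.Date("2014-01-10")
  pred <- starfm_predict(list(pair), coarse_tp)
  expect_identical(pred$bands, fine$bands)
})

test_that("uniform scenes with a uniform coarse shift add the shift exactly", {
  fine <- flat_scene("2014-01-01", c(green = 0.30, red = 0.30, nir = 0.30,
                                     swir2 = 0.30), n = 8)
  coarse <- flat_scene("2014-01-01", c(green = 0.31, red = 0.31, nir = 0.31,
                                       swir2 = 0.31), n = 8)
  coarse_tp <- flat_scene("2014-01-10", c(green = 0.36, red = 0.36,
                                          nir = 0.36, swir2 = 0.36), n = 8)
  pred <- starfm_predict(list(fusion_pair(fine, coarse)), coarse_tp)
  for (b in names(pred$bands))
    expect_true(all(pred$bands[[b]] == fine$bands[[b]] + 500L))
})

test_that("starfm matches the exhaustive brute-force oracle bitwise", {
  for (case in 1:6) {
    n <- if (case <= 3) 5L else 9L
    w <- if (case <= 3) 5L else 3L
    two_pairs <- case %% 2 == 0
    f1 <- random_scene("2014-01-01", n, seed = 100 + case,
                       p_nodata = 0.08, p_qa_bad = 0.08)
    c1 <- random_scene("2014-01-01", n, seed = 200 + case, p_qa_bad = 0.05)
    f2 <- random_scene("2014-02-02", n, seed = 300 + case, p_nodata = 0.05)
    c2 <- random_scene("2014-02-02", n, seed = 400 + case)
    ctp <- random_scene("2014-01-17", n, seed = 500 + case, p_nodata = 0.05)
    ctp$tier <- "coarse"
    pairs <- if (two_pairs) list(fusion_pair(f1, c1), fusion_pair(f2, c2))
             else list(fusion_pair(f1, c1))
    params <- fusion_params(window_half_width = w)
    pred <- starfm_predict(pairs, ctp, params)

    band_or_na <- function(s, b) {
      m <- s$bands[[b]] + 0
      m[!s$qa | m == -9999] <- NA
      m
    }
    for (b in c("green", "red", "nir", "swir2")) {
      Ls <- lapply(pairs, function(p) band_or_na(p$fine, b))
      Ms <- lapply(pairs, function(p) band_or_na(p$coarse, b))
      Mp <- band_or_na(ctp, b)
      thr <- vapply(Ls, function(m) 2 * sd(m[is.finite(m)]) / 4, numeric(1))
      want <- oracle_starfm(Ls, Ms, Mp, w, params$distance_scale, thr)
      got <- pred$bands[[b]] + 0
      got[got == -9999] <- NA
      want_int <- ifelse(is.na(want), NA,
                         trunc(abs(want) + 0.5) * sign(want))
      expect_identical(got, want_int)
    }
  }
})

test_that("predictions stay within the candidate-term envelope", {
  set.seed(77)
  f1 <- random_scene("2014-01-01", 9, seed = 601, p_nodata = 0.05)
  c1 <- random_scene("2014-01-01", 9, seed = 602)
  ctp <- random_scene("2014-01-17", 9, seed = 603)
  pred <- starfm_predict(list(fusion_pair(f1, c1)), ctp,
                         fusion_params(window_half_width = 4L))
  for (b in c("green", "red")) {
    L <- f1$bands[[b]] + 0
    L[!f1$qa | L == -9999] <- NA
    M <- c1$bands[[b]] + 0
    Mp <- ctp$bands[[b]] + 0
    terms <- Mp + L - M
    p <- pred$bands[[b]]
    ok <- p != -9999
    expect_true(all(p[ok] >= min(terms, na.rm = TRUE) - 0.5))
    expect_true(all(p[ok] <= max(terms, na.rm = TRUE) + 0.5))
  }
})

test_that("nodata is never fabricated", {
  # a pixel invalid in every input scene stays nodata; pixels with valid
  # neighbours (but missing central coarse) may still be predicted from
  # candidates, which is the documented behaviour
  knock <- function(s) {
    s$bands <- lapply(s$bands, function(m) {
      m[4, ] <- -9999L
      m
    })
    s
  }
  f1 <- knock(random_scene("2014-01-01", 7, seed = 71))
  c1 <- knock(random_scene("2014-01-01", 7, seed = 72))
  ctp <- knock(random_scene("2014-01-17", 7, seed = 73))
  pred <- starfm_predict(list(fusion_pair(f1, c1)), ctp)
  for (b in names(pred$bands))
    expect_true(all(pred$bands[[b]][4, ] == -9999L))
})

test_that("fusion accuracy metrics follow the complete-observation rule", {
  a <- random_scene("2014-01-01", 10, seed = 41)
  rep1 <- assess_fusion_accuracy(a, a)
  expect_true(all(rep1$spearman_rho == 1))
  expect_true(all(rep1$rmse == 0 & rep1$mae == 0))

  shifted <- a
  shifted$bands <- lapply(a$bands, function(m) m + 100L)
  rep2 <- assess_fusion_accuracy(shifted, a)
  expect_true(all(rep2$spearman_rho == 1))
  expect_true(all(rep2$rmse == 100 & rep2$mae == 100))

  # 3-pixel toy: pred 1,2,3 vs act 3,2,1
  g <- scene_geometry(1, 3, 30)
  mk <- function(v) raster_scene("2014-01-01", "fine", g,
                                 list(green = matrix(v, 1, 3),
                                      red = matrix(v, 1, 3),
                                      nir = matrix(v, 1, 3),
                                      swir2 = matrix(v, 1, 3)))
  rep3 <- assess_fusion_accuracy(mk(c(1L, 2L, 3L)), mk(c(3L, 2L, 1L)))
  expect_equal(rep3$spearman_rho, rep(-1, 4))
  expect_equal(rep3$rmse, rep(sqrt(8 / 3), 4))
  expect_equal(rep3$mae, rep(4 / 3, 4))

  # metrics only over jointly valid pixels
  holey <- a
  holey$bands$green[1, 1:5] <- -9999L
  rep4 <- assess_fusion_accuracy(holey, a)
  expect_equal(rep4$n[rep4$band == "green"], 95L)
  none <- a
  none$bands <- lapply(a$bands, function(m) matrix(-9999L, 10, 10))
  expect_error(assess_fusion_accuracy(none, a), "valid")
})

test_that("starfm_predict_series picks bracketing pairs", {
  dates <- as.Date("2014-01-01") + 0:32
  ser <- generate_scene_series(dates, n_fine = 20L, ratio = 5L,
                               fine_every = 16L, noise_sd = 0,
                               cloud_fraction = 0, phenology_amplitude = 0,
                               seed = 9)
  preds <- starfm_predict_series(ser$fine, ser$coarse,
                                 dates = as.Date("2014-01-08"),
                                 params = fusion_params(5L))
  expect_named(preds, "2014-01-08")
  # static pattern, no drift: prediction equals the anchor scene
  expect_identical(preds[["2014-01-08"]]$bands,
                   ser$fine[["2014-01-01"]]$bands)
})
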