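# Synthetic coarse/fine reflectance scene series with known per-pixel snow
# truth: a static land-class mosaic (open / forest) with per-pixel texture,
# a spatially uniform seasonal drift, a snow spectral signature overriding
# the land signature wherever the truth mask is snow, random cloud-QA
# patches on fine scenes, additive noise, and exact block-mean coarse
# scenes.

SPECTRAL_SIGNATURES <- list(
  open = c(green = 0.12, red = 0.14, nir = 0.30, swir2 = 0.25),
  forest = c(green = 0.08, red = 0.06, nir = 0.35, swir2 = 0.15),
  snow = c(green = 0.80, red = 0.75, nir = 0.70, swir2 = 0.10))

# smooth blobby forest mask from a seeded random field
make_class_map <- function(n, forest_fraction, seed) {
  with_seed(seed, {
    z <- matrix(rnorm(n * n), n, n)
    for (rep in 1:3) {  # 3x3 box smoothing passes
      zp <- rbind(z[1, ], z, z[n, ])
      zp <- cbind(zp[, 1], zp, zp[, n])
      z <- (zp[1:n, 1:n] + zp[1:n, 2:(n + 1)] + zp[1:n, 3:(n + 2)] +
            zp[2:(n + 1), 1:n] + zp[2:(n + 1), 2:(n + 1)] +
            zp[2:(n + 1), 3:(n + 2)] + zp[3:(n + 2), 1:n] +
            zp[3:(n + 2), 2:(n + 1)] + zp[3:(n + 2), 3:(n + 2)]) / 9
    }
    z <= quantile(z, forest_fraction)
  })
}

cloud_mask <- function(n, fraction, seed) {
  qa <- matrix(TRUE, n, n)
  if (fraction <= 0) return(qa)
  if (fraction >= 1) return(matrix(FALSE, n, n))
  with_seed(seed, {
    target <- round(fraction * n * n)
    tries <- 0L
    while (sum(!qa) < target && tries < 200L) {
      h <- sample(3:max(4, n %/% 4), 1)
      w <- sample(3:max(4, n %/% 4), 1)
      i <- sample(seq_len(max(n - h + 1L, 1L)), 1)
      j <- sample(seq_len(max(n - w + 1L, 1L)), 1)
      qa[i:(i + h - 1L), j:(j + w - 1L)] <- FALSE
      tries <- tries + 1L
    }
  })
  qa
}

#' Generate a synthetic coarse/fine scene series with snow truth
#'
#' @param dates `Date` vector of the series (coarse scenes are emitted
#'   daily; fine scenes every `fine_every` days starting at the first date)
#' @param snow_days `Date` vector of days on which the whole domain is
#'   snow-covered, or a `function(date)` returning a logical truth matrix
#' @param n_fine fine grid edge, pixels (default 60)
#' @param ratio integral coarse:fine cell ratio (default 10)
#' @param cellsize fine cell size, m (default 30)
#' @param fine_every days between fine acquisitions (default 16, the
#'   revisit of the fine sensor)
#' @param cloud_fraction expected QA-masked fraction of each fine scene
#' @param cloud_fraction_coarse same for coarse scenes (default 0)
#' @param noise_sd additive per-pixel noise SD in scaled units on fine
#'   scenes; coarse scenes get `noise_sd / ratio` (block averaging)
#' @param texture_sd SD of the static per-pixel reflectance texture
#' @param phenology_amplitude scaled-unit amplitude of the spatially
#'   uniform seasonal drift (applied to every band)
#' @param forest_fraction fraction of the domain assigned the forest class
#' @param seed integer seed; the series is deterministic given it
#' @return list with `fine` (named list of fine `raster_scene`s), `coarse`
#'   (named list, daily), `truth` (named list of logical snow-truth
#'   matrices, fine grid), `classes` (logical forest mask), `geom`
#' @export
generate_scene_series <- function(dates, snow_days = as.Date(character()),
                                  n_fine = 60L, ratio = 10L, cellsize = 30,
                                  fine_every = 16L,
                                  cloud_fraction = 0.05,
                                  cloud_fraction_coarse = 0,
                                  noise_sd = 50, texture_sd = 0.02,
                                  phenology_amplitude = 100,
                                  forest_fraction = 0.3, seed = 1L) {
  dates <- sort(as.Date(dates))
  if (n_fine %% ratio != 0L)
    stop("fine grid size must be divisible by the coarse:fine ratio")
  geom <- scene_geometry(n_fine, n_fine, cellsize)
  forest <- make_class_map(n_fine, forest_fraction, seed_stream(seed, "class"))
  texture <- lapply(stats::setNames(BAND_NAMES, BAND_NAMES), function(b)
    with_seed(seed_stream(seed, "texture", b),
              matrix(rnorm(n_fine^2, 0, texture_sd * REFL_SCALE),
                     n_fine, n_fine)))
  truth_of <- function(d) {
    if (is.function(snow_days)) snow_days(d)
    else matrix(d %in% snow_days, n_fine, n_fine)
  }
  span <- max(as.numeric(max(dates) - min(dates)), 1)
  fine_dates <- dates[(as.numeric(dates - dates[1]) %% fine_every) == 0]
  base_field <- function(d, band) {
    sig_land <- ifelse(forest, SPECTRAL_SIGNATURES$forest[band],
                       SPECTRAL_SIGNATURES$open[band]) * REFL_SCALE
    m <- sig_land + texture[[band]]
    tr <- truth_of(d)
    m[tr] <- SPECTRAL_SIGNATURES$snow[band] * REFL_SCALE + texture[[band]][tr]
    phen <- phenology_amplitude *
      sin(2 * pi * as.numeric(d - dates[1]) / span)
    m + phen
  }
  to_int <- function(m) {
    m <- round_half_away(pmin(pmax(m, 0), REFL_SCALE))
    storage.mode(m) <- "integer"
    m
  }
  fine <- list()
  coarse <- list()
  truth <- list()
  for (d in as.list(dates)) {
    key <- format(d)
    truth[[key]] <- truth_of(d)
    noisefree <- lapply(stats::setNames(BAND_NAMES, BAND_NAMES),
                        function(b) base_field(d, b))
    # coarse: exact block mean of the noise-free field + its own noise
    cf <- raster_scene(d, "fine", geom, lapply(noisefree, to_int))
    cscene <- block_mean_scene(cf, ratio)
    if (noise_sd > 0) {
      cn <- with_seed(seed_stream(seed, "cnoise", key), {
        lapply(cscene$bands, function(m)
          to_int(m + matrix(rnorm(length(m), 0, noise_sd / ratio),
                            nrow(m), ncol(m))))
      })
      cscene <- raster_scene(d, "coarse", cscene$geom, cn, cscene$qa)
    }
    cqa <- cloud_mask(nrow(cscene$qa), cloud_fraction_coarse,
                      seed_stream(seed, "cclouds", key))
    coarse[[key]] <- prepare_scene(cscene, cscene$qa & cqa)
    if (d %in% fine_dates) {
      fb <- noisefree
      if (noise_sd > 0)
        fb <- with_seed(seed_stream(seed, "fnoise", key),
                        lapply(fb, function(m)
                          m + matrix(rnorm(length(m), 0, noise_sd),
                                     n_fine, n_fine)))
      qa <- cloud_mask(n_fine, cloud_fraction,
                       seed_stream(seed, "fclouds", key))
      fine[[key]] <- prepare_scene(
        raster_scene(d, "fine", geom, lapply(fb, to_int)), qa)
    }
  }
  list(fine = fine, coarse = coarse, truth = truth, classes = forest,
       geom = geom)
}
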