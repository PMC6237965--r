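# STARFM-style spatiotemporal fusion: predict a synthetic fine-resolution
# scene on a coarse-only date from 1-2 same-day coarse/fine pairs.

#' Fusion parameters
#'
#' The source study defers to the original algorithm for these constants, so
#' defaults follow its published practice: moving-window half width 15 fine
#' pixels, m = 4 classes for the spectral-similarity threshold
#' (|L - L_center| <= 2 sd(L) / m), distance scale A equal to the window
#' half width.
#'
#' @param window_half_width moving-window half width, fine pixels (>= 1)
#' @param n_classes m, class count controlling the similarity threshold
#' @param distance_scale A, fine pixels (default = `window_half_width`)
#' @return a `fusion_params` list
#' @export
fusion_params <- function(window_half_width = 15L, n_classes = 4L,
                          distance_scale = window_half_width) {
  stopifnot(window_half_width >= 1L, n_classes >= 1L, distance_scale > 0)
  structure(list(window_half_width = as.integer(window_half_width),
                 n_classes = as.integer(n_classes),
                 distance_scale = as.numeric(distance_scale)),
            class = "fusion_params")
}

#' Pair a fine scene with its same-day coarse scene
#'
#' The coarse scene is resampled (nearest neighbour) to the fine geometry if
#' it is not already on it.  Dates must match.
#'
#' @param fine fine-tier `raster_scene`
#' @param coarse coarse-tier `raster_scene` (original or resampled grid)
#' @return a `fusion_pair` list with both scenes on the fine grid
#' @export
fusion_pair <- function(fine, coarse) {
  stopifnot(inherits(fine, "raster_scene"), inherits(coarse, "raster_scene"))
  if (!identical(as.Date(fine$date), as.Date(coarse$date)))
    stop("fusion pair dates differ")
  if (!geom_equal(fine$geom, coarse$geom))
    coarse <- resample_coarse_to_fine(coarse, fine$geom)
  structure(list(date = fine$date, fine = fine, coarse = coarse),
            class = "fusion_pair")
}

# band matrix as double with NA where nodata/QA-bad
band_na <- function(scene, band) {
  m <- scene$bands[[band]] + 0.0
  m[!scene$qa | scene$bands[[band]] == NODATA] <- NA_real_
  m
}

#' Predict a synthetic fine scene at the coarse-only date
#'
#' Per band, each target pixel is predicted from spectrally similar,
#' QA-good candidate pixels in the moving window of each input pair,
#' weighted by the inverse product of spectral difference S = |L - M|,
#' temporal difference T = |M(t_k) - M(t_p)| and distance factor
#' D = 1 + d/A (S, T floored at 1 scaled unit); the prediction is the
#' weighted mean of M(t_p) + L(t_k) - M(t_k).  An exact central
#' zero-difference (T = 0 or S = 0, unfloored) short-circuits to the exact
#' first-order relation; with no qualifying candidate the central-pixel
#' relation of the best pair is used; a pixel valid in no input stays
#' nodata.  Output is rounded half-away-from-zero to int16.
#'
#' @param pairs list of 1--2 [fusion_pair()]s
#' @param coarse_tp coarse `raster_scene` at the prediction date (any grid;
#'   resampled to fine if needed)
#' @param params a [fusion_params()]
#' @return fine-tier `raster_scene` at the prediction date
#' @export
starfm_predict <- function(pairs, coarse_tp, params = fusion_params()) {
  if (inherits(pairs, "fusion_pair")) pairs <- list(pairs)
  stopifnot(length(pairs) >= 1L, length(pairs) <= 2L,
            inherits(params, "fusion_params"))
  geom <- pairs[[1]]$fine$geom
  for (p in pairs) stopifnot(inherits(p, "fusion_pair"),
                             geom_equal(p$fine$geom, geom))
  if (!geom_equal(coarse_tp$geom, geom))
    coarse_tp <- resample_coarse_to_fine(coarse_tp, geom)
  bands <- list()
  valid <- matrix(FALSE, geom$nrow, geom$ncol)
  for (b in BAND_NAMES) {
    Lk <- lapply(pairs, function(p) band_na(p$fine, b))
    Mk <- lapply(pairs, function(p) band_na(p$coarse, b))
    Mp <- band_na(coarse_tp, b)
    thr <- vapply(Lk, function(m) {
      s <- sd(m[is.finite(m)])
      if (!is.finite(s)) s <- 0
      2 * s / params$n_classes
    }, numeric(1))
    pred <- starfm_band_cpp(Lk, Mk, Mp, params$window_half_width,
                            params$distance_scale, thr)
    out <- round_half_away(pred)
    out[is.na(out)] <- NODATA
    out[out != NODATA & out > 32767] <- 32767
    out[out != NODATA & out < -32768] <- -32768L
    storage.mode(out) <- "integer"
    valid <- valid | out != NODATA
    bands[[b]] <- out
  }
  raster_scene(coarse_tp$date, "fine", geom, bands, valid)
}

#' Accuracy of a predicted scene against an actual scene
#'
#' Metrics are computed per band over pixels valid in both scenes only
#' (complete-observation rule): Spearman rho, RMSE and MAE in scaled
#' reflectance units.
#'
#' @param predicted,actual fine `raster_scene`s on the same geometry
#' @return data.frame `band`, `n`, `spearman_rho`, `rmse`, `mae`
#' @export
assess_fusion_accuracy <- function(predicted, actual) {
  stopifnot(geom_equal(predicted$geom, actual$geom))
  out <- NULL
  for (b in BAND_NAMES) {
    p <- band_na(predicted, b)
    a <- band_na(actual, b)
    ok <- is.finite(p) & is.finite(a)
    if (!any(ok)) stop("no jointly valid pixels in band ", b)
    e <- p[ok] - a[ok]
    out <- rbind(out, data.frame(
      band = b, n = sum(ok),
      spearman_rho = suppressWarnings(cor(p[ok], a[ok], method = "spearman")),
      rmse = sqrt(mean(e^2)), mae = mean(abs(e))))
  }
  out
}

#' Predict fine scenes for all coarse-only dates of a series
#'
#' For each requested date lacking a fine scene, the nearest earlier and
#' later fine scenes (within `max_gap_days`, default two months either
#' side) with same-day coarse scenes form the input pairs; one-sided cases
#' use a single pair.
#'
#' @param fine_scenes list of fine `raster_scene`s (the observed anchors)
#' @param coarse_scenes list of coarse `raster_scene`s (daily)
#' @param dates `Date` vector to predict (default: all coarse dates without
#'   a fine scene)
#' @param params a [fusion_params()]
#' @param max_gap_days maximum pair distance from the prediction date
#' @return named list of predicted fine `raster_scene`s (by date)
#' @export
starfm_predict_series <- function(fine_scenes, coarse_scenes, dates = NULL,
                                  params = fusion_params(),
                                  max_gap_days = 62L) {
  fdates <- as.Date(vapply(fine_scenes, function(s) format(s$date),
                           character(1)))
  cdates <- as.Date(vapply(coarse_scenes, function(s) format(s$date),
                           character(1)))
  if (is.null(dates)) dates <- setdiff(cdates, fdates)
  dates <- as.Date(dates, origin = "1970-01-01")
  out <- list()
  usable <- fdates[fdates %in% cdates]
  for (d in as.list(dates)) {
    if (!d %in% cdates) stop("no coarse scene for ", format(d))
    before <- usable[usable < d & d - usable <= max_gap_days]
    after <- usable[usable > d & usable - d <= max_gap_days]
    anchors <- c(if (length(before)) max(before),
                 if (length(after)) min(after))
    if (!length(anchors)) stop("no usable pair near ", format(d))
    pairs <- lapply(as.list(as.Date(anchors, origin = "1970-01-01")),
                    function(a)
      fusion_pair(fine_scenes[[which(fdates == a)[1]]],
                  coarse_scenes[[which(cdates == a)[1]]]))
    out[[format(d)]] <- starfm_predict(pairs,
                                       coarse_scenes[[which(cdates == d)[1]]],
                                       params)
  }
  out
}
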