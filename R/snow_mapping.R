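# NDSI/NDVI computation, threshold snow classification, and plot-level
# snow flags from daily maps.

index_grid <- function(date, index, values, geom) {
  structure(list(date = as.Date(date), index = index, values = values,
                 geom = geom), class = "index_grid")
}

#' Normalized Difference Snow Index of a scene
#'
#' NDSI = (green - SWIR2) / (green + SWIR2) on unscaled reflectance.
#' Pixels with green reflectance <= `green_floor` (default 0.1) are masked
#' *before* computation to prevent NDSI overestimation over dark surfaces;
#' nodata and QA-bad pixels propagate.
#'
#' @param scene a fine `raster_scene`
#' @param green_floor inclusive green-reflectance mask threshold
#' @return an `index_grid` with values in \[-1, 1\] or NA
#' @export
compute_ndsi <- function(scene, green_floor = 0.1) {
  g <- band_na(scene, "green") / REFL_SCALE
  s <- band_na(scene, "swir2") / REFL_SCALE
  g[g <= green_floor] <- NA_real_
  den <- g + s
  v <- ifelse(is.na(g) | is.na(s) | den == 0, NA_real_, (g - s) / den)
  index_grid(scene$date, "NDSI", matrix(v, nrow(g), ncol(g)), scene$geom)
}

#' Normalized Difference Vegetation Index of a scene
#'
#' NDVI = (NIR - red) / (NIR + red) on unscaled reflectance; nodata
#' propagates.
#'
#' @param scene a fine `raster_scene`
#' @return an `index_grid`
#' @export
compute_ndvi <- function(scene) {
  n <- band_na(scene, "nir") / REFL_SCALE
  r <- band_na(scene, "red") / REFL_SCALE
  den <- n + r
  v <- ifelse(is.na(n) | is.na(r) | den == 0, NA_real_, (n - r) / den)
  index_grid(scene$date, "NDVI", matrix(v, nrow(n), ncol(n)), scene$geom)
}

#' Published year-specific NDSI thresholds
#'
#' 0.35 for the October 2013 -- May 2014 season and 0.30 for October 2015 --
#' May 2016 (snow in the warmer year is patchier, lowering the optimal
#' threshold).
#'
#' @return list of period entries (`start`, `end`, `threshold`)
#' @export
default_ndsi_thresholds <- function() {
  list(list(start = as.Date("2013-10-01"), end = as.Date("2014-05-31"),
            threshold = 0.35),
       list(start = as.Date("2015-10-01"), end = as.Date("2016-05-31"),
            threshold = 0.30))
}

#' Resolve the NDSI threshold for an acquisition date
#'
#' @param date acquisition `Date`
#' @param thresholds list of period entries as in
#'   [default_ndsi_thresholds()]
#' @return the period's threshold; error if no period covers the date
#' @export
ndsi_threshold_for <- function(date, thresholds = default_ndsi_thresholds()) {
  date <- as.Date(date)
  for (p in thresholds)
    if (date >= p$start && date <= p$end) return(p$threshold)
  stop("no NDSI threshold configured for ", format(date))
}

#' Classify snow from NDSI with the auxiliary NDVI rule
#'
#' A pixel is snow iff `threshold < NDSI <= 1`, or (auxiliary forest rule)
#' `ndsi_lo < NDSI < ndsi_hi` and `ndvi_lo <= NDVI <= ndvi_hi`.  Masked
#' NDSI propagates as masked; a pixel whose decision needs the auxiliary
#' rule but lacks NDVI is masked too.
#'
#' @param ndsi,ndvi `index_grid`s on the same geometry
#' @param threshold period-specific primary NDSI threshold (strict `>`)
#' @param ndvi_rule list with `ndsi_lo`, `ndsi_hi`, `ndvi_lo`, `ndvi_hi`
#' @return a `snow_map`: list with `date`, `state` matrix (0 no-snow,
#'   1 snow, 255 masked), `geom`
#' @export
classify_snow <- function(ndsi, ndvi, threshold,
                          ndvi_rule = list(ndsi_lo = 0.1, ndsi_hi = 0.3,
                                           ndvi_lo = 0.08, ndvi_hi = 0.12)) {
  stopifnot(identical(dim(ndsi$values), dim(ndvi$values)))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold))
    stop("missing or invalid NDSI threshold")
  s <- ndsi$values
  v <- ndvi$values
  state <- matrix(0L, nrow(s), ncol(s))
  primary <- !is.na(s) & s > threshold & s <= 1
  auxzone <- !is.na(s) & s > ndvi_rule$ndsi_lo & s < ndvi_rule$ndsi_hi
  aux <- auxzone & !is.na(v) & v >= ndvi_rule$ndvi_lo & v <= ndvi_rule$ndvi_hi
  state[primary | aux] <- 1L
  state[is.na(s)] <- 255L
  state[!primary & auxzone & is.na(v)] <- 255L
  structure(list(date = ndsi$date, state = state, geom = ndsi$geom),
            class = "snow_map")
}

#' Plot geometry for buffer extraction
#'
#' @param plot_id identifier
#' @param x,y plot center coordinates (scene CRS)
#' @param buffer buffer radius, m (default 15)
#' @return a `plot_geometry` list
#' @export
plot_geometry <- function(plot_id, x, y, buffer = 15) {
  structure(list(plot_id = plot_id, x = x, y = y, buffer = buffer),
            class = "plot_geometry")
}

# indices of pixels whose centers fall inside the plot buffer
buffer_pixels <- function(geom, plot) {
  cx <- geom$origin_x + (seq_len(geom$ncol) - 0.5) * geom$cellsize
  cy <- geom$origin_y - (seq_len(geom$nrow) - 0.5) * geom$cellsize
  if (plot$x + plot$buffer < min(cx) - geom$cellsize / 2 ||
      plot$x - plot$buffer > max(cx) + geom$cellsize / 2 ||
      plot$y + plot$buffer < min(cy) - geom$cellsize / 2 ||
      plot$y - plot$buffer > max(cy) + geom$cellsize / 2)
    stop("plot buffer lies outside the scene extent")
  dx <- outer(rep(1, geom$nrow), cx - plot$x)
  dy <- outer(cy - plot$y, rep(1, geom$ncol))
  which(dx^2 + dy^2 <= plot$buffer^2)
}

#' Daily plot snow flags (and season) from snow maps
#'
#' A day is plot-snow iff at least `pixel_quorum` of the unmasked pixels
#' whose centers fall in the plot buffer are classified snow (the NDSI
#' algorithm is reliable only for pixels with >= 50% snow cover, hence the
#' default quorum 0.5); a day with every buffer pixel masked is unknown.
#' When `window` is supplied the satellite snow season (SCD_S) is extracted
#' with the same longest-run rule as the sensor pipeline, for
#' comparability.
#'
#' @param maps named list (by date string) of `snow_map`s
#' @param plot a [plot_geometry()]
#' @param pixel_quorum required snow fraction among unmasked buffer pixels
#' @param window optional length-2 `Date` search window for the season
#' @return list with `flags` (plot-scope snow-flag data.frame) and
#'   `season` (NULL unless `window` given)
#' @export
plot_snow_from_maps <- function(maps, plot, pixel_quorum = 0.5,
                                window = NULL) {
  stopifnot(length(maps) >= 1L, inherits(plot, "plot_geometry"))
  idx <- buffer_pixels(maps[[1]]$geom, plot)
  if (!length(idx)) stop("no pixel center falls inside the plot buffer")
  dates <- as.Date(names(maps))
  o <- order(dates)
  flag <- vapply(maps[o], function(m) {
    st <- m$state[idx]
    known <- st != 255L
    if (!any(known)) return("unknown")
    if (sum(st[known] == 1L) / sum(known) >= pixel_quorum) "snow" else "no-snow"
  }, character(1))
  flags <- data.frame(date = dates[o], flag = unname(flag),
                      stringsAsFactors = FALSE)
  season <- NULL
  if (!is.null(window))
    season <- snow_season(flags, window[1], window[2])
  list(flags = flags, season = season)
}
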