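# Raster containers and preparation.
#
# Scenes are stored the way the fusion inputs are prepared in practice:
# reflectance x 10^4 as signed 16-bit integers, nodata -9999, with a boolean
# good-pixel QA mask.  No GDAL binding is assumed: I/O uses the flat-binary
# dialect (row-major int16 planes + a JSON geometry sidecar).

NODATA <- -9999L
REFL_SCALE <- 10000
BAND_NAMES <- c("green", "red", "nir", "swir2")

#' Construct a grid geometry
#'
#' Row 1 is the top of the grid; `origin_x`/`origin_y` give the top-left
#' corner.  The center of pixel (r, c) is at
#' (origin_x + (c - 0.5) cell, origin_y - (r - 0.5) cell).
#'
#' @param nrow,ncol grid dimensions
#' @param cellsize cell edge length (m)
#' @param origin_x,origin_y top-left corner coordinates
#' @param crs free-text CRS label (must match between combined scenes)
#' @return a `scene_geometry` list
#' @export
scene_geometry <- function(nrow, ncol, cellsize, origin_x = 0,
                           origin_y = nrow * cellsize, crs = "local") {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cellsize = cellsize, origin_x = origin_x,
                 origin_y = origin_y, crs = crs),
            class = "scene_geometry")
}

geom_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("nrow", "ncol", "cellsize",
                                "origin_x", "origin_y")],
                   unclass(b)[c("nrow", "ncol", "cellsize",
                                "origin_x", "origin_y")])) &&
    identical(a$crs, b$crs)
}

#' Construct a multiband reflectance scene
#'
#' @param date acquisition date (`Date`)
#' @param tier `"fine"` or `"coarse"`
#' @param geom a [scene_geometry()]
#' @param bands named list of integer matrices (green, red, nir, swir2),
#'   scaled reflectance (reflectance x 10^4), nodata -9999
#' @param qa logical good-pixel matrix (TRUE = usable); defaults to all good
#' @return a `raster_scene`
#' @export
raster_scene <- function(date, tier = c("fine", "coarse"), geom, bands,
                         qa = NULL) {
  tier <- match.arg(tier)
  stopifnot(inherits(geom, "scene_geometry"))
  if (!all(BAND_NAMES %in% names(bands)))
    stop("bands must contain: ", paste(BAND_NAMES, collapse = ", "))
  bands <- bands[BAND_NAMES]
  for (b in BAND_NAMES) {
    m <- bands[[b]]
    if (!is.matrix(m) || nrow(m) != geom$nrow || ncol(m) != geom$ncol)
      stop("band '", b, "' does not match scene geometry")
    storage.mode(m) <- "integer"
    bands[[b]] <- m
  }
  if (is.null(qa)) qa <- matrix(TRUE, geom$nrow, geom$ncol)
  stopifnot(is.logical(qa), nrow(qa) == geom$nrow, ncol(qa) == geom$ncol)
  structure(list(date = as.Date(date), tier = tier, geom = geom,
                 bands = bands, qa = qa),
            class = "raster_scene")
}

#' @export
print.raster_scene <- function(x, ...) {
  cat(sprintf("<raster_scene %s %s %dx%d @%gm, %.1f%% good>\n",
              x$tier, format(x$date), x$geom$nrow, x$geom$ncol,
              x$geom$cellsize, 100 * mean(x$qa)))
  invisible(x)
}

# valid-data mask: QA good and no band at nodata
scene_valid_mask <- function(scene) {
  ok <- scene$qa
  for (b in BAND_NAMES) ok <- ok & scene$bands[[b]] != NODATA
  ok
}

#' Apply QA masking and range validation to a raw scene
#'
#' QA-bad pixels are set to nodata in every band; remaining values are
#' clamped to the valid scaled-reflectance range \[0, 10^4\].
#'
#' @param scene a `raster_scene` (or list with bands/geom) to clean
#' @param qa optional logical good-pixel mask overriding `scene$qa`
#' @return a `raster_scene` with nodata where QA failed
#' @export
prepare_scene <- function(scene, qa = NULL) {
  stopifnot(inherits(scene, "raster_scene"))
  if (is.null(qa)) qa <- scene$qa
  if (!identical(dim(qa), c(scene$geom$nrow, scene$geom$ncol)))
    stop("QA mask geometry mismatch")
  bands <- scene$bands
  for (b in BAND_NAMES) {
    m <- bands[[b]]
    m[!qa] <- NODATA
    live <- m != NODATA
    m[live & m < 0L] <- 0L
    m[live & m > as.integer(REFL_SCALE)] <- as.integer(REFL_SCALE)
    bands[[b]] <- m
  }
  raster_scene(scene$date, scene$tier, scene$geom, bands, qa)
}

#' Nearest-neighbour resampling of a coarse scene to a fine grid
#'
#' Each fine pixel takes the value of the coarse pixel whose center is
#' nearest to the fine pixel's center; nodata and QA propagate.
#'
#' @param coarse a coarse-tier `raster_scene`
#' @param fine_geom target [scene_geometry()]
#' @return a `raster_scene` on `fine_geom` (tier kept as `"coarse"` to mark
#'   provenance)
#' @export
resample_coarse_to_fine <- function(coarse, fine_geom) {
  stopifnot(inherits(coarse, "raster_scene"),
            inherits(fine_geom, "scene_geometry"))
  cg <- coarse$geom
  if (!identical(cg$crs, fine_geom$crs)) stop("CRS mismatch")
  # fine pixel centers
  fx <- fine_geom$origin_x + (seq_len(fine_geom$ncol) - 0.5) * fine_geom$cellsize
  fy <- fine_geom$origin_y - (seq_len(fine_geom$nrow) - 0.5) * fine_geom$cellsize
  # nearest coarse index per axis
  ci <- pmin(pmax(round((cg$origin_y - fy) / cg$cellsize + 0.5), 1L), cg$nrow)
  cj <- pmin(pmax(round((fx - cg$origin_x) / cg$cellsize + 0.5), 1L), cg$ncol)
  # disjoint extents guard
  if (max(fx) < cg$origin_x || min(fx) > cg$origin_x + cg$ncol * cg$cellsize ||
      max(fy) > cg$origin_y || min(fy) < cg$origin_y - cg$nrow * cg$cellsize)
    stop("coarse and fine extents are disjoint")
  idx <- cbind(rep(ci, times = fine_geom$ncol),
               rep(cj, each = fine_geom$nrow))
  bands <- lapply(coarse$bands, function(m)
    matrix(m[idx], fine_geom$nrow, fine_geom$ncol))
  qa <- matrix(coarse$qa[idx], fine_geom$nrow, fine_geom$ncol)
  raster_scene(coarse$date, "coarse", fine_geom, bands, qa)
}

# Aggregate a fine scene to the coarse grid by exact block means (generator
# and tests only).  A block with no valid pixel becomes nodata.
block_mean_scene <- function(fine, ratio) {
  g <- fine$geom
  if (g$nrow %% ratio != 0 || g$ncol %% ratio != 0)
    stop("fine grid does not nest at ratio ", ratio)
  cn <- g$nrow %/% ratio
  cm <- g$ncol %/% ratio
  cg <- scene_geometry(cn, cm, g$cellsize * ratio, g$origin_x, g$origin_y,
                       g$crs)
  ri <- (seq_len(g$nrow) - 1L) %/% ratio + 1L
  cj <- (seq_len(g$ncol) - 1L) %/% ratio + 1L
  grp <- ri[row(fine$qa)] + (cj[col(fine$qa)] - 1L) * cn
  bands <- lapply(fine$bands, function(m) {
    v <- as.numeric(m)
    v[v == NODATA] <- NA
    mu <- tapply(v, grp, mean, na.rm = TRUE)
    out <- matrix(NODATA, cn, cm)
    out[as.integer(names(mu))] <- ifelse(is.nan(mu), NODATA,
                                         round_half_away(mu))
    storage.mode(out) <- "integer"
    out
  })
  qa <- matrix(tapply(as.logical(fine$qa), grp, any), cn, cm)
  qa[is.na(qa)] <- FALSE
  raster_scene(fine$date, "coarse", cg, bands, qa)
}

# ---- flat-binary I/O ---------------------------------------------------

#' Write a scene as flat int16 binary with a JSON sidecar
#'
#' Planes are written row-major in band order green, red, nir, swir2,
#' followed by a QA plane (1 good / 0 bad), as little-endian int16.
#'
#' @param scene a `raster_scene`
#' @param prefix file path prefix; writes `<prefix>.bin` and `<prefix>.json`
#' @return invisibly the two paths written
#' @export
write_scene_binary <- function(scene, prefix) {
  stopifnot(inherits(scene, "raster_scene"))
  binpath <- paste0(prefix, ".bin")
  planes <- c(lapply(scene$bands, function(m) as.integer(t(m))),
              list(qa = as.integer(t(scene$qa))))
  con <- file(binpath, "wb")
  on.exit(close(con))
  for (p in planes) writeBin(p, con, size = 2L, endian = "little")
  meta <- list(date = format(scene$date), tier = scene$tier,
               nrow = scene$geom$nrow, ncol = scene$geom$ncol,
               cellsize = scene$geom$cellsize,
               origin_x = scene$geom$origin_x,
               origin_y = scene$geom$origin_y, crs = scene$geom$crs,
               bands = c(BAND_NAMES, "qa"), nodata = NODATA,
               scale = REFL_SCALE, dtype = "int16le")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(binpath, paste0(prefix, ".json")))
}

#' Read a scene written by [write_scene_binary()]
#'
#' @param prefix file path prefix used at write time
#' @return a `raster_scene`
#' @export
read_scene_binary <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- meta$nrow * meta$ncol
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  planes <- lapply(seq_len(5L), function(i)
    matrix(readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                   endian = "little"),
           meta$nrow, meta$ncol, byrow = TRUE))
  geom <- scene_geometry(meta$nrow, meta$ncol, meta$cellsize, meta$origin_x,
                         meta$origin_y, meta$crs)
  raster_scene(as.Date(meta$date), meta$tier, geom,
               stats::setNames(planes[1:4], BAND_NAMES),
               planes[[5]] != 0L)
}
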