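#' @useDynLib coldsoil, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate anova coef cor dist kmeans lm
#'   pgamma pnorm predict pt qt quantile rbinom rgamma rnorm runif sd
#'   shapiro.test var complete.cases na.omit
#' @importFrom utils head read.csv tail write.csv
NULL

# ---- RNG ---------------------------------------------------------------

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generator functions do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-stream seed (< 2^31) from a base seed and string
# labels; order of labels matters, call order of streams does not.
seed_stream <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "|")
  bytes <- utf8ToInt(parts)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483563
  as.integer(h + 1L)
}

# ---- calendar ----------------------------------------------------------

# A "study year" runs December 1 .. November 30 and is labelled by its
# December calendar year (so Dec 2015 - Nov 2016 has start year 2015).
study_year_start <- function(dates) {
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  ifelse(m == 12L, y, y - 1L)
}

#' Meteorological season of a month
#'
#' Winter = Dec--Feb, spring = Mar--May, summer = Jun--Aug, fall = Sep--Nov.
#'
#' @param month integer month 1..12
#' @return character vector of season names
#' @export
season_of_month <- function(month) {
  stopifnot(all(month %in% 1:12))
  c("winter", "winter", "spring", "spring", "spring",
    "summer", "summer", "summer", "fall", "fall", "fall", "winter")[month]
}

date_seq <- function(from, to) seq(as.Date(from), as.Date(to), by = "day")

hour_seq <- function(from, to) {
  seq(as.POSIXct(paste(from, "00:00:00"), tz = "UTC"),
      as.POSIXct(paste(to, "23:00:00"), tz = "UTC"), by = "hour")
}

# ---- numeric helpers ---------------------------------------------------

# round half away from zero, to integer (int16 write convention)
round_half_away <- function(x) {
  out <- trunc(abs(x) + 0.5) * sign(x)
  out[x == 0] <- 0
  out
}

# longest run of TRUE in a logical vector (NA counts as FALSE);
# returns c(start_index, end_index, length) or NULL when no TRUE present
longest_true_run <- function(x) {
  x <- !is.na(x) & x
  if (!any(x)) return(NULL)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  best <- idx[which.max(r$lengths[idx])]
  c(start = starts[best], end = ends[best], length = r$lengths[best])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
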