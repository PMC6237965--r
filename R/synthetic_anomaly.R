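# Synthetic monthly temperature records for anomaly/proxy-year recovery
# tests: climatology + accelerating trend + noise, with one designated
# warm study year receiving a local anomaly spike that is largest in winter.

#' Generate synthetic reference and local temperature anomaly records
#'
#' Monthly temperatures are a sinusoidal climatology plus a
#' linear-plus-quadratic warming trend plus Gaussian noise; the reference
#' (hemispheric-mean-like) series is smoother than the local one.  One
#' designated warm study year receives an added local spike with annual
#' mean `spike` degC, weighted `1 + cos` so it peaks in winter.  Both
#' series are returned already anomalised against the baseline window via
#' [monthly_anomalies()].
#'
#' @param seed integer seed
#' @param ref_years,local_years calendar-year spans of the two series; the
#'   local span must contain the baseline window
#' @param study_years December start years of the candidate study years
#' @param warm_year December start year receiving the spike (NA for none)
#' @param spike annual-mean local anomaly added to the warm year, degC
#' @param trend_lin,trend_quad trend coefficients per year and year^2
#'   (relative to 1950)
#' @param noise_sd_ref,noise_sd_local monthly noise SDs, degC
#' @param baseline climatology window (default `c(1961, 1990)`)
#' @return list `reference`, `local` (data.frames `year`, `month`,
#'   `anomaly`) and `truth` (the injected warm year and spike)
#' @export
generate_anomaly_records <- function(seed = 1L,
                                     ref_years = 1900:2017,
                                     local_years = 1950:2017,
                                     study_years = 2012:2016,
                                     warm_year = 2015L,
                                     spike = 2.5,
                                     trend_lin = 0.008, trend_quad = 1.2e-4,
                                     noise_sd_ref = 0.3,
                                     noise_sd_local = 1.0,
                                     baseline = c(1961, 1990)) {
  if (baseline[1] < min(local_years) || baseline[2] > max(local_years) ||
      baseline[1] < min(ref_years) || baseline[2] > max(ref_years))
    stop("baseline window not inside the generated span")
  clim <- function(m) -1.1 - 14 * cos(2 * pi * (m - 1.5) / 12)
  trend <- function(y) trend_lin * (y - 1950) + trend_quad * pmax(y - 1950, 0)^2
  make <- function(years, sdn, tag) {
    g <- expand.grid(month = 1:12, year = years)
    g <- g[order(g$year, g$month), ]
    noise <- with_seed(seed_stream(seed, "anomaly", tag),
                       rnorm(nrow(g), 0, sdn))
    data.frame(year = g$year, month = g$month,
               value = clim(g$month) + trend(g$year) + noise)
  }
  ref <- make(ref_years, noise_sd_ref, "ref")
  loc <- make(local_years, noise_sd_local, "local")
  if (!is.na(warm_year)) {
    sy <- ifelse(loc$month == 12L, loc$year, loc$year - 1L)
    hit <- sy == warm_year
    # winter-peaked spike with annual mean = spike (weights average to 1)
    w <- 1 + 0.5 * cos(2 * pi * ((loc$month[hit] - 1) / 12))
    loc$value[hit] <- loc$value[hit] + spike * w
  }
  list(reference = monthly_anomalies(ref, baseline),
       local = monthly_anomalies(loc, baseline),
       truth = list(warm_year = warm_year, spike = spike,
                    study_years = study_years))
}
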