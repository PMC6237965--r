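# Synthetic sensor campaigns with known ground truth.
#
# The generator encodes the mechanisms the analysis assumes rather than a
# physical energy balance: air temperature is seasonal + diurnal sinusoids
# with AR(1) weather; the snowpack is a Bernoulli-day / Gamma-amount
# accumulation with degree-day melt; soil temperature couples to air
# temperature with a coupling that decays exponentially with snow depth
# (insulation) and is re-opened under shallow snow in proportion to LAI
# (tree-well effect).  A melting snowpack cannot conduct above-zero heat
# downward, so under snow the mean soil term couples to min(TA, 0).

#' Configuration for a synthetic sensor campaign
#'
#' Defaults state the emulated field conditions: a boreal site with mean
#' annual air temperature -1.1 degC, a proxy warm year that is 8 degC warmer
#' in winter (tapering to 0 in summer), snow onset delayed by 20 days and the
#' snowpack thinned to 40% (peak ~100 cm baseline vs ~40 cm warm), and sensor
#' noise at the logger calibration RMSE 0.11 degC.
#'
#' @param n_plots number of plots (>= 1)
#' @param sensors_per_plot soil-temperature sensors per plot (>= 1)
#' @param site_lai numeric vector of plot LAI values (unitless); default
#'   cycles 0.05 / 0.72 / 1.36 (open, partially forested, forested)
#' @param years named integer vector of study years; each value is the
#'   December start year (a study year runs Dec 1 .. Nov 30); series are
#'   generated from the preceding Oct 1 so the snow season is covered
#' @param warm_year name in `years` receiving the warm-year treatment
#' @param winter_ta_offset degC added to warm-year air temperature in
#'   Dec--Feb, tapering to 0 in summer
#' @param snow_onset_shift days the warm year delays the snowfall schedule
#' @param snow_depth_scale multiplier in (0, 1] thinning warm-year snowfall
#' @param noise_sd_ts,noise_sd_ta,noise_sd_rh additive hourly sensor noise SDs
#' @param ta_mean annual mean air temperature, degC
#' @param ta_annual_amplitude seasonal sinusoid amplitude, degC
#' @param ta_diurnal_amplitude diurnal sinusoid amplitude, degC
#' @param weather_ar,weather_sd AR(1) coefficient and innovation-scale SD of
#'   daily regional weather noise (stationary SD is
#'   `weather_sd / sqrt(1 - weather_ar^2)`)
#' @param plot_ta_sd SD of the constant per-plot air-temperature offset
#' @param precip_prob probability a sub-zero day receives snowfall
#' @param snow_shape,snow_scale Gamma parameters of snowfall amount (cm)
#' @param melt_rate snowpack melt, cm per positive degree-day
#' @param trace_depth cm below which the pack is flushed to zero at the end
#'   of a day (sub-trace cover is not snow cover)
#' @param insulation_depth e-folding snow depth (cm) of the mean soil-air
#'   coupling
#' @param diurnal_efold e-folding snow depth (cm) of the diurnal damping:
#'   even a few cm of snow kills the diurnal wave at the soil surface
#' @param soil_gain gain of snow-free mean soil coupling to smoothed TA
#' @param soil_diurnal_gain gain of snow-free diurnal soil wave relative to
#'   the air diurnal deviation
#' @param soil_lag_days e-folding memory (days) of the soil's smoothing of
#'   daily mean TA
#' @param treewell_gain increase of under-snow coupling per unit LAI when
#'   the pack is shallower than `treewell_depth`
#' @param treewell_depth cm below which the tree-well term is active
#' @param rh_mean,rh_ar,rh_sd hourly bounded-AR(1) parameters for RH (%)
#' @param rh_melt_boost percent added to RH on melt days (snow present,
#'   TA > 0)
#' @param seed integer master seed; all internal streams derive from it
#' @return a `campaign_config` list
#' @export
campaign_config <- function(n_plots = 5L, sensors_per_plot = 9L,
                            site_lai = NULL,
                            years = c(baseline = 2013L, warm = 2015L),
                            warm_year = "warm",
                            winter_ta_offset = 8, snow_onset_shift = 20L,
                            snow_depth_scale = 0.4,
                            noise_sd_ts = 0.11, noise_sd_ta = 0.3,
                            noise_sd_rh = 2,
                            ta_mean = -1.1, ta_annual_amplitude = 14,
                            ta_diurnal_amplitude = 4,
                            weather_ar = 0.8, weather_sd = 1.5,
                            plot_ta_sd = 0.3,
                            precip_prob = 0.15,
                            snow_shape = 4, snow_scale = 1.25,
                            melt_rate = 1.5, trace_depth = 1.5,
                            insulation_depth = 10, diurnal_efold = 0.8,
                            soil_gain = 0.9, soil_diurnal_gain = 0.6,
                            soil_lag_days = 2,
                            treewell_gain = 1.5, treewell_depth = 15,
                            rh_mean = 70, rh_ar = 0.9, rh_sd = 2,
                            rh_melt_boost = 7,
                            seed = 1L) {
  if (n_plots < 1L) stop("n_plots must be >= 1")
  if (sensors_per_plot < 1L) stop("sensors_per_plot must be >= 1")
  if (!(snow_depth_scale > 0 && snow_depth_scale <= 1))
    stop("snow_depth_scale must lie in (0, 1]")
  if (min(noise_sd_ts, noise_sd_ta, noise_sd_rh, weather_sd, plot_ta_sd) < 0)
    stop("noise SDs must be >= 0")
  if (is.null(site_lai))
    site_lai <- rep(c(0.05, 0.72, 1.36), length.out = n_plots)
  if (length(site_lai) != n_plots) stop("site_lai must have one value per plot")
  if (is.null(names(years)) || any(names(years) == ""))
    stop("years must be a named vector of December start years")
  if (!warm_year %in% names(years)) stop("warm_year not among years")
  structure(as.list(environment()), class = "campaign_config")
}

check_plot_year <- function(config, plot, year) {
  if (!(is.numeric(plot) && plot >= 1 && plot <= config$n_plots))
    stop("unknown plot: ", plot)
  if (!year %in% names(config$years)) stop("unknown year label: ", year)
}

# span generated for a study year: Oct 1 of the December year .. Nov 30 next
year_span <- function(config, year) {
  y0 <- config$years[[year]]
  list(from = as.Date(sprintf("%d-10-01", y0)),
       to = as.Date(sprintf("%d-11-30", y0 + 1L)))
}

# warm-offset taper by calendar month: 1 in DJF falling linearly to 0 in JJA
warm_taper <- function(month) {
  w <- c(1, 1, 2 / 3, 1 / 3, 1 / 6, 0, 0, 0, 1 / 6, 1 / 3, 2 / 3, 1)
  w[month]
}

#' Simulate hourly air temperature for one plot and study year
#'
#' Seasonal + diurnal sinusoids, daily AR(1) regional weather shared by all
#' plots of a year, a constant per-plot offset, and hourly sensor noise.  The
#' warm year adds `winter_ta_offset` degC in Dec--Feb, tapering to zero in
#' summer.  Deterministic given `config$seed`.
#'
#' @param config a [campaign_config()]
#' @param plot plot index in `1..n_plots`
#' @param year name of a study year in `config$years`
#' @return a [sensor_series()] with variable `"TA"`
#' @export
simulate_air_temperature <- function(config, plot, year) {
  check_plot_year(config, plot, year)
  span <- year_span(config, year)
  days <- date_seq(span$from, span$to)
  hours <- hour_seq(span$from, span$to)
  lt <- as.POSIXlt(hours, tz = "UTC")
  doy <- lt$yday + 1L
  month <- lt$mon + 1L
  hod <- lt$hour
  seasonal <- config$ta_mean -
    config$ta_annual_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  diurnal <- -config$ta_diurnal_amplitude * cos(2 * pi * (hod - 14) / 24)
  offset <- if (identical(year, config$warm_year))
    config$winter_ta_offset * warm_taper(month) else 0
  weather <- with_seed(seed_stream(config$seed, "weather", year), {
    n <- length(days)
    w <- numeric(n)
    innov <- rnorm(n, 0, config$weather_sd)
    w[1] <- innov[1] / sqrt(max(1 - config$weather_ar^2, 1e-12))
    for (i in seq_len(n - 1L)) w[i + 1L] <- config$weather_ar * w[i] + innov[i + 1L]
    w
  })
  plot_off <- with_seed(seed_stream(config$seed, "plot_ta", plot, year),
                        rnorm(1, 0, config$plot_ta_sd))
  meas <- with_seed(seed_stream(config$seed, "ta_noise", plot, year),
                    rnorm(length(hours), 0, config$noise_sd_ta))
  day_idx <- floor(as.numeric(hours) / 86400) - as.numeric(days[1]) + 1L
  value <- seasonal + diurnal + offset + weather[day_idx] + plot_off + meas
  sensor_series(plot, "TA1", "TA", hours, pmin(pmax(value, -60), 60))
}

#' Simulate the daily snowpack for one plot and study year
#'
#' Snowfall occurs on stochastic sub-zero days (Bernoulli day, Gamma amount);
#' melt is degree-day when daily TA > 0.  In the warm year the whole snowfall
#' schedule is shifted `snow_onset_shift` days later and amounts are scaled
#' by `snow_depth_scale`; melt is unchanged.  Packs thinner than
#' `trace_depth` at the end of a day are flushed to zero.
#'
#' @param ta_daily data.frame with columns `date`, `ta` (daily mean air
#'   temperature, degC) covering at least Oct--May, with no gap > 7 days
#' @param config a [campaign_config()]
#' @param year study-year name (controls warm treatment and the snowfall
#'   random stream)
#' @return data.frame with columns `date`, `depth` (cm, >= 0)
#' @export
simulate_snowpack <- function(ta_daily, config, year) {
  if (!year %in% names(config$years)) stop("unknown year label: ", year)
  stopifnot(is.data.frame(ta_daily), all(c("date", "ta") %in% names(ta_daily)))
  dates <- as.Date(ta_daily$date)
  if (any(diff(as.numeric(dates)) > 7)) stop("gap > 7 days in TA series")
  y0 <- config$years[[year]]
  need <- c(as.Date(sprintf("%d-10-15", y0)), as.Date(sprintf("%d-05-15", y0 + 1L)))
  if (min(dates) > need[1] || max(dates) < need[2])
    stop("TA series must cover Oct--May of the study year")
  n <- length(dates)
  warm <- identical(year, config$warm_year)
  sf <- with_seed(seed_stream(config$seed, "precip", year), {
    eligible <- ta_daily$ta < 0
    ev <- rbinom(n, 1L, config$precip_prob) == 1L & eligible
    amt <- rgamma(n, shape = config$snow_shape, scale = config$snow_scale)
    ifelse(ev, amt, 0)
  })
  if (warm) {
    shift <- as.integer(config$snow_onset_shift)
    sf <- c(numeric(shift), sf)[seq_len(n)] * config$snow_depth_scale
  }
  depth <- numeric(n)
  d <- 0
  for (i in seq_len(n)) {
    d <- d + sf[i]
    if (ta_daily$ta[i] > 0) d <- d - config$melt_rate * ta_daily$ta[i]
    if (d < config$trace_depth) d <- 0
    depth[i] <- d
  }
  data.frame(date = dates, depth = depth)
}

#' Simulate hourly soil temperature for one sensor
#'
#' Snow-free, the soil tracks an exponentially smoothed daily-mean TA with
#' gain `soil_gain` plus a damped diurnal wave.  Under snow, the mean term
#' couples to `min(smoothed TA, 0)` with coupling `exp(-depth /
#' insulation_depth)`, inflated by `1 + treewell_gain * lai` when the pack is
#' shallower than `treewell_depth` (capped at 1), and the diurnal wave is
#' damped by `exp(-depth / diurnal_efold)`.  Additive N(0, `noise_sd_ts`)
#' sensor noise.
#'
#' @param ta_hourly a TA [sensor_series()] for the plot
#' @param snow_depth data.frame (`date`, `depth` cm) spanning the TA dates
#' @param lai plot leaf area index (unitless, >= 0)
#' @param config a [campaign_config()]
#' @param sensor_id sensor label (also selects the noise stream)
#' @param year study-year name used for the noise stream
#' @return a [sensor_series()] with variable `"TS"`
#' @export
simulate_soil_temperature <- function(ta_hourly, snow_depth, lai, config,
                                      sensor_id = "TS1", year = "y") {
  stopifnot(inherits(ta_hourly, "sensor_series"), ta_hourly$variable == "TA")
  if (any(snow_depth$depth < 0)) stop("negative snow depth")
  dates <- series_dates(ta_hourly)
  udays <- sort(unique(dates))
  if (!all(udays %in% as.Date(snow_depth$date)))
    stop("snow depth series does not span the TA series")
  day_idx <- match(dates, udays)
  ta_day <- as.numeric(rowsum(ta_hourly$value, day_idx) /
                         tabulate(day_idx, length(udays)))
  alpha <- 1 - exp(-1 / config$soil_lag_days)
  ema <- numeric(length(udays))
  ema[1] <- ta_day[1]
  for (i in seq_along(ema)[-1]) ema[i] <- alpha * ta_day[i] + (1 - alpha) * ema[i - 1]
  depth <- snow_depth$depth[match(udays, as.Date(snow_depth$date))]
  cmean <- exp(-depth / config$insulation_depth)
  shallow <- depth > 0 & depth < config$treewell_depth
  cmean[shallow] <- pmin(1, cmean[shallow] * (1 + config$treewell_gain * lai))
  ddamp <- exp(-depth / config$diurnal_efold)
  snow <- depth > 0
  mean_term <- ifelse(snow, cmean * pmin(ema, 0), config$soil_gain * ema)
  dgain <- ifelse(snow, config$soil_diurnal_gain * ddamp,
                  config$soil_diurnal_gain)
  dev <- ta_hourly$value - ta_day[day_idx]
  value <- mean_term[day_idx] + dgain[day_idx] * dev
  noise <- with_seed(seed_stream(config$seed, "ts_noise", ta_hourly$plot_id,
                                 year, sensor_id),
                     rnorm(length(value), 0, config$noise_sd_ts))
  sensor_series(ta_hourly$plot_id, sensor_id, "TS", ta_hourly$time,
                pmin(pmax(value + noise, -60), 60))
}

# hourly RH as bounded AR(1), elevated on melt days
simulate_rh <- function(config, plot, year, melt_dates) {
  span <- year_span(config, year)
  hours <- hour_seq(span$from, span$to)
  n <- length(hours)
  x <- with_seed(seed_stream(config$seed, "rh", plot, year), {
    innov <- rnorm(n, 0, config$rh_sd)
    meas <- rnorm(n, 0, config$noise_sd_rh)
    z <- numeric(n)
    z[1] <- innov[1] / sqrt(max(1 - config$rh_ar^2, 1e-12))
    for (i in seq_len(n - 1L)) z[i + 1L] <- config$rh_ar * z[i] + innov[i + 1L]
    z + meas
  })
  boost <- config$rh_melt_boost *
    (floor(as.numeric(hours) / 86400) %in% as.numeric(melt_dates))
  sensor_series(plot, "RH1", "RH", hours,
                pmin(pmax(config$rh_mean + x + boost, 0), 100))
}

#' Generate a full synthetic campaign with ground truth
#'
#' Produces hourly TS (per sensor), TA and RH (per plot) for every plot and
#' study year, plus a truth record per plot-year: the daily snow-depth
#' series, the boolean presence series (`depth > 0`), and the snow season
#' (start, end, duration) defined as the longest contiguous presence run
#' inside the Oct 1 -- May 31 search window.
#'
#' @param config a [campaign_config()]
#' @return a list with elements `config`, `series` (nested
#'   `series[[year]][[plot]]` with `ta`, `rh`, `ts` list), and `truth`
#'   (data.frame keyed by year/plot) plus `truth_daily` (per plot-year daily
#'   depth/presence)
#' @export
generate_campaign <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  series <- list()
  truth <- NULL
  truth_daily <- list()
  for (year in names(config$years)) {
    series[[year]] <- vector("list", config$n_plots)
    for (plot in seq_len(config$n_plots)) {
      ta <- simulate_air_temperature(config, plot, year)
      dates <- series_dates(ta)
      udays <- sort(unique(dates))
      di <- match(dates, udays)
      ta_daily <- data.frame(date = udays,
                             ta = as.numeric(rowsum(ta$value, di) /
                                               tabulate(di, length(udays))))
      pack <- simulate_snowpack(ta_daily, config, year)
      melt_dates <- pack$date[pack$depth > 0 & ta_daily$ta > 0]
      rh <- simulate_rh(config, plot, year, melt_dates)
      ts <- lapply(seq_len(config$sensors_per_plot), function(s)
        simulate_soil_temperature(ta, pack, config$site_lai[plot], config,
                                  sensor_id = paste0("TS", s), year = year))
      series[[year]][[plot]] <- list(ta = ta, rh = rh, ts = ts)
      present <- pack$depth > 0
      y0 <- config$years[[year]]
      win <- pack$date >= as.Date(sprintf("%d-10-01", y0)) &
        pack$date <= as.Date(sprintf("%d-05-31", y0 + 1L))
      run <- longest_true_run(present & win)
      rec <- data.frame(
        year = year, plot = plot,
        snow_start = if (is.null(run)) as.Date(NA) else pack$date[win][run["start"]],
        snow_end = if (is.null(run)) as.Date(NA) else pack$date[win][run["end"]],
        duration = if (is.null(run)) 0L else as.integer(run["length"]))
      truth <- rbind(truth, rec)
      truth_daily[[paste(year, plot, sep = ".")]] <-
        data.frame(year = year, plot = plot, date = pack$date,
                   depth = pack$depth, snow_present = present)
    }
  }
  list(config = config, series = series, truth = truth,
       truth_daily = truth_daily)
}

#' Write campaign sensor data as tidy CSV
#'
#' Columns: plot_id, sensor_id, variable, timestamp (ISO-8601 UTC), value.
#'
#' @param campaign result of [generate_campaign()]
#' @param path output CSV path
#' @return invisibly `path`
#' @export
write_sensor_csv <- function(campaign, path) {
  rows <- list()
  for (year in names(campaign$series)) for (pl in campaign$series[[year]]) {
    rows <- c(rows, list(as.data.frame(pl$ta), as.data.frame(pl$rh)),
              lapply(pl$ts, as.data.frame))
  }
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sensor CSV written by [write_sensor_csv()]
#'
#' @param path CSV path
#' @return list of [sensor_series()]
#' @export
read_sensor_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "sensor_id", "variable", "timestamp", "value")
  if (!all(need %in% names(df))) stop("sensor CSV missing columns")
  key <- paste(df$plot_id, df$sensor_id, df$variable, sep = "\r")
  lapply(split(df, key), function(d) {
    d <- d[order(d$timestamp), ]
    sensor_series(d$plot_id[1], d$sensor_id[1], d$variable[1],
                  as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC"),
                  d$value)
  })
}
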