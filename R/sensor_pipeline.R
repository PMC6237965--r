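# Daily summaries, snow detection, snow seasons, freeze-thaw counts and
# seasonal statistics from hourly sensor series.

#' Daily mean/min/max summaries of an hourly series
#'
#' One record per calendar day; days with fewer than `min_hours`
#' contributing observations keep their count but have NA statistics
#' (treated as "unknown" downstream).  Days absent from the series inside
#' the spanned range are included with `n_hours = 0`.
#'
#' @param series a [sensor_series()]
#' @param min_hours minimum hourly observations for a day to be summarised
#' @return data.frame with columns `date`, `mean`, `min`, `max`, `range`
#'   (daily max - min, the Delta-TS statistic), `n_hours`
#' @export
daily_summaries <- function(series, min_hours = 18L) {
  stopifnot(inherits(series, "sensor_series"))
  d <- series_dates(series)
  all_days <- date_seq(min(d), max(d))
  idx <- match(d, all_days)
  n <- tabulate(idx, nbins = length(all_days))
  mu <- rep(NA_real_, length(all_days))
  lo <- hi <- mu
  groups <- split(series$value, idx)
  at <- as.integer(names(groups))
  mu[at] <- vapply(groups, sum, numeric(1)) / n[at]
  lo[at] <- vapply(groups, min, numeric(1))
  hi[at] <- vapply(groups, max, numeric(1))
  bad <- n < min_hours
  mu[bad] <- lo[bad] <- hi[bad] <- NA_real_
  data.frame(date = all_days, mean = mu, min = lo, max = hi,
             range = hi - lo, n_hours = n)
}

#' Detect daily snow presence from the diurnal soil-temperature range
#'
#' Day d is flagged snow iff Delta-TS <= `range_max` on each of the
#' `window_days` days ending at d (the "over 48 hours" rule at the default
#' 2) and the daily maximum TS on day d is strictly below `tmax_max`.
#' Unknown days break the window and are themselves flagged unknown.
#'
#' @param daily data.frame from [daily_summaries()], sorted by date
#' @param range_max maximum daily TS range, degC (default 1)
#' @param tmax_max exclusive upper bound on daily maximum TS, degC (default 2)
#' @param window_days consecutive calendar days the range rule must hold
#' @return data.frame `date`, `flag` in `"snow"`, `"no-snow"`, `"unknown"`
#'   (sensor-scope snow-flag series)
#' @export
detect_snow_days <- function(daily, range_max = 1.0, tmax_max = 2.0,
                             window_days = 2L) {
  stopifnot(all(c("date", "range", "max") %in% names(daily)))
  if (is.unsorted(daily$date)) stop("daily summaries must be sorted by date")
  known <- !is.na(daily$range) & !is.na(daily$max)
  quiet <- known & daily$range <= range_max
  n <- nrow(daily)
  winok <- rep(TRUE, n)
  for (k in 0:(window_days - 1L)) {
    sh <- c(rep(FALSE, k), quiet[seq_len(n - k)])
    winok <- winok & sh
  }
  snow <- winok & known & daily$max < tmax_max
  flag <- ifelse(!known, "unknown", ifelse(snow, "snow", "no-snow"))
  data.frame(date = daily$date, flag = flag, stringsAsFactors = FALSE)
}

#' Plot-level snow consensus across sensors
#'
#' A day is plot-snow iff the fraction of sensors with a known flag that
#' report snow is at least `quorum` (>= 50% by default, matching the rule
#' used to compare against satellite maps).  Days with no known sensor are
#' unknown.
#'
#' @param flags list of sensor-scope snow-flag data.frames
#' @param quorum required fraction of known sensors reporting snow
#' @return plot-scope snow-flag data.frame (`date`, `flag`)
#' @export
plot_snow_consensus <- function(flags, quorum = 0.5) {
  stopifnot(length(flags) >= 1L)
  all_dates <- sort(unique(as.Date(unlist(lapply(flags, function(f)
    as.character(f$date))))))
  n_snow <- n_known <- integer(length(all_dates))
  for (f in flags) {
    i <- match(as.Date(f$date), all_dates)
    kn <- f$flag != "unknown"
    n_known[i] <- n_known[i] + kn
    n_snow[i] <- n_snow[i] + (f$flag == "snow")
  }
  flag <- ifelse(n_known == 0L, "unknown",
                 ifelse(n_snow / pmax(n_known, 1L) >= quorum,
                        "snow", "no-snow"))
  data.frame(date = all_dates, flag = flag, stringsAsFactors = FALSE)
}

#' Extract the snow season from a plot snow-flag series
#'
#' The season is the longest contiguous run of snow days inside the search
#' window (Oct 1 -- May 31 of a study year by convention); its length is the
#' snow-cover duration SCD.  No snow days yields the empty-season sentinel
#' (NA dates, duration 0).
#'
#' @param flags plot-scope snow-flag data.frame
#' @param window_start,window_end search window bounds (`Date`)
#' @return list with `snow_start`, `snow_end` (`Date` or NA) and `duration`
#'   (days)
#' @export
snow_season <- function(flags, window_start, window_end) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  d <- as.Date(flags$date)
  if (min(d) > window_start || max(d) < window_end)
    stop("flags do not cover the search window")
  sel <- d >= window_start & d <= window_end
  sub <- flags[sel, ]
  run <- longest_true_run(sub$flag == "snow")
  if (is.null(run))
    return(list(snow_start = as.Date(NA), snow_end = as.Date(NA),
                duration = 0L))
  list(snow_start = as.Date(sub$date[run["start"]]),
       snow_end = as.Date(sub$date[run["end"]]),
       duration = as.integer(run["length"]))
}

#' Count freeze-thaw events in a period
#'
#' A freeze-thaw event is operationalized as a day whose daily mean TS is
#' at or below `threshold` (default -5 degC, the level at which soil
#' microbial activity is strongly inhibited); at most one event per day, so
#' the count is the number of qualifying days.  Note this is a freeze-state
#' day count, not a freeze-to-thaw transition count.
#'
#' @param daily data.frame from [daily_summaries()]
#' @param threshold inclusive daily-mean threshold, degC
#' @param period length-2 `Date` vector (inclusive bounds); default spans
#'   the summaries
#' @return integer count of event days
#' @export
count_freeze_thaw_events <- function(daily, threshold = -5,
                                     period = range(daily$date)) {
  sel <- daily$date >= as.Date(period[1]) & daily$date <= as.Date(period[2])
  sum(!is.na(daily$mean[sel]) & daily$mean[sel] <= threshold)
}

#' Seasonal statistics from daily summaries
#'
#' Daily values are aggregated to monthly means (of the daily mean, daily
#' minimum and daily maximum), then each season's value is the unweighted
#' mean of its three monthly values.  Seasons: winter Dec--Feb, spring
#' Mar--May, summer Jun--Aug, fall Sep--Nov; December belongs to the
#' following winter, i.e. to the study year labelled by its December.
#' Seasons missing a month are emitted with `complete = FALSE`.
#'
#' @param daily data.frame from [daily_summaries()]
#' @param plot_id,sensor_id identifiers copied into the output
#' @return data.frame `plot_id`, `sensor_id`, `year_start` (December
#'   calendar year of the study year), `season`, `statistic` (`mean`,
#'   `avg_min`, `avg_max`), `value`, `complete`
#' @export
seasonal_statistics <- function(daily, plot_id = NA, sensor_id = NA) {
  ok <- !is.na(daily$mean)
  if (!any(ok)) stop("no summarised days")
  d <- daily[ok, ]
  ym <- format(d$date, "%Y-%m")
  mon <- data.frame(
    ym = sort(unique(ym)),
    mean = as.numeric(tapply(d$mean, ym, mean)),
    avg_min = as.numeric(tapply(d$min, ym, mean)),
    avg_max = as.numeric(tapply(d$max, ym, mean)))
  first <- as.Date(paste0(mon$ym, "-01"))
  mon$year_start <- study_year_start(first)
  mon$season <- season_of_month(as.integer(format(first, "%m")))
  out <- NULL
  for (key in unique(paste(mon$year_start, mon$season))) {
    sub <- mon[paste(mon$year_start, mon$season) == key, ]
    for (stat in c("mean", "avg_min", "avg_max")) {
      out <- rbind(out, data.frame(
        plot_id = plot_id, sensor_id = sensor_id,
        year_start = sub$year_start[1], season = sub$season[1],
        statistic = stat, value = mean(sub[[stat]]),
        complete = nrow(sub) == 3L, stringsAsFactors = FALSE))
    }
  }
  out[order(out$year_start, out$season, out$statistic), ]
}
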