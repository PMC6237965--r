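# SensorSeries: one logger's hourly record of one variable.

#' Construct an hourly sensor series
#'
#' @param plot_id plot identifier
#' @param sensor_id sensor identifier within the plot
#' @param variable one of `"TS"` (soil temperature, degC), `"TA"` (air
#'   temperature, degC), `"RH"` (relative humidity, %)
#' @param time `POSIXct` timestamps (UTC), strictly increasing, hourly cadence
#'   (gaps allowed)
#' @param value measurements; TS/TA must lie in \[-60, 60\], RH in \[0, 100\]
#' @return a `sensor_series` object
#' @export
sensor_series <- function(plot_id, sensor_id, variable, time, value) {
  variable <- match.arg(variable, c("TS", "TA", "RH"))
  if (length(time) == 0L) stop("empty sensor series")
  if (length(time) != length(value)) stop("time/value length mismatch")
  if (!inherits(time, "POSIXct")) stop("time must be POSIXct")
  dt <- diff(as.numeric(time))
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  fin <- is.finite(value)
  if (variable %in% c("TS", "TA")) {
    if (any(fin & (value < -60 | value > 60)))
      stop(variable, " values outside [-60, 60] degC")
  } else if (any(fin & (value < 0 | value > 100))) {
    stop("RH values outside [0, 100] %")
  }
  structure(list(plot_id = plot_id, sensor_id = sensor_id,
                 variable = variable, time = time, value = as.numeric(value)),
            class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("<sensor_series %s plot=%s sensor=%s n=%d %s..%s>\n",
              x$variable, x$plot_id, x$sensor_id, length(x$value),
              format(min(x$time)), format(max(x$time))))
  invisible(x)
}

#' @export
as.data.frame.sensor_series <- function(x, ...) {
  data.frame(plot_id = x$plot_id, sensor_id = x$sensor_id,
             variable = x$variable,
             timestamp = format(x$time, "%Y-%m-%dT%H:%M:%SZ"),
             value = x$value, stringsAsFactors = FALSE)
}

series_dates <- function(series) {
  tz <- attr(series$time, "tzone")
  if (identical(tz, "UTC"))  # fast path: pure arithmetic, no strftime
    as.Date(floor(as.numeric(series$time) / 86400), origin = "1970-01-01")
  else as.Date(format(series$time, "%Y-%m-%d"))
}
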