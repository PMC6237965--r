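test_that("daily_summaries computes mean/min/max/range and honours min_hours", {
  s <- sensor_series(1, "TS1", "TS",
                     hour_seq(as.Date("2015-01-01"), as.Date("2015-01-01")),
                     0:23)
  d <- daily_summaries(s)
  expect_equal(d$min, 0)
  expect_equal(d$max, 23)
  expect_equal(d$mean, 11.5)
  expect_equal(d$range, 23)
  expect_equal(d$n_hours, 24L)

  s2 <- sensor_series(1, "TS1", "TS",
                      hour_seq(as.Date("2015-01-01"), as.Date("2015-01-01")),
                      rep(5, 24))
  d2 <- daily_summaries(s2)
  expect_equal(c(d2$mean, d2$min, d2$max, d2$range), c(5, 5, 5, 0))

  # a day with 3 readings at min_hours 18 is unknown but keeps its count
  t3 <- as.POSIXct("2015-01-02 00:00:00", tz = "UTC") + c(0, 3600, 7200)
  s3 <- sensor_series(1, "TS1", "TS", c(s$time, t3), c(0:23, 1, 2, 3))
  d3 <- daily_summaries(s3, min_hours = 18L)
  expect_true(is.na(d3$mean[2]))
  expect_equal(d3$n_hours[2], 3L)
  expect_error(sensor_series(1, "TS1", "TS", as.POSIXct(character()),
                             numeric()), "empty")
})

test_that("detect_snow_days implements the 48-hour range + max rule", {
  d <- daily_df(mean = c(0, 0), min = c(0.5, 0.5), max = c(1, 1))
  d$range <- c(0.5, 0.5)
  expect_equal(detect_snow_days(d)$flag[2], "snow")

  d$range <- c(0.5, 1.5)          # window broken on day 2
  expect_equal(detect_snow_days(d)$flag[2], "no-snow")

  d$range <- c(0.5, 0.5)          # max exactly 2: strict "<" fails
  d$max <- c(1, 2.0)
  expect_equal(detect_snow_days(d)$flag[2], "no-snow")

  # unknown day breaks the window and is itself unknown
  d3 <- daily_df(mean = c(0, NA, 0, 0), min = 0, max = c(1, NA, 1, 1))
  d3$range <- c(0.4, NA, 0.4, 0.4)
  f <- detect_snow_days(d3)$flag
  expect_equal(f, c("no-snow", "unknown", "no-snow", "snow"))
})

test_that("detect_snow_days matches the brute-force oracle on random series", {
  set.seed(101)
  for (rep in 1:300) {
    n <- sample(5:50, 1)
    rng <- round(runif(n, 0, 3), 2)
    mx <- round(runif(n, -2, 4), 2)
    na <- runif(n) < 0.15
    rng[na] <- NA
    mx[na] <- NA
    d <- data.frame(date = as.Date("2015-01-01") + 0:(n - 1),
                    mean = mx - 1, min = mx - rng, max = mx, range = rng,
                    n_hours = 24L)
    expect_identical(detect_snow_days(d)$flag,
                     oracle_snow_days(rng, mx))
  }
})

test_that("plot consensus applies the >=50% known-sensor quorum", {
  mk <- function(n_snow, n_total) {
    lapply(seq_len(n_total), function(i)
      flags_df(if (i <= n_snow) "snow" else "no-snow"))
  }
  expect_equal(plot_snow_consensus(mk(5, 9))$flag, "snow")
  expect_equal(plot_snow_consensus(mk(4, 9))$flag, "no-snow")
  expect_equal(plot_snow_consensus(mk(4, 8))$flag, "snow")  # >=, not >
  # unknown sensors drop out of the denominator
  fl <- c(mk(1, 2), list(flags_df("unknown")))
  expect_equal(plot_snow_consensus(fl)$flag, "snow")
  expect_equal(plot_snow_consensus(list(flags_df("unknown")))$flag, "unknown")
})

test_that("plot consensus is invariant to sensor order", {
  set.seed(7)
  n <- 60L
  flags <- lapply(1:9, function(i)
    flags_df(sample(c("snow", "no-snow", "unknown"), n, replace = TRUE)))
  base <- plot_snow_consensus(flags)
  for (rep in 1:5)
    expect_identical(plot_snow_consensus(sample(flags)), base)
})

test_that("snow_season picks the longest run; brute-force cross-check", {
  runs <- c(rep("no-snow", 2), rep("snow", 3), rep("no-snow", 4),
            rep("snow", 120), "no-snow", rep("snow", 2), rep("no-snow", 3))
  fl <- flags_df(runs)
  ss <- snow_season(fl, fl$date[1], fl$date[nrow(fl)])
  orc <- oracle_season(runs == "snow")
  expect_equal(ss$snow_start, fl$date[orc$start])
  expect_equal(ss$snow_end, fl$date[orc$end])
  expect_equal(ss$duration, orc$length)

  all_sn <- flags_df(rep("snow", 10))
  s2 <- snow_season(all_sn, all_sn$date[1], all_sn$date[10])
  expect_equal(s2$snow_start, all_sn$date[1])
  expect_equal(s2$snow_end, all_sn$date[10])
  expect_equal(s2$duration, 10L)

  none <- flags_df(rep("no-snow", 10))
  s3 <- snow_season(none, none$date[1], none$date[10])
  expect_equal(s3$duration, 0L)
  expect_true(is.na(s3$snow_start))

  # randomised agreement with the enumeration oracle
  set.seed(11)
  for (rep in 1:50) {
    v <- sample(c("snow", "no-snow", "unknown"), 80, replace = TRUE,
                prob = c(0.4, 0.4, 0.2))
    fl <- flags_df(v)
    ss <- snow_season(fl, fl$date[1], fl$date[80])
    orc <- oracle_season(v == "snow")
    expect_equal(ss$duration, orc$length)
    if (orc$length > 0) expect_equal(ss$snow_start, fl$date[orc$start])
  }
})

test_that("freeze-thaw events count days at or below the threshold", {
  d <- daily_df(mean = c(-6, -5, -4.9))
  expect_equal(count_freeze_thaw_events(d), 2)          # <= is inclusive
  expect_equal(count_freeze_thaw_events(daily_df(rep(1, 30))), 0)
  expect_equal(count_freeze_thaw_events(daily_df(rep(-10, 365))), 365)
  # period subsetting
  expect_equal(count_freeze_thaw_events(d, period = c(d$date[3], d$date[3])),
               0)
})

test_that("FTE count is invariant to within-day permutation of hourly values", {
  set.seed(3)
  vals <- rnorm(24 * 30, -5, 3)
  t0 <- hour_seq(as.Date("2015-01-01"), as.Date("2015-01-30"))
  s <- sensor_series(1, "TS1", "TS", t0, vals)
  perm <- as.vector(apply(matrix(seq_along(vals), nrow = 24), 2, sample))
  s2 <- sensor_series(1, "TS1", "TS", t0, vals[perm])
  expect_equal(count_freeze_thaw_events(daily_summaries(s)),
               count_freeze_thaw_events(daily_summaries(s2)))
})

test_that("seasonal statistics average monthly values with December shifted", {
  # Dec -2, Jan -4, Feb -6 at constant daily values -> winter mean -4
  days <- date_seq("2015-12-01", "2016-02-29")
  mon <- as.integer(format(days, "%m"))
  mu <- c(`12` = -2, `1` = -4, `2` = -6)[as.character(mon)]
  d <- daily_df(mean = mu, start = "2015-12-01")
  st <- seasonal_statistics(d, 1, "TS1")
  w <- st[st$season == "winter" & st$statistic == "mean", ]
  expect_equal(nrow(w), 1L)
  expect_equal(w$year_start, 2015L)      # December year labels the winter
  expect_equal(w$value, -4)
  expect_true(w$complete)

  # constant -3 over a full winter
  d2 <- daily_df(mean = rep(-3, length(days)), start = "2015-12-01")
  w2 <- seasonal_statistics(d2)
  expect_equal(w2$value[w2$season == "winter" & w2$statistic == "mean"], -3)

  # missing January -> incomplete
  keep <- mon != 1L
  d3 <- d[keep, ]
  st3 <- seasonal_statistics(d3, 1, "TS1")
  expect_false(any(st3$complete[st3$season == "winter"]))
})
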