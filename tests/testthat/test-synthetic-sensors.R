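test_that("air temperature degenerates to the annual mean and is seeded", {
  cfg <- tiny_config(ta_annual_amplitude = 0, ta_diurnal_amplitude = 0,
                     weather_sd = 0, plot_ta_sd = 0, winter_ta_offset = 0)
  ta <- simulate_air_temperature(cfg, 1, "baseline")
  expect_true(all(abs(ta$value - cfg$ta_mean) < 1e-12))

  cfg2 <- tiny_config()
  a <- simulate_air_temperature(cfg2, 1, "baseline")
  b <- simulate_air_temperature(cfg2, 1, "baseline")
  expect_identical(a$value, b$value)
  c2 <- simulate_air_temperature(cfg2, 2, "baseline")
  expect_false(identical(a$value, c2$value))
  expect_error(simulate_air_temperature(cfg2, 99, "baseline"), "plot")
  expect_error(simulate_air_temperature(cfg2, 1, "nope"), "year")
})

test_that("warm-minus-baseline DJF air temperature recovers the offset", {
  # Monte-Carlo mean over replicate campaigns; weather/noise average out
  diffs <- vapply(1:100, function(s) {
    cfg <- campaign_config(n_plots = 1L, sensors_per_plot = 1L,
                           noise_sd_ta = 1, winter_ta_offset = 8,
                           seed = 1000L + s)
    djf <- function(y) {
      ta <- simulate_air_temperature(cfg, 1, y)
      m <- as.integer(format(ta$time, "%m"))
      yy <- as.integer(format(ta$time, "%Y"))
      sel <- (m == 12L & yy == cfg$years[[y]]) |
        (m %in% 1:2 & yy == cfg$years[[y]] + 1L)
      mean(ta$value[sel])
    }
    djf("warm") - djf("baseline")
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 8), 0.5)
})

test_that("snowpack accumulates only below freezing and scales linearly", {
  cfg <- tiny_config()
  days <- date_seq("2013-10-01", "2014-11-30")
  warm_ta <- data.frame(date = days, ta = rep(10, length(days)))
  expect_true(all(simulate_snowpack(warm_ta, cfg, "baseline")$depth == 0))

  # fixed sub-zero schedule, no melt: depth_scale scales the pack exactly
  # (the warm-year span is Oct 2015 -- Nov 2016)
  wdays <- date_seq("2015-10-01", "2016-11-30")
  cold_ta <- data.frame(date = wdays, ta = rep(-5, length(wdays)))
  cfg_full <- tiny_config(snow_depth_scale = 1, snow_onset_shift = 0L)
  cfg_thin <- tiny_config(snow_depth_scale = 0.4, snow_onset_shift = 0L)
  p1 <- simulate_snowpack(cold_ta, cfg_full, "warm")
  p2 <- simulate_snowpack(cold_ta, cfg_thin, "warm")
  expect_equal(max(p2$depth), 0.4 * max(p1$depth), tolerance = 1e-12)

  # onset shift moves the first snow day by exactly the shift
  cfg_sh <- tiny_config(snow_depth_scale = 1, snow_onset_shift = 20L)
  p3 <- simulate_snowpack(cold_ta, cfg_sh, "warm")
  expect_equal(which(p3$depth > 0)[1], which(p1$depth > 0)[1] + 20L)

  gap <- warm_ta[-(20:40), ]
  expect_error(simulate_snowpack(gap, cfg, "baseline"), "gap")
})

test_that("soil temperature is pinned and quiet under deep snow", {
  cfg <- tiny_config()
  ta <- simulate_air_temperature(cfg, 1, "baseline")
  dates <- sort(unique(as.Date(format(ta$time, "%Y-%m-%d"))))
  deep <- data.frame(date = dates, depth = 100)
  ts <- simulate_soil_temperature(ta, deep, 0.05, cfg)
  d <- daily_summaries(ts)
  expect_true(all(d$range < 1))
  expect_true(all(abs(d$mean) < 2))
  expect_error(simulate_soil_temperature(ta, transform(deep, depth = -1),
                                         0.05, cfg), "negative")
})

test_that("snow-free soil tracks damped lagged air temperature", {
  cfg <- campaign_config(n_plots = 1L, sensors_per_plot = 1L,
                         noise_sd_ts = 0, noise_sd_ta = 0, seed = 5L)
  ta <- simulate_air_temperature(cfg, 1, "baseline")
  dates <- sort(unique(as.Date(format(ta$time, "%Y-%m-%d"))))
  ts <- simulate_soil_temperature(ta, data.frame(date = dates, depth = 0),
                                  0.05, cfg)
  dts <- daily_summaries(ts)
  dta <- daily_summaries(ta)
  n <- nrow(dts)
  expect_gt(cor(dts$mean[2:n], dta$mean[1:(n - 1)]), 0.95)
})

test_that("tree-well effect: higher LAI under thin snow gives colder soil", {
  cfg <- tiny_config(ta_mean = -10, ta_annual_amplitude = 0,
                     weather_sd = 0, plot_ta_sd = 0, winter_ta_offset = 0)
  ta <- simulate_air_temperature(cfg, 1, "baseline")
  dates <- sort(unique(as.Date(format(ta$time, "%Y-%m-%d"))))
  thin <- data.frame(date = dates, depth = 10)
  forested <- simulate_soil_temperature(ta, thin, 1.36, cfg)
  open <- simulate_soil_temperature(ta, thin, 0.05, cfg)
  df <- daily_summaries(forested)
  do <- daily_summaries(open)
  expect_lt(mean(df$mean), mean(do$mean))
  expect_gt(count_freeze_thaw_events(df), count_freeze_thaw_events(do))
})

test_that("generate_campaign is deterministic and truth-consistent", {
  cfg <- tiny_config()
  a <- generate_campaign(cfg)
  b <- generate_campaign(cfg)
  expect_identical(a$series$baseline[[1]]$ts[[1]]$value,
                   b$series$baseline[[1]]$ts[[1]]$value)
  expect_identical(a$truth, b$truth)
  for (td in a$truth_daily)
    expect_identical(td$snow_present, td$depth > 0)
  # truth season bounds presence runs
  for (i in seq_len(nrow(a$truth))) {
    r <- a$truth[i, ]
    td <- a$truth_daily[[paste(r$year, r$plot, sep = ".")]]
    expect_true(all(td$snow_present[td$date >= r$snow_start &
                                      td$date <= r$snow_end]))
  }
})

test_that("warmer winters shorten the generated snow season", {
  dur <- vapply(c(0, 12), function(off) {
    mean(vapply(1:5, function(s) {
      cfg <- campaign_config(n_plots = 1L, sensors_per_plot = 1L,
                             winter_ta_offset = off, snow_onset_shift = 0L,
                             snow_depth_scale = 1, seed = 500L + s)
      camp <- generate_campaign(cfg)
      mean(camp$truth$duration[camp$truth$year == "warm"])
    }, numeric(1)))
  }, numeric(1))
  expect_lt(dur[2], dur[1])
})

test_that("RH is bounded and elevated on melt days", {
  cfg <- tiny_config(noise_sd_rh = 2)
  camp <- generate_campaign(cfg)
  rh <- camp$series$baseline[[1]]$rh
  expect_true(all(rh$value >= 0 & rh$value <= 100))
  td <- camp$truth_daily[["baseline.1"]]
  ta <- camp$series$baseline[[1]]$ta
  ta_day <- tapply(ta$value, as.Date(format(ta$time, "%Y-%m-%d")), mean)
  melt <- td$date[td$snow_present & ta_day[as.character(td$date)] > 0]
  dr <- daily_summaries(rh)
  if (length(melt) >= 5) {
    other <- !dr$date %in% melt
    expect_gt(mean(dr$mean[dr$date %in% melt]) - mean(dr$mean[other]), 2)
  }
})

test_that("sensor CSV round-trips", {
  cfg <- campaign_config(n_plots = 1L, sensors_per_plot = 2L, seed = 9L,
                         years = c(baseline = 2013L, warm = 2015L))
  camp <- generate_campaign(cfg)
  f <- tempfile(fileext = ".csv")
  write_sensor_csv(camp, f)
  back <- read_sensor_csv(f)
  orig <- camp$series$baseline[[1]]$ts[[1]]
  key <- vapply(back, function(s)
    s$variable == "TS" && s$sensor_id == "TS1" &&
      as.Date(format(s$time[1], "%Y-%m-%d")) == as.Date("2013-10-01"),
    logical(1))
  got <- back[[which(key)[1]]]
  m <- match(format(orig$time), format(got$time))
  expect_equal(got$value[m], orig$value, tolerance = 1e-9)
  unlink(f)
})
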