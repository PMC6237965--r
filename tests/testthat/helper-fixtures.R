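# Small in-code fixtures shared across tests.

# scene with every band constant at the given reflectances (unscaled)
flat_scene <- function(date, refl = c(green = 0.3, red = 0.3, nir = 0.3,
                                      swir2 = 0.3),
                       n = 6L, tier = "fine", cellsize = 30, qa = NULL) {
  geom <- scene_geometry(n, n, cellsize)
  bands <- lapply(refl[c("green", "red", "nir", "swir2")], function(v)
    matrix(as.integer(round(v * 10000)), n, n))
  names(bands) <- c("green", "red", "nir", "swir2")
  raster_scene(as.Date(date), tier, geom, bands, qa)
}

# scene from one matrix of scaled values replicated across bands
matrix_scene <- function(date, m, tier = "fine", cellsize = 30, qa = NULL) {
  geom <- scene_geometry(nrow(m), ncol(m), cellsize)
  storage.mode(m) <- "integer"
  raster_scene(as.Date(date), tier, geom,
               list(green = m, red = m, nir = m, swir2 = m), qa)
}

# random scaled-reflectance scene with optional nodata/QA holes
random_scene <- function(date, n, seed, sd = 800, mean = 3000,
                         p_nodata = 0, p_qa_bad = 0, cellsize = 30) {
  set.seed(seed)
  geom <- scene_geometry(n, n, cellsize)
  bands <- lapply(1:4, function(b) {
    m <- matrix(as.integer(pmin(pmax(round(rnorm(n * n, mean, sd)), 0),
                                10000)), n, n)
    m[matrix(runif(n * n) < p_nodata, n, n)] <- -9999L
    m
  })
  names(bands) <- c("green", "red", "nir", "swir2")
  qa <- matrix(runif(n * n) >= p_qa_bad, n, n)
  raster_scene(as.Date(date), "fine", geom, bands, qa)
}

# hourly series with one value per hour over a run of days
hourly_series <- function(values_by_day, start = "2015-01-01", plot = 1,
                          sensor = "TS1", variable = "TS") {
  n_days <- length(values_by_day)
  times <- hour_seq(as.Date(start), as.Date(start) + n_days - 1L)
  sensor_series(plot, sensor, variable, times,
                rep(unlist(values_by_day), each = if (is.list(values_by_day))
                  1L else 24L)[seq_along(times)])
}

# daily-summary data.frame straight from vectors
daily_df <- function(mean, min = mean, max = mean, start = "2015-01-01",
                     n_hours = 24L) {
  data.frame(date = as.Date(start) + seq_along(mean) - 1L,
             mean = mean, min = min, max = max, range = max - min,
             n_hours = n_hours)
}

flags_df <- function(flags, start = "2015-01-01") {
  data.frame(date = as.Date(start) + seq_along(flags) - 1L, flag = flags,
             stringsAsFactors = FALSE)
}

# seasonal-statistic draws for contrast-recovery simulations: nested
# plot/sensor random effects plus an injected year effect
sim_contrast_data <- function(seed, effect, n_plots = 5L, n_sensors = 9L,
                              plot_sd = 0.3, sensor_sd = 0.2,
                              noise_sd = 0.3) {
  set.seed(seed)
  site <- rep(c("open", "partially forested", "forested"),
              length.out = n_plots)
  pe <- rnorm(n_plots, 0, plot_sd)
  rows <- list()
  for (p in seq_len(n_plots)) for (s in seq_len(n_sensors)) {
    se <- rnorm(1, 0, sensor_sd)
    for (yr in c("baseline", "warm")) {
      val <- -1 + pe[p] + se + (yr == "warm") * effect +
        rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        plot = p, sensor = paste0("TS", s), year = yr, site = site[p],
        value = val)
    }
  }
  d <- do.call(rbind, rows)
  d$year <- factor(d$year, levels = c("baseline", "warm"))
  d
}

# small fast campaign configuration; ... overrides the quiet defaults
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_plots = 2L, sensors_per_plot = 2L, noise_sd_ts = 0,
         noise_sd_ta = 0, noise_sd_rh = 0, seed = 42L),
    list(...))
  do.call(campaign_config, args)
}
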