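# End-to-end experiment: simulate -> sensors -> proxy -> fuse -> snowmap ->
# compare, with a single structured report.

#' Pipeline configuration
#'
#' @param campaign a [campaign_config()]
#' @param stages character subset of `c("sensors", "proxy", "satellite",
#'   "compare")`; the sensor stage is always run
#' @param min_hours,quorum,fte_threshold sensor-stage parameters (see
#'   [daily_summaries()], [plot_snow_consensus()],
#'   [count_freeze_thaw_events()])
#' @param n_fine,ratio,noise_sd,cloud_fraction scene-generator parameters
#'   (see [generate_scene_series()])
#' @param fusion a [fusion_params()]
#' @param ndsi_warm,ndsi_baseline period NDSI thresholds (published values
#'   0.30 / 0.35)
#' @param anomaly list of overrides passed to [generate_anomaly_records()]
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(campaign = campaign_config(),
                            stages = c("sensors", "proxy", "satellite",
                                       "compare"),
                            min_hours = 18L, quorum = 0.5,
                            fte_threshold = -5,
                            n_fine = 60L, ratio = 10L, noise_sd = 50,
                            cloud_fraction = 0.05,
                            fusion = fusion_params(),
                            ndsi_warm = 0.30, ndsi_baseline = 0.35,
                            anomaly = list()) {
  stopifnot(inherits(campaign, "campaign_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

season_window <- function(config, year) {
  y0 <- config$years[[year]]
  c(as.Date(sprintf("%d-10-01", y0)), as.Date(sprintf("%d-05-31", y0 + 1L)))
}

study_window <- function(config, year) {
  y0 <- config$years[[year]]
  c(as.Date(sprintf("%d-12-01", y0)), as.Date(sprintf("%d-11-30", y0 + 1L)))
}

# sensor-side products for a generated campaign
sensor_stage <- function(campaign, min_hours = 18L, quorum = 0.5,
                         fte_threshold = -5) {
  cfg <- campaign$config
  flags <- list()
  seasons <- NULL
  fte <- NULL
  stats <- NULL
  for (year in names(cfg$years)) {
    flags[[year]] <- vector("list", cfg$n_plots)
    win <- season_window(cfg, year)
    per <- study_window(cfg, year)
    for (plot in seq_len(cfg$n_plots)) {
      pl <- campaign$series[[year]][[plot]]
      dailies <- lapply(pl$ts, daily_summaries, min_hours = min_hours)
      sflags <- lapply(dailies, detect_snow_days)
      cons <- plot_snow_consensus(sflags, quorum = quorum)
      flags[[year]][[plot]] <- cons
      ss <- snow_season(cons, win[1], win[2])
      seasons <- rbind(seasons, data.frame(
        year = year, plot = plot, snow_start = ss$snow_start,
        snow_end = ss$snow_end, duration = ss$duration))
      cnt <- vapply(dailies, count_freeze_thaw_events,
                    numeric(1), threshold = fte_threshold, period = per)
      fte <- rbind(fte, data.frame(year = year, plot = plot,
                                   mean_fte = mean(cnt),
                                   sd_fte = sd(cnt)))
      for (s in seq_along(dailies)) {
        st <- seasonal_statistics(dailies[[s]], plot_id = plot,
                                  sensor_id = paste0("TS", s))
        st$year <- names(cfg$years)[match(st$year_start, cfg$years)]
        stats <- rbind(stats, st[!is.na(st$year), ])
      }
    }
  }
  list(flags = flags, seasons = seasons, fte = fte, seasonal_stats = stats)
}

# satellite-side products: scene generation, fusion, snow maps, plot flags
satellite_stage <- function(campaign, n_fine = 60L, ratio = 10L,
                            noise_sd = 50, cloud_fraction = 0.05,
                            fusion = fusion_params(),
                            ndsi_warm = 0.30, ndsi_baseline = 0.35,
                            quorum = 0.5) {
  cfg <- campaign$config
  out <- list()
  for (year in names(cfg$years)) {
    win <- season_window(cfg, year)
    dates <- date_seq(win[1], win[2])
    td <- campaign$truth_daily[[paste(year, 1, sep = ".")]]
    snow_days <- td$date[td$snow_present]
    scenes <- generate_scene_series(
      dates, snow_days = snow_days, n_fine = n_fine, ratio = ratio,
      noise_sd = noise_sd, cloud_fraction = cloud_fraction,
      seed = seed_stream(cfg$seed, "scenes", year))
    preds <- starfm_predict_series(scenes$fine, scenes$coarse,
                                   params = fusion)
    thr <- if (identical(year, cfg$warm_year)) ndsi_warm else ndsi_baseline
    maps <- list()
    for (key in names(scenes$coarse)) {
      sc <- scenes$fine[[key]] %||% preds[[key]]
      if (is.null(sc)) next
      maps[[key]] <- classify_snow(compute_ndsi(sc), compute_ndvi(sc), thr)
    }
    geom <- scenes$geom
    plots <- lapply(seq_len(cfg$n_plots), function(p) {
      j <- round(n_fine * p / (cfg$n_plots + 1))
      plot_geometry(p,
                    geom$origin_x + (j - 0.5) * geom$cellsize,
                    geom$origin_y - (j - 0.5) * geom$cellsize)
    })
    per_plot <- lapply(plots, function(pg)
      plot_snow_from_maps(maps, pg, pixel_quorum = quorum, window = win))
    out[[year]] <- list(scenes = scenes, predictions = preds, maps = maps,
                        plots = per_plot)
  }
  out
}

#' Run the full synthetic experiment pipeline
#'
#' Simulates a campaign, derives sensor products (daily flags, snow
#' seasons, freeze-thaw counts, seasonal statistics), selects proxy years
#' from synthetic anomaly records, optionally generates and fuses scene
#' series into daily snow maps, and compares: winter soil-temperature
#' year-by-site contrasts, SCD and FTE tables, and the sensor-satellite
#' agreement matrix.  Deterministic given the campaign seed.
#'
#' @param config a [pipeline_config()]
#' @return a report list (tables + fitted objects); see vignette
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$campaign
  campaign <- tryCatch(generate_campaign(cfg),
                       error = function(e) stop("stage simulate: ",
                                                conditionMessage(e)))
  sens <- tryCatch(sensor_stage(campaign, config$min_hours, config$quorum,
                                config$fte_threshold),
                   error = function(e) stop("stage sensors: ",
                                            conditionMessage(e)))
  report <- list(config = config, truth = campaign$truth,
                 seasons = sens$seasons, fte = sens$fte,
                 seasonal_stats = sens$seasonal_stats)

  sites <- classify_sites_by_lai(stats::setNames(cfg$site_lai,
                                                 seq_len(cfg$n_plots)),
                                 seed = cfg$seed)
  report$site_classes <- sites

  if ("proxy" %in% config$stages) {
    anargs <- utils::modifyList(
      list(seed = seed_stream(cfg$seed, "anomaly"),
           warm_year = cfg$years[[cfg$warm_year]],
           study_years = sort(unname(cfg$years))), config$anomaly)
    rec <- do.call(generate_anomaly_records, anargs)
    report$proxy <- tryCatch(
      classify_proxy_years(rec$local, rec$reference,
                           candidate_years = anargs$study_years),
      error = function(e) stop("stage proxy: ", conditionMessage(e)))
    report$proxy$truth <- rec$truth
  }

  sat <- NULL
  if ("satellite" %in% config$stages) {
    sat <- tryCatch(
      satellite_stage(campaign, config$n_fine, config$ratio,
                      config$noise_sd, config$cloud_fraction, config$fusion,
                      config$ndsi_warm, config$ndsi_baseline, config$quorum),
      error = function(e) stop("stage satellite: ", conditionMessage(e)))
    scd_s <- NULL
    for (year in names(sat)) for (p in seq_along(sat[[year]]$plots)) {
      s <- sat[[year]]$plots[[p]]$season
      scd_s <- rbind(scd_s, data.frame(
        year = year, plot = p, snow_start = s$snow_start,
        snow_end = s$snow_end, duration = s$duration))
    }
    report$scd_satellite <- scd_s
  }

  if ("compare" %in% config$stages) {
    plot_class <- sites$classes[as.character(seq_len(cfg$n_plots))]
    wstats <- sens$seasonal_stats
    wstats <- wstats[wstats$season == "winter" & wstats$statistic == "mean" &
                       wstats$complete, ]
    labels <- names(cfg$years)
    base_label <- setdiff(labels, cfg$warm_year)[1]
    d <- data.frame(plot = wstats$plot_id, sensor = wstats$sensor_id,
                    year = factor(wstats$year,
                                  levels = c(base_label, cfg$warm_year)),
                    site = plot_class[as.character(wstats$plot_id)],
                    value = wstats$value)
    report$winter_ts_contrast <- tryCatch(
      fit_year_site_contrast(d),
      error = function(e) stop("stage compare: ", conditionMessage(e)))

    fte <- merge(sens$fte,
                 data.frame(plot = seq_len(cfg$n_plots), site = plot_class))
    agg <- aggregate(mean_fte ~ year + site, fte, mean)
    wide <- stats::reshape(agg, idvar = "site", timevar = "year",
                           direction = "wide")
    bcol <- paste0("mean_fte.", base_label)
    wcol <- paste0("mean_fte.", cfg$warm_year)
    wide$pct_change <- ifelse(wide[[bcol]] > 0,
                              (wide[[wcol]] - wide[[bcol]]) /
                                wide[[bcol]] * 100, NA_real_)
    report$fte_by_site <- wide

    if (!is.null(sat)) {
      pooled <- matrix(0, 2, 2,
                       dimnames = list(c("snow", "no-snow"),
                                       c("snow", "no-snow")))
      per_year <- NULL
      for (year in names(sat)) {
        ytab <- matrix(0, 2, 2)
        for (p in seq_len(cfg$n_plots)) {
          ag <- snow_agreement(sens$flags[[year]][[p]],
                               sat[[year]]$plots[[p]]$flags)
          pooled <- pooled + ag$matrix
          ytab <- ytab + ag$matrix
        }
        per_year <- rbind(per_year, data.frame(
          year = year, accuracy = sum(diag(ytab)) / sum(ytab),
          n = sum(ytab)))
      }
      report$agreement <- list(matrix = pooled,
                               accuracy = sum(diag(pooled)) / sum(pooled),
                               per_year = per_year)
    }
  }
  report
}

#' Write pipeline report tables to disk
#'
#' Emits a JSON summary plus one CSV per table.
#'
#' @param report result of [run_pipeline()]
#' @param dir output directory (created if needed)
#' @return invisibly the JSON path
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(seasons = report$seasons, fte = report$fte,
               seasonal_stats = report$seasonal_stats,
               truth = report$truth,
               scd_satellite = report$scd_satellite,
               fte_by_site = report$fte_by_site)
  for (nm in names(tabs)) if (!is.null(tabs[[nm]]))
    write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  summary <- list(
    seed = report$config$campaign$seed,
    site_classes = as.list(report$site_classes$classes),
    site_centers = report$site_classes$centers,
    proxy = if (!is.null(report$proxy))
      list(baseline_year = report$proxy$baseline_year,
           warm_year = report$proxy$warm_year, notes = report$proxy$notes),
    winter_ts_contrast = if (!is.null(report$winter_ts_contrast))
      report$winter_ts_contrast$contrasts,
    agreement = if (!is.null(report$agreement))
      list(accuracy = report$agreement$accuracy,
           matrix = report$agreement$matrix,
           per_year = report$agreement$per_year))
  path <- file.path(dir, "report.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
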