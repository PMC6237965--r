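# Site classification from LAI, year x site mixed-model contrasts, and
# sensor-vs-satellite snow agreement.

#' Classify plots into site classes by LAI k-means
#'
#' k-means (k = 3, multiple restarts, seeded) on plot LAI values; cluster
#' centers are ordered ascending and labelled open, partially forested,
#' forested.
#'
#' @param lai named numeric vector, plot -> LAI
#' @param k number of clusters (default 3)
#' @param seed RNG seed for the restarts
#' @return list with `classes` (named character vector per plot),
#'   `centers` (ascending)
#' @export
classify_sites_by_lai <- function(lai, k = 3L, seed = 1L) {
  if (length(lai) < k) stop("need at least ", k, " plots")
  if (length(unique(lai)) < k)
    stop("degenerate clusters: fewer than ", k, " distinct LAI values")
  labels <- c("open", "partially forested", "forested")
  if (k != 3L) labels <- paste0("class", seq_len(k))
  if (length(lai) == k) {
    # every plot is its own cluster; stats::kmeans requires k < n
    km <- list(centers = matrix(lai, ncol = 1),
               cluster = seq_along(lai))
  } else {
    km <- with_seed(seed, kmeans(matrix(lai, ncol = 1), centers = k,
                                 nstart = 25L))
  }
  ord <- order(km$centers)
  rank_of <- match(km$cluster, ord)
  classes <- stats::setNames(labels[rank_of],
                             names(lai) %||% seq_along(lai))
  list(classes = classes, centers = as.numeric(km$centers[ord]))
}

#' Year-by-site contrast with nested random effects
#'
#' Fits `value ~ year * site` by REML with random intercepts for sensors
#' nested in plots (`~1 | plot/sensor`), the design for replicated loggers.
#' Reports per-site warm-minus-baseline differences (the second year level
#' minus the first) with Wald t tests on the model's inner-stratum
#' denominator degrees of freedom.  If residuals fail a Shapiro test at
#' alpha = 0.01 and the response is positive, the response is
#' log-transformed (`log_transform = "auto"`); with a single plot the
#' random structure degenerates and the model falls back to a sensor-only
#' random intercept, flagged in the result.
#'
#' @param data data.frame with columns `plot`, `sensor`, `year` (2-level
#'   factor or character; first level = baseline), `site`, `value`
#' @param log_transform `"auto"`, `TRUE` or `FALSE`
#' @return list: `model` (nlme fit), `transform`, `contrasts` (per-site
#'   estimate/se/df/t/p), `fixed` (fixed-effect table), `ranef_sd`,
#'   `fallback_single_plot`
#' @export
fit_year_site_contrast <- function(data, log_transform = "auto") {
  need <- c("plot", "sensor", "year", "site", "value")
  if (!all(need %in% names(data))) stop("data must have columns: ",
                                        paste(need, collapse = ", "))
  d <- data.frame(plot = factor(data$plot), sensor = factor(paste(data$plot,
                  data$sensor, sep = ":")), year = factor(data$year),
                  site = factor(data$site), value = as.numeric(data$value))
  if (nlevels(d$year) != 2L) stop("exactly two year levels required")
  if (any(!stats::complete.cases(d))) d <- d[stats::complete.cases(d), ]
  single_plot <- nlevels(d$plot) == 1L
  one_site <- nlevels(d$site) == 1L
  # degenerate design: every sensor shows the same year difference (e.g. two
  # identical years) -> REML is singular; report the common difference exactly
  yr1 <- levels(d$year)[1]
  dif <- merge(d[d$year != yr1, c("sensor", "site", "value")],
               d[d$year == yr1, c("sensor", "value")], by = "sensor")
  if (nrow(dif) && var(dif$value.x - dif$value.y) == 0) {
    delta <- dif$value.x - dif$value.y
    contrasts <- do.call(rbind, lapply(levels(d$site), function(s)
      data.frame(site = s, estimate = mean(delta[dif$site == s]), se = 0,
                 df = NA_real_, t = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE)))
    return(list(model = NULL, transform = "identity", contrasts = contrasts,
                fixed = NULL, ranef_sd = NULL,
                fallback_single_plot = single_plot, degenerate = TRUE))
  }
  form <- if (one_site) value ~ year else value ~ year * site
  fit_once <- function(dd) {
    if (single_plot)
      nlme::lme(form, random = ~ 1 | sensor, data = dd, method = "REML")
    else
      nlme::lme(form, random = ~ 1 | plot / sensor, data = dd,
                method = "REML")
  }
  fit <- fit_once(d)
  transform <- "identity"
  if (isTRUE(log_transform) ||
      (identical(log_transform, "auto") &&
       tryCatch(shapiro.test(stats::resid(fit))$p.value, error = function(e) 1) < 0.01 &&
       all(d$value > 0))) {
    if (all(d$value > 0)) {
      d$value <- log(d$value)
      fit <- fit_once(d)
      transform <- "log"
    }
  }
  beta <- nlme::fixef(fit)
  V <- stats::vcov(fit)
  sites <- levels(d$site)
  yr2 <- levels(d$year)[2]
  df_year <- fit$fixDF$X[[grep("^year", names(beta))[1]]]
  contrasts <- do.call(rbind, lapply(sites, function(s) {
    L <- stats::setNames(numeric(length(beta)), names(beta))
    L[grep("^year", names(L), value = TRUE)[1]] <- 1
    inter <- paste0("year", yr2, ":site", s)
    if (inter %in% names(L)) L[inter] <- 1
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tval <- est / se
    data.frame(site = s, estimate = est, se = se, df = df_year, t = tval,
               p = 2 * pt(-abs(tval), df_year), stringsAsFactors = FALSE)
  }))
  vc <- nlme::VarCorr(fit)
  sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
  list(model = fit, transform = transform, contrasts = contrasts,
       fixed = data.frame(term = names(beta), estimate = unname(beta)),
       ranef_sd = stats::setNames(sds, rownames(vc)),
       fallback_single_plot = single_plot, degenerate = FALSE)
}

#' Agreement between sensor- and satellite-derived snow flags
#'
#' Builds the 2x2 confusion matrix over plot-days where both series have a
#' known flag (reference = sensor SCD_ST flags, predicted = satellite
#' SCD_S flags); overall accuracy is the trace over the total.  Days
#' unknown in either series are excluded and counted.
#'
#' @param reference,predicted plot-scope snow-flag data.frames
#' @return list: `matrix` (2x2 counts, reference rows), `accuracy`, `n`,
#'   `excluded`
#' @export
snow_agreement <- function(reference, predicted) {
  m <- merge(reference, predicted, by = "date", suffixes = c("_ref", "_pred"))
  if (!nrow(m)) stop("no overlapping dates")
  known <- m$flag_ref != "unknown" & m$flag_pred != "unknown"
  excluded <- sum(!known)
  m <- m[known, ]
  if (!nrow(m)) stop("no jointly known plot-days")
  lev <- c("snow", "no-snow")
  tab <- table(factor(m$flag_ref, lev), factor(m$flag_pred, lev))
  list(matrix = unclass(tab), accuracy = sum(diag(tab)) / sum(tab),
       n = sum(tab), excluded = excluded)
}
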