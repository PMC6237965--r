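# Temperature anomalies, hemispheric trend fitting, and robust selection of
# proxy baseline / warm years.

#' Monthly anomalies against a baseline climatology
#'
#' anomaly(y, m) = value(y, m) - mean(value(., m)) over the baseline window,
#' the convention of the 1961--1990 hemispheric anomaly products.
#'
#' @param series data.frame with columns `year`, `month`, `value` (degC)
#' @param baseline inclusive year window of the climatology (default
#'   `c(1961, 1990)`)
#' @return data.frame `year`, `month`, `anomaly`
#' @export
monthly_anomalies <- function(series, baseline = c(1961, 1990)) {
  stopifnot(all(c("year", "month", "value") %in% names(series)))
  base <- series[series$year >= baseline[1] & series$year <= baseline[2], ]
  missing <- setdiff(1:12, unique(base$month))
  if (length(missing))
    stop("baseline window has no observations for month(s): ",
         paste(month.abb[missing], collapse = ", "))
  clim <- tapply(base$value, base$month, mean)
  data.frame(year = series$year, month = series$month,
             anomaly = series$value - as.numeric(clim[as.character(series$month)]))
}

#' Fit a polynomial trend to annual anomalies
#'
#' Ordinary least-squares polynomial of degree `degree` (default 2, a smooth
#' accelerating curve), with fitted values and pointwise standard errors.
#'
#' @param annual data.frame with columns `year`, `anomaly`
#' @param degree polynomial degree
#' @return list with `coefficients`, `fitted`, `se` (pointwise), `model`
#' @export
fit_anomaly_trend <- function(annual, degree = 2L) {
  stopifnot(all(c("year", "anomaly") %in% names(annual)))
  if (nrow(annual) < degree + 2L) stop("need at least degree + 2 annual points")
  if (length(unique(annual$year)) <= degree)
    stop("rank-deficient design: too few distinct years")
  fit <- lm(anomaly ~ poly(year, degree, raw = TRUE), data = annual)
  pr <- predict(fit, se.fit = TRUE)
  list(coefficients = unname(coef(fit)), fitted = as.numeric(pr$fit),
       se = as.numeric(pr$se.fit), model = fit)
}

#' Yuen's trimmed-means two-sample test
#'
#' Welch-type test on trimmed means with winsorized variances; the standard
#' robust location comparison (default 20% trim).
#'
#' @param x,y numeric samples
#' @param trim per-tail trimming fraction
#' @return list `estimate` (trimmed mean difference x - y), `t`, `df`, `p`
#'   (two-sided)
#' @export
yuen_test <- function(x, y, trim = 0.2) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  g1 <- floor(trim * n1); g2 <- floor(trim * n2)
  h1 <- n1 - 2 * g1; h2 <- n2 - 2 * g2
  if (h1 < 2 || h2 < 2) stop("samples too small for trimmed test")
  winsor_var <- function(v, g) {
    s <- sort(v)
    if (g > 0L) {
      s[seq_len(g)] <- s[g + 1L]
      s[(length(s) - g + 1L):length(s)] <- s[length(s) - g]
    }
    var(s)
  }
  m1 <- mean(x, trim = trim); m2 <- mean(y, trim = trim)
  d1 <- (n1 - 1) * winsor_var(x, g1) / (h1 * (h1 - 1))
  d2 <- (n2 - 1) * winsor_var(y, g2) / (h2 * (h2 - 1))
  tstat <- (m1 - m2) / sqrt(d1 + d2)
  df <- (d1 + d2)^2 / (d1^2 / (h1 - 1) + d2^2 / (h2 - 1))
  list(estimate = m1 - m2, t = tstat, df = df,
       p = 2 * pt(-abs(tstat), df))
}

study_year_table <- function(anom) {
  data.frame(anom,
             study_year = ifelse(anom$month == 12L, anom$year, anom$year - 1L))
}

#' Select proxy baseline and warm years from anomalies
#'
#' Candidate study years (December--November, labelled by their December
#' calendar year) with a full 12 months of local anomalies are compared to
#' the reference anomaly distribution over the same span with Yuen's
#' trimmed test.  The candidate with the lowest annual mean anomaly that
#' does not differ significantly from the reference (alpha) becomes the
#' baseline; the candidate with the highest annual mean that is
#' significantly above the reference becomes the warm year.  Because the
#' warm candidate is the maximum of k candidates, its declaration threshold
#' is Bonferroni-adjusted to alpha / k, which keeps the family-wise type-I
#' rate at alpha.  Roles that no candidate satisfies are reported as NA
#' with an explanatory note -- never a silent fallback.
#'
#' @param local data.frame `year`, `month`, `anomaly` for the study area
#' @param reference data.frame `year`, `month`, `anomaly` (hemispheric)
#' @param candidate_years December start years of the candidate study years
#'   (e.g. the field-campaign span); default: every complete study year in
#'   `local`
#' @param alpha significance level
#' @param trim trimming fraction for [yuen_test()]
#' @return list with `baseline_year`, `warm_year` (December start years or
#'   NA), `candidates` (per-year annual mean/sd, seasonal means, p-values),
#'   `alpha`, `notes`
#' @export
classify_proxy_years <- function(local, reference, candidate_years = NULL,
                                 alpha = 0.05, trim = 0.2) {
  loc <- study_year_table(local)
  cnt <- table(loc$study_year)
  cand_years <- as.integer(names(cnt)[cnt == 12L])
  if (!is.null(candidate_years)) {
    missing <- setdiff(candidate_years, cand_years)
    if (length(missing))
      stop("candidate study years without 12 local months: ",
           paste(missing, collapse = ", "))
    cand_years <- as.integer(candidate_years)
  }
  if (length(cand_years) < 2L) stop("need at least 2 complete candidate study years")
  ref <- study_year_table(reference)
  ref_sample <- ref$anomaly[ref$study_year %in% cand_years]
  if (length(ref_sample) < 12L) ref_sample <- ref$anomaly
  seasons <- season_of_month(1:12)
  rows <- lapply(cand_years, function(y) {
    v <- loc[loc$study_year == y, ]
    v <- v[order((v$month - 12) %% 12), ]
    ytest <- yuen_test(v$anomaly, ref_sample, trim = trim)
    se <- stats::setNames(tapply(v$anomaly, season_of_month(v$month), mean),
                          NULL)
    sn <- sort(unique(season_of_month(v$month)))
    out <- data.frame(study_year = y, annual_mean = mean(v$anomaly),
                      annual_sd = sd(v$anomaly), estimate = ytest$estimate,
                      p = ytest$p)
    for (i in seq_along(sn)) out[[paste0(sn[i], "_mean")]] <- se[i]
    out
  })
  tab <- do.call(rbind, rows)
  k <- nrow(tab)
  notes <- character()
  i_lo <- which.min(tab$annual_mean)
  baseline <- NA_integer_
  if (tab$p[i_lo] >= alpha) baseline <- tab$study_year[i_lo]
  else notes <- c(notes, "no baseline: lowest-anomaly year differs significantly from reference")
  i_hi <- which.max(tab$annual_mean)
  warm <- NA_integer_
  # one-sided (greater) test for the warm role, Bonferroni-adjusted over the
  # k candidates the maximum was selected from
  p_one <- if (tab$estimate[i_hi] > 0) tab$p[i_hi] / 2 else
    1 - tab$p[i_hi] / 2
  if (p_one < alpha / k) warm <- tab$study_year[i_hi]
  else notes <- c(notes, "no warm year: highest-anomaly year not significantly above reference")
  if (!is.na(baseline) && !is.na(warm) && baseline == warm) {
    warm <- NA_integer_
    notes <- c(notes, "no warm year: coincides with baseline")
  }
  list(baseline_year = baseline, warm_year = warm, candidates = tab,
       alpha = alpha, notes = notes)
}
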