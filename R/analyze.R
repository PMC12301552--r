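#' Full reference-interval analysis of one measurand series
#'
#' Runs the complete per-series pipeline:
#' \enumerate{
#'   \item iterative outlier screening ([iterative_screen()]; Horn for
#'     current n > 30, Dixon otherwise, repeated until clean);
#'   \item descriptive statistics on the retained values;
#'   \item Shapiro-Wilk normality assessment, only when the post-screening
#'     n is in the full band (n >= 40);
#'   \item method selection on the post-screening n ([select_method()]);
#'   \item reference limits by the selected method;
#'   \item percentile-bootstrap 90% CIs of both limits -- computed only for
#'     the parametric and nonparametric-percentile methods (min-max and
#'     descriptive-only rows report no CI);
#'   \item CI/RI width ratios with imprecision flags (ratio > 0.2).
#' }
#' Degenerate inputs never error: a constant series (e.g. an analyte below
#' the detection limit reported as all zeros) short-circuits to descriptive
#' statistics with no limits, and an empty series yields an all-absent
#' result.
#'
#' @param series A [measurand_series()] or bare numeric vector.
#' @param policy An [ri_policy()].
#' @param seed Bootstrap stream seed; by default derived from
#'   `policy$rng_seed` and the series' measurand/partition labels, so a
#'   study re-run is reproducible measurand by measurand.
#' @return A `reference_interval_result` with fields `measurand`, `unit`,
#'   `partition`, `screen` (the audit trail), `descriptive`, `normality`,
#'   `method`, `lower_limit`/`upper_limit`, `lrl_ci`/`url_ci`,
#'   `lrl_ratio`/`url_ratio`, `imprecise_lower`/`imprecise_upper`,
#'   `distribution_label` (`"G"`, `"NG"` or `NA`).
#' @examples
#' set.seed(7)
#' res <- analyze_measurand(rnorm(86, 10, 2))
#' res$method
#' c(res$lower_limit, res$upper_limit)
#' @export
analyze_measurand <- function(series, policy = ri_policy(), seed = NULL) {
  if (!inherits(series, "measurand_series")) {
    series <- measurand_series("value", "", "All", series)
  }
  if (is.null(seed)) {
    seed <- derive_seed(policy$rng_seed,
                        paste(series$measurand, series$partition, sep = "|"))
  }

  res <- list(measurand = series$measurand, unit = series$unit,
              partition = series$partition, screen = NULL,
              descriptive = NULL, normality = NULL, method = "no_report",
              lower_limit = NA_real_, upper_limit = NA_real_,
              lrl_ci = NULL, url_ci = NULL,
              lrl_ratio = NA_real_, url_ratio = NA_real_,
              imprecise_lower = NA, imprecise_upper = NA,
              distribution_label = NA_character_)
  class(res) <- "reference_interval_result"

  if (length(series$values) == 0) return(res)

  screen <- iterative_screen(series, policy)
  x <- screen$retained
  res$screen <- screen
  if (length(x) == 0) return(res)
  res$descriptive <- descriptive_stats(x)

  # constant series (e.g. all values at the detection floor): descriptives
  # only, mirroring the dash-only rows of below-limit analytes
  if (length(x) >= 2 && stats::var(x) == 0) {
    res$method <- "no_report"
    return(res)
  }

  n <- length(x)
  gaussian <- NA
  if (n >= policy$band_full[1]) {
    res$normality <- assess_normality(x, policy)
    gaussian <- res$normality$gaussian
    if (!is.na(gaussian)) {
      res$distribution_label <- if (gaussian) "G" else "NG"
    }
  }
  method <- select_method(n, gaussian, policy)
  res$method <- method

  if (method %in% c("descriptive_only", "no_report")) return(res)

  estimator <- switch(method,
    parametric = function(v) parametric_ri(v, policy),
    nonparametric = function(v) nonparametric_percentile_ri(v, policy),
    minmax = minmax_ri)
  limits <- estimator(x)
  res$lower_limit <- unname(limits[1])
  res$upper_limit <- unname(limits[2])

  if (method %in% c("parametric", "nonparametric")) {
    ci <- bootstrap_limit_ci(x, estimator, policy, seed = seed)
    res$lrl_ci <- ci$lower
    res$url_ci <- ci$upper
    ri <- c(res$lower_limit, res$upper_limit)
    if (diff(ri) > 0) {
      res$lrl_ratio <- ci_ri_ratio(ci$lower, ri)
      res$url_ratio <- ci_ri_ratio(ci$upper, ri)
      res$imprecise_lower <- res$lrl_ratio > policy$ci_ratio_flag_threshold
      res$imprecise_upper <- res$url_ratio > policy$ci_ratio_flag_threshold
    }
  }
  res
}

#' @export
print.reference_interval_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else formatC(v, digits = 4, format = "g")
  cat(sprintf("<reference_interval_result> %s (%s), partition %s\n",
              x$measurand, x$unit, x$partition))
  if (!is.null(x$descriptive)) {
    cat("  ")
    print(x$descriptive)
  }
  if (!is.null(x$screen) && nrow(x$screen$removed) > 0) {
    cat(sprintf("  outliers removed: %d over %d iteration(s)\n",
                nrow(x$screen$removed), x$screen$iterations))
  }
  cat(sprintf("  method: %s%s\n", x$method,
              if (!is.na(x$distribution_label)) {
                paste0(" (distribution ", x$distribution_label, ")")
              } else ""))
  if (!is.na(x$lower_limit)) {
    cat(sprintf("  RI: %s - %s\n", fmt(x$lower_limit), fmt(x$upper_limit)))
  }
  if (!is.null(x$lrl_ci)) {
    cat(sprintf("  LRL 90%% CI: %s - %s (CI/RI %.3f%s)\n",
                fmt(x$lrl_ci[1]), fmt(x$lrl_ci[2]), x$lrl_ratio,
                if (isTRUE(x$imprecise_lower)) ", imprecise" else ""))
    cat(sprintf("  URL 90%% CI: %s - %s (CI/RI %.3f%s)\n",
                fmt(x$url_ci[1]), fmt(x$url_ci[2]), x$url_ratio,
                if (isTRUE(x$imprecise_upper)) ", imprecise" else ""))
  }
  invisible(x)
}
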