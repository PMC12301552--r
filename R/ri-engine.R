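#' Shapiro-Wilk normality assessment with a strict gate
#'
#' Runs the Shapiro-Wilk test and classifies the sample as Gaussian only
#' when the p-value *strictly* exceeds `policy$normality_alpha`
#' (default 0.2 -- a deliberately conservative gate, so borderline samples
#' are routed to the nonparametric method; p exactly at the cut-off counts
#' as non-Gaussian).  Constant or too-short/too-long samples are not
#' assessable and return `NA` fields.
#'
#' @param values Numeric vector; assessable for 3 <= n <= 5000 and
#'   non-constant input.
#' @param policy An [ri_policy()].
#' @return A `normality_assessment` list: `w_stat`, `p_value`, `gaussian`
#'   (all `NA` when not assessable).
#' @export
assess_normality <- function(values, policy = ri_policy()) {
  n <- length(values)
  not_assessable <- structure(
    list(w_stat = NA_real_, p_value = NA_real_, gaussian = NA),
    class = "normality_assessment")
  if (n < 3 || n > 5000 || stats::var(values) == 0) {
    return(not_assessable)
  }
  sw <- stats::shapiro.test(values)
  structure(list(w_stat = unname(sw$statistic),
                 p_value = sw$p.value,
                 gaussian = sw$p.value > policy$normality_alpha),
            class = "normality_assessment")
}

#' @export
print.normality_assessment <- function(x, ...) {
  if (is.na(x$gaussian)) {
    cat("<normality> not assessable\n")
  } else {
    cat(sprintf("<normality> W = %.4f, p = %.4g -> %s\n", x$w_stat, x$p_value,
                if (x$gaussian) "Gaussian (G)" else "non-Gaussian (NG)"))
  }
  invisible(x)
}

#' Sample-size-banded method selection
#'
#' Routes a sample to an estimation method from its (post-screening) size
#' and, in the full band, its Gaussianity:
#' \describe{
#'   \item{`n >= 40`}{`"parametric"` when the Shapiro-Wilk gate passes,
#'     else `"nonparametric"` (2.5/97.5 percentile limits).  The band is
#'     open-ended upward: nothing changes for larger samples.}
#'   \item{`20 <= n < 40`}{`"minmax"` -- percentile limits are unreliable
#'     here, so the RI is the observed minimum and maximum.}
#'   \item{`10 <= n < 20`}{`"descriptive_only"` -- descriptive statistics
#'     are reported but no RI.}
#'   \item{`n < 10`}{`"no_report"`.}
#' }
#' Band edges are half-open and configurable via the policy.
#'
#' @param n Sample size (after outlier screening).
#' @param gaussian `TRUE`/`FALSE`/`NA` from [assess_normality()]; only used
#'   in the full band, where `NA` (not assessable) falls back to the
#'   nonparametric method.
#' @param policy An [ri_policy()].
#' @return One of `"parametric"`, `"nonparametric"`, `"minmax"`,
#'   `"descriptive_only"`, `"no_report"`.
#' @examples
#' select_method(86, gaussian = FALSE)  # "nonparametric"
#' select_method(86, gaussian = TRUE)   # "parametric"
#' select_method(28, gaussian = NA)     # "minmax"
#' select_method(17, gaussian = NA)     # "descriptive_only"
#' @export
select_method <- function(n, gaussian = NA, policy = ri_policy()) {
  stopifnot(n >= 0)
  in_band <- function(b) n >= b[1] && n < b[2]
  if (in_band(policy$band_full)) {
    if (isTRUE(gaussian)) "parametric" else "nonparametric"
  } else if (in_band(policy$band_minmax)) {
    "minmax"
  } else if (in_band(policy$band_descriptive_only)) {
    "descriptive_only"
  } else {
    "no_report"
  }
}

#' Parametric (Gaussian) reference limits
#'
#' Central 95% limits under a Gaussian model: `mean +/- z * sd` with
#' `z = qnorm(0.975) = 1.959964` by default.  Computed at full precision;
#' rounding is a display concern.
#'
#' @param values Numeric vector, length >= 2.
#' @param policy An [ri_policy()].
#' @return Named numeric vector `c(lower, upper)`.  A constant sample gives
#'   a zero-width (degenerate) interval with a warning.
#' @examples
#' x <- scale(rnorm(50))[, 1] * 10.82 + 48.17  # sample with exact mean/sd
#' round(parametric_ri(x), 2)                  # 26.96, 69.38
#' @export
parametric_ri <- function(values, policy = ri_policy()) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) warning("constant input: degenerate zero-width interval")
  c(lower = m - policy$z_multiplier * s, upper = m + policy$z_multiplier * s)
}

# Rank-interpolated percentile. "n_plus_1": value at rank p*(n+1)
# (CLSI-style, = quantile type 6); "n_minus_1": rank 1 + p*(n-1) (type 7).
# Ranks are clamped to [1, n], so limits never leave [min, max].
rank_percentile <- function(sorted, p, convention) {
  n <- length(sorted)
  h <- if (convention == "n_plus_1") p * (n + 1) else 1 + p * (n - 1)
  h <- min(max(h, 1), n)
  lo <- floor(h)
  hi <- ceiling(h)
  sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo])
}

#' Nonparametric percentile reference limits
#'
#' Distribution-free limits at the 2.5th and 97.5th sample percentiles,
#' interpolated between order statistics at rank `p * (n + 1)` (clamped to
#' `[1, n]`).  This is the CLSI-style convention (quantile type 6); the
#' `1 + p * (n - 1)` convention (type 7) is available through the policy.
#' Recommended for n >= 40; callable on smaller samples.
#'
#' @param values Numeric vector, length >= 1.
#' @param policy An [ri_policy()].
#' @return Named numeric vector `c(lower, upper)`, always inside
#'   `[min(values), max(values)]`.
#' @examples
#' nonparametric_percentile_ri(1:39)  # ranks 1 and 39 exactly -> c(1, 39)
#' @export
nonparametric_percentile_ri <- function(values, policy = ri_policy()) {
  stopifnot(length(values) >= 1)
  s <- sort(values)
  c(lower = rank_percentile(s, policy$lower_p, policy$percentile_convention),
    upper = rank_percentile(s, policy$upper_p, policy$percentile_convention))
}

#' Min-max reference limits for small samples
#'
#' For 20 <= n < 40 the extreme percentiles cannot be estimated, so the RI
#' is reported as the observed sample minimum and maximum, exactly.
#'
#' @param values Numeric vector, length >= 2.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
minmax_ri <- function(values) {
  if (length(values) < 2) {
    stop("min-max limits need at least 2 values", call. = FALSE)
  }
  c(lower = min(values), upper = max(values))
}

# Deterministic 31-bit stream id from the global seed and a string label,
# so each (measurand, partition) gets its own reproducible bootstrap stream.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Percentile-bootstrap confidence intervals of the reference limits
#'
#' Draws `B` resamples with replacement, recomputes both reference limits on
#' each, and reports the central `ci_level` (default 90%) percentile
#' interval of each limit's bootstrap distribution.  Deterministic for a
#' fixed seed; the RNG state of the caller is left untouched.
#'
#' @param values Numeric vector, the screened sample.
#' @param limit_estimator Function `values -> c(lower, upper)`, one of
#'   [parametric_ri()] or [nonparametric_percentile_ri()] (possibly
#'   policy-curried).
#' @param policy An [ri_policy()] (supplies `bootstrap_B`, `ci_level`).
#' @param seed Integer seed for the bootstrap stream (default derived from
#'   `policy$rng_seed`).
#' @return List with `lower` and `upper`, each a named `c(low, high)` 90%
#'   interval.
#' @export
bootstrap_limit_ci <- function(values, limit_estimator, policy = ri_policy(),
                               seed = policy$rng_seed) {
  n <- length(values)
  stopifnot(n >= 2)
  B <- policy$bootstrap_B
  alpha <- 1 - policy$ci_level
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  if (stats::var(values) == 0) {
    lim <- c(values[1], values[1])
    return(list(lower = c(low = lim[1], high = lim[1]),
                upper = c(low = lim[2], high = lim[2])))
  }
  boots <- matrix(NA_real_, nrow = B, ncol = 2)
  for (b in seq_len(B)) {
    boots[b, ] <- limit_estimator(values[sample.int(n, n, replace = TRUE)])
  }
  probs <- c(alpha / 2, 1 - alpha / 2)
  lo_ci <- stats::quantile(boots[, 1], probs, names = FALSE, type = 7)
  hi_ci <- stats::quantile(boots[, 2], probs, names = FALSE, type = 7)
  list(lower = c(low = lo_ci[1], high = lo_ci[2]),
       upper = c(low = hi_ci[1], high = hi_ci[2]))
}

#' CI width to RI width ratio
#'
#' Precision diagnostic of a reference limit: the width of its confidence
#' interval divided by the width of the reference interval.  Ratios above
#' `policy$ci_ratio_flag_threshold` (default 0.2) mark the limit as
#' imprecise.  Ratios above 1 are permitted (and flagged).
#'
#' @param ci Numeric length-2 interval (the limit's CI).
#' @param ri Numeric length-2 interval (the reference interval); must have
#'   positive width.
#' @return The ratio (a scalar).
#' @examples
#' ci_ri_ratio(c(7.9, 9.43), c(8.62, 16.78))  # ~0.1875
#' @export
ci_ri_ratio <- function(ci, ri) {
  stopifnot(length(ci) == 2, length(ri) == 2)
  ri_width <- ri[2] - ri[1]
  if (ri_width <= 0) {
    stop("zero-width reference interval: CI/RI ratio undefined", call. = FALSE)
  }
  unname((ci[2] - ci[1]) / ri_width)
}

#' Between-partition location comparison
#'
#' Two-sided two-sample test of a location difference between partitions
#' (e.g. males vs females).  Defaults to the Wilcoxon rank-sum test because
#' most panel measurands are non-Gaussian; Welch's t-test is available via
#' the policy.
#'
#' @param a,b Numeric vectors, each length >= 3.
#' @param policy An [ri_policy()].
#' @return A `partition_comparison` list: `statistic`, `p_value`,
#'   `significant` (at `policy$partition_test_alpha`).  Degenerate inputs
#'   (too short, or both constant at the same value) return `NA` fields.
#' @export
compare_partitions <- function(a, b, policy = ri_policy()) {
  degenerate <- structure(list(statistic = NA_real_, p_value = NA_real_,
                               significant = NA),
                          class = "partition_comparison")
  if (length(a) < 3 || length(b) < 3) return(degenerate)
  if (stats::var(c(a, b)) == 0) return(degenerate)
  ht <- if (policy$partition_test == "ranksum") {
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  } else {
    stats::t.test(a, b)
  }
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 significant = ht$p.value < policy$partition_test_alpha),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  if (is.na(x$p_value)) {
    cat("<partition_comparison> not assessable\n")
  } else {
    cat(sprintf("<partition_comparison> statistic %.4g, p = %.4g%s\n",
                x$statistic, x$p_value,
                if (isTRUE(x$significant)) " (significant)" else ""))
  }
  invisible(x)
}
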