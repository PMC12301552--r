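#' Method policy: every tunable decision of the RI workflow
#'
#' A `ri_policy` bundles the statistical conventions used throughout the
#' pipeline: the Shapiro-Wilk gate, the sample-size bands that route a series
#' to the parametric, nonparametric-percentile, min-max or descriptive-only
#' branch, the outlier-screen settings, the bootstrap settings and the
#' quantile conventions.  Defaults follow common ASVCP/CLSI-style reference
#' interval practice for moderately sized reference populations.
#'
#' @param normality_alpha Gaussianity is accepted only when the Shapiro-Wilk
#'   p-value strictly exceeds this cut-off.  Default `0.2`: deliberately more
#'   conservative than 0.05 so that a parametric RI is only used when the data
#'   look convincingly Gaussian.
#' @param partition_test_alpha Significance level for the between-partition
#'   location test (default `0.05`).
#' @param z_multiplier Multiplier of the SD in the parametric limits
#'   `mean +/- z * sd`.  Default `qnorm(0.975)` = 1.959964 (central 95%
#'   reference interval), not the rounded 1.96.
#' @param lower_p,upper_p Reference-limit probabilities (default 0.025 and
#'   0.975, i.e. a central 95% interval).
#' @param band_full Inclusive `[lo, hi)` half-open count band routed to the
#'   full parametric/nonparametric machinery; the upper edge is `Inf` because
#'   nothing changes for larger reference samples.  Default `c(40, Inf)`.
#' @param band_minmax Count band `[lo, hi)` whose RI is the sample min-max
#'   (default `c(20, 40)`): in this range the 2.5/97.5 percentiles cannot be
#'   estimated reliably.
#' @param band_descriptive_only Count band `[lo, hi)` for which descriptive
#'   statistics are reported but no RI (default `c(10, 20)`).
#' @param horn_min_n Horn's method is used when the *current* n of the
#'   screening loop is at least this value (default 31, i.e. n > 30);
#'   otherwise Dixon's test.
#' @param fence_k Tukey fence multiplier on the transformed scale
#'   (default 1.5).
#' @param dixon_ratio_threshold Gap/range rejection threshold of the Dixon
#'   screen (default 1/3).
#' @param dixon_variant `"ratio"` (default) uses the fixed gap-to-range
#'   threshold; `"critical"` uses the classical two-sided 5% critical-value
#'   table of Dixon's r statistics instead.
#' @param boxcox_search Closed interval searched for the Box-Cox exponent
#'   (default `c(-3, 3)`).
#' @param quartile_type Quantile type (in the sense of [stats::quantile()])
#'   used for the Tukey fences (default 7, linear interpolation at rank
#'   `1 + p*(n-1)`).
#' @param percentile_convention Rank convention of the nonparametric
#'   reference limits: `"n_plus_1"` (default; value at rank `p*(n+1)`,
#'   CLSI-style, equals quantile type 6) or `"n_minus_1"` (rank
#'   `1 + p*(n-1)`, quantile type 7).
#' @param bootstrap_B Number of bootstrap resamples (default 2000,
#'   minimum 200).
#' @param ci_level Confidence level of the reference-limit CIs
#'   (default 0.90).
#' @param ci_ratio_flag_threshold A reference limit is flagged imprecise when
#'   the width of its CI exceeds this fraction of the RI width (default 0.2).
#' @param partition_test `"ranksum"` (default, Wilcoxon) or `"welch"` for the
#'   between-partition comparison.
#' @param rng_seed Integer seed from which per-measurand bootstrap streams
#'   are derived.
#'
#' @return An object of class `ri_policy` (a validated named list).
#' @examples
#' pol <- ri_policy()
#' pol$z_multiplier
#' ri_policy(bootstrap_B = 500, rng_seed = 42)
#' @export
ri_policy <- function(normality_alpha = 0.2,
                      partition_test_alpha = 0.05,
                      z_multiplier = stats::qnorm(0.975),
                      lower_p = 0.025,
                      upper_p = 0.975,
                      band_full = c(40, Inf),
                      band_minmax = c(20, 40),
                      band_descriptive_only = c(10, 20),
                      horn_min_n = 31,
                      fence_k = 1.5,
                      dixon_ratio_threshold = 1 / 3,
                      dixon_variant = c("ratio", "critical"),
                      boxcox_search = c(-3, 3),
                      quartile_type = 7,
                      percentile_convention = c("n_plus_1", "n_minus_1"),
                      bootstrap_B = 2000,
                      ci_level = 0.90,
                      ci_ratio_flag_threshold = 0.2,
                      partition_test = c("ranksum", "welch"),
                      rng_seed = 20210601L) {
  policy <- list(
    normality_alpha = normality_alpha,
    partition_test_alpha = partition_test_alpha,
    z_multiplier = z_multiplier,
    lower_p = lower_p,
    upper_p = upper_p,
    band_full = band_full,
    band_minmax = band_minmax,
    band_descriptive_only = band_descriptive_only,
    horn_min_n = horn_min_n,
    fence_k = fence_k,
    dixon_ratio_threshold = dixon_ratio_threshold,
    dixon_variant = match.arg(dixon_variant),
    boxcox_search = boxcox_search,
    quartile_type = quartile_type,
    percentile_convention = match.arg(percentile_convention),
    bootstrap_B = bootstrap_B,
    ci_level = ci_level,
    ci_ratio_flag_threshold = ci_ratio_flag_threshold,
    partition_test = match.arg(partition_test),
    rng_seed = as.integer(rng_seed)
  )
  class(policy) <- "ri_policy"
  validate_policy(policy)
}

validate_policy <- function(policy) {
  stopifnot(
    inherits(policy, "ri_policy"),
    policy$normality_alpha > 0, policy$normality_alpha < 1,
    policy$partition_test_alpha > 0, policy$partition_test_alpha < 1,
    policy$z_multiplier > 0,
    policy$lower_p > 0, policy$lower_p < policy$upper_p, policy$upper_p < 1,
    length(policy$band_full) == 2L,
    length(policy$band_minmax) == 2L,
    length(policy$band_descriptive_only) == 2L,
    policy$fence_k > 0,
    policy$dixon_ratio_threshold > 0, policy$dixon_ratio_threshold < 1,
    length(policy$boxcox_search) == 2L,
    policy$boxcox_search[1] < policy$boxcox_search[2],
    policy$quartile_type %in% 1:9,
    policy$bootstrap_B >= 200,
    policy$ci_level > 0, policy$ci_level < 1,
    policy$ci_ratio_flag_threshold > 0
  )
  # bands must be disjoint and ordered: descriptive-only < minmax < full
  b1 <- policy$band_descriptive_only
  b2 <- policy$band_minmax
  b3 <- policy$band_full
  if (!(b1[1] < b1[2] && b1[2] <= b2[1] && b2[1] < b2[2] &&
        b2[2] <= b3[1] && b3[1] < b3[2])) {
    stop("sample-size bands must be disjoint and ordered", call. = FALSE)
  }
  policy
}

#' @export
print.ri_policy <- function(x, ...) {
  cat("<ri_policy>\n")
  cat(sprintf("  bands: no-report [0,%g) | descriptive [%g,%g) | min-max [%g,%g) | full [%g,%s)\n",
              x$band_descriptive_only[1], x$band_descriptive_only[1],
              x$band_descriptive_only[2], x$band_minmax[1], x$band_minmax[2],
              x$band_full[1], if (is.finite(x$band_full[2])) x$band_full[2] else "Inf"))
  cat(sprintf("  normality gate: Shapiro-Wilk p > %g\n", x$normality_alpha))
  cat(sprintf("  parametric limits: mean +/- %.6f * sd\n", x$z_multiplier))
  cat(sprintf("  outlier screen: Horn (n >= %d, fence k = %g) / Dixon (%s, threshold %.4g)\n",
              x$horn_min_n, x$fence_k, x$dixon_variant, x$dixon_ratio_threshold))
  cat(sprintf("  bootstrap: B = %d, CI level %g, imprecision flag ratio > %g\n",
              x$bootstrap_B, x$ci_level, x$ci_ratio_flag_threshold))
  cat(sprintf("  percentile convention: %s; seed %d\n",
              x$percentile_convention, x$rng_seed))
  invisible(x)
}

#' Read a method policy from a JSON configuration file
#'
#' Every field of [ri_policy()] can be bound in a flat JSON object; fields
#' absent from the file keep their defaults.  Unknown fields are an error so
#' that typos do not silently fall back to defaults.
#'
#' @param path Path to a JSON file.
#' @return An `ri_policy`.
#' @examples
#' cfg <- tempfile(fileext = ".json")
#' writeLines('{"bootstrap_B": 500, "rng_seed": 7}', cfg)
#' read_policy_config(cfg)$bootstrap_B
#' @export
read_policy_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(ri_policy))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown policy field(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (f in intersect(c("band_full", "band_minmax", "band_descriptive_only"),
                      names(cfg))) {
    cfg[[f]] <- as.numeric(cfg[[f]])  # accepts the "Inf" string round trip
  }
  do.call(ri_policy, cfg)
}

#' Write a method policy to a JSON configuration file
#'
#' @param policy An `ri_policy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_policy_config <- function(policy, path) {
  validate_policy(policy)
  x <- unclass(policy)
  # Inf has no JSON literal; serialize band edges as strings where needed
  x$band_full <- ifelse(is.finite(x$band_full), x$band_full, "Inf")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
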