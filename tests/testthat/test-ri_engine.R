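test_that("normality gate is strict at the 0.2 cut-off", {
  set.seed(201)
  x <- rnorm(86)
  a <- assess_normality(x)
  sw <- shapiro.test(x)
  expect_equal(a$w_stat, unname(sw$statistic))
  expect_equal(a$p_value, sw$p.value)
  expect_identical(a$gaussian, sw$p.value > 0.2)

  # strict ">": p exactly at the cut-off is non-Gaussian
  pol <- ri_policy(normality_alpha = sw$p.value)
  expect_false(assess_normality(x, pol)$gaussian)

  expect_true(is.na(assess_normality(rep(3, 50))$gaussian))
  expect_true(is.na(assess_normality(c(1, 2))$gaussian))
})

test_that("method selection reproduces the banded routing rules", {
  expect_equal(select_method(86, FALSE), "nonparametric")
  expect_equal(select_method(86, TRUE), "parametric")
  expect_equal(select_method(86, NA), "nonparametric")  # unassessable -> NP
  expect_equal(select_method(28, TRUE), "minmax")
  expect_equal(select_method(17, NA), "descriptive_only")
  expect_equal(select_method(6, NA), "no_report")
  # half-open band edges
  expect_equal(select_method(40, TRUE), "parametric")
  expect_equal(select_method(39, TRUE), "minmax")
  expect_equal(select_method(20, NA), "minmax")
  expect_equal(select_method(19, NA), "descriptive_only")
  expect_equal(select_method(10, NA), "descriptive_only")
  expect_equal(select_method(9, NA), "no_report")
  expect_equal(select_method(5000, TRUE), "parametric")  # open-ended upward
})

test_that("parametric limits are the exact closed form mean +/- z*sd", {
  set.seed(202)
  for (i in 1:5) {
    x <- rnorm(50, runif(1, 5, 100), runif(1, 1, 10))
    ri <- parametric_ri(x)
    z <- qnorm(0.975)
    expect_equal(unname(ri), c(mean(x) - z * sd(x), mean(x) + z * sd(x)))
  }
  # printed-summary reproductions (exact sample moments by construction)
  expect_equal(round(parametric_ri(sample_with_moments(86, 48.17, 10.82)), 2),
               c(lower = 26.96, upper = 69.38))
  expect_equal(round(parametric_ri(sample_with_moments(57, 31.63, 4.96))[["lower"]], 2),
               21.91)
  expect_equal(round(parametric_ri(sample_with_moments(85, 4.60, 0.87))[["lower"]], 2),
               2.89)
  expect_warning(parametric_ri(c(3, 3, 3)), "constant")
})

test_that("percentile limits follow the rank p*(n+1) convention", {
  # integer ranks: 0.025*40 = 1 and 0.975*40 = 39
  expect_equal(nonparametric_percentile_ri(1:39), c(lower = 1, upper = 39))

  # fractional rank: n = 84, 2nd/3rd order stats 9900/10000
  # -> rank 0.025*85 = 2.125 -> 9900 + 0.125 * 100 = 9912.5
  set.seed(203)
  x <- c(9800, 9900, 10000, runif(81, 10500, 30000))
  expect_equal(nonparametric_percentile_ri(x)[["lower"]], 9912.5)

  # the alternative 1 + p*(n-1) convention is a policy switch
  pol7 <- ri_policy(percentile_convention = "n_minus_1")
  expect_equal(unname(nonparametric_percentile_ri(x, pol7)),
               unname(quantile(x, c(0.025, 0.975), type = 7)))
})

test_that("percentile limits equal the sort-and-interpolate oracle", {
  set.seed(204)
  for (i in 1:200) {
    n <- sample(5:120, 1)
    x <- switch(sample(3, 1), rnorm(n), rlnorm(n), runif(n, -5, 5))
    got <- nonparametric_percentile_ri(x)
    want <- quantile(x, c(0.025, 0.975), type = 6, names = FALSE)
    # type 6 is exactly rank p*(n+1) interpolation with clamping to [1, n]
    expect_equal(unname(got), want)
    expect_gte(got[["lower"]], min(x))
    expect_lte(got[["upper"]], max(x))
  }
})

test_that("min-max limits are the sample extremes, exactly", {
  x <- sample_with_range(28, 8.7, 16.8, seed = 205)
  expect_identical(minmax_ri(x), c(lower = 8.7, upper = 16.8))
  expect_identical(minmax_ri(c(5, 5)), c(lower = 5, upper = 5))
  expect_error(minmax_ri(3), "at least 2")
})

test_that("bootstrap CIs are seed-deterministic and leave the RNG alone", {
  set.seed(206)
  x <- rnorm(60, 20, 4)
  pol <- ri_policy(bootstrap_B = 400)
  ci1 <- bootstrap_limit_ci(x, function(v) parametric_ri(v, pol), pol, seed = 99)
  ci2 <- bootstrap_limit_ci(x, function(v) parametric_ri(v, pol), pol, seed = 99)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_limit_ci(x, function(v) parametric_ri(v, pol), pol, seed = 100)
  expect_false(identical(ci1, ci3))

  set.seed(1); before <- runif(1)
  set.seed(1); invisible(bootstrap_limit_ci(x, minmax_ri, pol, seed = 5))
  expect_identical(runif(1), before)

  # constant input -> zero-width CIs
  cc <- bootstrap_limit_ci(rep(2, 30), minmax_ri, pol)
  expect_equal(unname(diff(cc$lower)), 0)
  expect_equal(unname(diff(cc$upper)), 0)

  # CI ordering and rough location sanity
  expect_lt(ci1$lower[["low"]], ci1$lower[["high"]])
  expect_lt(ci1$upper[["low"]], ci1$upper[["high"]])
})

test_that("CI/RI ratio is the width quotient with correct edge handling", {
  expect_equal(ci_ri_ratio(c(7.9, 9.43), c(8.62, 16.78)), 1.53 / 8.16)
  expect_equal(ci_ri_ratio(c(3, 3), c(1, 5)), 0)
  expect_gt(ci_ri_ratio(c(0, 10), c(4, 6)), 1)  # wider than the RI: allowed
  expect_error(ci_ri_ratio(c(1, 2), c(5, 5)), "zero-width")
})

test_that("partition comparison behaves across effect sizes", {
  set.seed(207)
  x <- rnorm(50)
  same <- compare_partitions(x, x)
  expect_gte(same$p_value, 0.99)
  expect_false(same$significant)

  far <- compare_partitions(rnorm(50), rnorm(50, 5))
  expect_lt(far$p_value, 1e-6)
  expect_true(far$significant)

  welch <- compare_partitions(rnorm(50), rnorm(50, 5),
                              ri_policy(partition_test = "welch"))
  expect_lt(welch$p_value, 1e-6)

  expect_true(is.na(compare_partitions(c(1, 2), rnorm(10))$p_value))
  expect_true(is.na(compare_partitions(rep(1, 5), rep(1, 5))$p_value))
})

test_that("analyze_measurand routes each band to the right output shape", {
  pol <- ri_policy(bootstrap_B = 300)

  # 17 values: descriptive statistics only, no limits, no CI
  set.seed(208)
  r17 <- analyze_measurand(rnorm(17, 10, 3), pol)
  expect_equal(r17$method, "descriptive_only")
  expect_true(is.na(r17$lower_limit) && is.na(r17$upper_limit))
  expect_null(r17$lrl_ci)
  expect_equal(r17$descriptive$n, 17L)

  # constant series (analyte below detection): short-circuit, no limits
  r0 <- analyze_measurand(rep(0, 87), pol)
  expect_equal(r0$method, "no_report")
  expect_true(is.na(r0$lower_limit))
  expect_equal(r0$descriptive$n, 87L)
  expect_true(is.na(r0$distribution_label))

  # Gaussian n = 86 passing the gate: parametric closed form + CIs
  x <- sample_with_moments(86, 50, 5, seed = 209)
  r86 <- analyze_measurand(x, pol)
  expect_equal(r86$method, "parametric")
  expect_equal(r86$distribution_label, "G")
  ret <- r86$screen$retained
  z <- qnorm(0.975)
  expect_equal(r86$lower_limit, mean(ret) - z * sd(ret))
  expect_equal(r86$upper_limit, mean(ret) + z * sd(ret))
  expect_false(is.null(r86$lrl_ci))
  expect_false(is.na(r86$lrl_ratio))

  # min-max band: limits are the extremes, CIs suppressed
  rmm <- analyze_measurand(sample_with_range(28, 8.7, 16.8, seed = 210), pol)
  expect_equal(rmm$method, "minmax")
  expect_identical(c(rmm$lower_limit, rmm$upper_limit), c(8.7, 16.8))
  expect_null(rmm$lrl_ci)
  expect_true(is.na(rmm$distribution_label))  # normality not assessed < 40

  # empty series
  re <- analyze_measurand(numeric(0), pol)
  expect_equal(re$method, "no_report")
  expect_null(re$descriptive)
})

test_that("analyze_measurand is deterministic given the policy seed", {
  set.seed(211)
  x <- rlnorm(70, 2, 0.5)
  s <- measurand_series("GGT", "U/L", "All", x)
  pol <- ri_policy(bootstrap_B = 300, rng_seed = 123)
  r1 <- analyze_measurand(s, pol)
  r2 <- analyze_measurand(s, pol)
  expect_identical(r1[c("lower_limit", "upper_limit", "lrl_ci", "url_ci")],
                   r2[c("lower_limit", "upper_limit", "lrl_ci", "url_ci")])
})
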