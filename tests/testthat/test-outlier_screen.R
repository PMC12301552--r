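# Independent oracle for the Box-Cox exponent: profile log-likelihood on a
# lambda grid at 0.01 resolution, written from the definition.
boxcox_grid_oracle <- function(x, grid = seq(-3, 3, by = 0.01)) {
  n <- length(x)
  slog <- sum(log(x))
  ll <- vapply(grid, function(lam) {
    z <- if (abs(lam) < 1e-12) log(x) else (x^lam - 1) / lam
    -(n / 2) * log(sum((z - mean(z))^2) / n) + (lam - 1) * slog
  }, numeric(1))
  grid[which.max(ll)]
}

test_that("Box-Cox exponent matches a profile-likelihood grid oracle", {
  set.seed(101)
  x_lognorm <- exp(rnorm(200))
  bc <- boxcox_transform(x_lognorm)
  expect_lt(abs(bc$lambda_hat), 0.25)
  expect_lt(abs(bc$lambda_hat - boxcox_grid_oracle(x_lognorm)), 0.011)

  set.seed(102)
  x_gauss <- rnorm(200, 10, 1)
  bc2 <- boxcox_transform(x_gauss)
  expect_lt(abs(bc2$lambda_hat - 1), 0.5)
  expect_lt(abs(bc2$lambda_hat - boxcox_grid_oracle(x_gauss)), 0.011)
})

test_that("Box-Cox handles shifts and rejects degenerate input", {
  expect_error(boxcox_transform(c(0, 1, 2, 3), shift = FALSE),
               "strictly positive")
  expect_error(boxcox_transform(rep(4, 10)), "constant")
  expect_error(boxcox_transform(c(1, 2)), "at least 3")
  expect_error(boxcox_transform(c(1, 2, NaN)), "finite")

  bc <- boxcox_transform(c(-2, 0, 5, 7, 9))  # shifted by 1 - (-2) = 3
  expect_equal(bc$shift, 3)
  expect_length(bc$transformed, 5)
})

test_that("Box-Cox transform preserves order (strictly monotone)", {
  set.seed(103)
  for (i in 1:10) {
    x <- rlnorm(30, meanlog = runif(1, -1, 2), sdlog = runif(1, 0.2, 1))
    bc <- boxcox_transform(x)
    expect_identical(order(bc$transformed), order(x))
  }
})

test_that("Horn screen reproduces hand-computed fences on the identity scale", {
  # {1..11, 100}: type-7 quartiles 3.75 / 9.25, IQR 5.5, upper fence 17.5
  h <- horn_screen(c(1:11, 100), lambda = 1)
  f <- attr(h, "fences")
  expect_equal(f$q1, 3.75)
  expect_equal(f$q3, 9.25)
  expect_equal(f$upper_fence, 17.5)
  expect_equal(f$lower_fence, -4.5)
  expect_equal(h$removed$value, 100)
  expect_equal(sort(h$retained), 1:11)
})

test_that("Horn screen is permutation-invariant and empty on clean data", {
  set.seed(104)
  x <- rnorm(60, 50, 5)
  expect_equal(nrow(horn_screen(x)$removed), 0L)

  y <- c(x, 200)
  perm <- sample(length(y))
  expect_equal(sort(horn_screen(y)$removed$value),
               sort(horn_screen(y[perm])$removed$value))
  expect_equal(nrow(horn_screen(rep(7, 40))$removed), 0L)  # constant
})

test_that("Horn flags are monotone in the fence multiplier", {
  set.seed(105)
  for (i in 1:8) {
    x <- c(rnorm(40, 20, 3), rnorm(3, 20, 15))
    flagged_15 <- horn_screen(x, ri_policy(fence_k = 1.5))$removed$value
    flagged_30 <- horn_screen(x, ri_policy(fence_k = 3.0))$removed$value
    expect_true(all(flagged_30 %in% flagged_15))
  }
})

# Brute-force restatement of the gap-to-range rule.
dixon_oracle <- function(x, threshold = 1 / 3) {
  s <- sort(x)
  n <- length(s)
  rng <- s[n] - s[1]
  if (n < 3 || rng == 0) return(numeric(0))
  r_low <- (s[2] - s[1]) / rng
  r_high <- (s[n] - s[n - 1]) / rng
  if (max(r_low, r_high) < threshold) return(numeric(0))
  if (r_high >= r_low) s[n] else s[1]
}

test_that("Dixon screen matches direct arithmetic and the brute-force oracle", {
  expect_equal(dixon_screen(c(1, 2, 3, 4, 100))$removed$value, 100)
  r <- attr(dixon_screen(c(1, 2, 3, 4, 100)), "ratios")
  expect_equal(unname(r["high"]), 96 / 99)

  expect_equal(nrow(dixon_screen(c(1, 2, 3, 4, 5))$removed), 0L)  # max 0.25
  expect_equal(nrow(dixon_screen(c(7, 7, 7, 7))$removed), 0L)     # zero range
  expect_warning(out <- dixon_screen(c(1, 2)), "at least 3")
  expect_equal(nrow(out$removed), 0L)

  # exhaustive-ish: all short vectors over a small alphabet, plus random ones
  set.seed(106)
  alphabet <- c(0, 1, 2, 5, 50)
  for (i in 1:300) {
    n <- sample(3:8, 1)
    x <- sample(alphabet, n, replace = TRUE)
    expect_equal(dixon_screen(x)$removed$value, dixon_oracle(x),
                 info = paste(x, collapse = ","))
  }
})

test_that("Dixon critical-value variant uses the classical table", {
  pol <- ri_policy(dixon_variant = "critical")
  # n = 5, r10 = 96/99 = 0.97 >= cv 0.710 -> flagged
  expect_equal(dixon_screen(c(1, 2, 3, 4, 100), pol)$removed$value, 100)
  # n = 5, clean -> r10 = 0.25 < 0.710
  expect_equal(nrow(dixon_screen(1:5 * 1.0, pol)$removed), 0L)
  # the ratio rule and the table can disagree near the boundary:
  # [0,1,2,3,4,10]: r_high = 6/10 = 0.6 >= 1/3 (ratio) but < 0.625 (cv, n=6)
  x <- c(0, 1, 2, 3, 4, 10)
  expect_equal(dixon_screen(x)$removed$value, 10)
  expect_equal(nrow(dixon_screen(x, pol)$removed), 0L)
})

test_that("iterative screen removes a gross outlier then reaches a fixed point", {
  set.seed(110)
  x <- rnorm(50, 100, 10)
  planted <- 100 + 10 * 10
  res <- iterative_screen(c(x, planted))
  expect_equal(res$removed$value, planted)
  expect_equal(sort(res$retained), sort(x))

  again <- iterative_screen(res$retained)
  expect_equal(nrow(again$removed), 0L)
})

test_that("masked small-sample outlier is caught on the second Dixon pass", {
  x <- c(10:19, 45, 100)  # n = 12; 100 masks 45 on the first pass
  res <- iterative_screen(x)
  expect_equal(res$removed$value, c(100, 45))
  expect_equal(res$removed$iteration, c(1L, 2L))
  expect_equal(res$removed$method, c("dixon", "dixon"))
  expect_equal(sort(res$retained), 10:19)
})

test_that("clean and degenerate inputs pass through the loop untouched", {
  set.seed(108)
  x <- rnorm(40)
  res <- iterative_screen(x)
  expect_equal(res$retained, x)
  expect_equal(nrow(res$removed), 0L)
  expect_equal(res$iterations, 1L)

  empty <- iterative_screen(numeric(0))
  expect_length(empty$retained, 0L)
  expect_equal(empty$iterations, 0L)
  expect_equal(iterative_screen(rep(0, 87))$removed$value, numeric(0))
})

test_that("conservation, idempotence and termination hold across seeds", {
  set.seed(109)
  for (i in 1:20) {
    n <- sample(c(5, 12, 25, 31, 50, 80), 1)
    x <- rlnorm(n, 3, 0.5)
    n_bad <- sample(0:2, 1)
    if (n_bad > 0) x <- c(x, max(x) * (2 + runif(n_bad, 0, 3)))
    res <- iterative_screen(x)
    # conservation as multisets
    expect_equal(sort(c(res$retained, res$removed$value)), sort(x))
    # idempotence
    expect_equal(nrow(iterative_screen(res$retained)$removed), 0L)
    # termination
    expect_lte(res$iterations, length(x))
    # method is re-chosen from the n current at each pass
    if (nrow(res$removed) > 0) {
      removed_before <- vapply(res$removed$iteration, function(it) {
        sum(res$removed$iteration < it)
      }, integer(1))
      n_at_pass <- length(x) - removed_before
      expect_equal(res$removed$method,
                   ifelse(n_at_pass >= 31, "horn", "dixon"))
    }
  }
})
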