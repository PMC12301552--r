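#' Box-Cox power transform with profile-likelihood exponent
#'
#' Transforms a sample toward symmetry with `(x^lambda - 1)/lambda`
#' (`log(x)` at `lambda = 0`), choosing `lambda` by maximizing the Box-Cox
#' profile log-likelihood
#' `-(n/2) log(sigma_hat^2(lambda)) + (lambda - 1) sum(log(x))`
#' over a closed search interval.  Data that are not strictly positive are
#' shifted by `1 - min(x)` first (the shift is reported); the transform is a
#' strictly increasing map of the input either way, so order statistics are
#' preserved.
#'
#' @param values Numeric vector, length >= 3, all finite.
#' @param lambda_search Closed search interval for the exponent
#'   (default `c(-3, 3)`).
#' @param shift Allow the positivity shift (default `TRUE`).  With
#'   `shift = FALSE`, non-positive input is a domain error.
#' @param lambda Optional fixed exponent; skips the likelihood search
#'   (used to pin the transform, e.g. to the identity `lambda = 1`).
#' @return A list of class `boxcox_transform` with `lambda_hat`, `shift` and
#'   `transformed`.
#' @examples
#' set.seed(1)
#' bc <- boxcox_transform(exp(rnorm(100)))
#' abs(bc$lambda_hat) < 0.5  # log-normal data want lambda near 0
#' @export
boxcox_transform <- function(values, lambda_search = c(-3, 3),
                             shift = TRUE, lambda = NULL) {
  if (length(values) < 3) {
    stop("Box-Cox transform needs at least 3 values", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("Box-Cox transform: input must be finite", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    stop("Box-Cox transform: constant input is degenerate", call. = FALSE)
  }
  delta <- 0
  if (min(values) <= 0) {
    if (!shift) {
      stop("Box-Cox transform: input must be strictly positive", call. = FALSE)
    }
    delta <- 1 - min(values)
  }
  x <- values + delta

  bc <- function(lam) {
    if (abs(lam) < 1e-12) log(x) else (x^lam - 1) / lam
  }
  if (is.null(lambda)) {
    n <- length(x)
    slog <- sum(log(x))
    profile_ll <- function(lam) {
      z <- bc(lam)
      -(n / 2) * log(sum((z - mean(z))^2) / n) + (lam - 1) * slog
    }
    lambda <- stats::optimize(profile_ll, interval = lambda_search,
                              maximum = TRUE, tol = 1e-6)$maximum
  }
  structure(list(lambda_hat = lambda, shift = delta, transformed = bc(lambda)),
            class = "boxcox_transform")
}

new_screen_result <- function(input, keep, method, iteration = 1L) {
  removed <- data.frame(value = input[!keep],
                        iteration = rep(iteration, sum(!keep)),
                        method = rep(method, sum(!keep)))
  structure(list(retained = input[keep], removed = removed,
                 iterations = iteration),
            class = "outlier_screen")
}

#' @export
print.outlier_screen <- function(x, ...) {
  cat(sprintf("<outlier_screen> retained %d | removed %d | iterations %d\n",
              length(x$retained), nrow(x$removed), x$iterations))
  if (nrow(x$removed) > 0) {
    print(x$removed, row.names = FALSE)
  }
  invisible(x)
}

#' Horn's outlier screen (single pass)
#'
#' Applies Tukey's interquartile fences to the Box-Cox-transformed sample:
#' quartiles `q1`, `q3` of the transformed values, fences
#' `q1 - k*IQR` and `q3 + k*IQR`, and every value whose transform lies
#' *strictly* outside the fences is flagged (ties at a fence are retained).
#' A constant sample has zero IQR and is defined outlier-free.  Intended for
#' n > 30; callable on smaller vectors.
#'
#' @param values Numeric vector.
#' @param policy An [ri_policy()] (supplies `fence_k`, `quartile_type`,
#'   `boxcox_search`).
#' @param lambda Optional fixed Box-Cox exponent (e.g. `1` to screen on the
#'   raw scale).
#' @return An `outlier_screen` result.  Attribute `"fences"` carries the
#'   fence geometry mapped back to the measurement scale (`q1`, `q3`,
#'   `lower_fence`, `upper_fence`; infinite when a fence falls outside the
#'   transform's range) plus the raw transformed-scale geometry, the fitted
#'   `lambda_hat` and the positivity `shift`.
#' @export
horn_screen <- function(values, policy = ri_policy(), lambda = NULL) {
  n <- length(values)
  if (n < 3 || stats::var(values) == 0) {
    return(new_screen_result(values, rep(TRUE, n), "horn"))
  }
  bc <- boxcox_transform(values, lambda_search = policy$boxcox_search,
                         lambda = lambda)
  z <- bc$transformed
  q <- stats::quantile(z, c(0.25, 0.75), type = policy$quartile_type,
                       names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - policy$fence_k * iqr
  hi <- q[2] + policy$fence_k * iqr
  keep <- z >= lo & z <= hi
  out <- new_screen_result(values, keep, "horn")
  # report the fence geometry back on the measurement scale (the transform
  # is strictly increasing, so flagging is the same on either scale); a
  # fence outside the transform's range maps to an infinite fence
  inv <- function(v, low_side) {
    lam <- bc$lambda_hat
    if (abs(lam) < 1e-12) return(exp(v) - bc$shift)
    if (abs(lam - 1) < 1e-12) return(v + 1 - bc$shift)  # pure shift
    base <- lam * v + 1
    if (base > 0) base^(1 / lam) - bc$shift
    else if (low_side == (lam > 0)) -Inf else Inf
  }
  attr(out, "fences") <- list(
    q1 = inv(q[1], TRUE), q3 = inv(q[2], FALSE),
    lower_fence = inv(lo, TRUE), upper_fence = inv(hi, FALSE),
    transformed = list(q1 = q[1], q3 = q[2], iqr = iqr,
                       lower_fence = lo, upper_fence = hi),
    lambda_hat = bc$lambda_hat, shift = bc$shift)
  out
}

# Two-sided 5% critical values of Dixon's r statistics (r10 for n 3-7,
# r11 for 8-10, r21 for 11-13, r22 for 14-30), Rorabacher's tabulation.
dixon_cv_table <- c(
  `3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625, `7` = 0.568,
  `8` = 0.615, `9` = 0.570, `10` = 0.534,
  `11` = 0.625, `12` = 0.592, `13` = 0.565,
  `14` = 0.590, `15` = 0.568, `16` = 0.548, `17` = 0.531, `18` = 0.516,
  `19` = 0.503, `20` = 0.489, `21` = 0.478, `22` = 0.467, `23` = 0.457,
  `24` = 0.449, `25` = 0.440, `26` = 0.434, `27` = 0.428, `28` = 0.421,
  `29` = 0.416, `30` = 0.411
)

dixon_ratios <- function(x, variant) {
  s <- sort(x)
  n <- length(s)
  rng <- s[n] - s[1]
  if (variant == "ratio") {
    list(low = (s[2] - s[1]) / rng, high = (s[n] - s[n - 1]) / rng)
  } else {
    # classical r statistic: the gap skips suspected neighbours / trims the
    # opposite tail as n grows
    if (n <= 7) {
      list(low = (s[2] - s[1]) / rng,
           high = (s[n] - s[n - 1]) / rng)
    } else if (n <= 10) {
      list(low = (s[2] - s[1]) / (s[n - 1] - s[1]),
           high = (s[n] - s[n - 1]) / (s[n] - s[2]))
    } else if (n <= 13) {
      list(low = (s[3] - s[1]) / (s[n - 1] - s[1]),
           high = (s[n] - s[n - 2]) / (s[n] - s[2]))
    } else {
      list(low = (s[3] - s[1]) / (s[n - 2] - s[1]),
           high = (s[n] - s[n - 2]) / (s[n] - s[3]))
    }
  }
}

#' Dixon's outlier screen (single pass)
#'
#' Small-sample gap-to-range screen for 3 <= n <= 30.  On the sorted sample
#' the two extreme ratios are `r_low = (x(2) - x(1)) / range` and
#' `r_high = (x(n) - x(n-1)) / range`; the extreme with the larger ratio is
#' flagged if that ratio reaches the rejection threshold (default 1/3).
#' At most one value is flagged per pass -- the iterative loop catches a
#' second outlier on its next pass.  With
#' `policy$dixon_variant = "critical"` the classical two-sided 5%
#' critical-value table of Dixon's r statistics is used instead of the fixed
#' threshold.
#'
#' @param values Numeric vector, 3 to 30 values.
#' @param policy An [ri_policy()].
#' @return An `outlier_screen` result.
#' @examples
#' dixon_screen(c(1, 2, 3, 4, 100))$removed$value  # 100
#' nrow(dixon_screen(1:5)$removed)                 # 0
#' @export
dixon_screen <- function(values, policy = ri_policy()) {
  n <- length(values)
  if (n < 3) {
    warning("Dixon screen needs at least 3 values; nothing flagged")
    return(new_screen_result(values, rep(TRUE, n), "dixon"))
  }
  if (n > 30) {
    warning("Dixon screen applied to n > 30; Horn's method is intended there")
  }
  rng <- max(values) - min(values)
  if (rng == 0) {
    return(new_screen_result(values, rep(TRUE, n), "dixon"))
  }
  r <- dixon_ratios(values, policy$dixon_variant)
  threshold <- if (policy$dixon_variant == "ratio") {
    policy$dixon_ratio_threshold
  } else {
    dixon_cv_table[[as.character(min(n, 30))]]
  }
  # larger-ratio extreme first; ties resolve to the high extreme
  side <- if (r$high >= r$low) "high" else "low"
  stat <- max(r$high, r$low)
  keep <- rep(TRUE, n)
  if (stat >= threshold) {
    idx <- if (side == "high") which.max(values) else which.min(values)
    keep[idx] <- FALSE
  }
  out <- new_screen_result(values, keep, "dixon")
  attr(out, "ratios") <- c(low = r$low, high = r$high, threshold = threshold)
  out
}

#' Iterative outlier screen of a measurand series
#'
#' Repeats single-pass screening until a pass flags nothing (or fewer than 3
#' values remain): on each pass the method is chosen from the *current*
#' sample size -- Horn's fences on the Box-Cox transformed data when
#' `n >= policy$horn_min_n` (default n > 30), Dixon's gap-to-range test
#' otherwise -- flagged values are removed, and the pass is rerun.  The
#' Box-Cox exponent is re-estimated on every pass.  The result keeps a full
#' audit trail: every removed value with the pass index and method that
#' removed it.
#'
#' @param series A [measurand_series()] or bare numeric vector.
#' @param policy An [ri_policy()].
#' @return An `outlier_screen` with fields `retained`, `removed`
#'   (value / iteration / method), `iterations`.  Conservation holds:
#'   retained plus removed equal the input as multisets, and re-screening
#'   the retained values flags nothing.
#' @export
iterative_screen <- function(series, policy = ri_policy()) {
  values <- if (inherits(series, "measurand_series")) series$values else series
  stopifnot(is.numeric(values), all(is.finite(values)))
  current <- values
  removed <- data.frame(value = numeric(0), iteration = integer(0),
                        method = character(0))
  iter <- 0L
  repeat {
    if (length(current) < 3) break
    iter <- iter + 1L
    pass <- if (length(current) >= policy$horn_min_n) {
      horn_screen(current, policy)
    } else {
      suppressWarnings(dixon_screen(current, policy))
    }
    if (nrow(pass$removed) == 0) break
    pass$removed$iteration <- iter
    removed <- rbind(removed, pass$removed)
    current <- pass$retained
  }
  if (iter == 0L && length(current) >= 3) iter <- 1L
  structure(list(retained = current, removed = removed,
                 iterations = max(iter, if (length(values) == 0) 0L else 1L)),
            class = "outlier_screen")
}
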