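# Shared fixture builders; everything is generated in code, seeded.

# Sample with *exact* mean and sd (standardize, then rescale).
sample_with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- as.numeric(scale(stats::rnorm(n)))
  mean + sd * z
}

# Sample with exact min/max and an evenly spaced, lightly jittered interior,
# so no single point is gap-isolated and the outlier screen removes nothing.
sample_with_range <- function(n, min, max, seed = 1) {
  set.seed(seed)
  interior <- seq(min, max, length.out = n)[-c(1, n)]
  jitter_amt <- (max - min) / (20 * n)
  c(min, pmin(pmax(interior + stats::runif(n - 2, -jitter_amt, jitter_amt),
                   min), max), max)
}

# Small well-formed long-format table: one measurand, 60 M + 30 F.
toy_table <- function(n_m = 60, n_f = 30, measurand = "Hb", unit = "g/dL",
                      seed = 1) {
  set.seed(seed)
  n <- n_m + n_f
  study_table(data.frame(
    animal_id = sprintf("A%03d", seq_len(n)),
    sex = rep(c("M", "F"), c(n_m, n_f)),
    measurand = measurand, unit = unit,
    value = stats::rnorm(n, 12, 1.5)))
}

write_table_text <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
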