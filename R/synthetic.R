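#' Packaged summary fixture of a multi-measurand reference panel
#'
#' Per-group summary rows (n, mean, SD, median, min, max, reference limits,
#' Shapiro-Wilk p, distribution and method labels) for a 40+-measurand
#' hematology / biochemistry / blood-gas panel of an adult elephant
#' reference population, with per-sex partitions.  These printed summaries
#' parameterize the synthetic generator and anchor the method-routing
#' regression tests; they are summaries of real laboratory data, not raw
#' values.
#'
#' @return A data.frame, one row per (measurand, partition); absent cells
#'   are `NA`.
#' @export
panel_fixture <- function() {
  path <- system.file("extdata", "panel_summary.tsv", package = "rivet",
                      mustWork = TRUE)
  utils::read.delim(path, na.strings = "NA", check.names = FALSE,
                    colClasses = c(panel = "character",
                                   measurand = "character",
                                   unit = "character", sex = "character"))
}

#' Specification of one synthetic measurand
#'
#' Defines the generating distribution of one measurand: the family
#' (`gaussian`, `lognormal` -- moment-matched to the given mean/SD -- or
#' `gamma`), per-sex location/scale, a missingness rate, and a gross-outlier
#' contamination model (with probability `epsilon` a draw is displaced
#' upward by `shift` SDs).  Values below `floor` (default 0, the physical
#' floor of a concentration) are redrawn rather than truncated, so the
#' family's shape is approximately preserved.
#'
#' @param name Measurand name.
#' @param unit Unit string.
#' @param family `"gaussian"`, `"lognormal"` or `"gamma"`.
#' @param mean,sd Named numeric vectors with entries per sex (e.g.
#'   `c(M = 11.5, F = 12.5)`); an unnamed scalar applies to every sex.
#' @param missing_rate Probability that an (animal, measurand) cell is
#'   missing (default 0).
#' @param contamination_eps Contamination probability (default 0).
#' @param contamination_shift Displacement in SD units (default 8).
#' @param floor Lowest physically possible value (default 0; use `-Inf`
#'   for signed quantities such as base excess).
#' @return A `measurand_spec`.
#' @export
measurand_spec <- function(name, unit, family = c("gaussian", "lognormal", "gamma"),
                           mean, sd, missing_rate = 0,
                           contamination_eps = 0, contamination_shift = 8,
                           floor = 0) {
  family <- match.arg(family)
  stopifnot(all(sd >= 0), missing_rate >= 0, missing_rate <= 1,
            contamination_eps >= 0, contamination_eps <= 1)
  structure(list(name = name, unit = unit, family = family,
                 mean = mean, sd = sd, missing_rate = missing_rate,
                 contamination_eps = contamination_eps,
                 contamination_shift = contamination_shift, floor = floor),
            class = "measurand_spec")
}

spec_params <- function(spec, sex) {
  pick <- function(v) {
    if (is.null(names(v)) || length(v) == 1L && names(v)[1] == "") {
      v[[1]]
    } else if (sex %in% names(v)) {
      v[[sex]]
    } else {
      v[[1]]
    }
  }
  c(mean = pick(spec$mean), sd = pick(spec$sd))
}

draw_family <- function(family, n, mu, sigma) {
  if (sigma == 0) return(rep(mu, n))
  switch(family,
    gaussian = stats::rnorm(n, mu, sigma),
    lognormal = {
      s2 <- log(1 + (sigma / mu)^2)
      stats::rlnorm(n, meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
    },
    gamma = stats::rgamma(n, shape = (mu / sigma)^2, rate = mu / sigma^2))
}

#' Draw one synthetic measurand sample
#'
#' `n` draws from the spec's family at the given sex's location/scale; each
#' draw is independently displaced upward by `contamination_shift` SDs with
#' probability `contamination_eps`; draws below the physical floor are
#' redrawn.  Deterministic for a fixed seed.
#'
#' @param spec A [measurand_spec()].
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @param sex Sex label used to pick location/scale (default `"M"`).
#' @return Numeric vector of length `n`, with attribute `"contaminated"`
#'   giving the indices of displaced draws.
#' @examples
#' sp <- measurand_spec("Ca", "mg/dL", "gaussian", mean = 9.04, sd = 1.44)
#' x <- generate_measurand(sp, 100, seed = 1)
#' identical(x, generate_measurand(sp, 100, seed = 1))
#' @export
generate_measurand <- function(spec, n, seed, sex = "M") {
  stopifnot(inherits(spec, "measurand_spec"), n >= 1)
  p <- spec_params(spec, sex)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  x <- draw_family(spec$family, n, p["mean"], p["sd"])
  if (p["sd"] > 0) {
    for (tries in 1:100) {
      below <- x < spec$floor
      if (!any(below)) break
      x[below] <- draw_family(spec$family, sum(below), p["mean"], p["sd"])
    }
  }
  contaminated <- integer(0)
  if (spec$contamination_eps > 0) {
    hit <- stats::runif(n) < spec$contamination_eps
    x[hit] <- x[hit] + spec$contamination_shift * p["sd"]
    contaminated <- which(hit)
  }
  attr(x, "contaminated") <- contaminated
  unname(x)
}

#' Study-level configuration for the synthetic generator
#'
#' @param specs List of [measurand_spec()]s.
#' @param n_male,n_female Cohort sizes (defaults 62 and 30: a 92-animal
#'   cohort with the roughly 2:1 male skew typical of working-animal
#'   populations).
#' @param seed Integer master seed; per-(measurand, sex) streams are
#'   derived from it.
#' @return A `study_config`.
#' @export
study_config <- function(specs, n_male = 62, n_female = 30, seed = 20210601L) {
  stopifnot(length(specs) > 0,
            all(vapply(specs, inherits, logical(1), "measurand_spec")),
            n_male >= 0, n_female >= 0, n_male + n_female >= 1)
  structure(list(specs = specs, n_male = n_male, n_female = n_female,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Default synthetic study emulating the packaged panel
#'
#' Builds a [study_config()] from [panel_fixture()]: one spec per measurand,
#' per-sex means/SDs taken from the fixture's partition rows (pooled rows
#' where a sex row is absent), `lognormal` for measurands labelled
#' non-Gaussian and `gaussian` otherwise, per-measurand missingness matched
#' to the fixture's pooled n out of 92, and mild gross-outlier
#' contamination.
#'
#' @param seed Master seed.
#' @param contamination_eps Contamination probability (default 0.02).
#' @param contamination_shift Displacement in SD units (default 8).
#' @return A `study_config` with 40+ measurand specs.
#' @export
default_study_config <- function(seed = 20210601L, contamination_eps = 0.02,
                                 contamination_shift = 8) {
  fx <- panel_fixture()
  n_total <- 92
  specs <- list()
  for (m in unique(fx$measurand)) {
    rows <- fx[fx$measurand == m, , drop = FALSE]
    all_row <- rows[rows$sex == "All", , drop = FALSE]
    if (nrow(all_row) == 0 || is.na(all_row$mean[1])) next
    pick <- function(sex, col) {
      r <- rows[rows$sex == sex, , drop = FALSE]
      if (nrow(r) == 1 && !is.na(r[[col]])) r[[col]] else all_row[[col]][1]
    }
    family <- if (identical(all_row$distribution[1], "G")) "gaussian"
              else if (identical(all_row$distribution[1], "NG")) "lognormal"
              else "gaussian"  # small-n rows: no label printed; assume symmetric
    specs[[m]] <- measurand_spec(
      name = m, unit = all_row$unit[1], family = family,
      mean = c(M = pick("M", "mean"), F = pick("F", "mean")),
      sd = c(M = pick("M", "sd"), F = pick("F", "sd")),
      missing_rate = max(0, 1 - all_row$n[1] / n_total),
      contamination_eps = if (all_row$sd[1] > 0) contamination_eps else 0,
      contamination_shift = contamination_shift,
      floor = if (all_row$min[1] < 0) -Inf else 0)
  }
  study_config(unname(specs), seed = seed)
}

#' Generate a synthetic long-format study table
#'
#' Draws every (animal, measurand) cell of the configured study:
#' per-sex sample sizes are honored, missingness is applied independently
#' per cell, and contamination follows each spec.  A truth log (generating
#' parameters and the animal ids of contaminated values) is attached as
#' attribute `"truth"` so recovery tests can score the pipeline.
#'
#' @param config A [study_config()].
#' @return A [study_table()] with attribute `"truth"`.
#' @examples
#' cfg <- study_config(list(
#'   measurand_spec("Hb", "g/dL", "gaussian", mean = c(M = 11.5, F = 12.5),
#'                  sd = c(M = 1.4, F = 2.2))), seed = 1)
#' tab <- generate_study(cfg)
#' length(unique(tab$animal_id)) == 92
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  ids <- sprintf("EL%03d", seq_len(config$n_male + config$n_female))
  sexes <- rep(c("M", "F"), c(config$n_male, config$n_female))
  out <- vector("list", length(config$specs) * 2L)
  truth <- list(seed = config$seed, n_male = config$n_male,
                n_female = config$n_female, measurands = list())
  k <- 0L
  for (spec in config$specs) {
    contaminated_ids <- character(0)
    for (sex in c("M", "F")) {
      idx <- which(sexes == sex)
      if (length(idx) == 0) next
      sd_seed <- derive_seed(config$seed, paste(spec$name, sex, sep = "|"))
      x <- generate_measurand(spec, length(idx), seed = sd_seed, sex = sex)
      contaminated_ids <- c(contaminated_ids,
                            ids[idx][attr(x, "contaminated")])
      # per-cell missingness on its own derived stream
      miss_seed <- derive_seed(config$seed, paste(spec$name, sex, "miss",
                                                  sep = "|"))
      keep <- rep(TRUE, length(idx))
      if (spec$missing_rate > 0) {
        old_seed <- if (exists(".Random.seed", globalenv())) {
          get(".Random.seed", globalenv())
        }
        set.seed(miss_seed)
        keep <- stats::runif(length(idx)) >= spec$missing_rate
        if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
      }
      if (!any(keep)) next
      k <- k + 1L
      out[[k]] <- data.frame(animal_id = ids[idx][keep], sex = sex,
                             measurand = spec$name, unit = spec$unit,
                             value = as.numeric(x)[keep])
    }
    truth$measurands[[spec$name]] <- list(
      family = spec$family, mean = spec$mean, sd = spec$sd,
      missing_rate = spec$missing_rate,
      contamination_eps = spec$contamination_eps,
      contamination_shift = spec$contamination_shift,
      contaminated_ids = contaminated_ids)
  }
  tab <- study_table(do.call(rbind, out[seq_len(k)]))
  attr(tab, "truth") <- truth
  tab
}
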