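---
title: "Reference-interval estimation with rivet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-interval estimation with rivet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivet)
```

## The problem

A reference interval (RI) is the central 95% range of a measurand in a
healthy reference population; its endpoints are the lower and upper
reference limits (LRL/URL). Veterinary panels — hematology, serum
biochemistry, blood gas — are routinely interpreted against RIs, but for
most non-domestic species the reference samples are small (tens of
animals), unevenly split across sexes, contaminated by occasional
pre-analytical gross errors, and incomplete (each measurand has its own
*n*). `rivet` implements the de novo RI workflow recommended by
ASVCP/CLSI-style guidance for exactly this regime, as a tested library
rather than an ad hoc script.

## The model and its assumptions

The unit of analysis is one measurand's values in one partition
(`measurand_series`). The pipeline assumes values are exchangeable
measurements from a single healthy population, possibly contaminated by a
small fraction of gross outliers; measurands are treated independently
(no multivariate modeling), and partitions (e.g. sex) are analyzed
separately plus pooled.

**Outlier screening.** For current *n* > 30, Horn's method: a Box–Cox
transform `(x^λ − 1)/λ` (log at λ = 0) with λ maximizing the profile
log-likelihood over [−3, 3], then Tukey fences `Q1 − k·IQR`,
`Q3 + k·IQR` (k = 1.5, type-7 quartiles) on the transformed sample;
values strictly outside are flagged (ties at a fence are kept). For
*n* ≤ 30, Dixon's gap-to-range test: the extreme with the larger
`gap/range` ratio is flagged when the ratio reaches 1/3, one value per
pass, so a masked second outlier is caught by the next pass. Removal and
re-screening repeat — with the method and the Box-Cox λ re-chosen from the
current sample each pass — until a pass flags nothing. Every removal is
recorded (value, pass, method): the exclusion trail is part of the result.

**Normality gate.** Shapiro–Wilk on the *raw* retained values (the
Box–Cox transform exists only inside the screen). "Gaussian" requires
p *strictly* greater than 0.2: at reference-sample sizes the test has low
power, so the threshold is deliberately conservative and borderline
samples go to the nonparametric branch. The gate is only consulted when
the post-screening *n* reaches the full band (≥ 40).

**Banded estimation.** With *n* ≥ 40: parametric limits
`mean ± z·SD` (z = qnorm(0.975) = 1.959964, not the rounded 1.96) when
Gaussian, otherwise percentile limits at 2.5/97.5% using the rank
`p·(n+1)` interpolation convention (quantile type 6), clamped to the
observed range. With 20 ≤ *n* < 40 the extreme percentiles are not
estimable and the RI is the observed min–max. With 10 ≤ *n* < 20 only
descriptive statistics are reported; below 10, nothing. The band edges
are half-open (`[40, ∞)`, `[20, 40)`, `[10, 20)`) — this is the only
reading consistent with published routing at n = 41 (full), n = 38
(min–max) and n = 20 (min–max) — and the full band extends upward
unchanged because nothing in the method depends on an upper limit.

**Uncertainty.** Each limit of a parametric or percentile RI gets a 90%
percentile-bootstrap CI (B = 2000 resamples, seeded per measurand and
partition so studies re-run identically, including under parallel
execution). Min–max and descriptive-only rows never get CIs: a bootstrap
of an extreme order statistic at these *n* is vacuous. The ratio
CI-width/RI-width above 0.2 flags an imprecise limit.

**Partition comparison.** Two-sided Wilcoxon rank-sum by default (most
panel measurands fail the normality gate, so a rank test is the safer
default; Welch's t is a policy option). Computed on the screened per-sex
samples and reported once per measurand.

## Tunable parameters

All conventions live in `ri_policy()`; the defaults are the stated
workflow. The ones that matter most:

| parameter | default | meaning |
|---|---|---|
| `normality_alpha` | 0.2 | Shapiro–Wilk gate (strict `>`) |
| `z_multiplier` | 1.959964 | SD multiplier of the parametric limits |
| `band_full` / `band_minmax` / `band_descriptive_only` | [40, ∞) / [20, 40) / [10, 20) | sample-size routing |
| `horn_min_n` | 31 | Horn when current n ≥ 31, Dixon below |
| `fence_k` | 1.5 | Tukey fence multiplier |
| `dixon_ratio_threshold` | 1/3 | Dixon rejection ratio |
| `percentile_convention` | `n_plus_1` | rank `p(n+1)` (type 6) vs `1+p(n−1)` (type 7) |
| `bootstrap_B`, `ci_level` | 2000, 0.90 | limit CIs |
| `ci_ratio_flag_threshold` | 0.2 | imprecision flag |

The `n_plus_1` percentile convention is the CLSI-style choice; it is what
produces a fractional lower limit such as 9912.5 from an n = 84 leucocyte
count sample whose 2nd/3rd order statistics are 9900/10000
(rank 0.025·85 = 2.125). The alternative convention is kept as a policy
switch because software differs on this point and the choice is visible
exactly at such fractional ranks.

## Design choices where the design was open

- **Dixon variant.** "Dixon's test" in RI practice usually means the fixed
  gap-to-range ≥ 1/3 rejection rule, not the classical tabulated Q test;
  the 1/3 rule is the default and the classical two-sided 5%
  critical-value table (r10/r11/r21/r22 by n) is available as
  `dixon_variant = "critical"`. The two disagree only in a narrow ratio
  window (e.g. ratio 0.6 at n = 6 rejects under the rule, not under the
  table).
- **One-at-a-time removal.** When both Dixon extremes exceed the
  threshold, only the larger-ratio extreme is removed in that pass; the
  loop catches the other. Ties go to the high extreme. This matches the
  "identify → exclude → rerun" loop semantics and makes audit trails
  unambiguous.
- **Constant input** (e.g. an analyte at the detection floor reported as
  all zeros) is defined outlier-free and unreportable: zero IQR/range
  short-circuits the screen, the normality gate returns "not assessable",
  and the result carries descriptive statistics with no limits.
- **Non-positive data** are shifted by `1 − min(x)` before the Box–Cox
  step (shift reported); fences are mapped back to the measurement scale
  for reporting, with a fence outside the transform's range reported as
  infinite.
- **λ re-estimation.** The Box–Cox exponent is re-fit on every screening
  pass (the rerun-from-scratch reading of the iterate-until-clean loop);
  whether the original practice refit or froze λ is not decidable from
  published descriptions, and the difference only matters when early
  passes remove many points.
- **Parametric limits are not floored at zero.** For a strongly skewed
  measurand wrongly routed parametric, `mean − 1.96·SD` can be negative;
  the package reports the closed form and leaves physical flooring to
  interpretation (published tables occasionally print such a lower limit
  as 0).

## The synthetic generator: what it emulates, what it does not

`generate_study()` draws a long-format study (default 92 animals,
62 male / 30 female — the hard total with the roughly 2:1 male skew of
working-animal cohorts) for 40+ measurands parameterized by
`inst/extdata/panel_summary.tsv`, a fixture of published per-group
summaries (n, mean, SD, median, min, max, normality/method labels) from a
real elephant panel. Measurands labelled non-Gaussian are drawn lognormal
(moment-matched to the printed mean/SD), Gaussian-labelled ones normal;
per-measurand missingness reproduces the fixture's pooled n out of 92;
contamination displaces each draw upward by 8 SD with probability 0.02
(defaults chosen once: 8 SD makes a contaminant unambiguous, 2% matches
the sparse gross-error rate the screening stage is designed for); draws
below the physical floor (0 for concentrations; −∞ for base excess) are
redrawn, not truncated. A truth log (attribute `"truth"`) records the
generating parameters and which records were contaminated.

What it does *not* emulate: between-measurand correlation (hemoglobin and
PCV are generated independently; real panels are strongly correlated),
analyzer rounding, batch effects, and any age structure. A green
end-to-end test therefore establishes that the pipeline recovers known
marginal structure per measurand — not that it would model a real panel's
joint behavior.

## Numerical notes and honest limitations

- **Screening bias at large n.** Tukey fences sit near ±2.70σ for
  Gaussian data, so the screen flags the extreme ~0.7% of *clean* values;
  iterating to a fixed point trims them, deflating the retained SD by
  ~4% at n = 10⁴ and pulling parametric limits inward by 3–8% (more when
  contamination skews the fitted λ). At panel-scale n ≈ 90 the expected
  spurious removal is ~0.6 values and the effect is negligible — the
  method is designed for that regime, and the package's recovery tests
  assert the estimators themselves are within 1% of μ ± 1.96σ at n = 10⁵
  *without* screening, while the post-screening pipeline is held to the
  attainable ≥90% gross-outlier recovery with <3% false removal.
- **Bootstrap coverage.** The percentile bootstrap of `mean ± z·SD` at
  n = 86, B = 2000 covers the true limits with probability ≈ 0.88
  (slightly below nominal 0.90, as expected for the percentile method at
  this n); the coverage test uses 2000 Monte-Carlo replicates so its
  standard error (~0.007) cannot masquerade as a coverage defect.
- **Printed-table rounding.** Published tables round each column
  independently from unrounded internals; reproductions from printed
  summaries are therefore exact only to the printed precision (e.g. an
  upper cholesterol limit recomputed from rounded mean/SD lands at 69.38
  against a printed 69.39, and three published min–max rows differ from
  their printed Min/Max by ≤ 0.05).
- **Determinism.** All randomness flows from explicit seeds
  (`ri_policy(rng_seed=)`, per-measurand derived streams); library calls
  restore the caller's RNG state. Reports regenerate bit-identically
  under a fixed seed and config.
- The package does not implement robust RI methods, Harris–Boyd
  partitioning statistics, age-class partitioning, or unit conversion.
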