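Package: rivet
Title: Reference Intervals for Veterinary Clinical Pathology Panels
Version: 0.1.0
Authors@R:
    person("Sandbox", "Developer", email = "dev@example.org", role = c("aut", "cre"))
Description: Estimation of clinical-pathology reference intervals (RIs) in the
    ASVCP/CLSI style for hematology, serum biochemistry and blood-gas panels.
    Implements iterative outlier exclusion (Horn's method with Tukey fences on
    Box-Cox transformed data for n > 30, Dixon's gap-to-range test for
    n <= 30), Shapiro-Wilk gated selection between parametric and
    nonparametric percentile limits by sample-size band, min-max limits for
    small samples, percentile-bootstrap confidence intervals of the reference
    limits with CI/RI width-ratio imprecision flags, and partitioned (e.g.
    by-sex) reporting.  A synthetic-study generator emulates a realistic
    multi-measurand panel (Gaussian and right-skewed measurands, sex effects,
    gross-outlier contamination, missingness) so every stage of the pipeline
    can be exercised without access to raw laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
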