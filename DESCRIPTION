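Package: trajalign
Title: Biologically Aligned Developmental Trajectory Modelling and Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal developmental-cohort analysis in which
    each subject's chronological age is aligned to a biological maturation
    marker (e.g. tibial epiphyseal closure) before modelling. Provides a
    seeded synthetic-cohort generator (binomial session performance with
    task-variant difficulty offsets, Gaussian firing-rate and white-matter
    tract outcomes with subject random effects), penalized-spline mixed-model
    trajectory fitting (cubic shrinkage basis, REML) with predictions on a
    fixed 100-point maturation grid, detection of significant developmental
    change windows from finite-difference derivatives with simultaneous
    confidence bands, Benjamini-Hochberg correction across outcomes, and a
    trajectory-similarity statistic (Pearson r of z-scored curves plus RMSE
    of baseline-shifted absolute curves) with maxT permutation inference,
    orchestrated end-to-end by a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    MASS,
    stats,
    utils,
    tools,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
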