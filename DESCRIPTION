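Package: mdximmune
Title: Immune-Driven Muscle Degeneration and Regeneration Dynamics in the
    mdx Mouse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic ordinary-differential-equation model of the
    interplay between the immune response (macrophages, CD4+ helper and
    CD8+ cytotoxic T cells) and skeletal-muscle fiber turnover (normal,
    damaged, regenerating) in the dystrophin-deficient mdx mouse, with a
    lognormal time-to-failure mechanical damage input.  Provides
    stiff-capable simulation with conservation checking, in-silico
    immune-cell depletion experiments, multi-dataset weighted
    least-squares calibration (seeded global differential-evolution
    search followed by bounded Levenberg-Marquardt refinement),
    parameter-recovery assessment on synthetic literature-style time
    courses, and sensitivity analyses: initial-condition ensembles,
    two-level factorial ensembles over parameter ranges, one-dimensional
    parameter sweeps, two-parameter asymptotic heat maps, and long-run
    regime classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
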