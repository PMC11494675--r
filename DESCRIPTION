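Package: glycostab
Title: Analytical Precision and Time-Dependent Stability of the IgG N-Glycome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the analytical precision and the short- and
    long-term temporal stability of immunoglobulin G (IgG) N-glycan profiles
    measured as relative peak areas (CGE-LIF or HILIC-UPLC). Implements
    intermediate (between-run) precision statistics over a plates-by-replicates
    design with relative-abundance-tiered acceptance grading, the standard
    glycomics preprocessing chain (total-area normalization, log transform,
    parametric empirical-Bayes batch correction, derived glycan traits,
    inverse rank-normal transform), cohort-level mixed-model time-effect
    estimation and single-subject trend estimation on baseline-normalized
    trajectories, extreme-value and sample-swap flagging, and a synthetic-data
    generator that emulates plasma-pool precision designs, short-term cohort
    designs with menstrual-cycle periodicity, and multi-year single-subject
    series with ageing drift and intervention episodes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    lme4,
    lmerTest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    ggplot2,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
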