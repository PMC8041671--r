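Package: volscroll
Title: Scroll-Pattern Analysis of Volumetric Image Reading Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-stamped scroll logs recorded while
    readers navigate stacked (CT-style) image volumes during computer-based
    tests. The package segments slice-navigation trajectories into runs
    between local extrema to quantify the percentage of time spent on full
    runs (global search), computes dwell time on expert-defined
    question-relevant slice ranges, aggregates question-level metrics to the
    test level, and fits two-level longitudinal mixed models (Gaussian and
    binomial) of expertise development and diagnostic accuracy with
    cluster-robust standard errors. A synthetic-data module generates both
    micro-level scroll logs and macro-level cohorts with known parameters so
    the whole pipeline can be exercised and validated without access to raw
    test logfiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    IRanges,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
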