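Package: petvoi
Title: Cost-Effectiveness and Value of Implementation of Surgery plus
    Endocrine Therapy versus Primary Endocrine Therapy in Early Breast
    Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A partitioned survival decision model comparing surgery plus
    adjuvant endocrine therapy with primary endocrine therapy (PET) for
    women aged 70 and over with operable early-stage breast cancer, from
    the perspective of the NHS in England. Provides parametric survival
    fitting and model selection for extrapolating trial Kaplan-Meier data,
    reconstruction of individual participant data from digitized survival
    curves with numbers-at-risk, a deterministic three-state partitioned
    survival engine with half-cycle correction and discounting,
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves and per-person expected value of perfect
    information, and expected value of perfect implementation at the
    individual and population level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
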