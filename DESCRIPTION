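Package: flotcea
Title: Semi-Markov Cost-Effectiveness Modelling of Perioperative
    Immunochemotherapy for Resectable Gastric Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for cohort-level cost-effectiveness
    analysis of perioperative durvalumab plus FLOT chemotherapy versus FLOT
    alone in resectable gastric and gastroesophageal junction adenocarcinoma.
    Provides synthetic two-arm trial evidence generation, Guyot-style
    reconstruction of pseudo individual patient data from digitized
    Kaplan-Meier coordinates and number-at-risk tables, parametric and
    flexible (Royston-Parmar spline, fractional polynomial, mixture-cure)
    survival extrapolation, a four-state semi-Markov cohort engine with
    residence-time-dependent transitions, half-cycle correction and
    discounting, cost and quality-adjusted life-year accounting with
    incremental cost-effectiveness ratios, and one-way and probabilistic
    sensitivity analysis with acceptability curves and expected value of
    perfect information.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    tools,
    survival,
    flexsurv,
    pracma,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
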