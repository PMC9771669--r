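Package: vbcohort
Title: Stochastic Von Bertalanffy Growth Curves for Overlapping Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates Von Bertalanffy growth curves from length-at-age data in
    which every individual is measured once, while accounting for variation in
    environmental growth limitation over time, between cohorts and between
    individuals. The length distribution of each cohort is propagated across a
    discrete time-by-age lattice with closed-form mean and variance recursions
    derived from a stochastic (Ornstein-Uhlenbeck type) form of the Von
    Bertalanffy growth equation, and all cohorts are fitted jointly by weighted
    Gaussian maximum likelihood in log-transformed parameter space. Includes a
    survey-style synthetic data simulator (Euler-Maruyama paths, length-biased
    catchability with inverse-CPUE weighting), leave-one-year-out jackknife
    diagnostics, AIC/likelihood-ratio model comparison, broom-style tidiers and
    ggplot2 visualisations, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
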