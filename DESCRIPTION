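Package: phenoscan
Title: Genotype-Specific Parameter Estimation for Maize Anthesis by
    Quasi-Random Database Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how well genotype-specific parameters (GSPs)
    of an ecophysiological crop model can be recovered from multi-environment
    anthesis-date observations. Implements the CERES-Maize anthesis-date
    submodel (thermal time, photoperiod-sensitive tassel initiation, leaf
    expansion to pollen shed), construction of a Sobol quasi-random database
    of simulated anthesis dates across site-years, per-line inversion by
    minimum-RMSE scan with exact tie (equifinality) accounting, phenotype
    space expressivity mapping with nearest-achievable assignment, a
    differential-evolution continuous-search cross-check, and a crossed
    random-effects stability test with a boundary likelihood-ratio test on
    the site-year-subset variance component. A synthetic-data generator
    emulates the structure of the multi-site maize nested association
    mapping trials so the full pipeline runs without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
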