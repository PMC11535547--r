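Package: rasim
Title: Mechanistic Multiscale Simulation of Rheumatoid Arthritis Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A quantitative systems pharmacology simulator of the inflamed
    rheumatoid-arthritis joint. An ordinary-differential-equation network of
    nine synovial cell types and seventeen soluble mediators is coupled to a
    clinical score layer (model DAS28-CRP and ACR response categories),
    pharmacokinetic/pharmacodynamic models of methotrexate, adalimumab and
    tocilizumab, virtual-cohort generation with plausibility filtering,
    virtual-population calibration against published trial statistics with
    probabilistic placebo correction, and local (tornado) and global (Sobol)
    sensitivity analysis. Tabular results are returned as tibbles so the
    pipeline composes with tidyverse tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
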