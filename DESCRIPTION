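Package: adaptci
Title: Exact One-Sided Confidence Limits for Adaptive One-Arm Two-Stage Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact one-sided lower confidence limits for the binomial
    response rate after an adaptive one-arm two-stage clinical trial in
    which the second-stage sample size is a non-increasing function of the
    first-stage response count. Implements Clopper-Pearson inversion of the
    terminal sample space under six stochastic orderings (tail-area RR,
    p-value PV, two-step RR-A, average response rate RR-B, RR-LR, and
    RR-Score), together with exact coverage-probability curves, simple
    average and expected interval length, and the practical G2(CI)
    subsample space used to compare the orderings. Designs are supplied as
    JSON or CSV files or synthesized for testing; all probabilities are
    exact binomial sums, never asymptotic approximations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
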