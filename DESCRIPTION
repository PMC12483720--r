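Package: ebifactor
Title: Exact Exploratory Bi-Factor Analysis by Constrained Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns an exact bi-factor loading structure from multivariate
    data without pre-specifying which variables load on which group factor.
    The bi-factor pattern (each variable loads on the general factor and on
    at most one of G possibly correlated group factors) is encoded as a set
    of bilinear equality constraints on the loading matrix, and the
    normal-theory maximum-likelihood factor problem is solved under those
    constraints with an augmented Lagrangian method. Includes BIC selection
    of the number of group factors with an unconstrained exploratory factor
    analysis baseline, a simulation engine for exact and approximate
    bi-factor population models, and structure-recovery metrics (exact match,
    average correctness, loading mean squared error up to column permutation
    and sign flips, selection correctness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml,
    tibble,
    generics,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
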