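Package: morphoclock
Title: Bayesian Tip Dating with Morphological Clocks and Historical Biogeography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating phylogenies from discrete morphological
    characters with fossil tips. Implements the Mk(v) likelihood with
    ascertainment correction and discrete-gamma rate variation, strict and
    relaxed morphological clocks (TK02, ILN, IGR, WN), the fossilized
    birth-death tree prior with sampled ancestors and tip-age calibrations,
    a Metropolis-Hastings sampler with standard convergence diagnostics
    (ASDSF, PSRF, ESS), stepping-stone marginal-likelihood estimation and
    Bayes-factor model comparison, posterior tree summaries (consensus
    topologies, HPD node ages), stochastic character mapping with
    ER/SYM/ARD model selection by AIC, and dispersal-extinction-cladogenesis
    ancestral-range estimation on non-ultrametric trees with epoch-wise
    connectivity matrices. Includes simulators for fossilized birth-death
    trees, clocked character matrices, and geographic ranges, with truth
    manifests for calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
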