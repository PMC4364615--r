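Package: cortexsheet
Title: Columnar Cortical Sheet Networks: Wiring, Dynamics and Noise Robustness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a 1 mm^2 sheet of layer 2/3 pyramidal neurons with either a
    columnar or a salt-and-pepper ("non-columnar") feature map. Connectivity is
    sampled from a joint distance- and tuning-dependent probability rule, synaptic
    conductances follow a common-neighbor clustering rule with an optional
    synaptic-failure correction, and cells are integrated as three-compartment
    conductance models with delayed global shunting inhibition. Includes the
    evaluation protocol built on Pearson similarity of population spike-count
    vectors: orientation discrimination curves, noise-recovery curves, and
    time-to-convergence, plus control networks (shuffled amplitudes,
    distance-only wiring, simple Hebbian weights).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
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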