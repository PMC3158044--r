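Package: hfqnet
Title: Deterministic Kinetics of Hfq-Mediated Small RNA Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates Hfq-mediated sRNA-target mRNA duplex formation as a
    deterministic mass-action reaction network.  Arbitrary n x m networks of
    small RNAs and target mRNAs compete for a shared pool of Hfq hexamers;
    the package solves the resulting stiff ODE system to steady state,
    sweeps Hfq production to map duplex-formation dose-response curves, and
    computes efficiency and robustness metrics (percent duplex, Hfq
    allocation, sequestration, lower/upper Hfq bounds and their log-fold
    range).  Kinetic regimes are parameterised through composite y-parameters
    covering heterotropic cooperativity, RNA dissociation, cognate selection
    and non-cognate exclusion, and a scenario library encodes the standard
    simulation designs (network scaling, stability mixes, indiscriminate
    pairing, production imbalances, unpartnered mRNA pools).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
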