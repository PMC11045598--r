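Package: reddlcm
Title: Land-Cover Change Projection and REDD Carbon Accounting
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for multitemporal categorical land-cover
    analysis: seeded synthetic landscape generation with known ground truth,
    spectral-temporal metric features and tree-ensemble classification of
    image stacks, cross-tabulation change detection, Markov-chain transition
    estimation with multilayer-perceptron transition-potential surfaces and
    ranked spatial allocation, Pontius Kno/Klocation/Kquantity map agreement
    statistics, and BioCarbon-Fund style REDD carbon budgets (baseline,
    actual, leakage, net reduction) over a multi-decade horizon with
    periodic reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
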