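Package: imrcat
Title: Invariant Molecular Representations for Adsorption-Energy Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Learns exchange-correlation-functional-invariant representations
    of surface reaction intermediates and uses them to predict adsorption
    energies on a functional that was held out of representation training.
    A Siamese neural network with a bias-free odd readout head is fit to
    within-functional pairwise adsorption-energy differences; its subnetwork
    output (the invariant molecular representation, IMR) feeds conventional
    regressors (ridge, elastic net, kernel ridge, support vector regression).
    Includes a SMILES parser for C/H surface intermediates with free
    valences, 24-length flat and Morgan fingerprints, a synthetic
    multi-functional data generator, the full trial/cross-validation
    evaluation protocol with t-tests and D2 goodness-of-fit scores, and
    integrated-gradients feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    glmnet,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
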