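Package: fpgan
Title: Fingerprint-Based Generative Adversarial Networks for Compound
    Library Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generative adversarial networks that operate directly on binary
    molecular fingerprints (MACCS keys by default) for de novo design of
    drug-like and target-biased compound libraries. Provides six deep
    convolutional discriminator architectures adapted to one-dimensional
    fingerprint input, unconditional and conditional GAN training loops,
    a substructure-preserving mask layer that pins maximum-common-substructure
    feature bits in every generated fingerprint, property-matched decoy
    selection by principal-component density sampling, stratified
    cross-validation, generation-quality metrics (uniqueness, novelty,
    diversity, similarity), Tanimoto similarity search against compound
    libraries at banded thresholds, and two-round substructure confirmation
    of retrieved hits. Molecule handling (SMILES/SDF parsing, MACCS and FP2
    fingerprints, SMARTS matching, physicochemical properties) is backed by
    Open Babel through ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
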