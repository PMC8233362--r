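Package: brushmech
Title: Mechanics of Injectable Bottlebrush Elastomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tissue-mimetic bottlebrush elastomer
    networks. Implements the strain-stiffening equation of state for brush
    polymer networks and its nonlinear least-squares fitting to uniaxial
    tensile data, derived moduli and theoretical extensibility, the
    architectural scaling law linking structural modulus to side-chain
    length and strand pre-extension, gel-point detection from oscillatory
    rheology time sweeps, texture-profile-analysis metrics from cyclic
    compression traces, inverse design of network architecture for target
    mechanics, and seeded synthetic-data generators emulating all three
    instrument inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
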