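Package: jamuda
Title: Multivariate Mining of Blended Herbal Medicine Formularies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for relating the ingredient composition of blended herbal
    medicines (Jamu) to their registered efficacy classes. Provides data
    structures and I/O for binary formula-by-plant usage matrices, efficacy
    labels and plant-by-activity annotations; PCA with biplot coordinates for
    plant-efficacy frequency tables; NIPALS partial least squares discriminant
    analysis (PLS-DA) with dummy-coded responses and confusion-matrix
    reporting; permutation tests on PLS-DA coefficients to identify
    main-ingredient plants; trilinear N-PLS(-DA) regression on the
    formula x plant x activity tensor with an activity-significance rule;
    Ward/Euclidean clustergrams of significance matrices; and a synthetic
    formulary generator with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
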