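Package: cradlefinder
Title: Locating Allopolyploid Formation Cradles with Ensemble Species
    Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for locating the potential formation
    centers ("cradles") of an allopolyploid plant from the bioclimatic
    niches of its parental taxa. Fits presence/background suitability
    models with four algorithm families (GLM, random forest, MARS-style
    hinge regression, and a regularized log-linear maximum-entropy
    surrogate), builds weighted-average bootstrap ensembles with AUC/TSS
    evaluation, projects them to past climate periods with multi-GCM
    consensus, extracts occurrence-derived low-suitability intervals,
    intersects the parental low-suitability areas over a gypsum-soil
    mask, and filters the resulting cradles by a survival threshold
    tracked through time. A synthetic-landscape module generates
    spatially autocorrelated predictor stacks, virtual taxa with known
    Gaussian response curves, presence samples, and patchy soil masks so
    that every stage can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
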