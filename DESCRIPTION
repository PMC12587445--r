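Package: abcqsar
Title: Consensus QSAR Modeling of ABC Transporter Substrates and
    Inhibitors with Brain-Exposure Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curates heterogeneous bioactivity records for the ABC efflux
    transporters P-gp, BCRP, MRP1 and MRP2 into binary substrate and
    inhibition datasets using rule-driven record classification, majority
    voting, structure standardization and similarity-based dataset
    balancing; trains multi-algorithm consensus QSAR classifiers (random
    forest, support vector machine, gradient boosted trees and a
    feed-forward network over circular fingerprints, MACCS keys and a
    physicochemical descriptor panel) with stratified cross-validation and
    a probability-band applicability domain; ranks influential MACCS
    substructures by Shapley attribution; and combines efflux-substrate
    predictions with polar surface area and hydrogen-bonding counts into a
    brain-exposure score evaluated against unbound brain-to-plasma ratios.
    A synthetic-data generator with planted structure-activity signal and
    realistic curation hazards makes every stage testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    e1071,
    nnet,
    randomForest,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
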