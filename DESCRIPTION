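Package: crystalnn
Title: Neural-Network Prediction of Protein Crystallization Propensity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting the propensity of a protein sequence to
    yield diffraction-quality crystals. Computes a 428-dimensional sequence
    feature vector (amino-acid and dipeptide frequencies, isoelectric point,
    mean GES hydrophobicity, secondary-structure/disorder/transmembrane
    annotation fractions, length and molecular weight), feeds it to a small
    feed-forward neural network (428-100-1, logistic units) trained by
    per-example back-propagation with early stopping, selects a decision
    cutoff maximizing the Matthews correlation coefficient over 10-fold
    cross-validation, and scores 61-residue sliding windows along a sequence
    for construct design. Includes ROC/AROC and DeLong paired-AROC
    evaluation, single-linkage redundancy clustering over user-supplied
    pairwise similarity scores, and a seeded synthetic sequence generator
    with a controllable compositional effect size for testing and demos.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
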