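Package: nabhelix
Title: Detection of Nucleic Acid-Binding Helices in Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies short helical peptides with nucleic acid-binding
    potential directly from protein sequence. Candidate helices are found
    with a residue-composition sliding-window rule, described by twenty
    physicochemical features (charge, isoelectric point, instability index,
    residue-class frequencies, helix/sheet/turn propensities, hydropathy and
    related scales), and scored by an eight-classifier ensemble whose
    agreement is summarised in the NABh consensus index at three confidence
    tiers. Includes a seeded synthetic-data generator emulating the
    KhpB-versus-albumin training design, model training and evaluation
    utilities (stratified splits, grid search, cross-validation, permutation
    feature relevance, feature saturation), and an end-to-end FASTA-to-CSV
    prediction pipeline with a keyword-based recovery summariser.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    class,
    e1071,
    glmnet,
    nnet,
    ranger,
    rpart,
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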