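Package: chezod
Title: Per-Residue Protein Disorder Prediction from Sequence Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts continuous per-residue protein disorder (NMR chemical
    shift Z-scores, "CheZOD scores") from per-residue embedding matrices using
    shallow models: ordinary and single-dimension linear regression, ridge
    logistic regression, a two-layer feed-forward network and a two-layer
    convolutional network trained with Adam and early stopping. Includes
    readers/writers for a self-describing CheZOD score format and an HDF5
    embedding container, a seeded synthetic data generator with planted
    signal structure, bootstrapped Spearman/AUC evaluation with ROC curves,
    AlphaFold2-derived disorder proxies (pLDDT extraction from PDB B-factors,
    sliding-window smoothing, pre-filter cost/gain analysis) and
    organism-level 8-bin disorder spectra with PCA projection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    rhdf5,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
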