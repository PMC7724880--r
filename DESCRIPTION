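Package: amnet
Title: Attentional Memory Networks for Drug-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts unobserved drug-disease associations by nonlinearly
    fusing two collaborative-filtering views of a binary association matrix:
    an attention-weighted external-memory representation of the drugs already
    linked to a disease (the neighborhood view), and latent factors extracted
    by denoising autoencoders from association rows/columns together with
    drug-drug and disease-disease similarity side information (the global
    view). The two views are combined through a learned output layer and
    trained jointly with negative sampling under a binary cross-entropy plus
    reconstruction objective. Includes readers and writers for edge-list,
    MatrixMarket and CSV similarity formats, a synthetic-data generator with
    planted low-rank structure, ten-fold cross-validation and cold-start
    ("new drug") evaluation protocols with AUC, AUPR and hit-ratio metrics,
    and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
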