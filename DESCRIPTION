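Package: lncpair
Title: Recurrent Sequence-Pair Classification for Non-Coding RNA
    Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts interactions between long non-coding RNAs and short
    partner molecules (micro-RNAs or proteins) directly from raw sequences.
    Variable-length sequences are made fixed-length either by classical
    padding/truncation or by keeping only positional sub-regions (first X,
    last Y, or first-X-plus-last-Y residues); pairs are tokenized into
    overlapping k-mers and classified by a lightweight single-layer LSTM
    with DropConnect regularization, max/mean/last pooling, batch
    normalization and a dense softmax head, trained with decoupled weight
    decay (AdamW). Includes stratified cross-validation, grid search,
    region-informativeness sweeps, the seven standard binary-classifier
    metrics (including MCC and rank-based AUROC), and a seeded synthetic
    corpus generator with region-localized motifs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
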