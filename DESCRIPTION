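Package: spinr
Title: Scalable Functional Classification of Protein Sequences from
    Language-Model Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies homologous protein sequences into a fixed set of
    functional classes from per-residue embeddings produced by a pluggable
    sequence encoder. A question-answering style span predictor locates the
    functional domain inside each sequence, the embeddings within the
    predicted span are mean-pooled, and a small feed-forward head assigns
    class probabilities. Ships the weighted multi-task training loss with
    inverse-frequency class weights, imbalance-aware evaluation metrics
    (macro-weighted F1 and weighted accuracy), bootstrap confidence
    intervals for domain-boundary accuracy, temperature-scaling confidence
    calibration with expected calibration error, confidence-threshold
    abstention, residue- and chunk-reshuffle null-sequence generators, and
    a deterministic synthetic planted-motif family generator plus toy
    encoder so the whole pipeline runs without pretrained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
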