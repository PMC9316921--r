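Package: mixdecon
Title: Single-Unknown-Tissue Deconvolution of Pooled RNA-Seq Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the per-gene expression profile of one tissue that is
    present in a uniformly pooled multi-tissue RNA-seq library but has no
    reference samples of its own, by inverting the linear mixture model that
    relates the pool's normalised (FPKM) expression to the per-tissue mean
    profiles. Includes read-count filtering and FPKM normalisation, median
    imputation for mix tissues lacking reference data, removal of negative
    predictions, independence-based propagation of the prediction standard
    deviation, gene-wise scaling with hierarchical clustering of samples,
    Pearson correlation against external reference expression tables with an
    upper interquartile-range outlier rule, and a synthetic-data generator
    with known ground truth for parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
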