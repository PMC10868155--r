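Package: vaenet
Title: Functional Association Networks from Sparse Omics Matrices via
    Variational Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers weighted functional association networks from sparse,
    redundant expression matrices such as single-cell RNA-seq counts or
    bulk proteomics abundances. The condition dimension is compressed with
    a variational autoencoder trained on the [0,1]-scaled matrix, gene
    pairs are scored by Pearson correlation of their latent embeddings,
    raw scores are calibrated into posterior probabilities of shared
    pathway membership against a gold standard, and calibrated networks
    from multiple data types are merged with prior-corrected noisy-OR
    combination. Includes a synthetic-data generator with planted
    co-expression modules, dropout and redundant conditions, and
    benchmarking utilities producing cumulative true/false positive
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
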