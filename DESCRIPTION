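Package: scPairVAE
Title: Paired Cell and Gene Variational Autoencoders for Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Couples a cell-level variational autoencoder over single-cell
    expression profiles with a gene-level variational autoencoder over
    precomputed static gene embeddings (for example, embeddings exported
    from protein or text language models). The two decoders are joined by
    an inner-product reconstruction of the expression matrix, yielding
    aligned, context-aware cell and gene representations. Includes a
    three-step optimization schedule with KL warm-up and a latent-space
    alignment regularizer, leave-one-gene-out expression imputation,
    integration metrics (ARI, NMI, silhouette, batch-ASW, graph LISI),
    gene-module discovery by clustering contextual gene embeddings, and a
    synthetic-data generator with planted cell types, batches and gene
    modules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    FNN,
    igraph,
    mclust,
    cluster,
    methods,
    stats,
    utils
Suggests:
    rhdf5,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
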