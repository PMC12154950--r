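#' Simulation configuration
#'
#' Describes a synthetic single-cell study: low-rank expression built from
#' cell loadings (drawn around cell-type-specific means) and gene loadings
#' (drawn around gene-module-specific means), with per-gene intercepts,
#' additive per-batch offsets and Gaussian noise, plus a static
#' gene-embedding table whose relation to the planted modules is set by
#' `embedding_mode`: `informative` embeddings are a noisy affine image of
#' the true gene loadings (so module identity is linearly decodable),
#' `shuffled` permutes those rows, `random` is pure noise.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_cell_types,n_batches,n_modules planted structure counts.
#' @param latent_rank rank of the generating factors.
#' @param batch_effect_sd sd of the per-batch, per-gene additive offsets.
#' @param noise_sd sd of the entry-wise Gaussian noise.
#' @param embedding_dim D of the static embedding table.
#' @param embedding_noise_sd sd of the noise added to informative
#'   embeddings.
#' @param embedding_mode `"informative"`, `"shuffled"` or `"random"`.
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 500L, n_genes = 200L, n_cell_types = 4L,
                       n_batches = 2L, n_modules = 5L, latent_rank = 8L,
                       batch_effect_sd = 0.5, noise_sd = 0.5,
                       embedding_dim = 32L, embedding_noise_sd = 0.1,
                       embedding_mode = c("informative", "shuffled", "random"),
                       seed = 0L) {
  embedding_mode <- match.arg(embedding_mode)
  stopifnot(n_cells >= 2, n_genes >= 2, n_cell_types >= 1, n_batches >= 1,
            n_modules >= 1, n_modules <= n_genes, n_cell_types <= n_cells,
            latent_rank >= 1, batch_effect_sd >= 0, noise_sd >= 0,
            embedding_dim >= 1, embedding_noise_sd >= 0)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_cell_types = as.integer(n_cell_types),
                 n_batches = as.integer(n_batches),
                 n_modules = as.integer(n_modules),
                 latent_rank = as.integer(latent_rank),
                 batch_effect_sd = batch_effect_sd, noise_sd = noise_sd,
                 embedding_dim = as.integer(embedding_dim),
                 embedding_noise_sd = embedding_noise_sd,
                 embedding_mode = embedding_mode, seed = as.integer(seed)),
            class = "sim_config")
}

# within-group spread of the loadings relative to the unit-variance group
# means; fixed by design (strongly separated groups)
.WITHIN_SD <- 0.3

#' Generate a paired synthetic dataset
#'
#' Expression is generated directly on the continuous scale matching the
#' inner-product decoder: `cell_loadings %*% t(gene_loadings)` plus a
#' per-gene intercept, per-batch offsets and Gaussian noise, then
#' per-gene standardized (and clipped at 10) exactly as [preprocess()]
#' scales real data. With `count_mode = TRUE` the continuous signal is
#' converted to Poisson counts through a softplus rate and run through
#' the full [preprocess()] contract instead.
#'
#' @param cfg a [sim_config()].
#' @param count_mode generate Poisson counts instead of continuous values.
#' @return list of class `synthetic_dataset`: `expr` (an
#'   [expression_matrix()] with `batch` and `cell_type` filled), `table`
#'   (a [gene_embedding_table()]), `true_module`, `true_cell_type`,
#'   `true_batch`, `true_cell_loadings`, `true_gene_loadings`, `cfg`.
#' @export
generate <- function(cfg = sim_config(), count_mode = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  N <- cfg$n_cells; M <- cfg$n_genes; r <- cfg$latent_rank

  cell_type <- sample(rep_len(seq_len(cfg$n_cell_types), N))
  type_means <- matrix(stats::rnorm(cfg$n_cell_types * r), cfg$n_cell_types, r)
  L_cell <- type_means[cell_type, , drop = FALSE] +
    matrix(stats::rnorm(N * r, sd = .WITHIN_SD), N, r)

  module <- sample(rep_len(seq_len(cfg$n_modules), M))
  module_means <- matrix(stats::rnorm(cfg$n_modules * r), cfg$n_modules, r)
  L_gene <- module_means[module, , drop = FALSE] +
    matrix(stats::rnorm(M * r, sd = .WITHIN_SD), M, r)

  intercept <- stats::rnorm(M, sd = 0.5)
  batch <- sample(rep_len(seq_len(cfg$n_batches), N))
  batch_offsets <- matrix(stats::rnorm(cfg$n_batches * M,
                                       sd = cfg$batch_effect_sd),
                          cfg$n_batches, M)

  raw <- tcrossprod(L_cell, L_gene) +
    matrix(intercept, N, M, byrow = TRUE) +
    batch_offsets[batch, , drop = FALSE] +
    matrix(stats::rnorm(N * M, sd = cfg$noise_sd), N, M)

  cell_ids <- sprintf("cell_%04d", seq_len(N))
  gene_ids <- sprintf("gene_%04d", seq_len(M))

  if (count_mode) {
    counts <- matrix(stats::rpois(N * M, lambda = softplus(raw)), N, M)
    expr <- preprocess(expression_matrix(counts + 0.0, cell_ids, gene_ids,
                                         batch = batch, cell_type = cell_type))
  } else {
    scaled <- .scale_genes(raw, clip = 10, warn = FALSE)
    expr <- expression_matrix(scaled, cell_ids, gene_ids, batch = batch,
                              cell_type = cell_type)
  }

  A <- matrix(stats::rnorm(r * cfg$embedding_dim, sd = 1 / sqrt(r)),
              r, cfg$embedding_dim)
  informative <- L_gene %*% A +
    matrix(stats::rnorm(M * cfg$embedding_dim, sd = cfg$embedding_noise_sd),
           M, cfg$embedding_dim)
  vectors <- switch(cfg$embedding_mode,
    informative = informative,
    shuffled = {
      perm <- sample.int(M)
      while (all(perm == seq_len(M))) perm <- sample.int(M)
      informative[perm, , drop = FALSE]
    },
    random = matrix(stats::rnorm(M * cfg$embedding_dim), M, cfg$embedding_dim)
  )
  table <- gene_embedding_table(vectors, gene_ids,
                                source_tag = paste0("synthetic|",
                                                    cfg$embedding_mode))
  structure(list(expr = expr, table = table, true_module = module,
                 true_cell_type = cell_type, true_batch = batch,
                 true_cell_loadings = L_cell, true_gene_loadings = L_gene,
                 cfg = cfg),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Emits `matrix.mtx` (cells x genes, Matrix Market real), `genes.tsv`,
#' `barcodes.tsv`, `embeddings.csv` (gene id + D columns), `metadata.tsv`
#' (cell id, batch, cell type) and `gene_modules.tsv` (gene id, planted
#' module). The files round-trip through [load_expression()] /
#' [load_gene_embeddings()] within floating-point tolerance.
#'
#' @param ds a [generate()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(ds$expr$values, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(ds$expr$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(ds$expr$cell_ids, file.path(dir, "barcodes.tsv"))
  emb <- data.frame(gene = ds$table$gene_ids, ds$table$vectors,
                    check.names = FALSE)
  colnames(emb) <- c("gene", paste0("d", seq_len(ncol(ds$table$vectors))))
  data.table::fwrite(emb, file.path(dir, "embeddings.csv"))
  meta <- data.frame(cell = ds$expr$cell_ids, batch = ds$expr$batch,
                     cell_type = ds$expr$cell_type)
  data.table::fwrite(meta, file.path(dir, "metadata.tsv"), sep = "\t")
  truth <- data.frame(gene = ds$expr$gene_ids, module = ds$true_module)
  data.table::fwrite(truth, file.path(dir, "gene_modules.tsv"), sep = "\t")
  invisible(dir)
}
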