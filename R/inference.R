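#' Extract cell embeddings from a trained model
#'
#' Projects expression profiles through the trained cell encoder. The
#' default `mean` mode returns the posterior means (deterministic, the
#' right choice for clustering and other reproducible downstream
#' analyses); `sampled` draws one latent per cell under `seed`.
#'
#' @param model a trained [paired_model()].
#' @param expr an [expression_matrix()] whose genes match the model's.
#' @param mode `"mean"` or `"sampled"`.
#' @param seed seed for the `sampled` mode.
#' @return list of class `embedding_result`: `z` (rows x K), `ids`,
#'   `mode`, and `seed` when sampled.
#' @export
embed_cells <- function(model, expr, mode = c("mean", "sampled"), seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is.null(model$gene_ids) && !identical(expr$gene_ids, model$gene_ids))
    stop("expression gene set does not match the model's training genes")
  post <- encode_cell(model, expr$values)
  z <- if (mode == "mean") post$mu else {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    reparameterize(post)
  }
  rownames(z) <- expr$cell_ids
  structure(list(z = z, ids = expr$cell_ids, mode = mode,
                 seed = if (mode == "sampled") as.integer(seed) else NULL),
            class = "embedding_result")
}

#' Extract contextual gene embeddings from a trained model
#'
#' Projects static gene embeddings through the trained gene encoder into
#' the shared K-dimensional latent space. Genes never seen in training are
#' accepted as long as they carry a D-dimensional static vector (the
#' zero-shot projection path).
#'
#' @param model a trained [paired_model()].
#' @param table a [gene_embedding_table()] with the model's D.
#' @param mode `"mean"` or `"sampled"`.
#' @param seed seed for the `sampled` mode.
#' @return an `embedding_result` (see [embed_cells()]).
#' @export
embed_genes <- function(model, table, mode = c("mean", "sampled"), seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "gene_embedding_table"))
  post <- encode_gene(model, table$vectors)
  z <- if (mode == "mean") post$mu else {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    reparameterize(post)
  }
  rownames(z) <- table$gene_ids
  structure(list(z = z, ids = table$gene_ids, mode = mode,
                 seed = if (mode == "sampled") as.integer(seed) else NULL),
            class = "embedding_result")
}

#' Reconstruct the full expression matrix
#'
#' Mean-mode latents on both sides are decoded and combined through the
#' inner-product reconstruction with the trained per-gene bias.
#'
#' @param model a trained [paired_model()].
#' @param expr an [expression_matrix()] aligned to the model.
#' @param table the [gene_embedding_table()] aligned to `expr`.
#' @return `N x M` reconstruction matrix with dimnames.
#' @export
reconstruct_matrix <- function(model, expr, table) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(table, "gene_embedding_table"))
  if (!identical(expr$gene_ids, table$gene_ids))
    stop("expression and embedding tables are not gene-aligned")
  z_c <- encode_cell(model, expr$values)$mu
  z_g <- encode_gene(model, table$vectors)$mu
  h_c <- decode_cell(model, z_c)
  h_g <- decode_gene(model, z_g)
  out <- reconstruct_hidden(h_c, h_g, model$params$b_gene)
  dimnames(out) <- list(expr$cell_ids, expr$gene_ids)
  out
}

#' Leave-one-gene-out expression imputation
#'
#' The target gene is masked from the expression matrix (it must already
#' be absent from `expr_minus_j`), a model is trained on the remaining
#' genes, and the target's expression is predicted from its static
#' embedding alone: the static vector is encoded through the gene VAE,
#' decoded to its last-hidden vector, and combined with every cell's
#' last-hidden vector via the inner product. Because the per-gene bias is
#' a trained parameter the held-out gene never had, the default predicts
#' with zero bias; `bias = "mean_bias"` uses the mean trained bias
#' instead. Predictions are on the scaled expression scale.
#'
#' @param expr_minus_j an [expression_matrix()] without the target gene.
#' @param table_full a [gene_embedding_table()] containing the target gene
#'   and (at least) the training genes.
#' @param target_gene identifier of the held-out gene.
#' @param mcfg,tcfg model/training configurations used when training.
#' @param model optional pretrained [paired_model()] trained on the genes
#'   of `expr_minus_j` (the fast path for batched evaluation); when NULL a
#'   model is trained here.
#' @param bias `"zero"` (default) or `"mean_bias"` for the unseen-gene
#'   bias rule.
#' @return named numeric vector of length N in `expr_minus_j` cell order.
#' @export
impute_gene <- function(expr_minus_j, table_full, target_gene,
                        mcfg = model_config(), tcfg = train_config(),
                        model = NULL, bias = c("zero", "mean_bias")) {
  bias <- match.arg(bias)
  stopifnot(inherits(expr_minus_j, "expression_matrix"),
            inherits(table_full, "gene_embedding_table"))
  if (target_gene %in% expr_minus_j$gene_ids)
    stop("target gene ", target_gene, " is present in the expression matrix")
  if (!target_gene %in% table_full$gene_ids)
    stop("target gene ", target_gene, " is missing from the embedding table")
  if (is.null(model)) {
    al <- align_genes(expr_minus_j, table_full, policy = "error_on_missing")
    model <- fit(al$expr, al$table, mcfg, tcfg)$model
  } else {
    if (!is.null(model$gene_ids) &&
        !identical(model$gene_ids, expr_minus_j$gene_ids))
      stop("pretrained model was not trained on the genes of expr_minus_j")
  }
  z_c <- encode_cell(model, expr_minus_j$values)$mu
  h_c <- decode_cell(model, z_c)
  g_t <- table_full$vectors[target_gene, , drop = FALSE]
  z_t <- encode_gene(model, g_t)$mu
  h_t <- decode_gene(model, z_t)
  b_hat <- if (bias == "zero") 0 else mean(model$params$b_gene)
  pred <- drop(reconstruct_hidden(h_c, h_t, b_hat))
  names(pred) <- expr_minus_j$cell_ids
  pred
}
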