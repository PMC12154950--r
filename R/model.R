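#' Model configuration for the paired cell/gene VAE
#'
#' The cell VAE encodes an M-dimensional expression profile into a
#' K-dimensional Gaussian posterior; the gene VAE does the same for a
#' D-dimensional static gene embedding. Both decoders emit a last-hidden
#' vector of width `l`, and expression is reconstructed entry-wise as
#' `<h_cell_i, h_gene_j> + b_j` (inner product plus a per-gene bias).
#' Both latent spaces share the dimensionality `K`, which the alignment
#' regularizer requires, and both decoders must share `l`, which the
#' inner-product reconstruction requires.
#'
#' @param K latent dimensionality shared by the cell and gene posteriors.
#' @param l width of the last hidden layer of both decoders.
#' @param cell_hidden integer vector of hidden-layer widths for the cell
#'   encoder (the decoder mirrors it). `integer(0)` gives affine maps.
#' @param gene_hidden same for the gene side.
#' @param beta_max ceiling of the KL weight (warm-up ramps up to it).
#' @param gamma weight of the latent alignment term (default 0.05).
#' @param activation hidden-layer nonlinearity: "softplus" (default),
#'   "relu", "tanh" or "identity". Decoder final layers are always affine.
#' @param seed integer seed controlling weight initialization.
#' @param shared_bias if TRUE (default) the per-gene bias of the hidden
#'   reconstruction and of the latent alignment reconstruction is one
#'   shared parameter vector; if FALSE they are separate.
#' @return an object of class `model_config`.
#' @export
model_config <- function(K = 32L, l = 64L, cell_hidden = 128L,
                         gene_hidden = 128L, beta_max = 1e-2, gamma = 0.05,
                         activation = "softplus", seed = 0L,
                         shared_bias = TRUE) {
  stopifnot(K >= 1, l >= 1, beta_max >= 0, gamma >= 0)
  .activation(activation)  # validates the name
  structure(list(K = as.integer(K), l = as.integer(l),
                 cell_hidden = as.integer(cell_hidden),
                 gene_hidden = as.integer(gene_hidden),
                 beta_max = beta_max, gamma = gamma, activation = activation,
                 seed = as.integer(seed), shared_bias = isTRUE(shared_bias)),
            class = "model_config")
}

#' Construct an untrained paired model
#'
#' Initializes all parameter tensors (cell encoder/decoder, gene
#' encoder/decoder, the Step-1 linear head `W_cell`/`b_head`, and the
#' per-gene bias) with a seeded fan-in Gaussian scheme. Parameter shapes
#' are deterministic functions of `M`, `D` and the configuration.
#'
#' @param M number of genes (expression columns).
#' @param D static gene-embedding dimensionality.
#' @param config a [model_config()].
#' @param gene_ids optional gene identifiers stored for alignment checks.
#' @return an object of class `paired_model`.
#' @export
paired_model <- function(M, D, config = model_config(), gene_ids = NULL) {
  stopifnot(inherits(config, "model_config"), M >= 2, D >= 1)
  if (!is.null(gene_ids) && length(gene_ids) != M)
    stop("gene_ids length does not match M")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  params <- list(
    cell_enc = .encoder_init(M, config$cell_hidden, config$K),
    cell_dec = .mlp_init(c(config$K, rev(config$cell_hidden), config$l)),
    gene_enc = .encoder_init(D, config$gene_hidden, config$K),
    gene_dec = .mlp_init(c(config$K, rev(config$gene_hidden), config$l)),
    head = .linear_init(config$l, M),
    b_gene = numeric(M)
  )
  if (!config$shared_bias) params$b_align <- numeric(M)
  structure(list(params = params, config = config, M = as.integer(M),
                 D = as.integer(D), gene_ids = gene_ids,
                 source_tag = NULL, trained = FALSE),
            class = "paired_model")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

.check_matrix <- function(x, what) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop(what, " must be numeric")
  if (anyNA(x) || any(!is.finite(x))) stop(what, " contains NaN/Inf values")
  x
}

#' Encode cells into their Gaussian posteriors
#'
#' @param model a [paired_model()].
#' @param c_mat batch of expression rows, `N_b x M`.
#' @return a `gaussian_posterior` with `mu` and `log_var`, each `N_b x K`.
#' @export
encode_cell <- function(model, c_mat) {
  c_mat <- .check_matrix(c_mat, "expression batch")
  if (ncol(c_mat) != model$M)
    stop("expression batch has ", ncol(c_mat), " columns; model expects M = ", model$M)
  act <- .activation(model$config$activation)
  fw <- .encoder_forward(model$params$cell_enc, c_mat, act)
  gaussian_posterior(fw$mu, fw$log_var)
}

#' Encode genes (static embeddings) into their Gaussian posteriors
#'
#' Works for any rows in the static embedding space, including genes never
#' seen in training (the zero-shot projection path).
#'
#' @param model a [paired_model()].
#' @param g_mat batch of static gene embeddings, `M_b x D`.
#' @return a `gaussian_posterior` with `mu` and `log_var`, each `M_b x K`.
#' @export
encode_gene <- function(model, g_mat) {
  g_mat <- .check_matrix(g_mat, "gene embedding batch")
  if (ncol(g_mat) != model$D)
    stop("gene embedding batch has ", ncol(g_mat), " columns; model expects D = ", model$D)
  act <- .activation(model$config$activation)
  fw <- .encoder_forward(model$params$gene_enc, g_mat, act)
  gaussian_posterior(fw$mu, fw$log_var)
}

#' Gaussian posterior container
#'
#' @param mu matrix of posterior means (rows = samples, cols = latent dims).
#' @param log_var matrix of log variances, same shape.
#' @return an object of class `gaussian_posterior`.
#' @export
gaussian_posterior <- function(mu, log_var) {
  mu <- as.matrix(mu); log_var <- as.matrix(log_var)
  stopifnot(all(dim(mu) == dim(log_var)))
  if (any(!is.finite(mu)) || any(!is.finite(log_var)))
    stop("non-finite posterior parameters")
  structure(list(mu = mu, log_var = log_var), class = "gaussian_posterior")
}

#' Reparameterized sampling from a Gaussian posterior
#'
#' Computes `z = mu + eps * exp(0.5 * log_var)` element-wise, so gradients
#' can flow through the posterior parameters.
#'
#' @param post a [gaussian_posterior()].
#' @param eps a standard-normal draw matching `mu` in shape; drawn from the
#'   current RNG stream when missing.
#' @return latent matrix `z`, same shape as `mu`.
#' @export
reparameterize <- function(post, eps = NULL) {
  stopifnot(inherits(post, "gaussian_posterior"))
  if (is.null(eps)) {
    eps <- matrix(stats::rnorm(length(post$mu)), nrow(post$mu), ncol(post$mu))
  } else {
    eps <- as.matrix(eps)
    if (!all(dim(eps) == dim(post$mu))) stop("eps shape does not match mu")
  }
  post$mu + eps * exp(0.5 * post$log_var)
}

.decode <- function(model, side, z) {
  z <- .check_matrix(z, "latent batch")
  if (ncol(z) != model$config$K)
    stop("latent batch has ", ncol(z), " columns; model expects K = ", model$config$K)
  act <- .activation(model$config$activation)
  .mlp_forward(model$params[[side]], z, act, act_last = FALSE)$out
}

#' Decode cell latents to last-hidden outputs
#'
#' Runs the cell decoder, which deliberately has no final linear projection
#' to gene space; the output is the width-`l` last-hidden vector used by
#' the inner-product reconstruction.
#'
#' @param model a [paired_model()].
#' @param z latent matrix `N_b x K`.
#' @return matrix `N_b x l`.
#' @export
decode_cell <- function(model, z) .decode(model, "cell_dec", z)

#' Decode gene latents to last-hidden outputs
#'
#' @param model a [paired_model()].
#' @param z latent matrix `M_b x K`.
#' @return matrix `M_b x l`.
#' @export
decode_gene <- function(model, z) .decode(model, "gene_dec", z)

#' Inner-product reconstruction from decoder last-hidden outputs
#'
#' Entry `(i, j)` is `<h_cell[i, ], h_gene[j, ]> + b_gene[j]`.
#'
#' @param h_cell `N_b x l` cell decoder outputs.
#' @param h_gene `M_b x l` gene decoder outputs.
#' @param b_gene per-gene bias, length `M_b`.
#' @return reconstruction matrix `N_b x M_b`.
#' @export
reconstruct_hidden <- function(h_cell, h_gene, b_gene) {
  h_cell <- as.matrix(h_cell); h_gene <- as.matrix(h_gene)
  if (ncol(h_cell) != ncol(h_gene))
    stop("h_cell and h_gene have different widths")
  if (length(b_gene) != nrow(h_gene))
    stop("b_gene length does not match the number of genes")
  sweep(tcrossprod(h_cell, h_gene), 2L, b_gene, "+")
}

#' Inner-product reconstruction from the latents (alignment path)
#'
#' Same bilinear form as [reconstruct_hidden()] but applied directly to the
#' K-dimensional latents; this is the quantity the alignment regularizer
#' pushes towards the observed expression, which makes individual latent
#' dimensions of the two spaces correspond.
#'
#' @param z_cell `N_b x K` cell latents.
#' @param z_gene `M_b x K` gene latents.
#' @param b_gene per-gene bias, length `M_b`.
#' @return reconstruction matrix `N_b x M_b`.
#' @export
reconstruct_latent <- function(z_cell, z_gene, b_gene)
  reconstruct_hidden(z_cell, z_gene, b_gene)

#' KL divergence of a diagonal Gaussian posterior from N(0, I)
#'
#' Closed form per sample: `0.5 * sum_k (mu^2 + sigma^2 - 1 - log sigma^2)`.
#' Always nonnegative; zero exactly when the posterior equals the prior.
#'
#' @param post a [gaussian_posterior()].
#' @return numeric vector, one nonnegative value per row of `mu`.
#' @export
kl_gaussian <- function(post) {
  stopifnot(inherits(post, "gaussian_posterior"))
  rowSums(0.5 * (post$mu^2 + exp(post$log_var) - 1 - post$log_var))
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single-file archive holding the parameter tensors,
#' configuration, gene identifiers and embedding provenance tag, plus a
#' schema version for forward compatibility.
#'
#' @param model a [paired_model()].
#' @param path file path for the checkpoint.
#' @return `path`, invisibly (for `save_model`); the model (for `load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "paired_model"))
  saveRDS(list(schema = 1L, model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, 1L)) stop("unsupported checkpoint schema: ", ck$schema)
  structure(ck$model, class = "paired_model")
}

#' @export
print.paired_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("paired_model: M = %d genes, D = %d embedding dims, K = %d, l = %d\n",
              x$M, x$D, cfg$K, cfg$l))
  cat(sprintf("  cell hidden: [%s]  gene hidden: [%s]  activation: %s\n",
              paste(cfg$cell_hidden, collapse = ","),
              paste(cfg$gene_hidden, collapse = ","), cfg$activation))
  cat(sprintf("  trained: %s\n", x$trained))
  invisible(x)
}
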