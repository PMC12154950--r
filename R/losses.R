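# Objectives of the three-step schedule, each with its analytic backward
# pass. Conventions (documented in the methods vignette):
#   * reconstruction and cell-KL sums over cells are divided by the batch
#     size N_b, so the loss is batch-size invariant;
#   * the gene KL (steps 2-3) runs over all M genes once per optimization
#     step and is divided by M, balancing it against the per-cell terms;
#   * step 2 uses the frozen cell side in posterior-mean mode by default.

.check_finite_loss <- function(components) {
  bad <- names(components)[!vapply(components, function(x) all(is.finite(x)), logical(1))]
  if (length(bad))
    stop("non-finite loss; diverging term(s): ", paste(bad, collapse = ", "))
}

.rnorm_like <- function(x) matrix(stats::rnorm(length(x)), nrow(x), ncol(x))

# posterior-parameter gradients from dz plus the beta-weighted KL term
.posterior_grads <- function(fw, eps, dz, beta, denom) {
  sd <- exp(0.5 * fw$log_var)
  dmu <- dz + beta * fw$mu / denom
  dlv <- dz * eps * 0.5 * sd + beta * 0.5 * (exp(fw$log_var) - 1) / denom
  list(dmu = dmu, dlv = dlv)
}

.step1_core <- function(model, c_batch, eps, beta, want_grad) {
  p <- model$params; act <- .activation(model$config$activation)
  c_batch <- .check_matrix(c_batch, "expression batch")
  if (ncol(c_batch) != model$M) stop("expression batch column mismatch")
  Nb <- nrow(c_batch)
  if (is.null(eps)) eps <- matrix(stats::rnorm(Nb * model$config$K), Nb, model$config$K)

  enc <- .encoder_forward(p$cell_enc, c_batch, act)
  z <- enc$mu + eps * exp(0.5 * enc$log_var)
  dec <- .mlp_forward(p$cell_dec, z, act, act_last = FALSE)
  chat <- .affine(dec$out, p$head)
  E <- chat - c_batch
  recon <- sum(E^2) / Nb
  kl <- sum(kl_gaussian(gaussian_posterior(enc$mu, enc$log_var))) / Nb
  components <- list(recon = recon, kl_cell = kl, beta = beta)
  .check_finite_loss(components[c("recon", "kl_cell")])
  loss <- recon + beta * kl
  out <- list(loss = loss, components = components)
  if (!want_grad) return(out)

  dchat <- 2 * E / Nb
  g_head <- list(W = crossprod(dec$out, dchat), b = colSums(dchat))
  dh <- tcrossprod(dchat, p$head$W)
  bk_dec <- .mlp_backward(p$cell_dec, dec, dh, act, act_last = FALSE)
  pg <- .posterior_grads(enc, eps, bk_dec$dX, beta, Nb)
  g_enc <- .encoder_backward(p$cell_enc, enc, pg$dmu, pg$dlv, act)
  out$grads <- list(cell_enc = g_enc, cell_dec = bk_dec$grads, head = g_head)
  out
}

# shared forward of the gene side (used by steps 2 and 3)
.gene_forward <- function(model, g_all, eps_gene, act) {
  p <- model$params
  g_all <- .check_matrix(g_all, "gene embedding table")
  if (ncol(g_all) != model$D) stop("gene embedding column mismatch")
  M <- nrow(g_all)
  if (is.null(eps_gene)) eps_gene <- matrix(stats::rnorm(M * model$config$K), M, model$config$K)
  enc <- .encoder_forward(p$gene_enc, g_all, act)
  z <- enc$mu + eps_gene * exp(0.5 * enc$log_var)
  dec <- .mlp_forward(p$gene_dec, z, act, act_last = FALSE)
  list(enc = enc, z = z, dec = dec, eps = eps_gene, M = M)
}

.step2_core <- function(model, c_batch, g_all, eps_gene, beta, want_grad,
                        cell_mode = "mean", eps_cell = NULL) {
  p <- model$params; act <- .activation(model$config$activation)
  c_batch <- .check_matrix(c_batch, "expression batch")
  if (ncol(c_batch) != model$M) stop("expression batch column mismatch")
  Nb <- nrow(c_batch)

  # frozen cell side: no gradients flow here
  enc_c <- .encoder_forward(p$cell_enc, c_batch, act)
  z_c <- if (identical(cell_mode, "mean")) enc_c$mu else {
    if (is.null(eps_cell)) eps_cell <- .rnorm_like(enc_c$mu)
    enc_c$mu + eps_cell * exp(0.5 * enc_c$log_var)
  }
  h_cell <- .mlp_forward(p$cell_dec, z_c, act, act_last = FALSE)$out

  gf <- .gene_forward(model, g_all, eps_gene, act)
  if (gf$M != model$M) stop("step 2 requires the full gene table (all M genes)")
  chat <- reconstruct_hidden(h_cell, gf$dec$out, p$b_gene)
  E <- chat - c_batch
  recon <- sum(E^2) / Nb
  kl_g <- sum(kl_gaussian(gaussian_posterior(gf$enc$mu, gf$enc$log_var))) / gf$M
  components <- list(recon = recon, kl_gene = kl_g, beta = beta)
  .check_finite_loss(components[c("recon", "kl_gene")])
  out <- list(loss = recon + beta * kl_g, components = components)
  if (!want_grad) return(out)

  dchat <- 2 * E / Nb
  dh_g <- crossprod(dchat, h_cell)          # M x l
  db_gene <- colSums(dchat)
  bk_dec <- .mlp_backward(p$gene_dec, gf$dec, dh_g, act, act_last = FALSE)
  pg <- .posterior_grads(gf$enc, gf$eps, bk_dec$dX, beta, gf$M)
  g_enc <- .encoder_backward(p$gene_enc, gf$enc, pg$dmu, pg$dlv, act)
  out$grads <- list(gene_enc = g_enc, gene_dec = bk_dec$grads, b_gene = db_gene)
  out
}

.step3_core <- function(model, c_batch, g_all, eps_cell, eps_gene, beta, gamma,
                        want_grad) {
  p <- model$params; act <- .activation(model$config$activation)
  c_batch <- .check_matrix(c_batch, "expression batch")
  if (ncol(c_batch) != model$M) stop("expression batch column mismatch")
  Nb <- nrow(c_batch)
  if (is.null(eps_cell)) eps_cell <- matrix(stats::rnorm(Nb * model$config$K), Nb, model$config$K)

  enc_c <- .encoder_forward(p$cell_enc, c_batch, act)
  z_c <- enc_c$mu + eps_cell * exp(0.5 * enc_c$log_var)
  dec_c <- .mlp_forward(p$cell_dec, z_c, act, act_last = FALSE)

  gf <- .gene_forward(model, g_all, eps_gene, act)
  if (gf$M != model$M) stop("step 3 requires the full gene table (all M genes)")

  b_align <- if (model$config$shared_bias) p$b_gene else p$b_align
  chat <- reconstruct_hidden(dec_c$out, gf$dec$out, p$b_gene)
  ahat <- reconstruct_latent(z_c, gf$z, b_align)
  E <- chat - c_batch
  A <- ahat - c_batch
  recon <- sum(E^2) / Nb
  align <- sum(A^2) / Nb
  kl_c <- sum(kl_gaussian(gaussian_posterior(enc_c$mu, enc_c$log_var))) / Nb
  kl_g <- sum(kl_gaussian(gaussian_posterior(gf$enc$mu, gf$enc$log_var))) / gf$M
  components <- list(recon = recon, align = align, kl_cell = kl_c,
                     kl_gene = kl_g, beta = beta, gamma = gamma)
  .check_finite_loss(components[c("recon", "align", "kl_cell", "kl_gene")])
  out <- list(loss = recon + gamma * align + beta * (kl_c + kl_g),
              components = components)
  if (!want_grad) return(out)

  dchat <- 2 * E / Nb
  dahat <- 2 * gamma * A / Nb
  # hidden-path gradients
  dh_c <- dchat %*% gf$dec$out              # N_b x l
  dh_g <- crossprod(dchat, dec_c$out)       # M x l
  db_hidden <- colSums(dchat)
  db_align <- colSums(dahat)
  bk_dec_c <- .mlp_backward(p$cell_dec, dec_c, dh_c, act, act_last = FALSE)
  bk_dec_g <- .mlp_backward(p$gene_dec, gf$dec, dh_g, act, act_last = FALSE)
  # alignment-path gradients enter the latents directly
  dz_c <- bk_dec_c$dX + dahat %*% gf$z
  dz_g <- bk_dec_g$dX + crossprod(dahat, z_c)
  pg_c <- .posterior_grads(enc_c, eps_cell, dz_c, beta, Nb)
  pg_g <- .posterior_grads(gf$enc, gf$eps, dz_g, beta, gf$M)
  g_enc_c <- .encoder_backward(p$cell_enc, enc_c, pg_c$dmu, pg_c$dlv, act)
  g_enc_g <- .encoder_backward(p$gene_enc, gf$enc, pg_g$dmu, pg_g$dlv, act)
  grads <- list(cell_enc = g_enc_c, cell_dec = bk_dec_c$grads,
                gene_enc = g_enc_g, gene_dec = bk_dec_g$grads)
  if (model$config$shared_bias) {
    grads$b_gene <- db_hidden + db_align
  } else {
    grads$b_gene <- db_hidden
    grads$b_align <- db_align
  }
  out$grads <- grads
  out
}

#' Step-1 objective: cell VAE with a linear reconstruction head
#'
#' Per-cell squared reconstruction error of the expression profile through
#' the cell VAE and the linear head (`c_hat = h_cell %*% W_cell + b_head`),
#' plus `beta` times the cell KL. Sums over the batch are divided by the
#' batch size.
#'
#' @param model a [paired_model()].
#' @param c_batch `N_b x M` expression batch.
#' @param eps optional explicit standard-normal draw (`N_b x K`); drawn
#'   from the RNG when NULL.
#' @param beta KL weight in effect.
#' @return list with `loss` (scalar) and `components` (named list).
#' @export
loss_step1 <- function(model, c_batch, eps = NULL, beta = 0) {
  .step1_core(model, c_batch, eps, beta, want_grad = FALSE)[c("loss", "components")]
}

#' Step-2 objective: gene VAE against the frozen cell side
#'
#' Reconstruction of the expression batch via the inner product of frozen
#' cell decoder outputs with gene decoder outputs over all M genes, plus
#' `beta` times the gene KL (averaged over genes).
#'
#' @inheritParams loss_step1
#' @param g_all full `M x D` static gene-embedding matrix.
#' @param eps_gene optional explicit `M x K` standard-normal draw.
#' @param cell_mode "mean" (default) uses the frozen posterior means for
#'   the cell side; "sample" draws `eps_cell`.
#' @param eps_cell optional cell-side draw when `cell_mode = "sample"`.
#' @return list with `loss` and `components`.
#' @export
loss_step2 <- function(model, c_batch, g_all, eps_gene = NULL, beta = 0,
                       cell_mode = c("mean", "sample"), eps_cell = NULL) {
  cell_mode <- match.arg(cell_mode)
  .step2_core(model, c_batch, g_all, eps_gene, beta, want_grad = FALSE,
              cell_mode = cell_mode, eps_cell = eps_cell)[c("loss", "components")]
}

#' Step-3 objective: joint optimization with the alignment regularizer
#'
#' Hidden-path reconstruction plus `gamma` times the latent alignment
#' reconstruction plus `beta` times both KL terms.
#'
#' @inheritParams loss_step2
#' @param eps_cell optional explicit `N_b x K` draw for the cell side.
#' @param gamma alignment weight (default 0.05).
#' @return list with `loss` and `components`.
#' @export
loss_step3 <- function(model, c_batch, g_all, eps_cell = NULL,
                       eps_gene = NULL, beta = 0, gamma = 0.05) {
  .step3_core(model, c_batch, g_all, eps_cell, eps_gene, beta, gamma,
              want_grad = FALSE)[c("loss", "components")]
}
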