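# Shared fixtures: tiny models, small synthetic datasets, finite-difference
# gradients and two-loop loss oracles (independent of the vectorized paths).

tiny_model <- function(M = 7, D = 4, K = 3, l = 4, seed = 1,
                       activation = "softplus") {
  paired_model(M, D, model_config(K = K, l = l, cell_hidden = 5L,
                                  gene_hidden = 6L, activation = activation,
                                  seed = seed))
}

small_sim <- function(seed = 1, ...) {
  sim_config(n_cells = 120L, n_genes = 60L, n_cell_types = 3L, n_batches = 2L,
             n_modules = 3L, latent_rank = 4L, embedding_dim = 8L,
             seed = seed, ...)
}

fast_tcfg <- function(seed = 1, epochs = c(10L, 10L, 10L), ...) {
  train_config(epochs_per_step = epochs, batch_size = 64L, seed = seed, ...)
}

small_mcfg <- function(seed = 1) {
  model_config(K = 6L, l = 8L, cell_hidden = 32L, gene_hidden = 16L,
               seed = seed)
}

# central finite differences over a parameter subtree
numeric_gradient <- function(loss_fn, params, h = 1e-6) {
  gr <- params
  walk <- function(path) {
    node <- params[[path]]
    if (is.list(node)) {
      for (nm in names(node)) walk(c(path, nm))
      return(invisible())
    }
    g <- node
    for (i in seq_along(node)) {
      p2 <- params
      v <- p2[[path]]; v[i] <- v[i] + h; p2[[path]] <- v
      up <- loss_fn(p2)
      v[i] <- v[i] - 2 * h; p2[[path]] <- v
      dn <- loss_fn(p2)
      g[i] <- (up - dn) / (2 * h)
    }
    gr[[path]] <<- g
  }
  for (nm in names(params)) walk(nm)
  gr
}

max_tree_diff <- function(a, b) {
  if (is.list(a)) max(vapply(seq_along(a),
                             function(i) max_tree_diff(a[[i]], b[[i]]),
                             numeric(1)))
  else max(abs(a - b))
}

# per-row encoding/decoding through the package primitives; loss assembly
# (inner products, bias broadcast, batch scaling) recomputed with explicit
# scalar loops
kl_scalar <- function(mu, lv) sum(0.5 * (mu^2 + exp(lv) - 1 - lv))

oracle_step1 <- function(model, cb, eps, beta) {
  Nb <- nrow(cb)
  W <- model$params$head$W; bh <- model$params$head$b
  recon <- 0; kl <- 0
  for (i in seq_len(Nb)) {
    post <- encode_cell(model, cb[i, , drop = FALSE])
    z <- post$mu + eps[i, , drop = FALSE] * exp(0.5 * post$log_var)
    h <- decode_cell(model, z)
    for (j in seq_len(ncol(cb))) {
      chat <- sum(h * W[, j]) + bh[j]
      recon <- recon + (cb[i, j] - chat)^2
    }
    kl <- kl + kl_scalar(post$mu, post$log_var)
  }
  recon / Nb + beta * kl / Nb
}

oracle_step2 <- function(model, cb, G, eps_gene, beta) {
  Nb <- nrow(cb); M <- nrow(G)
  bg <- model$params$b_gene
  post_c <- encode_cell(model, cb)
  h_c <- decode_cell(model, post_c$mu)  # frozen side, mean mode
  recon <- 0; klg <- 0
  for (j in seq_len(M)) {
    post_g <- encode_gene(model, G[j, , drop = FALSE])
    z_g <- post_g$mu + eps_gene[j, , drop = FALSE] * exp(0.5 * post_g$log_var)
    h_g <- decode_gene(model, z_g)
    for (i in seq_len(Nb)) {
      chat <- sum(h_c[i, ] * h_g) + bg[j]
      recon <- recon + (cb[i, j] - chat)^2
    }
    klg <- klg + kl_scalar(post_g$mu, post_g$log_var)
  }
  recon / Nb + beta * klg / M
}

oracle_step3 <- function(model, cb, G, eps_cell, eps_gene, beta, gamma) {
  Nb <- nrow(cb); M <- nrow(G)
  bg <- model$params$b_gene
  recon <- 0; align <- 0; klc <- 0; klg <- 0
  z_c <- h_c <- vector("list", Nb)
  for (i in seq_len(Nb)) {
    post <- encode_cell(model, cb[i, , drop = FALSE])
    z_c[[i]] <- post$mu + eps_cell[i, , drop = FALSE] * exp(0.5 * post$log_var)
    h_c[[i]] <- decode_cell(model, z_c[[i]])
    klc <- klc + kl_scalar(post$mu, post$log_var)
  }
  z_g <- h_g <- vector("list", M)
  for (j in seq_len(M)) {
    post <- encode_gene(model, G[j, , drop = FALSE])
    z_g[[j]] <- post$mu + eps_gene[j, , drop = FALSE] * exp(0.5 * post$log_var)
    h_g[[j]] <- decode_gene(model, z_g[[j]])
    klg <- klg + kl_scalar(post$mu, post$log_var)
  }
  for (i in seq_len(Nb)) for (j in seq_len(M)) {
    recon <- recon + (cb[i, j] - (sum(h_c[[i]] * h_g[[j]]) + bg[j]))^2
    align <- align + (cb[i, j] - (sum(z_c[[i]] * z_g[[j]]) + bg[j]))^2
  }
  recon / Nb + gamma * align / Nb + beta * (klc / Nb + klg / M)
}

# leave-one-gene-out evaluation used by the acceptance harness: trains once
# on all-but-target-set (the batched fast path) and imputes each target
logo_mean_pcc <- function(seed, embedding_mode, n_targets = 10,
                          epochs = c(60L, 60L, 120L)) {
  ds <- generate(sim_config(seed = seed, embedding_mode = embedding_mode))
  set.seed(seed + 1000L)
  targets <- sample(ds$expr$gene_ids, n_targets)
  keep <- setdiff(ds$expr$gene_ids, targets)
  expr_m <- expression_matrix(ds$expr$values[, keep], ds$expr$cell_ids, keep,
                              batch = ds$expr$batch,
                              cell_type = ds$expr$cell_type)
  tab_m <- gene_embedding_table(ds$table$vectors[keep, , drop = FALSE], keep,
                                ds$table$source_tag)
  m <- fit(expr_m, tab_m, model_config(seed = seed),
           train_config(seed = seed, epochs_per_step = epochs))$model
  pccs <- vapply(targets, function(g) {
    pred <- impute_gene(expr_m, ds$table, g, model = m)
    stats::cor(pred, ds$expr$values[, g])
  }, numeric(1))
  mean(pccs)
}
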