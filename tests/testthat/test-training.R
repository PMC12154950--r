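test_that("beta warm-up ramps linearly and degenerates correctly", {
  cfg <- train_config(beta_warmup_epochs = 10L, beta_max = 1)
  expect_equal(beta_schedule(0, cfg), 0)
  expect_equal(beta_schedule(5, cfg), 0.5)
  expect_equal(beta_schedule(10, cfg), 1)
  expect_equal(beta_schedule(50, cfg), 1)
  cfg0 <- train_config(beta_warmup_epochs = 0L, beta_max = 0.7)
  expect_equal(beta_schedule(0, cfg0), 0.7)
  expect_equal(beta_schedule(3, cfg0), 0.7)
})

test_that("step objectives match the two-loop oracles and are additive in beta", {
  set.seed(4)
  m <- tiny_model(M = 3, D = 2, K = 2, l = 3)
  cb <- matrix(rnorm(4 * 3), 4, 3)
  G <- matrix(rnorm(3 * 2), 3, 2)
  eps_c <- matrix(rnorm(4 * 2), 4, 2)
  eps_g <- matrix(rnorm(3 * 2), 3, 2)

  l1_0 <- loss_step1(m, cb, eps = eps_c, beta = 0)
  expect_equal(l1_0$loss, oracle_step1(m, cb, eps_c, 0), tolerance = 1e-10)
  l1_b <- loss_step1(m, cb, eps = eps_c, beta = 0.4)
  expect_equal(l1_b$loss, l1_0$loss + 0.4 * l1_b$components$kl_cell,
               tolerance = 1e-10)
  expect_equal(l1_b$loss, oracle_step1(m, cb, eps_c, 0.4), tolerance = 1e-10)

  l2 <- loss_step2(m, cb, G, eps_gene = eps_g, beta = 0.4)
  expect_equal(l2$loss, oracle_step2(m, cb, G, eps_g, 0.4), tolerance = 1e-10)
  # KL term equals kl_gaussian summed over genes (M-averaged)
  expect_equal(l2$components$kl_gene,
               sum(kl_gaussian(encode_gene(m, G))) / nrow(G))

  l3 <- loss_step3(m, cb, G, eps_cell = eps_c, eps_gene = eps_g,
                   beta = 0.4, gamma = 0.05)
  expect_equal(l3$loss, oracle_step3(m, cb, G, eps_c, eps_g, 0.4, 0.05),
               tolerance = 1e-10)
  # bookkeeping identity: total equals the weighted component sum
  cmp <- l3$components
  expect_equal(l3$loss,
               cmp$recon + 0.05 * cmp$align + 0.4 * (cmp$kl_cell + cmp$kl_gene),
               tolerance = 1e-8)
})

test_that("gamma = 0 reduces step 3 to the step-2 objective plus the cell KL", {
  set.seed(5)
  m <- tiny_model(M = 4, D = 3, K = 2, l = 3)
  cb <- matrix(rnorm(5 * 4), 5, 4)
  G <- matrix(rnorm(4 * 3), 4, 3)
  eps_g <- matrix(rnorm(4 * 2), 4, 2)
  zero_eps <- matrix(0, 5, 2)  # pins the cell side at its posterior mean
  l3 <- loss_step3(m, cb, G, eps_cell = zero_eps, eps_gene = eps_g,
                   beta = 0.2, gamma = 0)
  l2 <- loss_step2(m, cb, G, eps_gene = eps_g, beta = 0.2)
  kl_c <- sum(kl_gaussian(encode_cell(m, cb))) / nrow(cb)
  expect_equal(l3$loss, l2$loss + 0.2 * kl_c, tolerance = 1e-10)
  # the alignment term is additive, never substitutive
  l3g <- loss_step3(m, cb, G, eps_cell = zero_eps, eps_gene = eps_g,
                    beta = 0.2, gamma = 0.05)
  expect_equal(l3g$components$recon, l3$components$recon)
  expect_gte(l3g$loss, l3$loss)
})

test_that("perfect linear reconstruction drives the step-1 loss to zero", {
  # rank-l data and a hand-built identity pathway: encoder mu = first K
  # coords, decoder identity, head maps h back to the generating basis
  K <- 2; l <- 2; M <- 4; N <- 6
  mcfg <- model_config(K = K, l = l, cell_hidden = integer(0),
                       gene_hidden = integer(0), activation = "identity",
                       seed = 1)
  m <- paired_model(M, 2, mcfg)
  set.seed(6)
  basis <- matrix(rnorm(K * M), K, M)
  scores <- matrix(rnorm(N * K), N, K)
  cb <- scores %*% basis
  # encoder: mu = c %*% t(pseudoinverse(basis)); here basis has full row rank
  pinv <- t(basis) %*% solve(basis %*% t(basis))
  m$params$cell_enc$mu$W <- pinv
  m$params$cell_enc$mu$b <- rep(0, K)
  m$params$cell_enc$logvar$W <- matrix(0, M, K)
  m$params$cell_enc$logvar$b <- rep(-15, K)  # variance ~ 0
  m$params$cell_dec$layer1$W <- diag(K)
  m$params$cell_dec$layer1$b <- rep(0, l)
  m$params$head$W <- basis
  m$params$head$b <- rep(0, M)
  res <- loss_step1(m, cb, eps = matrix(0, N, K), beta = 0)
  expect_lt(res$loss, 1e-12)
})

test_that("fit reduces the step-1 loss, freezes the cell side in step 2, and is seed-reproducible", {
  ds <- generate(small_sim(seed = 3))
  out <- fit(ds$expr, ds$table, small_mcfg(seed = 3), fast_tcfg(seed = 3))
  log1 <- out$log[out$log$step == 1, ]
  expect_lt(log1$loss[nrow(log1)], log1$loss[1])
  expect_true(all(is.finite(out$log$loss)))
  # squared errors and KLs are nonnegative in every epoch record
  expect_true(all(out$log$recon >= 0, na.rm = TRUE))
  expect_true(all(out$log$kl_cell >= 0, na.rm = TRUE))
  expect_true(all(out$log$kl_gene >= 0, na.rm = TRUE))
  expect_true(all(out$log$align >= 0, na.rm = TRUE))
  expect_true(all(diff(order(out$log$step, out$log$epoch)) == 1))

  # cell-side parameters after step 2 are bit-identical to the step-1 snapshot
  out12 <- fit(ds$expr, ds$table, small_mcfg(seed = 3), fast_tcfg(seed = 3),
               steps = 1:2)
  expect_identical(out12$model$params[c("cell_enc", "cell_dec", "head")],
                   out12$model$snapshots$step1_cell_side)

  # identical seeds and configs give identical logs
  out2 <- fit(ds$expr, ds$table, small_mcfg(seed = 3), fast_tcfg(seed = 3))
  expect_identical(out$log, out2$log)
  expect_identical(out$model$params, out2$model$params)
})

test_that("step-2 gradients never touch cell-side parameters", {
  set.seed(8)
  m <- tiny_model()
  cb <- matrix(rnorm(5 * 7), 5, 7)
  G <- matrix(rnorm(7 * 4), 7, 4)
  res <- scPairVAE:::.step2_core(m, cb, G, matrix(rnorm(7 * 3), 7, 3),
                                 0.1, TRUE)
  expect_named(res$grads, c("gene_enc", "gene_dec", "b_gene"))
  expect_false(any(c("cell_enc", "cell_dec", "head") %in% names(res$grads)))
})

test_that("fit requires gene-aligned inputs", {
  ds <- generate(small_sim(seed = 1))
  tab_bad <- gene_embedding_table(ds$table$vectors,
                                  rev(ds$table$gene_ids))
  expect_error(fit(ds$expr, tab_bad, small_mcfg(), fast_tcfg()),
               "align_genes")
})
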