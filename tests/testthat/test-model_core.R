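test_that("encoders return finite posteriors with contract shapes and determinism", {
  m <- tiny_model()
  cb <- matrix(rnorm(5 * 7), 5, 7)
  post <- encode_cell(m, cb)
  expect_equal(dim(post$mu), c(5L, 3L))
  expect_equal(dim(post$log_var), c(5L, 3L))
  expect_true(all(is.finite(post$mu)) && all(is.finite(post$log_var)))

  # identical rows give identical posterior rows
  cb2 <- cb[c(1, 1, 3), ]
  post2 <- encode_cell(m, cb2)
  expect_equal(post2$mu[1, ], post2$mu[2, ])

  g <- matrix(rnorm(4 * 4), 4, 4)
  pg <- encode_gene(m, g)
  expect_equal(dim(pg$mu), c(4L, 3L))
  pg2 <- encode_gene(m, g[c(2, 2), ])
  expect_equal(pg2$mu[1, ], pg2$mu[2, ])

  expect_error(encode_cell(m, cb[, 1:6]), "M = 7")
  expect_error(encode_gene(m, g[, 1:3]), "D = 4")
  cb[1, 1] <- NaN
  expect_error(encode_cell(m, cb), "NaN")
})

test_that("reparameterize implements z = mu + eps * exp(0.5 log_var)", {
  post <- gaussian_posterior(matrix(c(1, -2), 1, 2), matrix(c(log(4), 0), 1, 2))
  expect_equal(reparameterize(post, matrix(0, 1, 2)),
               matrix(c(1, -2), 1, 2))
  expect_equal(reparameterize(post, matrix(c(0.5, 1), 1, 2)),
               matrix(c(2, -1), 1, 2))
  zero <- gaussian_posterior(matrix(0, 2, 3), matrix(0, 2, 3))
  e <- matrix(rnorm(6), 2, 3)
  expect_equal(reparameterize(zero, e), e)
  expect_error(reparameterize(post, matrix(0, 2, 2)), "shape")
})

test_that("decoders emit width-l last-hidden outputs deterministically", {
  m <- tiny_model()
  z <- matrix(rnorm(3 * 3), 3, 3)
  h <- decode_cell(m, z)
  expect_equal(dim(h), c(3L, 4L))
  h2 <- decode_cell(m, z[c(1, 1), ])
  expect_equal(h2[1, ], h2[2, ])
  hg <- decode_gene(m, z)
  expect_equal(dim(hg), c(3L, 4L))
  expect_error(decode_cell(m, cbind(z, 1)), "K = 3")
})

test_that("inner-product reconstructions match hand values and a two-loop oracle", {
  expect_equal(reconstruct_hidden(matrix(c(1, 0), 1), matrix(c(0, 1), 1), 0),
               matrix(0, 1, 1))
  expect_equal(reconstruct_hidden(matrix(c(1, 2), 1), matrix(c(3, 4), 1), 1),
               matrix(12, 1, 1))
  expect_equal(reconstruct_latent(matrix(c(1, 1), 1), matrix(c(1, -1), 1), 0),
               matrix(0, 1, 1))
  expect_equal(reconstruct_latent(matrix(2, 1, 1), matrix(3, 1, 1), 0.5),
               matrix(6.5, 1, 1))
  # zero latents -> bias-only rows
  b <- c(1, -2, 3)
  expect_equal(reconstruct_latent(matrix(0, 2, 2), matrix(0, 3, 2), b),
               matrix(b, 2, 3, byrow = TRUE))
  # bias is broadcast per gene: columns differ only through h_cell
  hc <- matrix(rnorm(4), 2, 2); hg <- matrix(rnorm(2), 1, 2)
  r <- reconstruct_hidden(hc, hg, 5)
  expect_equal(r[1, 1] - r[2, 1], sum((hc[1, ] - hc[2, ]) * hg[1, ]))

  set.seed(3)
  for (rep in 1:3) {
    A <- matrix(rnorm(5 * 4), 5, 4); B <- matrix(rnorm(3 * 4), 3, 4)
    bb <- rnorm(3)
    r <- reconstruct_hidden(A, B, bb)
    for (i in 1:5) for (j in 1:3)
      expect_equal(r[i, j], sum(A[i, ] * B[j, ]) + bb[j])
  }
  expect_error(reconstruct_hidden(matrix(0, 1, 2), matrix(0, 1, 3), 0),
               "width")
})

test_that("kl_gaussian matches the closed form and is nonnegative", {
  expect_equal(kl_gaussian(gaussian_posterior(matrix(0, 1, 3), matrix(0, 1, 3))),
               0)
  expect_equal(kl_gaussian(gaussian_posterior(matrix(1, 1, 1), matrix(0, 1, 1))),
               0.5)
  expect_equal(kl_gaussian(gaussian_posterior(matrix(0, 1, 1), matrix(1, 1, 1))),
               0.5 * (exp(1) - 1 - 1), tolerance = 1e-10)
  set.seed(11)
  for (rep in 1:20) {
    post <- gaussian_posterior(matrix(rnorm(8), 2, 4),
                               matrix(runif(8, -2, 2), 2, 4))
    expect_true(all(kl_gaussian(post) >= 0))
  }
})

test_that("analytic gradients of all three objectives match finite differences", {
  set.seed(2)
  m <- tiny_model()
  cb <- matrix(rnorm(5 * 7), 5, 7)
  G <- matrix(rnorm(7 * 4), 7, 4)
  eps_c <- matrix(rnorm(5 * 3), 5, 3)
  eps_g <- matrix(rnorm(7 * 3), 7, 3)

  with_params <- function(p) { m2 <- m; m2$params[names(p)] <- p; m2 }

  s1 <- scPairVAE:::.step1_core(m, cb, eps_c, 0.3, TRUE)
  sub <- c("cell_enc", "cell_dec", "head")
  ng <- numeric_gradient(function(p)
    scPairVAE:::.step1_core(with_params(p), cb, eps_c, 0.3, FALSE)$loss,
    m$params[sub])
  expect_lt(max_tree_diff(s1$grads[sub], ng), 1e-5)

  s2 <- scPairVAE:::.step2_core(m, cb, G, eps_g, 0.3, TRUE)
  sub <- c("gene_enc", "gene_dec", "b_gene")
  ng <- numeric_gradient(function(p)
    scPairVAE:::.step2_core(with_params(p), cb, G, eps_g, 0.3, FALSE)$loss,
    m$params[sub])
  expect_lt(max_tree_diff(s2$grads[sub], ng), 1e-5)

  s3 <- scPairVAE:::.step3_core(m, cb, G, eps_c, eps_g, 0.3, 0.05, TRUE)
  sub <- c("cell_enc", "cell_dec", "gene_enc", "gene_dec", "b_gene")
  ng <- numeric_gradient(function(p)
    scPairVAE:::.step3_core(with_params(p), cb, G, eps_c, eps_g, 0.3, 0.05,
                            FALSE)$loss,
    m$params[sub])
  expect_lt(max_tree_diff(s3$grads[sub], ng), 1e-5)
})

test_that("full forward pass is deterministic given parameters and fixed eps", {
  m <- tiny_model()
  cb <- matrix(rnorm(4 * 7), 4, 7)
  eps <- matrix(rnorm(4 * 3), 4, 3)
  pass <- function() {
    z <- reparameterize(encode_cell(m, cb), eps)
    decode_cell(m, z)
  }
  expect_identical(pass(), pass())
})

test_that("model checkpoints round-trip through save/load", {
  m <- tiny_model()
  m$gene_ids <- paste0("g", 1:7)
  m$source_tag <- "test"
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$gene_ids, m$gene_ids)
  expect_s3_class(m2, "paired_model")
})
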