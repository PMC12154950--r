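# Dense-layer plumbing shared by the cell and gene networks: parameter
# trees (nested named lists with numeric leaves), MLP forward/backward,
# activations, and an Adam optimizer with global-norm gradient clipping.
# All of it is internal; user-facing entry points live in model.R/train.R.

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

.activation <- function(name) {
  switch(name,
    softplus = list(f = softplus, df = function(x) stats::plogis(x)),
    relu     = list(f = function(x) pmax(x, 0), df = function(x) (x > 0) + 0),
    tanh     = list(f = tanh, df = function(x) 1 - tanh(x)^2),
    identity = list(f = identity, df = function(x) x * 0 + 1),
    stop("unknown activation: ", name)
  )
}

# fan-in scaled Gaussian init; biases start at zero
.linear_init <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = 1 / sqrt(n_in)), n_in, n_out),
       b = numeric(n_out))
}

# sizes: vector of widths c(in, hidden..., out); returns named list of layers
.mlp_init <- function(sizes) {
  stopifnot(length(sizes) >= 2)
  layers <- vector("list", length(sizes) - 1L)
  for (k in seq_along(layers)) layers[[k]] <- .linear_init(sizes[k], sizes[k + 1L])
  names(layers) <- paste0("layer", seq_along(layers))
  layers
}

.affine <- function(X, layer) sweep(X %*% layer$W, 2L, layer$b, "+")

# act_last = FALSE leaves the final layer affine (used by the decoders so the
# inner-product reconstruction is not constrained in sign)
.mlp_forward <- function(layers, X, act, act_last = TRUE) {
  L <- length(layers)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1L]] <- X
  for (k in seq_len(L)) {
    Z[[k]] <- .affine(A[[k]], layers[[k]])
    A[[k + 1L]] <- if (k < L || act_last) act$f(Z[[k]]) else Z[[k]]
  }
  list(out = A[[L + 1L]], A = A, Z = Z)
}

.mlp_backward <- function(layers, cache, dOut, act, act_last = TRUE) {
  L <- length(layers)
  grads <- vector("list", L); names(grads) <- names(layers)
  dA <- dOut
  for (k in rev(seq_len(L))) {
    dZ <- if (k < L || act_last) dA * act$df(cache$Z[[k]]) else dA
    grads[[k]] <- list(W = crossprod(cache$A[[k]], dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[k]]$W)
  }
  list(grads = grads, dX = dA)
}

# --- encoder: optional MLP trunk + two linear heads (mu, log-variance) ------

.encoder_init <- function(n_in, hidden, K) {
  trunk <- if (length(hidden)) .mlp_init(c(n_in, hidden)) else list()
  width <- if (length(hidden)) hidden[length(hidden)] else n_in
  list(trunk = trunk, mu = .linear_init(width, K), logvar = .linear_init(width, K))
}

LOGVAR_CLAMP <- 15

.encoder_forward <- function(enc, X, act) {
  tr <- if (length(enc$trunk)) .mlp_forward(enc$trunk, X, act, act_last = TRUE)
        else list(out = X)
  H <- tr$out
  mu <- .affine(H, enc$mu)
  lv_raw <- .affine(H, enc$logvar)
  lv <- pmin(pmax(lv_raw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  list(mu = mu, log_var = lv, H = H, trunk_cache = tr,
       clamp_mask = (lv_raw > -LOGVAR_CLAMP & lv_raw < LOGVAR_CLAMP) + 0)
}

.encoder_backward <- function(enc, cache, dmu, dlv, act) {
  dlv <- dlv * cache$clamp_mask  # no gradient through the clamp
  grads <- list(
    mu = list(W = crossprod(cache$H, dmu), b = colSums(dmu)),
    logvar = list(W = crossprod(cache$H, dlv), b = colSums(dlv))
  )
  dH <- tcrossprod(dmu, enc$mu$W) + tcrossprod(dlv, enc$logvar$W)
  if (length(enc$trunk)) {
    bk <- .mlp_backward(enc$trunk, cache$trunk_cache, dH, act, act_last = TRUE)
    grads$trunk <- bk$grads
  } else {
    grads$trunk <- list()
  }
  grads[c("trunk", "mu", "logvar")]
}

# --- parameter-tree helpers -------------------------------------------------

.tree_map <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1L]]
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a))
      out[[i]] <- do.call(.tree_map, c(list(f), lapply(trees, `[[`, i)))
    out
  } else {
    do.call(f, trees)
  }
}

.tree_sumsq <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, .tree_sumsq, numeric(1))) else sum(tree^2)
}

.tree_zero <- function(tree) .tree_map(function(x) x * 0, tree)

# --- Adam -------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = .tree_zero(params), v = .tree_zero(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, clip = 5) {
  grads <- .tree_map(function(g) {
    if (is.matrix(g)) dimnames(g) <- NULL else names(g) <- NULL
    g
  }, grads)
  if (is.finite(clip)) {
    gn <- sqrt(.tree_sumsq(grads))
    if (gn > clip) grads <- .tree_map(function(g) g * (clip / gn), grads)
  }
  state$t <- state$t + 1L
  state$m <- .tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  params <- .tree_map(
    function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
    params, state$m, state$v
  )
  list(params = params, state = state)
}
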