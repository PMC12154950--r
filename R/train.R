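#' Training configuration for the three-step schedule
#'
#' @param epochs_per_step three positive integers: epochs for step 1 (cell
#'   VAE pretraining), step 2 (gene VAE pretraining against the frozen cell
#'   side) and step 3 (joint optimization with the alignment term).
#' @param batch_size cells per minibatch; the gene side always processes
#'   all M genes per optimization step.
#' @param learning_rate Adam learning rate.
#' @param beta_warmup_epochs epochs over which the KL weight ramps
#'   linearly from 0 to `beta_max`; the ramp restarts at each step.
#' @param beta_max KL weight ceiling (kept small so reconstruction
#'   dominates early training).
#' @param gamma alignment weight for step 3 (default 0.05).
#' @param seed integer seed driving minibatch order and all noise draws.
#' @param early_stop_patience optional integer; stop a step when its
#'   epoch loss has not improved for this many epochs.
#' @param grad_clip global gradient-norm clip (stabilizes the
#'   inner-product decoder); `Inf` disables.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs_per_step = c(100L, 100L, 200L),
                         batch_size = 128L, learning_rate = 1e-3,
                         beta_warmup_epochs = 10L, beta_max = 1e-2,
                         gamma = 0.05, seed = 0L,
                         early_stop_patience = NULL, grad_clip = 5) {
  stopifnot(length(epochs_per_step) == 3, all(epochs_per_step >= 1),
            batch_size >= 1, learning_rate > 0, beta_warmup_epochs >= 0,
            beta_max >= 0, gamma >= 0)
  structure(list(epochs_per_step = as.integer(epochs_per_step),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 beta_warmup_epochs = as.integer(beta_warmup_epochs),
                 beta_max = beta_max, gamma = gamma, seed = as.integer(seed),
                 early_stop_patience = early_stop_patience,
                 grad_clip = grad_clip),
            class = "train_config")
}

#' KL weight warm-up schedule
#'
#' Linear ramp from 0 at epoch 0 to `beta_max` at `beta_warmup_epochs`,
#' constant afterwards; with a zero-length warm-up the weight is
#' `beta_max` from the first epoch.
#'
#' @param epoch zero-based epoch index within the current step.
#' @param cfg a [train_config()].
#' @return the KL weight in effect.
#' @export
beta_schedule <- function(epoch, cfg) {
  stopifnot(epoch >= 0)
  if (cfg$beta_warmup_epochs == 0) return(cfg$beta_max)
  min(1, epoch / cfg$beta_warmup_epochs) * cfg$beta_max
}

.log_row <- function(step, epoch, beta, loss, comp) {
  data.frame(step = step, epoch = epoch, beta = beta, loss = loss,
             recon = comp$recon %||% NA_real_,
             kl_cell = comp$kl_cell %||% NA_real_,
             kl_gene = comp$kl_gene %||% NA_real_,
             align = comp$align %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the paired model with the three-step schedule
#'
#' Step 1 trains the cell VAE alone against the linear reconstruction
#' head. Its cell-side parameters are then snapshotted and held frozen
#' (bit-identical) throughout step 2, which trains the gene VAE to
#' reconstruct expression through the inner-product decoder. Step 3
#' optimizes all parameters jointly, adding the latent alignment
#' regularizer weighted by `gamma`. Identical seeds and configurations
#' yield identical training logs and parameters.
#'
#' @param expr an [expression_matrix()] of scaled log-normalized values.
#' @param table a [gene_embedding_table()] aligned to `expr` (same genes,
#'   same order; see [align_genes()]).
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param steps which steps to run (default `1:3`); earlier steps must be
#'   included for later ones to be meaningful. `steps = 1` trains the cell
#'   VAE alone.
#' @return list with `model` (trained [paired_model()], carrying the
#'   step-1 cell-side snapshot in `$snapshots`) and `log` (per-epoch
#'   data.frame of loss components and the KL weight in effect).
#' @export
fit <- function(expr, table, mcfg = model_config(), tcfg = train_config(),
                steps = 1:3) {
  stopifnot(all(steps %in% 1:3))
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(table, "gene_embedding_table"))
  if (!identical(expr$gene_ids, table$gene_ids))
    stop("expression and embedding tables are not gene-aligned; run align_genes() first")
  X <- expr$values
  G <- table$vectors
  N <- nrow(X); M <- ncol(X)
  model <- paired_model(M, ncol(G), mcfg, gene_ids = expr$gene_ids)
  model$source_tag <- table$source_tag

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(tcfg$seed)

  logs <- list()
  last_good <- model
  diverged <- FALSE

  run_step <- function(step_id, n_epochs, subtree, core_fn) {
    st <- .adam_init(model$params[subtree])
    best <- Inf; stale <- 0L
    for (epoch in seq_len(n_epochs)) {
      beta <- beta_schedule(epoch - 1L, tcfg)
      idx <- sample.int(N)
      starts <- seq(1L, N, by = tcfg$batch_size)
      acc <- NULL; nb <- 0L
      ok <- tryCatch({
        for (s in starts) {
          rows <- idx[s:min(s + tcfg$batch_size - 1L, N)]
          res <- core_fn(model, X[rows, , drop = FALSE], beta)
          upd <- .adam_step(model$params[subtree], res$grads[subtree], st,
                            lr = tcfg$learning_rate, clip = tcfg$grad_clip)
          model$params[subtree] <<- upd$params
          st <- upd$state
          nb <- nb + 1L
          comp <- c(res$components, list(loss = res$loss))
          acc <- if (is.null(acc)) comp else Map(`+`, acc, comp)
        }
        TRUE
      }, error = function(e) {
        warning("training step ", step_id, " diverged at epoch ", epoch,
                ": ", conditionMessage(e), "; returning last good checkpoint",
                call. = FALSE)
        FALSE
      })
      if (!ok) { diverged <<- TRUE; return(invisible(FALSE)) }
      mean_comp <- lapply(acc, function(v) v / nb)
      logs[[length(logs) + 1L]] <<-
        .log_row(step_id, epoch, beta, mean_comp$loss, mean_comp)
      last_good <<- model
      if (!is.null(tcfg$early_stop_patience)) {
        if (mean_comp$loss < best - 1e-8) { best <- mean_comp$loss; stale <- 0L }
        else stale <- stale + 1L
        if (stale >= tcfg$early_stop_patience) break
      }
    }
    invisible(TRUE)
  }

  cell_side <- c("cell_enc", "cell_dec", "head")
  gene_side <- c("gene_enc", "gene_dec", "b_gene")
  joint <- c("cell_enc", "cell_dec", "gene_enc", "gene_dec", "b_gene")
  if (!mcfg$shared_bias) joint <- c(joint, "b_align")

  ok1 <- if (1 %in% steps)
    run_step(1L, tcfg$epochs_per_step[1], cell_side,
             function(m, cb, beta) .step1_core(m, cb, NULL, beta, TRUE))
  else TRUE
  snapshot <- model$params[cell_side]
  ok2 <- if (ok1 && 2 %in% steps)
    run_step(2L, tcfg$epochs_per_step[2], gene_side,
             function(m, cb, beta) .step2_core(m, cb, G, NULL, beta, TRUE))
  else ok1
  if (ok2 && 3 %in% steps)
    run_step(3L, tcfg$epochs_per_step[3], joint,
             function(m, cb, beta)
               .step3_core(m, cb, G, NULL, NULL, beta, tcfg$gamma, TRUE))

  model <- if (diverged) last_good else model
  model$trained <- TRUE
  model$snapshots <- list(step1_cell_side = snapshot)
  log <- do.call(rbind, logs)
  class(log) <- c("train_log", "data.frame")
  attr(log, "diverged") <- diverged
  list(model = model, log = log)
}
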