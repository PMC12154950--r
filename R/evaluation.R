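# Integration, imputation and gene-module metrics. Standard quantities go
# through established packages (mclust for ARI, igraph for NMI and Leiden,
# cluster for silhouettes, FNN for k-NN); the scib-style aggregations
# (batch-ASW, graph LISI) are computed here directly.

.as_z <- function(z) {
  if (inherits(z, "embedding_result")) z <- z$z
  z <- as.matrix(z)
  if (anyNA(z) || any(!is.finite(z))) stop("embeddings contain NaN/Inf")
  z
}

.knn_graph <- function(z, k) {
  n <- nrow(z)
  if (k >= n) stop("n_neighbors must be smaller than the number of rows")
  nn <- FNN::get.knn(z, k = k)$nn.index
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

.leiden <- function(graph, resolution, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  igraph::membership(igraph::cluster_leiden(
    graph, objective_function = "modularity",
    resolution = resolution, n_iterations = 3))
}

#' Adjusted Rand index between two labelings
#' @param a,b label vectors of equal length.
#' @return ARI in `[-0.5, 1]`; 1 means identical partitions.
#' @export
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Normalized mutual information between two labelings
#' @param a,b label vectors of equal length.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  stopifnot(length(a) == length(b))
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)), method = "nmi")
}

#' Clustering agreement with reference labels (ARI/NMI)
#'
#' Builds a k-NN graph on the embedding, runs seeded Leiden community
#' detection across a resolution scan, and reports the best ARI and the
#' best NMI against the reference labels (the per-metric best resolutions
#' are recorded in the metadata, following common integration-benchmark
#' practice).
#'
#' @param z embedding matrix or [embed_cells()] result.
#' @param labels reference cell-type labels (>= 2 distinct values).
#' @param seed clustering seed.
#' @param n_neighbors k for the k-NN graph (default 15).
#' @param resolutions resolution scan (default `seq(0.1, 2, 0.1)`).
#' @return list with `ARI`, `NMI` and a `metadata` list.
#' @export
clustering_scores <- function(z, labels, seed = 0L, n_neighbors = 15L,
                              resolutions = seq(0.1, 2, by = 0.1)) {
  z <- .as_z(z)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(z))
  if (length(unique(labels)) < 2) stop("need at least 2 distinct labels")
  g <- .knn_graph(z, n_neighbors)
  aris <- nmis <- numeric(length(resolutions))
  for (i in seq_along(resolutions)) {
    mem <- .leiden(g, resolutions[i], seed)
    aris[i] <- ari(mem, labels)
    nmis[i] <- nmi(mem, labels)
  }
  list(ARI = max(aris), NMI = max(nmis),
       metadata = list(n_neighbors = n_neighbors, seed = seed,
                       resolutions = resolutions,
                       best_resolution_ari = resolutions[which.max(aris)],
                       best_resolution_nmi = resolutions[which.max(nmis)]))
}

# silhouette values with the zero convention for degenerate cells
.silhouette_values <- function(z, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(z))
  s <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, nrow(z))
  s[!is.finite(s)] <- 0
  s
}

#' Cell-type average silhouette width, scaled to [0, 1]
#'
#' Mean Euclidean silhouette over all cells with cell-type labels as the
#' grouping, rescaled as `(s + 1) / 2` so 1 means perfectly separated
#' types and 0.5 corresponds to no structure.
#'
#' @param z embedding matrix or `embedding_result`.
#' @param labels cell-type labels; every type needs >= 2 members.
#' @return scalar in `[0, 1]`.
#' @export
silhouette_celltype <- function(z, labels) {
  z <- .as_z(z)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(z))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 cell types")
  if (any(tab < 2))
    stop("cell type(s) with fewer than 2 members: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  (mean(.silhouette_values(z, labels)) + 1) / 2
}

#' Batch average silhouette width (integration flavor)
#'
#' Within each cell-type group, computes `1 - |silhouette|` of the batch
#' labeling per cell (1 when batches are indistinguishable within the
#' type) and averages; the final score averages over cell types. Cell
#' types present in a single batch are skipped with a message.
#'
#' @param z embedding matrix or `embedding_result`.
#' @param batch batch labels (>= 2 distinct values overall).
#' @param labels cell-type labels defining the groups.
#' @return scalar in `[0, 1]`; 1 = perfectly mixed batches.
#' @export
batch_asw <- function(z, batch, labels) {
  z <- .as_z(z)
  batch <- as.character(batch); labels <- as.character(labels)
  stopifnot(length(batch) == nrow(z), length(labels) == nrow(z))
  if (length(unique(batch)) < 2) stop("need at least 2 batches")
  per_type <- c()
  for (ct in unique(labels)) {
    rows <- which(labels == ct)
    b <- batch[rows]
    if (length(unique(b)) < 2) {
      message("batch_asw: cell type '", ct, "' present in one batch; skipped")
      next
    }
    s <- .silhouette_values(z[rows, , drop = FALSE], b)
    per_type <- c(per_type, mean(1 - abs(s)))
  }
  if (!length(per_type)) stop("no cell type spans more than one batch")
  mean(per_type)
}

#' Graph-based local inverse Simpson's index (iLISI / cLISI)
#'
#' For each cell, the inverse Simpson's index of label proportions over
#' its k-NN neighborhood (self included) is computed and normalized:
#' integration flavor `(LISI - 1) / (B - 1)` (1 = batches fully mixed),
#' cell-type flavor `(C - LISI) / (C - 1)` (1 = types fully separated).
#' The mean over cells is returned.
#'
#' @param z embedding matrix or `embedding_result`.
#' @param labels batch labels (integration) or cell-type labels (celltype).
#' @param kind `"integration"` or `"celltype"`.
#' @param n_neighbors neighborhood size (default 15, must be < N).
#' @return scalar in `[0, 1]`.
#' @export
graph_lisi <- function(z, labels, kind = c("integration", "celltype"),
                       n_neighbors = 15L) {
  kind <- match.arg(kind)
  z <- .as_z(z)
  labels <- as.integer(factor(as.character(labels)))
  n <- nrow(z)
  stopifnot(length(labels) == n)
  if (n_neighbors >= n) stop("n_neighbors must be smaller than N")
  B <- max(labels)
  if (B < 2) {
    if (kind == "integration") stop("need at least 2 label categories")
    return(1)  # one type: every neighborhood is pure
  }
  nn <- FNN::get.knn(z, k = n_neighbors)$nn.index
  hood <- cbind(seq_len(n), nn)
  lisi <- vapply(seq_len(n), function(i) {
    p <- tabulate(labels[hood[i, ]], nbins = B) / ncol(hood)
    1 / sum(p^2)
  }, numeric(1))
  if (kind == "integration") mean((lisi - 1) / (B - 1))
  else mean((B - lisi) / (B - 1))
}

#' Imputation accuracy metrics (PCC, SCC, JSD, RMSE)
#'
#' Pearson and Spearman correlations, base-2 Jensen-Shannon divergence and
#' root-mean-square error between a predicted and a measured expression
#' profile. For the JSD, both vectors are shifted by their minimum to be
#' nonnegative and normalized to sum to one (scaled expression can be
#' negative and has no canonical probability reading), which bounds the
#' JSD in `[0, 1]`. Zero-variance inputs yield `NaN` correlations with a
#' warning.
#'
#' @param pred,truth numeric vectors of equal length (N >= 3).
#' @return named list: `PCC`, `SCC`, `JSD`, `RMSE`.
#' @export
imputation_scores <- function(pred, truth) {
  pred <- as.numeric(pred); truth <- as.numeric(truth)
  stopifnot(length(pred) == length(truth), length(pred) >= 3)
  if (anyNA(pred) || anyNA(truth)) stop("inputs contain NA")
  novar <- stats::sd(pred) == 0 || stats::sd(truth) == 0
  if (novar) {
    warning("zero-variance input; correlations undefined (NaN)")
    pcc <- scc <- NaN
  } else {
    pcc <- stats::cor(pred, truth)
    scc <- stats::cor(pred, truth, method = "spearman")
  }
  list(PCC = pcc, SCC = scc, JSD = .jsd(pred, truth),
       RMSE = sqrt(mean((pred - truth)^2)))
}

.jsd <- function(p, q) {
  to_prob <- function(x) {
    x <- x - min(x)
    s <- sum(x)
    if (s == 0) rep(1 / length(x), length(x)) else x / s
  }
  p <- to_prob(p); q <- to_prob(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Gene-module discovery by clustering contextual gene embeddings
#'
#' Seeded Leiden community detection on a k-NN graph over the contextual
#' (latent) gene embeddings. Genes falling into singleton communities are
#' marked unassigned (label -1).
#'
#' @param z_genes embedding matrix or [embed_genes()] result.
#' @param resolution Leiden resolution (default 1).
#' @param n_neighbors k for the k-NN graph (default 15); at least
#'   `2 * n_neighbors` genes are required.
#' @param seed clustering seed.
#' @return list of class `gene_module_assignment`: `gene_ids`, `module`
#'   (integers, -1 = unassigned) and `parameters`.
#' @export
cluster_genes <- function(z_genes, resolution = 1, n_neighbors = 15L,
                          seed = 0L) {
  ids <- if (inherits(z_genes, "embedding_result")) z_genes$ids else rownames(z_genes)
  z <- .as_z(z_genes)
  if (nrow(z) < 2 * n_neighbors)
    stop("need at least ", 2 * n_neighbors, " genes for n_neighbors = ", n_neighbors)
  if (is.null(ids)) ids <- paste0("gene_", seq_len(nrow(z)))
  g <- .knn_graph(z, n_neighbors)
  mem <- as.integer(.leiden(g, resolution, seed))
  sizes <- table(mem)
  singleton <- as.integer(names(sizes)[sizes == 1])
  mem[mem %in% singleton] <- -1L
  # relabel remaining modules to consecutive integers starting at 1
  keep <- mem != -1L
  mem[keep] <- as.integer(factor(mem[keep]))
  structure(list(gene_ids = ids, module = mem,
                 parameters = list(resolution = resolution,
                                   n_neighbors = n_neighbors, seed = seed)),
            class = "gene_module_assignment")
}
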