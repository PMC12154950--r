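#' Expression matrix container
#'
#' Cells in rows, genes in columns, on the scaled log-normalized scale the
#' model consumes. Identifiers must be unique; values must be finite.
#'
#' @param values numeric `N x M` matrix (rows = cells).
#' @param cell_ids length-N unique identifiers.
#' @param gene_ids length-M unique identifiers.
#' @param batch optional length-N categorical batch labels.
#' @param cell_type optional length-N categorical cell-type labels.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cell_ids, gene_ids, batch = NULL,
                              cell_type = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cell_ids <- trimws(as.character(cell_ids))
  gene_ids <- trimws(as.character(gene_ids))
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("need at least 2 cells and 2 genes")
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  .stop_on_duplicates(gene_ids, "gene")
  .stop_on_duplicates(cell_ids, "cell")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values contain NaN/Inf")
  if (!is.null(batch) && length(batch) != nrow(values))
    stop("batch length does not match the number of cells")
  if (!is.null(cell_type) && length(cell_type) != nrow(values))
    stop("cell_type length does not match the number of cells")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 batch = batch, cell_type = cell_type),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes%s%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$batch)) sprintf(", %d batches", length(unique(x$batch))) else "",
              if (!is.null(x$cell_type)) sprintf(", %d cell types", length(unique(x$cell_type))) else ""))
  invisible(x)
}

#' Static gene-embedding table container
#'
#' One fixed D-dimensional vector per gene, exported from any external
#' model and consumed here purely as a numeric table.
#'
#' @param vectors numeric `M x D` matrix.
#' @param gene_ids length-M unique identifiers.
#' @param source_tag free-text provenance label.
#' @return an object of class `gene_embedding_table`.
#' @export
gene_embedding_table <- function(vectors, gene_ids, source_tag = "unspecified") {
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  gene_ids <- trimws(as.character(gene_ids))
  if (ncol(vectors) < 1) stop("embedding dimensionality must be >= 1")
  if (length(gene_ids) != nrow(vectors))
    stop("gene_ids length does not match the number of embedding rows")
  .stop_on_duplicates(gene_ids, "gene")
  if (anyNA(vectors) || any(!is.finite(vectors)))
    stop("embedding vectors contain NaN/Inf")
  rownames(vectors) <- gene_ids
  structure(list(vectors = vectors, gene_ids = gene_ids,
                 source_tag = source_tag),
            class = "gene_embedding_table")
}

#' @export
print.gene_embedding_table <- function(x, ...) {
  cat(sprintf("gene_embedding_table: %d genes x %d dims (source: %s)\n",
              nrow(x$vectors), ncol(x$vectors), x$source_tag))
  invisible(x)
}

.stop_on_duplicates <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " identifiers: ",
         paste(utils::head(dup, 10), collapse = ", "),
         if (length(dup) > 10) " ..." else "")
}

#' Load an expression matrix from disk
#'
#' Supported formats: dense CSV/TSV with a header of gene names and cell
#' identifiers in the first column; Matrix Market triplets (`mtx`) with
#' plain-text gene and cell index files; and an HDF5 AnnData-style
#' container (`h5`, requires the rhdf5 package) with `X` stored dense or
#' CSR and identifiers in `obs/_index` and `var/_index`.
#'
#' For MTX input the orientation is auto-detected from the index files
#' (genes x cells, the common 10x layout, is transposed to cells x genes);
#' when the two files cannot disambiguate, `orientation` must say.
#'
#' @param path file path (for `mtx`, either the matrix file with sibling
#'   index files or a directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`).
#' @param format one of `"csv"`, `"mtx"`, `"h5"`.
#' @param orientation `"auto"`, `"cells_by_genes"` or `"genes_by_cells"`.
#' @param genes_file,cells_file explicit index-file paths for `mtx`.
#' @return an [expression_matrix()].
#' @export
load_expression <- function(path, format = c("csv", "mtx", "h5"),
                            orientation = c("auto", "cells_by_genes",
                                            "genes_by_cells"),
                            genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    csv = .load_expression_csv(path),
    mtx = .load_expression_mtx(path, orientation, genes_file, cells_file),
    h5  = .load_expression_h5(path)
  )
}

.load_expression_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  cell_ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  expression_matrix(vals, cell_ids, colnames(dt)[-1])
}

.read_index <- function(path) {
  # 10x-style index files may carry extra columns (id, symbol); take col 1
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE, sep = "\t")
  trimws(as.character(dt[[1]]))
}

.load_expression_mtx <- function(path, orientation, genes_file, cells_file) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (is.null(genes_file)) genes_file <- file.path(path, "genes.tsv")
    if (is.null(cells_file)) cells_file <- file.path(path, "barcodes.tsv")
  } else {
    mtx <- path
    dir <- dirname(path)
    if (is.null(genes_file)) genes_file <- file.path(dir, "genes.tsv")
    if (is.null(cells_file)) cells_file <- file.path(dir, "barcodes.tsv")
  }
  for (f in c(mtx, genes_file, cells_file))
    if (!file.exists(f)) stop("file not found: ", f)
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- .read_index(genes_file)
  cells <- .read_index(cells_file)
  fits_cxg <- nrow(m) == length(cells) && ncol(m) == length(genes)
  fits_gxc <- nrow(m) == length(genes) && ncol(m) == length(cells)
  ori <- orientation
  if (ori == "auto") {
    if (fits_cxg && fits_gxc)
      stop("orientation ambiguous (square index sizes); pass orientation explicitly")
    if (fits_cxg) ori <- "cells_by_genes"
    else if (fits_gxc) ori <- "genes_by_cells"
    else stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
              " but index files list ", length(genes), " genes and ",
              length(cells), " cells")
  } else {
    ok <- if (ori == "cells_by_genes") fits_cxg else fits_gxc
    if (!ok) stop("dimension mismatch between matrix and index files")
  }
  if (ori == "genes_by_cells") m <- t(m)
  expression_matrix(m, cells, genes)
}

.load_expression_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("h5 input requires the rhdf5 package")
  ls <- rhdf5::h5ls(path)
  cells <- trimws(as.character(rhdf5::h5read(path, "obs/_index")))
  genes <- trimws(as.character(rhdf5::h5read(path, "var/_index")))
  x_is_group <- any(ls$name == "X" & ls$otype == "H5I_GROUP")
  if (x_is_group) {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    m <- as.matrix(Matrix::sparseMatrix(
      j = indices + 1L, p = indptr, x = data,
      dims = c(length(cells), length(genes))))
  } else {
    m <- rhdf5::h5read(path, "X")
    # HDF5 stores row-major; the anndata writer produces genes x cells on read
    if (nrow(m) == length(genes) && ncol(m) == length(cells) &&
        length(genes) != length(cells)) m <- t(m)
  }
  if (nrow(m) != length(cells) || ncol(m) != length(genes))
    stop("dimension mismatch between X and obs/var index in ", path)
  expression_matrix(m, cells, genes)
}

# per-gene standardization with the population (1/N) variance; constant
# genes become all-zero columns and are reported via a warning
.scale_genes <- function(m, clip = NULL, warn = TRUE) {
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  v[v < 0] <- 0
  sdv <- sqrt(v)
  const <- sdv < 1e-12
  sdv[const] <- 1
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
  if (any(const)) {
    out[, const] <- 0
    if (warn)
      warning("zero-variance gene(s) set to all-zero: ",
              paste(utils::head(colnames(m)[const] %||%
                                which(const), 10), collapse = ", "))
  }
  if (!is.null(clip)) out <- pmin(pmax(out, -clip), clip)
  out
}

#' Preprocess raw counts to scaled log-normalized expression
#'
#' Per-cell total-count normalization to `target_sum`, then `log1p`, then
#' per-gene standardization to mean 0 / sd 1 across cells (population
#' denominator), optionally clipped symmetrically. Zero-variance genes
#' become all-zero columns and are reported with a warning.
#'
#' @param counts nonnegative `N x M` matrix, or an [expression_matrix()]
#'   holding raw counts (annotations are carried through).
#' @param target_sum per-cell total after normalization (default 1e4).
#' @param clip symmetric clip bound for the scaled values (default 10);
#'   `NULL` disables clipping.
#' @param cell_ids,gene_ids identifiers used when `counts` is a bare
#'   matrix (defaults to its dimnames or generated ids).
#' @return an [expression_matrix()] of scaled values.
#' @export
preprocess <- function(counts, target_sum = 1e4, clip = 10,
                       cell_ids = NULL, gene_ids = NULL) {
  batch <- NULL; cell_type <- NULL
  if (inherits(counts, "expression_matrix")) {
    batch <- counts$batch; cell_type <- counts$cell_type
    cell_ids <- counts$cell_ids; gene_ids <- counts$gene_ids
    counts <- counts$values
  }
  counts <- as.matrix(counts)
  stopifnot(target_sum > 0)
  if (anyNA(counts) || any(!is.finite(counts))) stop("counts contain NaN/Inf")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(cell_ids))
    cell_ids <- rownames(counts) %||% paste0("cell_", seq_len(nrow(counts)))
  if (is.null(gene_ids))
    gene_ids <- colnames(counts) %||% paste0("gene_", seq_len(ncol(counts)))
  totals <- rowSums(counts)
  zero <- totals == 0
  if (any(zero))
    stop("all-zero cell(s): ",
         paste(utils::head(cell_ids[zero], 10), collapse = ", "))
  norm <- counts / totals * target_sum
  lg <- log1p(norm)
  colnames(lg) <- gene_ids
  scaled <- .scale_genes(lg, clip = clip)
  expression_matrix(scaled, cell_ids, gene_ids, batch = batch,
                    cell_type = cell_type)
}

#' Load a static gene-embedding table from disk
#'
#' CSV/TSV files carry the gene identifier in the first column and one
#' embedding dimension per remaining column. NPY input (`npy`) carries the
#' `M x D` matrix, with gene identifiers in a plain-text index file (one
#' per line).
#'
#' @param path file path.
#' @param format `"csv"`, `"tsv"` or `"npy"` (guessed from the extension
#'   by default).
#' @param index_file required for `npy`: path to the gene index.
#' @param source_tag provenance label stored on the table.
#' @return a [gene_embedding_table()].
#' @export
load_gene_embeddings <- function(path, format = NULL, index_file = NULL,
                                 source_tag = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "tsv", "npy")) ext else "csv"
  }
  if (is.null(source_tag)) source_tag <- basename(path)
  if (format == "npy") {
    if (is.null(index_file)) stop("npy format requires index_file")
    vec <- read_npy(path)
    ids <- readLines(index_file)
    if (length(ids) != nrow(vec))
      stop("index file lists ", length(ids), " genes but matrix has ",
           nrow(vec), " rows")
    return(gene_embedding_table(vec, ids, source_tag))
  }
  sep <- if (format == "tsv") "\t" else ","
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE, sep = sep,
                          fill = FALSE)
  ids <- as.character(dt[[1]])
  vec <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(vec)) stop("non-numeric embedding values (ragged rows?) in ", path)
  gene_embedding_table(vec, ids, source_tag)
}

#' Restrict expression and embedding tables to a common gene set
#'
#' Both outputs are reordered to the shared genes in expression order.
#' Genes are matched case-sensitively after whitespace stripping; no alias
#' resolution is attempted.
#'
#' @param expr an [expression_matrix()].
#' @param table a [gene_embedding_table()].
#' @param policy `"intersect"` drops genes absent from either side (counts
#'   are reported via a message); `"error_on_missing"` errors if any
#'   expression gene lacks an embedding.
#' @return list with elements `expr` and `table`, gene-aligned.
#' @export
align_genes <- function(expr, table, policy = c("intersect", "error_on_missing")) {
  policy <- match.arg(policy)
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(table, "gene_embedding_table"))
  missing_emb <- setdiff(expr$gene_ids, table$gene_ids)
  if (policy == "error_on_missing" && length(missing_emb))
    stop("expression genes without embeddings: ",
         paste(utils::head(missing_emb, 10), collapse = ", "),
         if (length(missing_emb) > 10) " ..." else "")
  shared <- expr$gene_ids[expr$gene_ids %in% table$gene_ids]
  if (length(shared) < 2)
    stop("fewer than 2 genes shared between expression and embedding table")
  dropped_expr <- length(expr$gene_ids) - length(shared)
  dropped_tab <- length(table$gene_ids) - length(shared)
  if (dropped_expr || dropped_tab)
    message("align_genes: dropped ", dropped_expr, " expression gene(s) and ",
            dropped_tab, " embedding row(s)")
  expr_out <- expression_matrix(
    expr$values[, shared, drop = FALSE], expr$cell_ids, shared,
    batch = expr$batch, cell_type = expr$cell_type)
  tab_out <- gene_embedding_table(
    table$vectors[shared, , drop = FALSE], shared, table$source_tag)
  list(expr = expr_out, table = tab_out)
}

#' Construct baseline gene-embedding variants
#'
#' Three ablation baselines for the external embeddings: `self_informed`
#' uses the transposed expression matrix itself as the gene features (so
#' D = N and no external knowledge enters); `random` replaces them with
#' standard-normal noise; `shuffled` permutes the rows of the external
#' table with a seeded non-identity permutation, deliberately breaking the
#' gene-to-embedding correspondence while keeping the marginal
#' distribution.
#'
#' @param expr an [expression_matrix()].
#' @param mode `"self_informed"`, `"random"` or `"shuffled"`.
#' @param table the external table (required for `shuffled`; supplies the
#'   default D for `random`).
#' @param seed integer seed for the random/shuffled draws.
#' @param D embedding dimensionality for `random` (default: table's D,
#'   else 512).
#' @return a [gene_embedding_table()] aligned to `expr`.
#' @export
make_baseline_embeddings <- function(expr, mode = c("self_informed", "random",
                                                    "shuffled"),
                                     table = NULL, seed = 0L, D = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expression_matrix"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  M <- length(expr$gene_ids)
  if (mode == "self_informed") {
    return(gene_embedding_table(t(expr$values), expr$gene_ids,
                                source_tag = "self_informed"))
  }
  if (mode == "random") {
    if (is.null(D)) D <- if (!is.null(table)) ncol(table$vectors) else 512L
    vec <- matrix(stats::rnorm(M * D), M, D)
    return(gene_embedding_table(vec, expr$gene_ids, source_tag = "random"))
  }
  # shuffled
  if (is.null(table)) stop("mode 'shuffled' requires the external table")
  if (!identical(table$gene_ids, expr$gene_ids))
    stop("mode 'shuffled' requires a table aligned to the expression matrix")
  perm <- sample.int(M)
  while (all(perm == seq_len(M))) perm <- sample.int(M)
  gene_embedding_table(table$vectors[perm, , drop = FALSE], expr$gene_ids,
                       source_tag = paste0(table$source_tag, "|shuffled"))
}
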