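test_that("dense CSV expression loads with cells in rows and genes in columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell,g1,g2", "c1,1,2", "c2,3,4"), f)
  em <- load_expression(f, format = "csv")
  expect_s3_class(em, "expression_matrix")
  expect_equal(dim(em$values), c(2L, 2L))
  expect_equal(em$gene_ids, c("g1", "g2"))
  expect_equal(em$cell_ids, c("c1", "c2"))
  expect_equal(unname(em$values[2, ]), c(3, 4))
})

test_that("MTX triplets load, auto-orient, and catch dimension mismatches", {
  dir <- withr::local_tempdir()
  # 2 cells x 3 genes with 3 nonzeros, written genes x cells (10x layout)
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "3 2 3", "1 1 5", "2 2 7", "3 1 2"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  em <- load_expression(dir, format = "mtx")
  expect_equal(dim(em$values), c(2L, 3L))
  expect_equal(sum(em$values != 0), 3)
  expect_equal(em$values["c1", "gA"], 5)
  expect_equal(em$values["c2", "gB"], 7)

  # index file listing fewer genes than matrix columns -> error
  writeLines(c("gA", "gB"), file.path(dir, "genes.tsv"))
  expect_error(load_expression(dir, format = "mtx"), "mismatch")
})

test_that("duplicate gene identifiers are rejected by name", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell,gX,gX", "c1,1,2", "c2,3,4"), f)
  expect_error(load_expression(f, format = "csv"), "gX")
})

test_that("preprocess normalizes, log-transforms and standardizes per gene", {
  # equal rows collapse to all-zero after scaling
  out <- suppressWarnings(
    preprocess(matrix(c(1, 2, 1, 2), 2, 2), target_sum = 10))
  expect_true(all(out$values == 0))

  # hand-computed: normalize -> log1p -> z-score with population sd
  out2 <- preprocess(matrix(c(0, 2, 2, 0), 2, 2), target_sum = 2)
  expect_equal(unname(out2$values), matrix(c(-1, 1, 1, -1), 2, 2))

  # constant gene column (equal row totals keep it constant) -> zeros + warning
  cnt <- cbind(c(1, 3, 2), c(2, 2, 2), c(5, 3, 4))
  expect_warning(out3 <- preprocess(cnt), "zero-variance")
  expect_true(all(out3$values[, 2] == 0))

  # non-constant genes have per-gene mean 0 and population sd 1
  set.seed(7)
  cnt2 <- matrix(rpois(200, 5) + 1, 20, 10)
  out4 <- preprocess(cnt2)
  expect_equal(colMeans(out4$values), rep(0, 10), tolerance = 1e-6,
               ignore_attr = TRUE)
  sds <- sqrt(colMeans(out4$values^2))
  expect_equal(unname(sds), rep(1, 10), tolerance = 1e-6)
})

test_that("preprocess rejects degenerate input", {
  expect_error(preprocess(matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE),
                          cell_ids = c("cA", "cB")), "cA")
  expect_error(preprocess(matrix(c(-1, 2, 3, 4), 2, 2)), "nonnegative")
})

test_that("gene embedding tables load from CSV and NPY with index", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,d1,d2,d3,d4",
               "g1,0.1,0.2,0.3,0.4",
               "g2,1,2,3,4",
               "g3,-1,0,1,2"), f)
  tab <- load_gene_embeddings(f)
  expect_equal(dim(tab$vectors), c(3L, 4L))
  expect_equal(tab$gene_ids, c("g1", "g2", "g3"))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,d1", "g1,1", "g1,2"), dup)
  expect_error(load_gene_embeddings(dup), "duplicate")

  npy <- withr::local_tempfile(fileext = ".npy")
  idx <- withr::local_tempfile(fileext = ".txt")
  mat <- matrix(rnorm(40), 5, 8)
  write_npy(mat, npy)
  writeLines(paste0("g", 1:5), idx)
  tab2 <- load_gene_embeddings(npy, format = "npy", index_file = idx)
  expect_equal(unname(tab2$vectors), mat)
  expect_equal(nrow(tab2$vectors), 5L)
  expect_equal(ncol(tab2$vectors), 8L)
})

test_that("read_npy parses a C-order file written byte-by-byte to the format spec", {
  f <- withr::local_tempfile(fileext = ".npy")
  dict <- "{'descr': '<f8', 'fortran_order': False, 'shape': (2, 3), }"
  pad <- (64 - (10 + nchar(dict) + 1) %% 64) %% 64
  header <- paste0(dict, strrep(" ", pad), "\n")
  con <- file(f, "wb")
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 1, 0)), con)
  writeBin(nchar(header), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(1:6), con, size = 8, endian = "little")  # row-major
  close(con)
  expect_equal(read_npy(f), matrix(1:6, 2, 3, byrow = TRUE))
})

test_that("align_genes intersects in expression order and is idempotent", {
  em <- expression_matrix(matrix(1:6, 2, 3), c("c1", "c2"), c("A", "B", "C"))
  tab <- gene_embedding_table(matrix(rnorm(6), 3, 2), c("B", "C", "D"))
  al <- suppressMessages(align_genes(em, tab))
  expect_equal(al$expr$gene_ids, c("B", "C"))
  expect_equal(al$table$gene_ids, c("B", "C"))
  al2 <- align_genes(al$expr, al$table)
  expect_identical(al2$expr$values, al$expr$values)
  expect_identical(al2$table$vectors, al$table$vectors)

  # identical sets, different orders -> expression order wins
  tab2 <- gene_embedding_table(matrix(1:6, 3, 2), c("C", "A", "B"))
  al3 <- align_genes(em, tab2)
  expect_equal(al3$table$gene_ids, c("A", "B", "C"))
  expect_equal(unname(al3$table$vectors[, 1]), c(2, 3, 1))

  tab3 <- gene_embedding_table(matrix(rnorm(4), 2, 2), c("X", "Y"))
  expect_error(align_genes(em, tab3), "fewer than 2")
  expect_error(align_genes(em, tab, policy = "error_on_missing"), "A")
})

test_that("baseline embedding variants follow their definitions", {
  vals <- matrix(rnorm(6), 3, 2)
  em <- expression_matrix(vals, paste0("c", 1:3), c("g1", "g2"))

  si <- make_baseline_embeddings(em, "self_informed")
  expect_equal(unname(si$vectors), t(vals))
  expect_equal(dim(si$vectors), c(2L, 3L))

  tab <- gene_embedding_table(matrix(1:4, 2, 2), c("g1", "g2"))
  sh <- make_baseline_embeddings(em, "shuffled", table = tab, seed = 5)
  expect_equal(unname(sh$vectors), unname(tab$vectors[2:1, ]))  # only non-identity perm of 2
  expect_equal(sh$gene_ids, c("g1", "g2"))

  r1 <- make_baseline_embeddings(em, "random", seed = 9, D = 7)
  r2 <- make_baseline_embeddings(em, "random", seed = 9, D = 7)
  expect_identical(r1$vectors, r2$vectors)
  expect_equal(ncol(r1$vectors), 7L)

  expect_error(make_baseline_embeddings(em, "shuffled"), "table")
})

test_that("shuffled baseline preserves the multiset of row vectors", {
  em <- expression_matrix(matrix(rnorm(40), 4, 10), paste0("c", 1:4),
                          paste0("g", 1:10))
  tab <- gene_embedding_table(matrix(rnorm(30), 10, 3), paste0("g", 1:10))
  for (s in 1:5) {
    sh <- make_baseline_embeddings(em, "shuffled", table = tab, seed = s)
    key <- function(m) sort(unname(apply(m, 1, paste, collapse = ",")))
    expect_equal(key(sh$vectors), key(tab$vectors))
    expect_false(identical(unname(sh$vectors), unname(tab$vectors)))
  }
})

test_that("h5 AnnData-style container loads when rhdf5 is present", {
  skip_if_not_installed("rhdf5")
  f <- withr::local_tempfile(fileext = ".h5")
  X <- matrix(rnorm(12), 3, 4)  # 3 cells x 4 genes
  rhdf5::h5createFile(f)
  rhdf5::h5write(t(X), f, "X")  # stored so that reading yields genes x cells
  rhdf5::h5createGroup(f, "obs"); rhdf5::h5createGroup(f, "var")
  rhdf5::h5write(paste0("c", 1:3), f, "obs/_index")
  rhdf5::h5write(paste0("g", 1:4), f, "var/_index")
  rhdf5::H5close()
  em <- load_expression(f, format = "h5")
  expect_equal(dim(em$values), c(3L, 4L))
  expect_equal(unname(em$values), X)
})
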