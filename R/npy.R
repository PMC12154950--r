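# Minimal NPY (v1.0) support for numeric 1-D/2-D arrays, enough to consume
# embedding matrices exported from numpy (`np.save`). Little-endian
# float32/float64/int32/int64 only.

#' Read a numeric NPY array
#'
#' @param path path to a `.npy` file (version 1.0, little-endian numeric).
#' @return a numeric vector (1-D input) or matrix (2-D input).
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", 2)
  if (ver[1] != as.raw(1)) stop("unsupported NPY version: ", as.integer(ver[1]))
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- regmatches(header, regexpr("'descr':\\s*'[^']+'", header))
  descr <- sub(".*'([^']+)'$", "\\1", descr)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- regmatches(header, regexpr("'shape':\\s*\\(([^)]*)\\)", header))
  shape <- as.integer(strsplit(gsub("[^0-9,]", "", shape_str), ",")[[1]])
  n <- prod(shape)
  data <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4, endian = "little"),
    "<i4" = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "<i8" = readBin(con, "double", n, size = 8, endian = "little"),  # lossy > 2^53
    stop("unsupported NPY dtype: ", descr)
  )
  if (length(shape) == 1) return(data)
  if (length(shape) != 2) stop("only 1-D/2-D NPY arrays are supported")
  if (fortran) matrix(data, shape[1], shape[2])
  else t(matrix(data, shape[2], shape[1]))  # C order: rows vary slowest
}

#' Write a numeric matrix as NPY (v1.0, float64, C order)
#'
#' @param x numeric vector or matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  shape <- if (is.matrix(x)) sprintf("(%d, %d)", nrow(x), ncol(x))
           else sprintf("(%d,)", length(x))
  dict <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }", shape)
  pad <- (64 - (10 + nchar(dict) + 1) %% 64) %% 64
  header <- paste0(dict, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 1, 0)), con)
  writeBin(nchar(header), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  vals <- if (is.matrix(x)) as.vector(t(x)) else as.numeric(x)
  writeBin(vals, con, size = 8, endian = "little")
  invisible(path)
}
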