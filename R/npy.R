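# Minimal NumPy .npy (format version 1.0) reader/writer for 2D arrays.
# Supports little-endian float64/float32 and uint8, C or Fortran order.

#' Read a 2D array from a NumPy \code{.npy} file
#'
#' Supports format version 1.0 with dtypes \code{<f8}, \code{<f4} and
#' \code{|u1}, in either C or Fortran order. Only 2D arrays are accepted;
#' this is the lossless float companion to the 8-bit PNG path.
#'
#' @param path Path to the \code{.npy} file.
#' @return A numeric matrix.
#' @seealso [write_npy()], [load_image()]
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (length(magic) < 6L ||
      !identical(magic, as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59)))) {
    stop(errorCondition(sprintf("'%s' is not an NPY file", path),
                        class = c("mw_unreadable_image", "error", "condition")))
  }
  readBin(con, "raw", n = 2L)                       # version, unused
  hlen <- readBin(con, "integer", n = 1L, size = 2L, endian = "little",
                  signed = FALSE)
  header <- rawToChar(readBin(con, "raw", n = hlen))
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_txt <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_txt), ",")[[1]])
  if (length(shape) != 2L) stop("read_npy supports 2D arrays only")
  n <- prod(shape)
  vals <- switch(descr,
    "<f8" = readBin(con, "double",  n = n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double",  n = n, size = 4L, endian = "little"),
    "|u1" = as.numeric(readBin(con, "integer", n = n, size = 1L,
                               signed = FALSE)) / 255,
    stop(sprintf("unsupported NPY dtype '%s'", descr)))
  if (length(vals) != n) {
    stop(errorCondition(sprintf("'%s' is truncated", path),
                        class = c("mw_unreadable_image", "error", "condition")))
  }
  if (fortran) matrix(vals, nrow = shape[1], ncol = shape[2])
  else t(matrix(vals, nrow = shape[2], ncol = shape[1]))
}

#' Write a 2D array to a NumPy \code{.npy} file
#'
#' Writes format version 1.0, dtype \code{<f8}, Fortran order.
#'
#' @param x A numeric matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_npy()]
#' @export
write_npy <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x))
  header <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': (%d, %d), }",
                    nrow(x), ncol(x))
  # total header block (magic 6 + version 2 + len 2 + dict) padded to 64 bytes
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(nchar(header), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}
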