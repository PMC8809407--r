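# Minimal NPY (v1.0) array serialisation for numeric arrays.
# Supports the dtypes that occur for binary association tensors saved from
# numpy (u1/i1/i2/i4/i8/f4/f8, either byte order marker, C or Fortran order).

.npyMagic <- as.raw(c(0x93, charToRaw("NUMPY")))

.npyParseHeader <- function(hdr) {
  descr <- regmatches(hdr, regexec("'descr'\\s*:\\s*'([^']+)'", hdr))[[1]][2]
  fort  <- regmatches(hdr, regexec("'fortran_order'\\s*:\\s*(True|False)", hdr))[[1]][2]
  shp   <- regmatches(hdr, regexec("'shape'\\s*:\\s*\\(([^)]*)\\)", hdr))[[1]][2]
  if (is.na(descr) || is.na(fort) || is.na(shp))
    stop("malformed NPY header")
  shape <- as.integer(strsplit(gsub("\\s", "", shp), ",")[[1]])
  shape <- shape[!is.na(shape)]
  list(descr = descr, fortran = identical(fort, "True"), shape = shape)
}

.npyReadValues <- function(con, descr, n) {
  code <- sub("^[<>|=]", "", descr)
  endian <- if (startsWith(descr, ">")) "big" else "little"
  switch(code,
    "b1" = ,
    "u1" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "i1" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "i2" = as.numeric(readBin(con, "integer", n = n, size = 2, endian = endian)),
    "i4" = as.numeric(readBin(con, "integer", n = n, size = 4, endian = endian)),
    "u2" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                              endian = endian)),
    "i8" = {
      raw <- readBin(con, "raw", n = 8 * n)
      m <- matrix(as.numeric(raw), nrow = 8)
      if (endian == "big") m <- m[8:1, , drop = FALSE]
      # two's complement via the high byte; exact for |x| < 2^53
      v <- colSums(m * 256^(0:7))
      ifelse(v >= 2^63, v - 2^64, v)
    },
    "f4" = as.numeric(readBin(con, "numeric", n = n, size = 4, endian = endian)),
    "f8" = readBin(con, "numeric", n = n, size = 8, endian = endian),
    stop(sprintf("unsupported NPY dtype '%s'", descr))
  )
}

#' Read a numeric array from an NPY file
#'
#' @param path Path to a \code{.npy} file (format version 1.x or 2.x,
#'   numeric dtype, any dimensionality).
#' @return A numeric vector or array with the file's shape.
#' @export
readNpy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6)
  if (!identical(magic, .npyMagic))
    stop(sprintf("'%s' is not an NPY file (bad magic)", path))
  ver <- readBin(con, "integer", n = 2, size = 1, signed = FALSE)
  hlen <- if (ver[1] >= 2)
    readBin(con, "integer", n = 1, size = 4, endian = "little")
  else
    readBin(con, "integer", n = 1, size = 2, signed = FALSE, endian = "little")
  hdr <- rawToChar(readBin(con, "raw", n = hlen))
  info <- .npyParseHeader(hdr)
  n <- prod(info$shape)
  if (length(info$shape) == 0L) n <- 1L
  vals <- .npyReadValues(con, info$descr, n)
  if (length(vals) != n)
    stop("truncated NPY payload")
  if (length(info$shape) <= 1L) return(vals)
  if (info$fortran) {
    array(vals, dim = info$shape)
  } else {
    # C-order stream: last axis varies fastest
    aperm(array(vals, dim = rev(info$shape)), rev(seq_along(info$shape)))
  }
}

#' Write a numeric array to an NPY file
#'
#' Writes format version 1.0, C (row-major) element order. Integer arrays
#' whose entries fit a byte are written as \code{|u1}, other values as
#' \code{<f8}.
#'
#' @param x Numeric vector, matrix or array.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeNpy <- function(x, path) {
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  vals <- if (length(shape) > 1L)
    as.vector(aperm(x, rev(seq_along(shape))))
  else as.vector(x)
  byteish <- all(vals == round(vals)) && all(vals >= 0) && all(vals <= 255)
  descr <- if (byteish) "|u1" else "<f8"
  shp <- if (length(shape) == 1L) sprintf("(%d,)", shape)
         else sprintf("(%s)", paste(shape, collapse = ", "))
  hdr <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                 descr, shp)
  total <- 6L + 2L + 2L + nchar(hdr) + 1L
  pad <- (16L - total %% 16L) %% 16L
  hdr <- paste0(hdr, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.npyMagic, con)
  writeBin(as.integer(c(1L, 0L)), con, size = 1)
  writeBin(nchar(hdr), con, size = 2, endian = "little")
  writeBin(charToRaw(hdr), con)
  if (byteish) writeBin(as.raw(vals), con)
  else writeBin(as.numeric(vals), con, size = 8, endian = "little")
  invisible(path)
}
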