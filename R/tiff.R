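#' Minimal 16-bit label TIFF I/O
#'
#' Reader and writer for the subset of baseline TIFF 6.0 used for label
#' masks: single-image, uncompressed, little-endian, one sample per pixel,
#' 16-bit unsigned grayscale, single strip. This is deliberately not a
#' general TIFF implementation; files produced by [write_label_tiff()]
#' round-trip losslessly through [read_label_tiff()], and files from other
#' software are accepted only if they match this subset (integer-valued,
#' uncompressed grayscale). Anything else raises a validation error naming
#' the file.
#'
#' @param path File path.
#' @param labels Integer matrix (row/column indexed) of labels in 0..65535.
#' @return `read_label_tiff()` returns an integer matrix; `write_label_tiff()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tif")
#' m <- matrix(0L, 8, 10); m[3:5, 4:7] <- 1L
#' write_label_tiff(m, f)
#' identical(read_label_tiff(f), m)
#' @name label_tiff
NULL

# TIFF tag ids used below
.TAG <- c(width = 256L, length = 257L, bps = 258L, compression = 259L,
          photometric = 262L, strip_offsets = 273L, spp = 277L,
          rows_per_strip = 278L, strip_byte_counts = 279L,
          sample_format = 339L)

#' @rdname label_tiff
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels))
  if (is.double(labels)) {
    if (any(labels != floor(labels), na.rm = TRUE))
      stop("labels must be integer-valued: ", path)
    storage.mode(labels) <- "integer"
  }
  if (anyNA(labels) || any(labels < 0L) || any(labels > 65535L))
    stop("labels must be in 0..65535: ", path)
  nr <- nrow(labels); nc <- ncol(labels)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header: II, magic 42, IFD offset 8
  writeBin(charToRaw("II"), con); w16(42L); w32(8L)
  n_tags <- 10L
  data_offset <- 8L + 2L + n_tags * 12L + 4L  # pixel data right after the IFD
  entry <- function(tag, type, count, value) { w16(tag); w16(type); w32(count); w32(value) }
  w16(n_tags)
  entry(.TAG[["width"]], 3L, 1L, nc)          # SHORT
  entry(.TAG[["length"]], 3L, 1L, nr)
  entry(.TAG[["bps"]], 3L, 1L, 16L)
  entry(.TAG[["compression"]], 3L, 1L, 1L)    # none
  entry(.TAG[["photometric"]], 3L, 1L, 1L)    # BlackIsZero
  entry(.TAG[["strip_offsets"]], 4L, 1L, data_offset)  # LONG
  entry(.TAG[["spp"]], 3L, 1L, 1L)
  entry(.TAG[["rows_per_strip"]], 3L, 1L, nr)
  entry(.TAG[["strip_byte_counts"]], 4L, 1L, 2L * nr * nc)
  entry(.TAG[["sample_format"]], 3L, 1L, 1L)  # unsigned integer
  w32(0L)  # no further IFD
  # row-major pixel order
  writeBin(as.integer(t(labels)), con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname label_tiff
#' @export
read_label_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file: ", path)
  rint <- function(off, size, n = 1L) {
    # unsigned reads; size-4 values are file offsets/counts, safely < 2^31
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = (size == 4L))
  }
  if (rint(2L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- rint(4L, 4L)
  n_tags <- rint(ifd, 2L)
  tags <- list()
  for (i in seq_len(n_tags)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- rint(off, 2L); type <- rint(off + 2L, 2L); count <- rint(off + 4L, 4L)
    val <- if (type == 3L) rint(off + 8L, 2L) else rint(off + 8L, 4L)
    if (count > 1L) {  # value field holds an offset to the array
      ptr <- rint(off + 8L, 4L)
      val <- rint(ptr, if (type == 3L) 2L else 4L, n = count)
    }
    tags[[as.character(tag)]] <- list(type = type, count = count, value = val)
  }
  need <- function(tag, default = NULL) {
    t <- tags[[as.character(tag)]]
    if (is.null(t)) {
      if (is.null(default)) stop("missing TIFF tag ", tag, " in ", path)
      return(default)
    }
    t$value
  }
  nc <- need(.TAG[["width"]]); nr <- need(.TAG[["length"]])
  bps <- need(.TAG[["bps"]], 1L)
  if (need(.TAG[["compression"]], 1L) != 1L)
    stop("compressed TIFF not supported: ", path)
  if (need(.TAG[["spp"]], 1L) != 1L)
    stop("multi-channel TIFF not supported (single label layer expected): ", path)
  sf <- need(.TAG[["sample_format"]], 1L)
  if (!all(sf %in% c(1L, 2L)))
    stop("non-integer (float) pixel data not supported: ", path)
  if (!all(bps %in% c(8L, 16L)))
    stop("unsupported bit depth ", paste(bps, collapse = ","), ": ", path)
  offs <- need(.TAG[["strip_offsets"]])
  counts <- need(.TAG[["strip_byte_counts"]])
  bytes <- bps[1] / 8L
  vals <- integer(0)
  for (s in seq_along(offs)) {
    n <- counts[s] / bytes
    v <- rint(offs[s], bytes, n = n)
    vals <- c(vals, v)
  }
  if (length(vals) != nr * nc) stop("TIFF pixel data size mismatch: ", path)
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}
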