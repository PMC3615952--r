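# Minimal baseline TIFF codec: uncompressed, single-sample greyscale,
# 8- or 16-bit, little-endian, one or more pages.  Written because no TIFF
# package ships with the target environment; covers the de-facto uCT
# interchange layout (stack of greyscale slices) and nothing more.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' Write a multipage greyscale TIFF
#'
#' @param slices list of integer matrices (row, col), all the same size.
#' @param path output file.
#' @param bits 8 or 16 bits per sample (unsigned).
#' @keywords internal
write_tiff_pages <- function(slices, path, bits = 8L) {
  stopifnot(length(slices) >= 1L, bits %in% c(8L, 16L))
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeChar("II", con, nchars = 2L, eos = NULL)
  w2(42L)
  nr <- nrow(slices[[1L]]); nc <- ncol(slices[[1L]])
  bpp <- bits %/% 8L
  data_bytes <- nr * nc * bpp
  ifd_size <- 2L + 10L * 12L + 4L
  # layout per page: [pixel data][IFD]; header points at page 1's IFD
  page_span <- data_bytes + ifd_size
  first_ifd <- 8L + data_bytes
  w4(first_ifd)
  for (i in seq_along(slices)) {
    m <- slices[[i]]
    if (nrow(m) != nr || ncol(m) != nc) stop("inconsistent slice dimensions")
    v <- as.integer(t(m))  # TIFF strips are row-major
    if (bits == 8L) {
      writeBin(as.raw(clamp(v, 0L, 255L)), con)
    } else {
      v <- clamp(v, 0L, 65535L)
      v[v > 32767L] <- v[v > 32767L] - 65536L  # two's complement for writeBin
      writeBin(v, con, size = 2L, endian = "little")
    }
    data_off <- 8L + (i - 1L) * page_span
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count)
      if (type == 3L) { w2(value); w2(0L) } else w4(value)
    }
    w2(10L)  # entry count
    entry(TIFF_TAGS[["width"]], 4L, 1L, nc)
    entry(TIFF_TAGS[["length"]], 4L, 1L, nr)
    entry(TIFF_TAGS[["bits"]], 3L, 1L, bits)
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_off)
    entry(TIFF_TAGS[["spp"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["rows_per_strip"]], 4L, 1L, nr)
    entry(TIFF_TAGS[["strip_bytes"]], 4L, 1L, data_bytes)
    entry(TIFF_TAGS[["sample_format"]], 3L, 1L, 1L)
    w4(if (i < length(slices)) 8L + i * page_span + data_bytes else 0L)
  }
  invisible(path)
}

#' Read a greyscale TIFF (all pages)
#'
#' Accepts baseline uncompressed greyscale TIFFs (any strip layout, either
#' byte order, 8 or 16 bit unsigned).
#'
#' @param path TIFF file.
#' @return list of integer matrices.
#' @keywords internal
read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop("not a TIFF file: ", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2L, signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4L,
                 endian = endian)
    if (v < 0) v + 2^32 else v
  }
  if (u16(2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- u32(4L)
  pages <- list()
  while (ifd != 0L) {
    n <- u16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      off <- ifd + 2L + (k - 1L) * 12L
      tag <- u16(off); type <- u16(off + 2L); count <- u32(off + 4L)
      size <- c(1L, 1L, 2L, 4L)[min(type, 4L)]
      inline <- size * count <= 4L
      voff <- if (inline) off + 8L else u32(off + 8L)
      vals <- vapply(seq_len(count), function(j) {
        if (type == 3L) u16(voff + (j - 1L) * 2L) else u32(voff + (j - 1L) * 4L)
      }, numeric(1))
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    wd <- g(256L); ht <- g(257L)
    if (is.null(wd) || is.null(ht)) stop("TIFF page missing dimensions")
    bits <- g(258L, 8L)[1L]
    if (!bits %in% c(8L, 16L)) stop("unsupported TIFF bit depth: ", bits)
    if (g(259L, 1L)[1L] != 1L) stop("unsupported TIFF compression")
    if (g(277L, 1L)[1L] != 1L) stop("only single-sample greyscale TIFFs supported")
    offs <- g(273L); cnts <- g(279L)
    if (is.null(offs)) stop("TIFF page missing strip offsets")
    if (is.null(cnts)) cnts <- wd * ht * (bits / 8L)
    buf <- raw(0)
    for (j in seq_along(offs)) {
      buf <- c(buf, raw[(offs[j] + 1):(offs[j] + cnts[j])])
    }
    v <- if (bits == 8L) {
      as.integer(buf)
    } else {
      readBin(buf, "integer", n = length(buf) / 2L, size = 2L,
              signed = FALSE, endian = endian)
    }
    pages[[length(pages) + 1L]] <- matrix(v, nrow = ht, ncol = wd,
                                          byrow = TRUE)
    ifd <- u32(ifd + 2L + n * 12L)
  }
  pages
}
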