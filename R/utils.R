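# Internal pixel-set and window helpers.
#
# A "pixel set" is an integer matrix with columns (row, col), 1-based.
# Windowed operations work on logical matrices; masks over a whole slice
# use the slice's dimensions.

px_empty <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("row", "col")))
}

px_set <- function(rows, cols) {
  m <- cbind(row = as.integer(rows), col = as.integer(cols))
  if (nrow(m) && anyNA(m)) stop("pixel coordinates must be finite")
  m
}

px_n <- function(px) if (is.null(px)) 0L else nrow(px)

# Linear (column-major) index of pixels within a matrix of `nr` rows.
px_linear <- function(px, nr) {
  (px[, 2L] - 1L) * nr + px[, 1L]
}

px_from_mask <- function(mask) {
  w <- which(mask)
  nr <- nrow(mask)
  px_set(((w - 1L) %% nr) + 1L, ((w - 1L) %/% nr) + 1L)
}

mask_from_px <- function(px, dim2) {
  m <- matrix(FALSE, dim2[1L], dim2[2L])
  if (px_n(px)) m[px_linear(px, dim2[1L])] <- TRUE
  m
}

# Set difference / intersection on pixel sets living on a common slice
# of `nr` rows (linear-index arithmetic keeps this O(n)).
px_setdiff <- function(a, b, nr) {
  if (!px_n(a)) return(px_empty())
  if (!px_n(b)) return(a)
  a[!(px_linear(a, nr) %in% px_linear(b, nr)), , drop = FALSE]
}

px_intersect_n <- function(a, b, nr) {
  if (!px_n(a) || !px_n(b)) return(0L)
  sum(px_linear(a, nr) %in% px_linear(b, nr))
}

# Sum of the 3x3 neighbourhood (centre included) of a numeric matrix.
box9_sum <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  p[1:nr,       1:nc      ] + p[1:nr,       2:(nc + 1L)] + p[1:nr,       3:(nc + 2L)] +
  p[2:(nr + 1L), 1:nc     ] + p[2:(nr + 1L), 2:(nc + 1L)] + p[2:(nr + 1L), 3:(nc + 2L)] +
  p[3:(nr + 2L), 1:nc     ] + p[3:(nr + 2L), 2:(nc + 1L)] + p[3:(nr + 2L), 3:(nc + 2L)]
}

# 8-connected binary dilation, `k` iterations.
dilate8 <- function(mask, k = 1L) {
  for (i in seq_len(k)) mask <- box9_sum(mask) > 0
  mask
}

# Lexicographic (row, then col) sort of a pixel set; canonical storage order.
px_sort <- function(px) {
  if (px_n(px) < 2L) return(px)
  px[order(px[, 1L], px[, 2L]), , drop = FALSE]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
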