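# Grey-level appearance model: a normalized histogram over fixed bins
# spanning the stack's global intensity range.  The histogram of a tracked
# root cross-section is the tracker's model of nearby root attenuation.

#' Build grey-level histogram breaks for a stack
#'
#' Breaks are shared by every appearance model built from one stack, so the
#' Bhattacharyya similarity compares like with like.
#'
#' @param values numeric vector or array of grey values (typically
#'   `stack$voxels`).
#' @param bins number of bins.
#' @return numeric vector of `bins + 1` break points.
#' @export
model_breaks <- function(values, bins = 64L) {
  r <- range(values, finite = TRUE)
  if (r[1L] == r[2L]) r <- r + c(-0.5, 0.5)  # constant image: one wide bin range
  seq(r[1L], r[2L], length.out = bins + 1L)
}

#' Grey-level appearance model
#'
#' @param values grey values of the member pixels.
#' @param breaks shared histogram breaks from [model_breaks()].
#' @return an `appearance_model`: normalized histogram (`hist`), the breaks,
#'   and the support count `n_pixels`.
#' @export
appearance_model <- function(values, breaks) {
  nb <- length(breaks) - 1L
  idx <- bin_index(values, breaks)
  counts <- tabulate(idx, nbins = nb)
  n <- length(values)
  h <- if (n > 0L) counts / n else rep(0, nb)
  structure(list(hist = h, breaks = breaks, n_pixels = as.integer(n)),
            class = "appearance_model")
}

# Bin membership with both tails clamped into the first/last bin.
bin_index <- function(values, breaks) {
  nb <- length(breaks) - 1L
  clamp(findInterval(values, breaks, all.inside = TRUE), 1L, nb)
}

#' Bhattacharyya similarity of two appearance models
#'
#' `sum(sqrt(a$hist * b$hist))`: 1 for identical histograms, 0 for disjoint
#' support.  Used as the reliability gate for model updates.
#'
#' @param a,b `appearance_model`s built over the same breaks.
#' @return scalar in `[0, 1]`.
#' @export
similarity <- function(a, b) {
  if (length(a$hist) != length(b$hist)) {
    stop("appearance models have different bin counts")
  }
  min(1, max(0, sum(sqrt(a$hist * b$hist))))
}

#' Conditionally adapt an appearance model
#'
#' The freshly observed histogram replaces the current model only when the
#' two are at least `beta`-similar (inclusive); otherwise the observation is
#' deemed unreliable (e.g. the tracker brushed organic matter) and the
#' current model is kept.
#'
#' @param current,observed `appearance_model`s over the same breaks.
#' @param beta similarity acceptance threshold in `[0, 1]`.
#' @return the accepted `appearance_model`.
#' @export
update_model <- function(current, observed, beta) {
  if (similarity(current, observed) >= beta) observed else current
}
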