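#' Tracker configuration
#'
#' Bundles every tunable of the slice tracker.  The two scientifically
#' meaningful parameters are `alpha` and `beta`; the remainder are numerical
#' controls exposed for reproducibility.
#'
#' @param alpha Weight in `[0, 1]` of the appearance data term against the
#'   curvature (smoothness) term in the level-set speed.  `alpha = 1` trusts
#'   grey values alone; `alpha = 0` is pure curvature flow (the region
#'   shrinks).  Default 0.6, close to the settings reported for real tomato
#'   scans (about 0.61).
#' @param beta Minimum Bhattacharyya similarity in `[0, 1]` between the
#'   current appearance model and a freshly observed root object for the
#'   model to be replaced (adapted).  Lower values adapt faster but risk
#'   drifting onto soil; default 0.25.
#' @param bins Number of grey-level histogram bins spanning the stack's
#'   global intensity range.  64 works for 8- and 16-bit data.
#' @param max_iter Iteration cap for one level-set evolution.
#' @param band_width Narrow-band half-width in pixels; also the margin used
#'   when windowing a slice around a tracked object.
#' @param min_area Minimum pixel count for a connected component to survive
#'   as a root object; smaller fragments are treated as target loss.
#' @param connectivity_2d In-slice pixel adjacency, 4 or 8.  8 keeps thin
#'   diagonal roots connected.
#' @param annulus_width Width in pixels of the background annulus around the
#'   initial region from which the background histogram is estimated.
#' @param seed_radius Radius in pixels of the initial disc grown around the
#'   user's seed click.
#' @param hist_smooth Gaussian kernel sd, in bins, applied to the root and
#'   background histograms when forming the foreground probability (small
#'   cross-sections cannot populate every bin their noise spans); 0
#'   disables.
#' @param overlap_threshold Minimum number of pixels a backward-look
#'   component must share with already-labelled voxels to be considered
#'   "already seen" (components below it become plagiotropic markers).
#' @param forward_only If `TRUE`, skip every backward-looking step: the
#'   classic top-to-bottom tracker that misses upward-growing laterals.
#' @param smooth_sigma Gaussian sigma (voxels) applied to the binary mask
#'   before iso-surface extraction; 0 meshes the raw voxel indicator.
#' @param mc_samples Monte Carlo sample count for convex-hull volume.
#' @param rng_seed Seed used wherever randomness is allowed (the Welzl
#'   shuffle and Monte Carlo integration; tracking itself is deterministic).
#'
#' @return An object of class `tracker_config` (a named list).
#' @export
#' @examples
#' cfg <- tracker_config(alpha = 0.606, beta = 0.246)
#' cfg$alpha
tracker_config <- function(alpha = 0.6, beta = 0.25, bins = 64L,
                           max_iter = 200L, band_width = 6L, min_area = 5L,
                           connectivity_2d = 8L, annulus_width = 5L,
                           hist_smooth = 1.5, seed_radius = 3L,
                           overlap_threshold = 1L,
                           forward_only = FALSE, smooth_sigma = 1,
                           mc_samples = 1e6, rng_seed = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1,
            min_area >= 1, bins >= 2, max_iter >= 1, band_width >= 1,
            annulus_width >= 1, seed_radius >= 1, overlap_threshold >= 1,
            smooth_sigma >= 0, mc_samples >= 1)
  if (!connectivity_2d %in% c(4L, 8L)) {
    stop("connectivity_2d must be 4 or 8")
  }
  structure(list(
    alpha = alpha, beta = beta, bins = as.integer(bins),
    max_iter = as.integer(max_iter), band_width = as.integer(band_width),
    min_area = as.integer(min_area),
    connectivity_2d = as.integer(connectivity_2d),
    annulus_width = as.integer(annulus_width),
    hist_smooth = hist_smooth,
    seed_radius = as.integer(seed_radius),
    overlap_threshold = as.integer(overlap_threshold),
    forward_only = isTRUE(forward_only),
    smooth_sigma = smooth_sigma,
    mc_samples = as.integer(mc_samples),
    rng_seed = as.integer(rng_seed)
  ), class = "tracker_config")
}

#' @export
print.tracker_config <- function(x, ...) {
  cat("tracker_config: alpha =", x$alpha, "beta =", x$beta,
      if (x$forward_only) "(forward-only)" else "(with look-back)", "\n")
  invisible(x)
}
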