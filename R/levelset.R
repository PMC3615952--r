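# Narrow-band level-set segmentation of one slice.
#
# The contour is represented implicitly by its interior pixel set and moves
# at most one pixel per iteration.  The speed at a boundary pixel x is
#
#   F(x) = alpha * (2 * p_root(I(x)) - 1) - (1 - alpha) * kappa(x)
#
# where p_root(g) = h_root(g) / (h_root(g) + h_bg(g)) combines the tracked
# object's appearance histogram h_root with a background histogram h_bg
# estimated from an annulus around the initial region, and kappa is a
# discrete curvature (1 - 2 * mean of the 3x3 occupancy; zero on a straight
# edge, positive on convex bumps).  Outer boundary pixels with F > 0 are
# added, inner boundary pixels with F < 0 removed; evolution stops when the
# set repeats (fixed point or 2-cycle) or after cfg$max_iter iterations.
# Everything is deterministic.

#' Evolve a level-set region on one slice
#'
#' Performs the local, appearance-driven segmentation used at every tracking
#' step: starting from a prior footprint, the region deforms to cover nearby
#' pixels whose grey values look like the model's and drops pixels that look
#' like background.
#'
#' @param slice_img numeric matrix, one slice of the stack.
#' @param init_pixels integer (row, col) matrix, the initial region.
#' @param model `appearance_model` of the expected root material.
#' @param cfg [tracker_config()].
#' @param exclude_pixels optional (row, col) matrix of pixels belonging to
#'   other tracked objects; excluded from the background annulus.
#' @return (row, col) matrix of the stabilised region; zero rows signal that
#'   the target was lost (region collapsed).
#' @export
evolve_levelset <- function(slice_img, init_pixels, model, cfg,
                            exclude_pixels = NULL) {
  if (!px_n(init_pixels)) stop("init_pixels must be non-empty")
  nr <- nrow(slice_img); nc <- ncol(slice_img)
  if (min(init_pixels) < 1L || max(init_pixels[, 1L]) > nr ||
      max(init_pixels[, 2L]) > nc) {
    stop("init_pixels outside image bounds")
  }
  pad <- cfg$band_width + cfg$annulus_width + 2L
  win <- list(r1 = max(1L, min(init_pixels[, 1L]) - pad),
              r2 = min(nr, max(init_pixels[, 1L]) + pad),
              c1 = max(1L, min(init_pixels[, 2L]) - pad),
              c2 = min(nc, max(init_pixels[, 2L]) + pad))

  p_of_bin <- prob_lookup(slice_img, init_pixels, model, cfg, exclude_pixels)

  make_window <- function(win, mask_px) {
    wr <- win$r1:win$r2; wc <- win$c1:win$c2
    img <- slice_img[wr, wc, drop = FALSE]
    p <- matrix(p_of_bin[bin_index(img, model$breaks)], nrow(img), ncol(img))
    m <- matrix(FALSE, nrow(img), ncol(img))
    m[(mask_px[, 2L] - win$c1) * nrow(img) + (mask_px[, 1L] - win$r1 + 1L)] <- TRUE
    list(p = p, mask = m)
  }

  w <- make_window(win, init_pixels)
  mask <- w$mask; p <- w$p
  alpha <- cfg$alpha
  prev1 <- NULL; prev2 <- NULL
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    mnum <- mask * 1
    b9 <- box9_sum(mnum)
    nbr <- b9 - mnum
    f <- alpha * (2 * p - 1) - (1 - alpha) * (1 - 2 * b9 / 9)
    add <- !mask & nbr > 0 & f > 0
    rem <- mask & nbr < 8 & f < 0
    new <- (mask & !rem) | add
    if (identical(new, mask) || (!is.null(prev1) && identical(new, prev1))) {
      mask <- new
      break
    }
    prev1 <- mask
    mask <- new
    # expand the window if the region reached its border (and can expand)
    if (touches_border(mask) &&
        (win$r1 > 1L || win$r2 < nr || win$c1 > 1L || win$c2 < nc)) {
      px_abs <- win_to_abs(mask, win)
      win <- list(r1 = max(1L, win$r1 - 8L), r2 = min(nr, win$r2 + 8L),
                  c1 = max(1L, win$c1 - 8L), c2 = min(nc, win$c2 + 8L))
      w <- make_window(win, px_abs)
      mask <- w$mask; p <- w$p
      prev1 <- NULL
    }
  }
  if (!any(mask)) return(px_empty())
  px_sort(win_to_abs(mask, win))
}

touches_border <- function(mask) {
  any(mask[1L, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1L]) || any(mask[, ncol(mask)])
}

win_to_abs <- function(mask, win) {
  px <- px_from_mask(mask)
  px[, 1L] <- px[, 1L] + win$r1 - 1L
  px[, 2L] <- px[, 2L] + win$c1 - 1L
  px
}

# Per-bin foreground probability p(g) = h_root / (h_root + h_bg), with the
# background histogram taken from an annulus of width cfg$annulus_width
# around the initial region, minus the region and other objects' pixels.
# Bins unseen in either histogram are neutral (0.5).
prob_lookup <- function(slice_img, init_pixels, model, cfg, exclude_pixels) {
  nr <- nrow(slice_img); nc <- ncol(slice_img)
  pad <- cfg$annulus_width + 1L
  r1 <- max(1L, min(init_pixels[, 1L]) - pad)
  r2 <- min(nr, max(init_pixels[, 1L]) + pad)
  c1 <- max(1L, min(init_pixels[, 2L]) - pad)
  c2 <- min(nc, max(init_pixels[, 2L]) + pad)
  wnr <- r2 - r1 + 1L
  core <- matrix(FALSE, wnr, c2 - c1 + 1L)
  core[(init_pixels[, 2L] - c1) * wnr + (init_pixels[, 1L] - r1 + 1L)] <- TRUE
  ring <- dilate8(core, cfg$annulus_width) & !core
  if (px_n(exclude_pixels)) {
    keep <- exclude_pixels[, 1L] >= r1 & exclude_pixels[, 1L] <= r2 &
            exclude_pixels[, 2L] >= c1 & exclude_pixels[, 2L] <= c2
    ex <- exclude_pixels[keep, , drop = FALSE]
    if (px_n(ex)) ring[(ex[, 2L] - c1) * wnr + (ex[, 1L] - r1 + 1L)] <- FALSE
  }
  nbins <- length(model$hist)
  ring_vals <- slice_img[r1:r2, c1:c2, drop = FALSE][ring]
  hb <- if (length(ring_vals)) {
    tabulate(bin_index(ring_vals, model$breaks), nbins) / length(ring_vals)
  } else {
    rep(1 / nbins, nbins)  # no annulus available: uninformative background
  }
  # kernel-smooth both histograms: a root cross-section is a few dozen
  # pixels, far too few to populate every bin its intensity noise spans
  hr <- smooth_hist(model$hist, cfg$hist_smooth)
  hb <- smooth_hist(hb, cfg$hist_smooth)
  tot <- hr + hb
  p <- ifelse(tot > 0, hr / ifelse(tot > 0, tot, 1), 0.5)
  p[tot == 0] <- 0.5
  p
}

# Gaussian smoothing of a histogram over bin index (kernel sd in bins,
# truncated at 3 sd); total mass is preserved.
smooth_hist <- function(h, sd_bins) {
  if (is.null(sd_bins) || sd_bins <= 0) return(h)
  r <- max(1L, ceiling(3 * sd_bins))
  w <- stats::dnorm(-r:r, sd = sd_bins)
  w <- w / sum(w)
  n <- length(h)
  out <- numeric(n)
  for (j in seq_along(w)) {
    off <- j - r - 1L
    src <- max(1L, 1L - off):min(n, n - off)
    out[src + off] <- out[src + off] + w[j] * h[src]
  }
  s <- sum(h)
  if (s > 0 && sum(out) > 0) out <- out * (s / sum(out))
  out
}

#' Initialise tracking from a user seed point
#'
#' Grows a root object around a single (row, col) click on the first slice:
#' a small disc around the seed provides the initial appearance histogram
#' and the level-set evolution is iterated, re-recording the histogram and
#' background annulus from the grown region each round, until the pixel
#' set stabilises (the annulus of the initial disc can sit entirely inside
#' a thick root, so a single evolution under-grows).  A seed whose grown
#' region ends up smaller than `min_area` is rejected.  A seed on uniform
#' background far from any structure deterministically yields a small
#' region with a near-background histogram; callers can reject it by its
#' appearance, but it is not an error if it reaches `min_area`.
#'
#' @param stack an `image_stack`.
#' @param seed length-2 numeric (row, col) on slice 1.
#' @param cfg [tracker_config()].
#' @param breaks optional precomputed [model_breaks()] for the stack.
#' @return a `root_object` (pixels, appearance model, centroid, slice 1).
#' @export
init_from_click <- function(stack, seed, cfg = tracker_config(),
                            breaks = NULL) {
  dims <- dim(stack$voxels)
  seed <- as.integer(round(seed))
  if (length(seed) != 2L || seed[1L] < 1L || seed[1L] > dims[1L] ||
      seed[2L] < 1L || seed[2L] > dims[2L]) {
    stop("seed must lie inside slice 1")
  }
  breaks <- breaks %||% model_breaks(stack$voxels, cfg$bins)
  img <- stack$voxels[, , 1L]
  px <- disc_pixels(seed, cfg$seed_radius, dims[1L], dims[2L])
  for (round in 1:6) {
    model <- appearance_model(img[px_linear(px, dims[1L])], breaks)
    grown <- evolve_levelset(img, px, model, cfg)
    if (px_n(grown) < cfg$min_area) { px <- grown; break }
    stable <- px_n(grown) == px_n(px) &&
      px_intersect_n(grown, px, dims[1L]) == px_n(px)
    px <- grown
    if (stable) break
  }
  if (px_n(px) < cfg$min_area) {
    stop("seed rejected: grown region smaller than min_area")
  }
  comps <- connected_components(px, cfg$connectivity_2d)
  # keep the component containing (or nearest to) the seed
  pick <- which(vapply(comps, function(p) {
    any(p[, 1L] == seed[1L] & p[, 2L] == seed[2L])
  }, logical(1)))
  if (!length(pick)) {
    d <- vapply(comps, function(p) {
      min((p[, 1L] - seed[1L])^2 + (p[, 2L] - seed[2L])^2)
    }, numeric(1))
    pick <- which.min(d)
  }
  px <- comps[[pick[1L]]]
  if (px_n(px) < cfg$min_area) {
    stop("seed rejected: grown region smaller than min_area")
  }
  new_root_object(slice_index = 1L, pixels = px,
                  model = appearance_model(img[px_linear(px, dims[1L])], breaks),
                  parent_id = NA_integer_, id = 1L, direction = "down")
}

disc_pixels <- function(center, radius, nr, nc) {
  rs <- max(1L, center[1L] - radius):min(nr, center[1L] + radius)
  cs <- max(1L, center[2L] - radius):min(nc, center[2L] + radius)
  g <- expand.grid(row = rs, col = cs)
  keep <- (g$row - center[1L])^2 + (g$col - center[2L])^2 <= radius^2
  px_sort(px_set(g$row[keep], g$col[keep]))
}

new_root_object <- function(slice_index, pixels, model, parent_id, id,
                            direction) {
  stopifnot(px_n(pixels) > 0L)
  structure(list(
    slice_index = as.integer(slice_index),
    pixels = pixels,
    model = model,
    centroid = c(row = mean(pixels[, 1L]), col = mean(pixels[, 2L])),
    parent_id = parent_id,
    id = as.integer(id),
    direction = direction
  ), class = "root_object")
}
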