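# Synthetic soil-column phantoms with voxel-level ground truth.
#
# The generator reproduces the two imaging properties that make root
# segmentation hard: (i) soil organic matter whose grey values are drawn
# from the root intensity distribution (root/soil attenuation overlap) and
# (ii) root attenuation drifting linearly with depth (water retention and
# tissue density change along the root).  Soil is an i.i.d. mixture of
# mineral grain, near-black pore and organic voxels.

#' Specify one root branch
#'
#' @param control_points numeric matrix with columns (slice, row, col); the
#'   piecewise-linear centerline, at least two points.
#' @param radius_start,radius_end branch radius in voxels at the two ends
#'   (linear taper along arc length).
#' @param parent id of the parent branch, or `NA` for the primary; child
#'   branches must start on the parent centerline.
#' @return a `branch_spec`; `plagiotropic` is `TRUE` if any segment
#'   decreases in slice index (grows upward).
#' @export
branch_spec <- function(control_points, radius_start, radius_end,
                        parent = NA_integer_) {
  cp <- as.matrix(control_points)
  stopifnot(ncol(cp) == 3L, nrow(cp) >= 2L,
            radius_start > 0, radius_end > 0)
  colnames(cp) <- c("slice", "row", "col")
  structure(list(control_points = cp, radius_start = radius_start,
                 radius_end = radius_end, parent = parent,
                 plagiotropic = any(diff(cp[, "slice"]) < 0)),
            class = "branch_spec")
}

#' Specify a phantom soil column
#'
#' Defaults state a plausible low-noise 8-bit scan: root material around
#' grey 150 at the surface drifting to 110 at depth (sd 8), mineral soil at
#' 80 (sd 12), 15 % near-black pores, and 2 % organic voxels drawn from the
#' root distribution.
#'
#' @param shape integer (rows, cols, slices) of the volume.
#' @param branches list of [branch_spec()]s, parents before children.
#' @param root_mu_top,root_mu_bottom mean root grey at slice 1 and the last
#'   slice (linear drift between them).
#' @param root_sigma root grey standard deviation.
#' @param soil_mu,soil_sigma mineral soil grey parameters.
#' @param organic_fraction fraction of soil voxels drawn from the root
#'   distribution at their depth (the root/soil overlap dial).
#' @param pore_fraction fraction of near-black air-filled soil voxels.
#' @param blur_sigma optional Gaussian blur (voxels) applied to the
#'   rendered volume; 0 disables (the default, so tests can separate
#'   algorithmic from imaging effects).
#' @param rng_seed integer seed; rendering is fully determined by it.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(shape, branches, root_mu_top = 150,
                         root_mu_bottom = 110, root_sigma = 8,
                         soil_mu = 80, soil_sigma = 12,
                         organic_fraction = 0.02, pore_fraction = 0.15,
                         blur_sigma = 0, rng_seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            organic_fraction >= 0, pore_fraction >= 0,
            organic_fraction <= 1, pore_fraction <= 1,
            organic_fraction + pore_fraction <= 1,
            root_sigma > 0, soil_sigma > 0, blur_sigma >= 0)
  structure(list(shape = as.integer(shape), branches = branches,
                 root_mu_top = root_mu_top, root_mu_bottom = root_mu_bottom,
                 root_sigma = root_sigma, soil_mu = soil_mu,
                 soil_sigma = soil_sigma,
                 organic_fraction = organic_fraction,
                 pore_fraction = pore_fraction, blur_sigma = blur_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Rasterise phantom branches to ground-truth masks
#'
#' Sweeps a ball of linearly tapering radius along each branch centerline
#' (sampling step 0.5 voxel).  Where branches overlap, the lowest branch id
#' wins, so junction voxels belong to the parent.
#'
#' @param spec a [phantom_spec()].
#' @return list with `mask` (logical array, union of branches) and `labels`
#'   (integer array of branch ids, 0 = soil).
#' @export
rasterize_branches <- function(spec) {
  dims <- spec$shape
  labels <- array(0L, dims)
  nr <- dims[1L]; nc <- dims[2L]; ns <- dims[3L]
  for (bi in seq_along(spec$branches)) {
    br <- spec$branches[[bi]]
    cp <- br$control_points
    seg_len <- sqrt(rowSums(diff(cp)^2))
    total <- sum(seg_len)
    arc0 <- c(0, cumsum(seg_len))
    for (si in seq_len(nrow(cp) - 1L)) {
      nstep <- max(2L, ceiling(seg_len[si] / 0.5) + 1L)
      t <- seq(0, 1, length.out = nstep)
      ctr <- cbind(cp[si, 1L] + t * (cp[si + 1L, 1L] - cp[si, 1L]),
                   cp[si, 2L] + t * (cp[si + 1L, 2L] - cp[si, 2L]),
                   cp[si, 3L] + t * (cp[si + 1L, 3L] - cp[si, 3L]))
      arc <- (arc0[si] + t * seg_len[si]) / max(total, 1e-9)
      rad <- br$radius_start + arc * (br$radius_end - br$radius_start)
      for (k in seq_len(nstep)) {
        s0 <- ctr[k, 1L]; r0 <- ctr[k, 2L]; c0 <- ctr[k, 3L]; rd <- rad[k]
        # the centerline must stay inside; swept balls are clipped at the
        # faces (a primary root legitimately enters through the top slice)
        if (s0 < 1 || s0 > ns || r0 < 1 || r0 > nr || c0 < 1 || c0 > nc) {
          stop(sprintf("branch %d exits the volume", bi))
        }
        ss <- max(1L, floor(s0 - rd)):min(ns, ceiling(s0 + rd))
        rs <- max(1L, floor(r0 - rd)):min(nr, ceiling(r0 + rd))
        cs <- max(1L, floor(c0 - rd)):min(nc, ceiling(c0 + rd))
        dr2 <- (rs - r0)^2
        dc2 <- (cs - c0)^2
        ds2 <- (ss - s0)^2
        inside <- outer(outer(dr2, dc2, `+`), ds2, `+`) <= rd^2
        sub <- labels[rs, cs, ss, drop = FALSE]
        sub[inside & sub == 0L] <- bi
        labels[rs, cs, ss] <- sub
      }
    }
  }
  list(mask = labels > 0L, labels = labels)
}

#' Render a phantom to a greyscale image stack
#'
#' @param mask logical ground-truth array from [rasterize_branches()].
#' @param spec the [phantom_spec()] (supplies intensities and the seed).
#' @param voxel_size_um voxel edge length recorded on the stack; defaults
#'   to 23.91, a typical scanning resolution for this kind of data.
#' @return an `image_stack` in the 8-bit intensity range.
#' @export
render_greyscale <- function(mask, spec, voxel_size_um = 23.91) {
  dims <- spec$shape
  stopifnot(all(dim(mask) == dims))
  set.seed(spec$rng_seed)
  n <- prod(dims)
  vox <- numeric(n)
  slice_of <- rep(seq_len(dims[3L]), each = dims[1L] * dims[2L])
  depth <- (slice_of - 1L) / max(1L, dims[3L] - 1L)
  mu_root <- spec$root_mu_top + depth * (spec$root_mu_bottom - spec$root_mu_top)

  is_root <- as.vector(mask)
  nroot <- sum(is_root)
  vox[is_root] <- stats::rnorm(nroot, mu_root[is_root], spec$root_sigma)

  soil_idx <- which(!is_root)
  u <- stats::runif(length(soil_idx))
  pore <- u < spec$pore_fraction
  organic <- !pore & u < spec$pore_fraction + spec$organic_fraction
  mineral <- !pore & !organic
  vox[soil_idx[pore]] <- stats::rnorm(sum(pore), 15, 8)
  vox[soil_idx[organic]] <- stats::rnorm(sum(organic),
                                         mu_root[soil_idx[organic]],
                                         spec$root_sigma)
  vox[soil_idx[mineral]] <- stats::rnorm(sum(mineral), spec$soil_mu,
                                         spec$soil_sigma)
  arr <- array(vox, dims)
  if (spec$blur_sigma > 0) arr <- gauss3(arr, spec$blur_sigma)
  arr <- round(clamp(arr, 0, 255))
  image_stack(arr, voxel_size_um = voxel_size_um)
}

#' Built-in phantom geometries
#'
#' Four canonical architectures used throughout the test suite:
#' \describe{
#'   \item{gravitropic}{a primary with two downward laterals; nothing grows
#'     upward, so forward-only and full tracking must agree.}
#'   \item{y_branch}{a primary splitting into two downward arms mid-stack.}
#'   \item{one_upward_lateral}{a primary plus one upward-growing lateral
#'     joining it in the lower half (about 10 % of root volume).}
#'   \item{fig2_like}{a primary with an upward branch that itself carries
#'     one downward sub-lateral, forcing at least three tracking passes.}
#' }
#'
#' @param name one of the four names above.
#' @param size_scale linear scale factor; 1 gives a 128 x 128 x 200 volume.
#' @param rng_seed seed stored on the spec (rendering noise).
#' @param organic_fraction,pore_fraction soil mixture overrides.
#' @return a `phantom_spec`.
#' @export
builtin_phantoms <- function(name = c("gravitropic", "y_branch",
                                      "one_upward_lateral", "fig2_like"),
                             size_scale = 1, rng_seed = 1L,
                             organic_fraction = 0.02, pore_fraction = 0.15) {
  name <- match.arg(name)
  s <- size_scale
  shape <- c(round(128 * s), round(128 * s), round(200 * s))
  ns <- shape[3L]
  mid_r <- shape[1L] / 2
  # radii shrink with the volume but stay resolvable
  rA <- max(2.2, 4.5 * s); rB <- max(1.8, 3.5 * s); rC <- max(1.5, 2.8 * s)
  cp <- function(...) matrix(c(...), ncol = 3L, byrow = TRUE)
  z <- function(f) max(2, round(ns * f))  # slice at a depth fraction
  # point on a slice-monotone centerline at a given slice
  on_line <- function(cpm, slice) {
    sl <- cpm[, 1L]
    i <- min(max(findInterval(slice, sl), 1L), nrow(cpm) - 1L)
    t <- (slice - sl[i]) / (sl[i + 1L] - sl[i])
    c(slice,
      cpm[i, 2L] + t * (cpm[i + 1L, 2L] - cpm[i, 2L]),
      cpm[i, 3L] + t * (cpm[i + 1L, 3L] - cpm[i, 3L]))
  }

  primary_col <- if (name == "fig2_like") shape[2L] * 0.3 else shape[2L] * 0.5
  primary_cp <- cp(2, mid_r, primary_col,
                   z(0.5), mid_r, primary_col + 4 * s,
                   ns - 1, mid_r, primary_col)
  primary <- branch_spec(primary_cp, radius_start = rA, radius_end = rB)

  branches <- switch(name,
    gravitropic = list(
      primary,
      branch_spec(rbind(on_line(primary_cp, z(0.3)),
                        c(z(0.75), mid_r - 30 * s, primary_col + 34 * s)),
                  radius_start = rC, radius_end = max(1.2, rC * 0.6),
                  parent = 1L),
      branch_spec(rbind(on_line(primary_cp, z(0.5)),
                        c(z(0.9), mid_r + 32 * s, primary_col - 26 * s)),
                  radius_start = rC, radius_end = max(1.2, rC * 0.6),
                  parent = 1L)),
    y_branch = list(
      primary,
      branch_spec(rbind(on_line(primary_cp, z(0.5)),
                        c(ns - 1, mid_r - 34 * s, primary_col + 30 * s)),
                  radius_start = rB, radius_end = max(1.4, rB * 0.7),
                  parent = 1L)),
    one_upward_lateral = list(
      primary,
      branch_spec(rbind(on_line(primary_cp, z(0.6)),
                        c(z(0.45), mid_r + 6 * s, primary_col + 22 * s),
                        c(z(0.22), mid_r + 10 * s, primary_col + 44 * s)),
                  radius_start = rC, radius_end = max(1.3, rC * 0.65),
                  parent = 1L)),
    fig2_like = {
      up_cp <- rbind(on_line(primary_cp, z(0.7)),
                     c(z(0.5), mid_r + 4 * s, primary_col + 26 * s),
                     c(z(0.25), mid_r + 8 * s, primary_col + 52 * s))
      up <- branch_spec(up_cp, radius_start = rC,
                        radius_end = max(1.4, rC * 0.7), parent = 1L)
      # the upward branch's own downward sub-lateral; starts on its
      # centerline (the up branch runs bottom-to-top, so flip for lookup)
      # and dives away perpendicular to the parent's sideways drift so the
      # two cross-sections separate within a couple of slices
      up_cp_sorted <- up_cp[order(up_cp[, 1L]), , drop = FALSE]
      origin <- on_line(up_cp_sorted, z(0.42))
      down <- branch_spec(
        rbind(origin,
              c(z(0.56), origin[2L] - 14 * s, origin[3L] + 2 * s),
              c(z(0.85), origin[2L] - 20 * s, origin[3L] + 12 * s)),
        radius_start = max(1.4, rC * 0.9), radius_end = max(1.2, rC * 0.6),
        parent = 2L)
      list(primary, up, down)
    })
  phantom_spec(shape, branches, rng_seed = rng_seed,
               organic_fraction = organic_fraction,
               pore_fraction = pore_fraction)
}

#' Ground-truth traits of a phantom
#'
#' Computes the same trait report as [measure_traits()] directly on the
#' ground-truth mask; `upward_fraction` is the voxel fraction belonging to
#' plagiotropic branches and `direction_changes` the number of growth
#' direction reversals implied by the branch topology.
#'
#' @param mask,labels outputs of [rasterize_branches()].
#' @param spec the [phantom_spec()].
#' @param voxel_size_um voxel edge length in micrometres.
#' @param mc_samples,rng_seed Monte Carlo controls for the hull volume.
#' @return a one-row `data.frame` (see [measure_traits()]).
#' @export
true_traits <- function(mask, labels, spec, voxel_size_um = 23.91,
                        mc_samples = 1e5, rng_seed = 1L) {
  plagio <- which(vapply(spec$branches, `[[`, logical(1), "plagiotropic"))
  nup <- sum(labels %in% plagio)
  ntot <- sum(mask)
  seg <- synthetic_segmentation(mask, voxel_size_um)
  tr <- measure_traits(seg, mc_samples = mc_samples, rng_seed = rng_seed)
  tr$upward_fraction <- if (ntot > 0L) nup / ntot else 0
  tr$direction_changes <- length(plagio) +
    sum(vapply(spec$branches, function(b) {
      !b$plagiotropic && !is.na(b$parent) &&
        isTRUE(spec$branches[[b$parent]]$plagiotropic)
    }, logical(1)))
  tr
}

#' Wrap a bare mask as a segmentation
#'
#' Utility for measuring ground-truth masks (or third-party masks) with the
#' trait functions: every voxel is labelled as found on a downward pass and
#' the marker log is empty.
#'
#' @param mask logical 3-D array.
#' @param voxel_size_um voxel edge length in micrometres.
#' @return a `root_segmentation`.
#' @export
synthetic_segmentation <- function(mask, voxel_size_um) {
  structure(list(
    mask = mask, direction_label = array(as.integer(mask), dim(mask)),
    marker_log = data.frame(slice_index = integer(0), n_pixels = integer(0),
                            direction = character(0), pass_id = integer(0),
                            status = character(0)),
    pass_count = 0L, slices_visited = 0L, first_pass_visits = 0L,
    voxel_size_um = voxel_size_um, seed = c(NA_real_, NA_real_),
    cfg = NULL), class = "root_segmentation")
}
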