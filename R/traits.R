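# Whole-root-system architectural traits measured on a segmentation.
# All physical scaling goes through the isotropic voxel edge length;
# geometry uses voxel centers at (index - 1) * voxel_size.

#' Root-system volume
#'
#' Voxel count times voxel size cubed — exact, with no dependence on
#' traversal order.
#'
#' @param seg a `root_segmentation`.
#' @param voxel_size_um voxel edge length in micrometres (defaults to the
#'   segmentation's own).
#' @return volume in mm^3.
#' @export
measure_volume <- function(seg, voxel_size_um = seg$voxel_size_um) {
  sum(seg$mask) * (voxel_size_um / 1000)^3
}

#' Root-system surface area
#'
#' Extracts the iso-surface of the mask at level 0.5 (after padding, so the
#' surface closes at the stack boundary, and after Gaussian smoothing of
#' the indicator with `smooth_sigma` — the raw binary surface over-reports
#' the area of smooth shapes) and sums the triangle areas.
#'
#' @param seg a `root_segmentation`.
#' @param voxel_size_um voxel edge length in micrometres.
#' @param smooth_sigma Gaussian sigma in voxels applied to the indicator
#'   before meshing; 0 meshes the raw binary mask.
#' @return list with `area_mm2` and `mesh` (indexed: `vertices` in 0-based
#'   voxel coordinates, `faces` 1-based triangle indices).
#' @export
measure_surface_area <- function(seg, voxel_size_um = seg$voxel_size_um,
                                 smooth_sigma = 1) {
  if (!any(seg$mask)) {
    return(list(area_mm2 = 0,
                mesh = list(vertices = matrix(0, 0, 3),
                            faces = matrix(0L, 0, 3))))
  }
  pad <- max(2L, ceiling(3 * smooth_sigma))
  d <- dim(seg$mask)
  vol <- array(0, d + 2L * pad)
  vol[pad + seq_len(d[1L]), pad + seq_len(d[2L]), pad + seq_len(d[3L])] <-
    seg$mask
  if (smooth_sigma > 0) vol <- gauss3(vol, smooth_sigma)
  tris <- iso_surface(vol, level = 0.5)
  area_vox <- mesh_area(tris)
  mesh <- index_mesh(tris)
  if (nrow(mesh$vertices)) mesh$vertices <- mesh$vertices - pad
  list(area_mm2 = area_vox * (voxel_size_um / 1000)^2, mesh = mesh)
}

#' Maximum root-system width
#'
#' Projects every labelled voxel center onto the slice plane and returns
#' the diameter of the exact minimum enclosing circle (Welzl's algorithm).
#'
#' @param seg a `root_segmentation` with at least one labelled voxel.
#' @param voxel_size_um voxel edge length in micrometres.
#' @param rng_seed seed for the Welzl shuffle (result is invariant to it).
#' @return list with `width_mm`, `center` ((row, col), 0-based voxel
#'   coordinates) and `radius` (voxels).
#' @export
measure_max_width <- function(seg, voxel_size_um = seg$voxel_size_um,
                              rng_seed = 1L) {
  if (!any(seg$mask)) stop("empty mask has no width")
  proj <- rowSums(seg$mask, dims = 2L) > 0
  pts <- which(proj, arr.ind = TRUE) - 1  # voxel centers, 0-based
  mec <- min_enclosing_circle(pts, rng_seed = rng_seed)
  list(width_mm = 2 * mec$radius * voxel_size_um / 1000,
       center = mec$center, radius = mec$radius)
}

#' Convex-hull volume of the root system
#'
#' Builds the 3-D convex hull of the labelled voxel centers with QuickHull
#' and estimates its volume by Monte Carlo integration over the hull's
#' bounding box; the exact fan-decomposition volume is returned alongside
#' for verification.
#'
#' @param seg a `root_segmentation`.
#' @param voxel_size_um voxel edge length in micrometres.
#' @param n_samples Monte Carlo sample count.
#' @param rng_seed seed for the sampler.
#' @return list with `hull_mm3` (the Monte Carlo estimate), `exact_mm3`,
#'   and the voxel-unit `hull` object.  Degenerate (< 4 non-coplanar
#'   voxels) masks give 0 with a warning.
#' @export
measure_convex_hull_volume <- function(seg,
                                       voxel_size_um = seg$voxel_size_um,
                                       n_samples = 1e5, rng_seed = 1L) {
  w <- which(seg$mask)
  if (!length(w)) return(list(hull_mm3 = 0, exact_mm3 = 0, hull = NULL))
  pts <- hull_candidate_points(seg$mask)
  hull <- quickhull3(pts)
  if (hull$degenerate) {
    warning("voxel centers are degenerate (coplanar or collinear); hull volume 0")
    return(list(hull_mm3 = 0, exact_mm3 = 0, hull = hull))
  }
  mc <- hull_volume_mc(hull, n_samples = n_samples, rng_seed = rng_seed)
  s3 <- (voxel_size_um / 1000)^3
  list(hull_mm3 = mc$estimate * s3, exact_mm3 = mc$exact * s3, hull = hull,
       mc = mc)
}

# Voxels with at least one missing face-neighbour: a superset of the hull
# vertices (an interior voxel is the midpoint of its axis neighbours).
hull_candidate_points <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  interior[c(1L, d[1L]), , ] <- FALSE
  interior[, c(1L, d[2L]), ] <- FALSE
  interior[, , c(1L, d[3L])] <- FALSE
  core <- interior
  core[2:(d[1L] - 1L), , ] <- mask[1:(d[1L] - 2L), , ] &
    mask[3:d[1L], , ] & core[2:(d[1L] - 1L), , ]
  core[, 2:(d[2L] - 1L), ] <- mask[, 1:(d[2L] - 2L), ] &
    mask[, 3:d[2L], ] & core[, 2:(d[2L] - 1L), ]
  core[, , 2:(d[3L] - 1L)] <- mask[, , 1:(d[3L] - 2L)] &
    mask[, , 3:d[3L]] & core[, , 2:(d[3L] - 1L)]
  which(mask & !core, arr.ind = TRUE) - 1
}

#' Upward-growing fraction of the root system
#'
#' Fraction of labelled voxels first discovered during an upward tracking
#' pass — the proportion of the root system that grows upward (junction
#' voxels carry the label of whichever pass reached them first).
#'
#' @param seg a `root_segmentation`.
#' @return scalar in `[0, 1]`; 0 for an empty mask.
#' @export
measure_upward_fraction <- function(seg) {
  n <- sum(seg$mask)
  if (n == 0L) return(0)
  sum(seg$direction_label == DIR_UP) / n
}

#' Number of growth-direction changes
#'
#' Each consumed marker is a point where the direction of root growth
#' reverses (an upward lateral joining a downward root, or vice versa).
#'
#' @param seg a `root_segmentation`.
#' @return integer count.
#' @export
count_direction_changes <- function(seg) {
  sum(seg$marker_log$status == "consumed")
}

#' Percent change between two trait values
#'
#' `100 * (after - before) / before`; the comparison statistic used to
#' contrast forward-only and full segmentations.  Rounding to two decimals
#' is left to the caller/reporting layer.
#'
#' @param before,after scalars, `before > 0`.
#' @return percent change.
#' @export
#' @examples
#' round(percent_change(260.76, 276.94), 2)  # 6.2
percent_change <- function(before, after) {
  if (!is.numeric(before) || before <= 0) stop("'before' must be > 0")
  100 * (after - before) / before
}

#' Measure all root-system traits
#'
#' @param seg a `root_segmentation`.
#' @param voxel_size_um voxel edge length in micrometres.
#' @param mc_samples Monte Carlo samples for the hull volume.
#' @param rng_seed seed for Monte Carlo and the Welzl shuffle.
#' @param smooth_sigma indicator smoothing for the surface mesh.
#' @return one-row `data.frame` with columns `voxel_count`, `volume_mm3`,
#'   `surface_area_mm2`, `max_width_mm`, `convex_hull_mm3`,
#'   `upward_fraction`, `direction_changes`.  An empty mask gives a row of
#'   zeros with a warning.
#' @export
measure_traits <- function(seg, voxel_size_um = seg$voxel_size_um,
                           mc_samples = 1e5, rng_seed = 1L,
                           smooth_sigma = 1) {
  n <- sum(seg$mask)
  if (n == 0L) {
    warning("empty segmentation: all traits are zero")
    return(data.frame(voxel_count = 0L, volume_mm3 = 0,
                      surface_area_mm2 = 0, max_width_mm = 0,
                      convex_hull_mm3 = 0, upward_fraction = 0,
                      direction_changes = 0L))
  }
  sa <- measure_surface_area(seg, voxel_size_um, smooth_sigma = smooth_sigma)
  mw <- measure_max_width(seg, voxel_size_um, rng_seed = rng_seed)
  ch <- measure_convex_hull_volume(seg, voxel_size_um,
                                   n_samples = mc_samples,
                                   rng_seed = rng_seed)
  data.frame(
    voxel_count = as.integer(n),
    volume_mm3 = measure_volume(seg, voxel_size_um),
    surface_area_mm2 = sa$area_mm2,
    max_width_mm = mw$width_mm,
    convex_hull_mm3 = ch$hull_mm3,
    upward_fraction = measure_upward_fraction(seg),
    direction_changes = count_direction_changes(seg)
  )
}
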