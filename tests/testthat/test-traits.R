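# Trait measurements: voxel volume, iso-surface area, Welzl width,
# QuickHull volume, direction statistics.

block_seg <- function(shape, lo, hi, voxel_um) {
  m <- array(FALSE, shape)
  m[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- TRUE
  synthetic_segmentation(m, voxel_um)
}

ball_seg <- function(r, voxel_um = 1000) {
  n <- 2L * r + 9L
  ctr <- (n + 1) / 2
  idx <- arrayInd(seq_len(n^3), c(n, n, n))
  m <- array(rowSums((idx - ctr)^2) <= r^2, c(n, n, n))
  synthetic_segmentation(m, voxel_um)
}

test_that("volume is exactly voxel count times voxel size cubed", {
  empty <- synthetic_segmentation(array(FALSE, c(3, 3, 3)), 23.91)
  expect_equal(measure_volume(empty), 0)
  one <- synthetic_segmentation(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)),
                                23.91)
  expect_equal(measure_volume(one), 0.02391^3)
  blk <- block_seg(c(12, 12, 12), c(2, 2, 2), c(11, 11, 11), 100)
  expect_equal(measure_volume(blk), 1.0)
})

test_that("surface area of a voxelised ball is within 4% of 4*pi*r^2", {
  seg <- ball_seg(20L)  # 1 mm voxels so mm^2 equals voxel units^2
  sa <- measure_surface_area(seg)
  expect_lt(abs(sa$area_mm2 / (4 * pi * 400) - 1), 0.04)
  expect_gt(nrow(sa$mesh$vertices), 0L)
  expect_true(all(sa$mesh$faces >= 1L) &&
              all(sa$mesh$faces <= nrow(sa$mesh$vertices)))
})

test_that("surface area scales quadratically with voxel size; empty is 0", {
  seg <- ball_seg(8L, voxel_um = 100)
  a1 <- measure_surface_area(seg, voxel_size_um = 100)$area_mm2
  a2 <- measure_surface_area(seg, voxel_size_um = 200)$area_mm2
  expect_equal(a2, 4 * a1, tolerance = 1e-12)
  empty <- synthetic_segmentation(array(FALSE, c(3, 3, 3)), 100)
  expect_equal(measure_surface_area(empty)$area_mm2, 0)
})

test_that("max width comes from the exact minimum enclosing circle", {
  one <- synthetic_segmentation(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)),
                                100)
  expect_equal(measure_max_width(one)$width_mm, 0)
  m <- array(FALSE, c(10, 10, 2))
  m[2, 2, 1] <- TRUE; m[2, 8, 2] <- TRUE  # 6 voxels apart in projection
  expect_equal(measure_max_width(synthetic_segmentation(m, 100))$width_mm,
               0.6)
  empty <- synthetic_segmentation(array(FALSE, c(3, 3, 3)), 100)
  expect_error(measure_max_width(empty), "empty")
})

test_that("Welzl equals the full O(n^3) brute force on random sets", {
  withr::with_seed(9, {
    for (rep in 1:3) {
      pts <- matrix(runif(120, 0, 50), ncol = 2)
      w <- min_enclosing_circle(pts, rng_seed = rep)
      b <- brute_mec(pts)  # full enumeration, no hull reduction
      expect_equal(w$radius, b$radius, tolerance = 1e-9)
      expect_equal(w$center, b$center, tolerance = 1e-7,
                   ignore_attr = TRUE)
      # containment with slack
      d <- sqrt((pts[, 1] - w$center[1])^2 + (pts[, 2] - w$center[2])^2)
      expect_true(all(d <= w$radius + 1e-9))
    }
  })
})

test_that("hull volume: cube corners exact, tetrahedron closed form", {
  m <- array(FALSE, c(10, 10, 10))
  m[c(1, 10), c(1, 10), c(1, 10)] <- TRUE  # 8 corner voxels
  seg <- synthetic_segmentation(m, 100)
  ch <- measure_convex_hull_volume(seg, n_samples = 1e5, rng_seed = 1)
  expect_equal(ch$exact_mm3, 0.9^3, tolerance = 1e-12)
  # MC estimate within 3 binomial standard errors
  p <- ch$mc$exact / ch$mc$bbox_volume
  se3 <- 3 * sqrt(p * (1 - p) / ch$mc$n_samples) * ch$mc$bbox_volume
  expect_lte(abs(ch$mc$estimate - ch$mc$exact), se3 + 1e-12)

  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  expect_equal(quickhull3(tet)$volume, 1 / (6 * sqrt(2)), tolerance = 1e-12)
})

test_that("degenerate voxel sets give zero hull volume with a warning", {
  m <- array(FALSE, c(10, 10, 10))
  m[3, 3, 1:8] <- TRUE  # collinear
  seg <- synthetic_segmentation(m, 100)
  expect_warning(ch <- measure_convex_hull_volume(seg), "degenerate")
  expect_equal(ch$hull_mm3, 0)
})

test_that("hull volume always contains the voxel volume", {
  seg <- tracked_fixture("one_upward_lateral")
  ch <- measure_convex_hull_volume(seg, n_samples = 2e4, rng_seed = 2)
  expect_gte(ch$exact_mm3, measure_volume(seg))
})

test_that("MC hull estimates track the exact volume across seeds", {
  withr::with_seed(4, pts <- matrix(rnorm(60), ncol = 3))
  h <- quickhull3(pts)
  for (s in 1:5) {
    mc <- hull_volume_mc(h, n_samples = 2e4, rng_seed = s)
    p <- mc$exact / mc$bbox_volume
    se3 <- 3 * sqrt(p * (1 - p) / mc$n_samples) * mc$bbox_volume
    expect_lte(abs(mc$estimate - mc$exact), se3)
  }
  # determinism under a fixed seed
  expect_identical(hull_volume_mc(h, 1e4, 7)$estimate,
                   hull_volume_mc(h, 1e4, 7)$estimate)
})

test_that("upward fraction and direction changes read the tracking labels", {
  segf <- tracked_fixture("one_upward_lateral", forward_only = TRUE)
  expect_equal(measure_upward_fraction(segf), 0)
  expect_equal(count_direction_changes(segf), 0L)
  seg <- tracked_fixture("one_upward_lateral")
  fx <- phantom_fixture("one_upward_lateral")
  truth_up <- sum(fx$truth$labels == 2L) / sum(fx$truth$mask)
  expect_gte(measure_upward_fraction(seg), truth_up - 0.1)
  expect_lte(measure_upward_fraction(seg), truth_up + 0.05)
  expect_equal(count_direction_changes(seg), 1L)
  # consistency with the written marker CSV
  d <- withr::local_tempdir()
  write_segmentation(seg, d)
  expect_equal(count_direction_changes(seg),
               nrow(utils::read.csv(file.path(d, "markers.csv"))))
  all_up <- synthetic_segmentation(array(TRUE, c(2, 2, 2)), 100)
  all_up$direction_label[] <- 2L
  expect_equal(measure_upward_fraction(all_up), 1)
})

test_that("percent_change matches hand arithmetic and guards its domain", {
  expect_equal(round(percent_change(260.76, 276.94), 2), 6.20)
  expect_equal(round(percent_change(34.17, 35.50), 2), 3.89)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(21.17, 24.69), 100 * (24.69 - 21.17) / 21.17)
  expect_error(percent_change(0, 1), "before")
  expect_error(percent_change(-2, 1), "before")
})

test_that("measure_traits assembles a consistent row and handles empties", {
  seg <- tracked_fixture("one_upward_lateral")
  tr <- measure_traits(seg, mc_samples = 2e4, rng_seed = 3)
  expect_equal(tr$volume_mm3,
               tr$voxel_count * (seg$voxel_size_um / 1000)^3)
  expect_gte(tr$convex_hull_mm3, tr$volume_mm3)
  expect_gte(tr$upward_fraction, 0); expect_lte(tr$upward_fraction, 1)
  empty <- synthetic_segmentation(array(FALSE, c(3, 3, 3)), 100)
  expect_warning(tre <- measure_traits(empty), "empty")
  expect_equal(tre$volume_mm3, 0)
  expect_equal(tre$max_width_mm, 0)
})
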