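# Slice-to-slice tracking, look-back markers, pass scheduling.

cylinder_fixture <- function(n_slices = 30, radius = 4, seed = 5L) {
  key <- paste("cyl", n_slices, radius, seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  spec <- phantom_spec(
    shape = c(48, 48, n_slices),
    branches = list(branch_spec(rbind(c(2, 24, 24), c(n_slices - 1, 24, 24)),
                                radius_start = radius, radius_end = radius)),
    rng_seed = seed)
  truth <- rasterize_branches(spec)
  stack <- render_greyscale(truth$mask, spec)
  fx <- list(spec = spec, truth = truth, stack = stack)
  .fixture_env[[key]] <- fx
  fx
}

test_that("a vertical cylinder tracks one object per slice with small drift", {
  fx <- cylinder_fixture()
  cfg <- tracker_config()
  ob <- init_from_click(fx$stack, c(24, 24), cfg)
  objs <- list(ob)
  for (n in 1:25) {
    objs <- advance(objs, fx$stack, cfg, "down")
    expect_length(objs, 1L)
    expect_lte(sqrt(sum((objs[[1L]]$centroid - c(24, 24))^2)), 1.5)
  }
})

test_that("a Y-branch splits one object into two at the branching depth", {
  fx <- phantom_fixture("y_branch", size_scale = 0.5)
  cfg <- tracker_config()
  ob <- init_from_click(fx$stack, fx$seed, cfg)
  objs <- list(ob)
  counts <- integer(0)
  for (n in 1:(dim(fx$stack$voxels)[3L] - 1L)) {
    objs <- advance(objs, fx$stack, cfg, "down")
    counts <- c(counts, length(objs))
    if (length(objs) == 0L) break
  }
  expect_equal(min(counts[1:40]), 1L)   # single object above the fork
  expect_equal(max(counts), 2L)         # two arms below it
  expect_gte(sum(counts == 2L), 20L)    # and the split persists
})

test_that("look-back yields no markers on a gravitropic phantom", {
  seg <- tracked_fixture("gravitropic")
  expect_equal(nrow(seg$marker_log), 0L)
  expect_equal(seg$pass_count, 1L)
  expect_true(all(seg$direction_label[seg$mask] == 1L))
})

test_that("an upward lateral produces exactly one up-marker near its junction", {
  fx <- phantom_fixture("one_upward_lateral")
  seg <- tracked_fixture("one_upward_lateral")
  log <- seg$marker_log
  expect_equal(nrow(log), 1L)
  expect_equal(log$direction, "up")
  expect_equal(log$status, "consumed")
  # the marker sits just above the junction slice of the phantom geometry
  # the marker appears a few slices above the junction, where the lateral's
  # cross-section first separates from the primary's (roughly the two radii
  # plus a soil gap, divided by the lateral's slope)
  junction <- fx$spec$branches[[2L]]$control_points[1L, "slice"]
  expect_lte(abs(log$slice_index - junction), 15L)
  expect_lt(log$slice_index, junction)
  # marker pixels never intersected the mask at creation: the upward pass
  # must have labelled fresh voxels
  expect_gt(sum(seg$direction_label == 2L), 0L)
})

test_that("first pass visits 2N - 1 slices on a marker-free stack", {
  fx <- cylinder_fixture()
  n <- dim(fx$stack$voxels)[3L]
  seg <- extract_root_system(fx$stack, c(24, 24), tracker_config())
  expect_equal(seg$first_pass_visits, 2L * n - 1L)
  expect_equal(nrow(seg$marker_log), 0L)
  segf <- extract_root_system(fx$stack, c(24, 24),
                              tracker_config(forward_only = TRUE))
  expect_equal(segf$first_pass_visits, n)
  expect_identical(seg$mask, segf$mask)
})

test_that("look-back makes the segmentation a superset of forward-only", {
  for (nm in c("gravitropic", "one_upward_lateral", "fig2_like")) {
    seg <- tracked_fixture(nm)
    segf <- tracked_fixture(nm, forward_only = TRUE)
    expect_false(any(segf$mask & !seg$mask), info = nm)
    if (nm == "gravitropic") expect_identical(seg$mask, segf$mask)
    else expect_gt(sum(seg$mask), sum(segf$mask))
  }
})

test_that("upward-pass voxels are labelled 2 and only those", {
  seg <- tracked_fixture("one_upward_lateral")
  expect_true(all(seg$direction_label[seg$mask] %in% c(1L, 2L)))
  expect_true(all(seg$direction_label[!seg$mask] == 0L))
  fx <- phantom_fixture("one_upward_lateral")
  up <- seg$direction_label == 2L
  # up-labelled voxels concentrate on the plagiotropic branch
  expect_gte(sum(up & fx$truth$labels == 2L) / sum(up), 0.9)
})

test_that("every labelled voxel stays 26-connected to the seed", {
  seg <- tracked_fixture("fig2_like")
  seedvox <- c(round(seg$seed), 1L)
  expect_true(all_connected_to(seg$mask, seedvox))
})

test_that("the scheduler terminates with all markers resolved", {
  seg <- tracked_fixture("fig2_like")
  expect_true(all(seg$marker_log$status %in% c("consumed", "discarded")))
  expect_lte(seg$pass_count, 1L + nrow(seg$marker_log))
  expect_gte(seg$pass_count, 3L)  # primary + upward + its downward lateral
  expect_setequal(unique(seg$marker_log$direction), c("up", "down"))
})

test_that("tracking is deterministic", {
  fx <- phantom_fixture("one_upward_lateral")
  a <- extract_root_system(fx$stack, fx$seed, tracker_config())
  b <- extract_root_system(fx$stack, fx$seed, tracker_config())
  expect_identical(a$mask, b$mask)
  expect_identical(a$direction_label, b$direction_label)
  expect_identical(a$marker_log, b$marker_log)
})

test_that("advance terminates cleanly when the root ends", {
  # a short root: below its tip the tracker must report target loss
  fx <- cylinder_fixture(n_slices = 30)
  spec <- phantom_spec(
    shape = c(48, 48, 40),
    branches = list(branch_spec(rbind(c(2, 24, 24), c(15, 24, 24)),
                                radius_start = 4, radius_end = 3)),
    rng_seed = 5L)
  truth <- rasterize_branches(spec)
  stack <- render_greyscale(truth$mask, spec)
  seg <- extract_root_system(stack, c(24, 24), tracker_config())
  labelled_slices <- which(apply(seg$mask, 3L, any))
  expect_lte(max(labelled_slices), 20L)
  expect_equal(seg$pass_count, 1L)
})
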