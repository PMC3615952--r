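# Appearance model, similarity gating, connected components and the
# level-set evolution.

test_that("appearance histograms are normalized over shared breaks", {
  br <- model_breaks(0:255, 64)
  m <- appearance_model(c(10, 10, 200, 30), br)
  expect_equal(sum(m$hist), 1, tolerance = 1e-12)
  expect_equal(m$n_pixels, 4L)
  expect_length(m$hist, 64L)
  empty <- appearance_model(numeric(0), br)
  expect_equal(sum(empty$hist), 0)
})

test_that("similarity is the Bhattacharyya coefficient with its identities", {
  br <- model_breaks(0:255, 64)
  a <- appearance_model(runif(200, 0, 255), br)
  expect_equal(similarity(a, a), 1, tolerance = 1e-9)
  lo <- appearance_model(runif(100, 0, 100), br)
  hi <- appearance_model(runif(100, 150, 255), br)
  expect_equal(similarity(lo, hi), 0)
  # uniform over 2 bins vs all mass in one of them -> sqrt(0.5)
  u2 <- structure(list(hist = c(0.5, 0.5), breaks = 0:2, n_pixels = 2L),
                  class = "appearance_model")
  one <- structure(list(hist = c(1, 0), breaks = 0:2, n_pixels = 1L),
                   class = "appearance_model")
  expect_equal(similarity(u2, one), sqrt(0.5), tolerance = 1e-12)
  expect_error(similarity(a, u2), "bin counts")
})

test_that("similarity is symmetric and bounded on random histograms", {
  br <- model_breaks(0:255, 32)
  withr::with_seed(1, {
    for (i in 1:20) {
      a <- appearance_model(runif(sample(5:300, 1), 0, 255), br)
      b <- appearance_model(runif(sample(5:300, 1), 0, 255), br)
      s <- similarity(a, b)
      expect_equal(s, similarity(b, a))
      expect_gte(s, 0); expect_lte(s, 1)
    }
  })
})

test_that("update_model replaces at similarity >= beta (inclusive) only", {
  br <- model_breaks(0:255, 64)
  cur <- appearance_model(runif(100, 0, 255), br)
  obs <- appearance_model(runif(100, 0, 255), br)
  # identical histograms: similarity 1, replaced for any beta <= 1
  twin <- appearance_model(rep(42, 30), br)
  expect_identical(update_model(twin, twin, beta = 1), twin)
  lo <- appearance_model(runif(50, 0, 100), br)
  hi <- appearance_model(runif(50, 150, 255), br)
  expect_identical(update_model(lo, hi, beta = 0.246), lo)  # sim 0 < beta
  s <- similarity(cur, obs)
  expect_identical(update_model(cur, obs, beta = s), obs)  # boundary: accept
  expect_equal(sum(update_model(cur, obs, beta = s)$hist), 1,
               tolerance = 1e-9)
})

test_that("connected components match definitions and stay a partition", {
  two <- rbind(c(2, 2), c(2, 3), c(10, 10))
  expect_length(connected_components(two, 8L), 2L)
  diag_px <- rbind(c(1, 1), c(2, 2))
  expect_length(connected_components(diag_px, 8L), 1L)
  expect_length(connected_components(diag_px, 4L), 2L)
  expect_length(connected_components(rhizotrack:::px_empty(), 8L), 0L)

  withr::with_seed(42, {
    for (rep in 1:5) {
      m <- matrix(runif(32 * 32) < 0.4, 32, 32)
      px <- which(m, arr.ind = TRUE)
      colnames(px) <- c("row", "col")
      for (conn in c(4L, 8L)) {
        got <- connected_components(px, conn)
        # partition: disjoint, union equals input
        expect_equal(sum(vapply(got, nrow, integer(1))), nrow(px))
        expect_equal(nrow(unique(do.call(rbind, got))), nrow(px))
        # identical to the BFS oracle, component by component
        ora <- bfs_label(px, conn)
        expect_equal(length(got), length(ora))
        for (i in seq_along(got)) {
          expect_equal(unname(got[[i]]), unname(ora[[i]]))
        }
      }
    }
  })
})

make_disc_slice <- function(n = 64, center = c(32, 32), radius = 8,
                            fg = 200, bg = 50, sd = 3, seed = 1) {
  withr::with_seed(seed, {
    img <- matrix(bg, n, n)
    d2 <- (row(img) - center[1L])^2 + (col(img) - center[2L])^2
    img[d2 <= radius^2] <- fg
    img + matrix(rnorm(n * n, 0, sd), n, n)
  })
}

test_that("evolving from the true region is (near) a fixed point", {
  img <- make_disc_slice()
  truth <- which((row(img) - 32)^2 + (col(img) - 32)^2 <= 64, arr.ind = TRUE)
  colnames(truth) <- c("row", "col")
  cfg <- tracker_config()
  br <- model_breaks(img, cfg$bins)
  model <- appearance_model(img[truth], br)
  out <- evolve_levelset(img, truth, model, cfg)
  # differences confined to a 1-pixel boundary band
  sym <- c(setdiff_px <- nrow(rhizotrack:::px_setdiff(out, truth, 64L)),
           nrow(rhizotrack:::px_setdiff(truth, out, 64L)))
  band <- nrow(truth[((truth[, 1L] - 32)^2 + (truth[, 2L] - 32)^2) > 49, ])
  expect_lte(sum(sym), band + 20)
  expect_gte(nrow(out), 0.8 * nrow(truth))
})

test_that("a disc is recovered from a seed against the Otsu oracle", {
  img <- make_disc_slice()
  st <- image_stack(array(img, c(64, 64, 1)), 10)
  ob <- init_from_click(st, c(32, 32), tracker_config())
  thr <- otsu_threshold(img)
  ora <- which(img > thr, arr.ind = TRUE)
  colnames(ora) <- c("row", "col")
  ora <- bfs_label(ora, 8L)
  seedcomp <- ora[[which(vapply(ora, function(p) {
    any(p[, 1L] == 32 & p[, 2L] == 32)
  }, logical(1)))]]
  inter <- rhizotrack:::px_intersect_n(ob$pixels, seedcomp, 64L)
  expect_gte(inter / nrow(seedcomp), 0.85)
  expect_gte(inter / nrow(ob$pixels), 0.85)
  expect_equal(sum(ob$model$hist), 1, tolerance = 1e-9)
})

test_that("alpha = 0 is pure curvature flow: area shrinks monotonically", {
  img <- make_disc_slice(sd = 0)
  truth <- which((row(img) - 32)^2 + (col(img) - 32)^2 <= 64, arr.ind = TRUE)
  colnames(truth) <- c("row", "col")
  br <- model_breaks(img, 64)
  model <- appearance_model(img[truth], br)
  areas <- integer(0)
  px <- truth
  for (it in 1:10) {
    px2 <- evolve_levelset(img, px, model,
                           tracker_config(alpha = 0, max_iter = 1))
    areas <- c(areas, nrow(px2))
    if (!nrow(px2)) break
    px <- px2
  }
  expect_true(all(diff(c(nrow(truth), areas)) <= 0))
  expect_lt(areas[length(areas)], nrow(truth))
})

test_that("evolution stays within the reachable band and can report loss", {
  img <- make_disc_slice()
  init <- rbind(c(10, 50), c(10, 51), c(11, 50), c(11, 51))
  colnames(init) <- c("row", "col")
  cfg <- tracker_config(max_iter = 15)
  br <- model_breaks(img, cfg$bins)
  # model of bright material, but seeded on background: region collapses
  truth <- which(img > 150, arr.ind = TRUE)
  model <- appearance_model(img[truth], br)
  out <- evolve_levelset(img, init, model, cfg)
  if (nrow(out)) {
    # speed is bounded by one pixel per iteration
    dmin <- min(outer(out[, 1L], init[, 1L], `-`)^2 +
                outer(out[, 2L], init[, 2L], `-`)^2)
    expect_lte(sqrt(dmin), cfg$max_iter + 1)
  }
  expect_lte(nrow(out), 4L)  # background seed under a root model collapses
})

test_that("seeds growing below min_area are rejected", {
  img <- make_disc_slice(radius = 2)  # 13-pixel disc
  st <- image_stack(array(img, c(64, 64, 1)), 10)
  expect_error(init_from_click(st, c(32, 32), tracker_config(min_area = 60)),
               "seed rejected")
  expect_error(init_from_click(st, c(500, 2), tracker_config()),
               "inside slice 1")
})
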