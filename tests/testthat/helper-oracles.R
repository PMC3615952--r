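# Independent oracles and shared fixtures for the test suite.  Everything
# here is deliberately implemented differently from the package internals
# it checks.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# --- queue-based BFS connected-component labeller (2-D oracle) ----------
bfs_label <- function(pixels, connectivity = 8L) {
  n <- nrow(pixels)
  if (!n) return(list())
  key <- paste(pixels[, 1L], pixels[, 2L])
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(n)) assign(key[i], i, envir = lookup)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L) {
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  seen <- logical(n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    queue <- i; seen[i] <- TRUE; members <- integer(0)
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, cur)
      for (o in seq_len(nrow(offs))) {
        k <- paste(pixels[cur, 1L] + offs[o, 1L],
                   pixels[cur, 2L] + offs[o, 2L])
        j <- mget(k, envir = lookup, ifnotfound = list(NULL))[[1L]]
        if (!is.null(j) && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
      }
    }
    m <- pixels[members, , drop = FALSE]
    comps[[length(comps) + 1L]] <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  }
  key2 <- vapply(comps, function(p) p[1L, 1L] * 2^26 + p[1L, 2L], numeric(1))
  comps[order(key2)]
}

# --- exact brute-force minimum enclosing circle --------------------------
# Enumerates candidate circles from point pairs and triples and keeps the
# smallest that contains every point.  `reduce_hull` first restricts the
# candidate determinants to convex-hull vertices (which provably contain
# the MEC's support set) so big instances stay feasible; containment is
# always checked against all points.
brute_mec <- function(pts, reduce_hull = FALSE) {
  pts <- as.matrix(pts)
  cand <- if (reduce_hull && nrow(pts) > 10L) {
    pts[grDevices::chull(pts[, 1L], pts[, 2L]), , drop = FALSE]
  } else pts
  m <- nrow(cand)
  contains <- function(c0, r0) {
    all((pts[, 1L] - c0[1L])^2 + (pts[, 2L] - c0[2L])^2 <= (r0 + 1e-9)^2)
  }
  best <- list(center = cand[1L, ], radius = Inf)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    c0 <- (cand[i, ] + cand[j, ]) / 2
    r0 <- sqrt(sum((cand[i, ] - cand[j, ])^2)) / 2
    if (r0 < best$radius && contains(c0, r0)) {
      best <- list(center = c0, radius = r0)
    }
  }
  if (m >= 3L) {
    for (i in seq_len(m - 2L)) for (j in (i + 1L):(m - 1L)) for (k in (j + 1L):m) {
      p <- cand[i, ]; q <- cand[j, ]; r <- cand[k, ]
      d <- 2 * (p[1L] * (q[2L] - r[2L]) + q[1L] * (r[2L] - p[2L]) +
                r[1L] * (p[2L] - q[2L]))
      if (abs(d) < 1e-12) next
      ux <- (sum(p^2) * (q[2L] - r[2L]) + sum(q^2) * (r[2L] - p[2L]) +
             sum(r^2) * (p[2L] - q[2L])) / d
      uy <- (sum(p^2) * (r[1L] - q[1L]) + sum(q^2) * (p[1L] - r[1L]) +
             sum(r^2) * (q[1L] - p[1L])) / d
      c0 <- c(ux, uy)
      r0 <- sqrt(sum((p - c0)^2))
      if (r0 < best$radius && contains(c0, r0)) {
        best <- list(center = c0, radius = r0)
      }
    }
  }
  best
}

# --- Otsu threshold (histogram between-class variance) -------------------
otsu_threshold <- function(v) {
  h <- hist(v, breaks = 64, plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- mids[1L]; bestv <- -Inf
  for (t in seq_along(mids)[-length(mids)]) {
    w0 <- sum(w[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(w[1:t] * mids[1:t]) / w0
    m1 <- sum(w[(t + 1):length(w)] * mids[(t + 1):length(w)]) / w1
    v_b <- w0 * w1 * (m0 - m1)^2
    if (v_b > bestv) { bestv <- v_b; best <- (mids[t] + mids[t + 1L]) / 2 }
  }
  best
}

# --- frontier-propagation reachability in 3-D (26-connectivity) ----------
all_connected_to <- function(mask, seed_voxel) {
  d <- dim(mask)
  pd <- d + 2L
  pm <- array(FALSE, pd)
  pm[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- mask
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  lin_offs <- offs[, 1L] + offs[, 2L] * pd[1L] + offs[, 3L] * pd[1L] * pd[2L]
  visited <- array(FALSE, pd)
  start <- (seed_voxel[3L]) * pd[1L] * pd[2L] + (seed_voxel[2L]) * pd[1L] +
    seed_voxel[1L] + 1L
  if (!pm[start]) return(FALSE)
  visited[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, lin_offs, `+`)))
    nb <- nb[pm[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  all(visited[pm])
}

# --- shared small phantom fixtures (built once per test run) -------------
.fixture_env <- new.env(parent = emptyenv())

phantom_fixture <- function(name, size_scale = 0.5, rng_seed = 7L,
                            organic_fraction = 0.02) {
  key <- paste(name, size_scale, rng_seed, organic_fraction)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  spec <- builtin_phantoms(name, size_scale = size_scale,
                          rng_seed = rng_seed,
                          organic_fraction = organic_fraction)
  truth <- rasterize_branches(spec)
  stack <- render_greyscale(truth$mask, spec)
  seed <- round(colMeans(which(truth$mask[, , 1L], arr.ind = TRUE)))
  fx <- list(spec = spec, truth = truth, stack = stack, seed = seed)
  .fixture_env[[key]] <- fx
  fx
}

tracked_fixture <- function(name, forward_only = FALSE, size_scale = 0.5,
                            rng_seed = 7L) {
  key <- paste("seg", name, forward_only, size_scale, rng_seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  fx <- phantom_fixture(name, size_scale, rng_seed)
  seg <- extract_root_system(fx$stack, fx$seed,
                             tracker_config(forward_only = forward_only))
  .fixture_env[[key]] <- seg
  seg
}

# minimal independent ascii-PLY parser (the package writer's oracle)
parse_ply <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  body <- which(lines == "end_header") + 1L
  verts <- if (nv > 0) {
    do.call(rbind, lapply(lines[body:(body + nv - 1L)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    }))
  } else matrix(0, 0, 3)
  faces <- if (nf > 0) {
    do.call(rbind, lapply(lines[(body + nv):(body + nv + nf - 1L)],
                          function(l) {
      as.integer(strsplit(trimws(l), "\\s+")[[1L]])[-1L] + 1L
    }))
  } else matrix(0L, 0, 3)
  list(vertices = verts, faces = faces)
}
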