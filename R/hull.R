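# 3-D convex hull by the QuickHull algorithm, plus exact and Monte Carlo
# hull volumes.  Written against the usual formulation: build an initial
# simplex from extreme points, then repeatedly lift the farthest outside
# point of any face, deleting the faces it sees and stitching new faces
# onto the horizon.

#' 3-D convex hull (QuickHull)
#'
#' @param points n x 3 numeric matrix.
#' @return list with `faces` (m x 3 indices into `points`, outward
#'   oriented), `normals` (m x 3 unit normals), `offsets` (m, so a point x
#'   is inside iff `normals %*% x <= offsets` for every face), `vertices`
#'   (indices of points on the hull), `volume` (exact, by fan
#'   decomposition), and `degenerate` (TRUE when the input has no 3-D
#'   extent; then volume is 0 and faces are empty).
#' @export
quickhull3 <- function(points) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("points must be n x 3")
  pts <- pts[!duplicated(round(pts, 12L)), , drop = FALSE]
  n <- nrow(pts)
  degen <- list(faces = matrix(0L, 0, 3), normals = matrix(0, 0, 3),
                offsets = numeric(0), vertices = integer(0), volume = 0,
                degenerate = TRUE)
  if (n < 4L) return(degen)
  scale <- max(1, max(abs(pts)))
  eps <- 1e-9 * scale

  # initial simplex: farthest pair among axis extremes, farthest from the
  # line, farthest from the plane
  ext <- unique(c(apply(pts, 2L, which.min), apply(pts, 2L, which.max)))
  best <- c(ext[1L], ext[2L]); bd <- -1
  for (i in ext) for (j in ext) {
    d <- sum((pts[i, ] - pts[j, ])^2)
    if (d > bd) { bd <- d; best <- c(i, j) }
  }
  p1 <- best[1L]; p2 <- best[2L]
  if (bd < eps^2) return(degen)
  ab <- pts[p2, ] - pts[p1, ]
  rel <- sweep(pts, 2L, pts[p1, ])
  cr <- cbind(rel[, 2L] * ab[3L] - rel[, 3L] * ab[2L],
              rel[, 3L] * ab[1L] - rel[, 1L] * ab[3L],
              rel[, 1L] * ab[2L] - rel[, 2L] * ab[1L])
  dline <- sqrt(rowSums(cr^2)) / sqrt(sum(ab^2))
  p3 <- which.max(dline)
  if (dline[p3] < eps) return(degen)
  nrm <- cross3(pts[p2, ] - pts[p1, ], pts[p3, ] - pts[p1, ])
  dplane <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  p4 <- which.max(dplane)
  if (dplane[p4] < eps) return(degen)

  centroid <- colMeans(pts[c(p1, p2, p3, p4), , drop = FALSE])
  faces <- list()
  add_face <- function(i, j, k, candidates) {
    nn <- cross3(pts[j, ] - pts[i, ], pts[k, ] - pts[i, ])
    ln <- sqrt(sum(nn^2))
    if (ln < 1e-300) return(NULL)
    nn <- nn / ln
    d <- sum(nn * pts[i, ])
    if (sum(nn * centroid) > d) { nn <- -nn; d <- -d; tmp <- j; j <- k; k <- tmp }
    out <- if (length(candidates)) {
      dist <- pts[candidates, , drop = FALSE] %*% nn - d
      candidates[dist > eps]
    } else integer(0)
    list(v = c(i, j, k), n = nn, d = d, outside = out, alive = TRUE)
  }
  all_idx <- setdiff(seq_len(n), c(p1, p2, p3, p4))
  combs <- rbind(c(p1, p2, p3), c(p1, p2, p4), c(p1, p3, p4), c(p2, p3, p4))
  for (r in 1:4) {
    f <- add_face(combs[r, 1L], combs[r, 2L], combs[r, 3L], all_idx)
    faces[[length(faces) + 1L]] <- f
  }

  repeat {
    keep <- vapply(faces, function(f) !is.null(f) && f$alive, logical(1))
    faces <- faces[keep]
    fi <- 0L
    for (i in seq_along(faces)) {
      f <- faces[[i]]
      if (!is.null(f) && f$alive && length(f$outside)) { fi <- i; break }
    }
    if (fi == 0L) break
    f <- faces[[fi]]
    dist <- pts[f$outside, , drop = FALSE] %*% f$n - f$d
    p <- f$outside[which.max(dist)]
    # faces visible from p
    visible <- integer(0)
    for (i in seq_along(faces)) {
      g <- faces[[i]]
      if (!is.null(g) && g$alive && sum(g$n * pts[p, ]) - g$d > eps) {
        visible <- c(visible, i)
      }
    }
    # horizon: edges appearing once among the visible faces
    edges <- do.call(rbind, lapply(faces[visible], function(g) {
      rbind(sort(g$v[c(1L, 2L)]), sort(g$v[c(2L, 3L)]), sort(g$v[c(1L, 3L)]))
    }))
    ekey <- paste(edges[, 1L], edges[, 2L])
    horizon <- edges[ekey %in% names(which(table(ekey) == 1L)), ,
                     drop = FALSE]
    orphan <- unique(unlist(lapply(faces[visible], `[[`, "outside")))
    orphan <- setdiff(orphan, p)
    for (i in visible) faces[[i]]$alive <- FALSE
    for (r in seq_len(nrow(horizon))) {
      nf <- add_face(horizon[r, 1L], horizon[r, 2L], p, orphan)
      if (!is.null(nf)) {
        faces[[length(faces) + 1L]] <- nf
        orphan <- setdiff(orphan, nf$outside)
      }
    }
  }

  alive <- vapply(faces, function(f) !is.null(f) && f$alive, logical(1))
  faces <- faces[alive]
  fv <- do.call(rbind, lapply(faces, `[[`, "v"))
  normals <- do.call(rbind, lapply(faces, `[[`, "n"))
  offsets <- vapply(faces, `[[`, numeric(1), "d")
  vol <- 0
  for (i in seq_along(faces)) {
    a <- pts[fv[i, 1L], ] - centroid
    b <- pts[fv[i, 2L], ] - centroid
    c_ <- pts[fv[i, 3L], ] - centroid
    vol <- vol + abs(sum(a * cross3(b, c_))) / 6
  }
  # map back to the caller's row indices (duplicates were dropped)
  list(faces = fv, normals = normals, offsets = offsets,
       vertices = sort(unique(as.vector(fv))), volume = vol,
       degenerate = FALSE, points = pts)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Monte Carlo volume of a convex hull
#'
#' Samples uniformly in the hull's axis-aligned bounding box and reports
#' `hits / n * bbox_volume`.
#'
#' @param hull result of [quickhull3()].
#' @param n_samples number of samples.
#' @param rng_seed seed (sampling is the only randomness).
#' @return list with `estimate`, `exact` (fan-decomposition volume),
#'   `hits`, `n_samples`, `bbox_volume`.
#' @export
hull_volume_mc <- function(hull, n_samples = 1e6, rng_seed = 1L) {
  if (hull$degenerate) {
    return(list(estimate = 0, exact = 0, hits = 0L,
                n_samples = as.integer(n_samples), bbox_volume = 0))
  }
  pts <- hull$points
  lo <- apply(pts, 2L, min); hi <- apply(pts, 2L, max)
  vbox <- prod(hi - lo)
  n_samples <- as.integer(n_samples)
  hits <- 0L
  with_seed(rng_seed, {
    chunk <- 50000L
    done <- 0L
    while (done < n_samples) {
      m <- min(chunk, n_samples - done)
      s <- cbind(stats::runif(m, lo[1L], hi[1L]),
                 stats::runif(m, lo[2L], hi[2L]),
                 stats::runif(m, lo[3L], hi[3L]))
      inside <- rep(TRUE, m)
      d <- s %*% t(hull$normals)
      inside <- rowSums(d > rep(hull$offsets + 1e-12, each = m)) == 0L
      hits <- hits + sum(inside)
      done <- done + m
    }
  })
  list(estimate = hits / n_samples * vbox, exact = hull$volume,
       hits = as.integer(hits), n_samples = n_samples, bbox_volume = vbox)
}
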