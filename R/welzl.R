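#' Minimum enclosing circle (Welzl's algorithm)
#'
#' Exact smallest circle containing a planar point set, by Welzl's
#' randomized incremental construction (expected linear time).  The shuffle
#' is seeded for reproducibility but the result — the unique minimum
#' enclosing circle — does not depend on it.
#'
#' @param points n x 2 numeric matrix.
#' @param rng_seed seed for the initial shuffle.
#' @return list with `center` (length 2) and `radius`.
#' @export
#' @examples
#' min_enclosing_circle(rbind(c(0, 0), c(2, 0)))$radius  # 1
min_enclosing_circle <- function(points, rng_seed = 1L) {
  pts <- as.matrix(points)
  if (!nrow(pts)) stop("point set is empty")
  if (ncol(pts) != 2L) stop("points must be n x 2")
  pts <- pts[!duplicated(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n == 1L) return(list(center = as.numeric(pts[1L, ]), radius = 0))
  if (n > 500L) {
    # only convex-hull points can determine the circle
    h <- grDevices::chull(pts[, 1L], pts[, 2L])
    pts <- pts[h, , drop = FALSE]
    n <- nrow(pts)
  }
  perm <- with_seed(rng_seed, sample.int(n))
  pts <- pts[perm, , drop = FALSE]
  eps <- 1e-10 * (1 + max(abs(pts)))
  inside <- function(c, p) {
    sqrt(sum((p - c$center)^2)) <= c$radius + eps
  }
  circ2 <- function(p, q) {
    list(center = (p + q) / 2, radius = sqrt(sum((p - q)^2)) / 2)
  }
  circ3 <- function(p, q, r) {
    d <- 2 * (p[1L] * (q[2L] - r[2L]) + q[1L] * (r[2L] - p[2L]) +
              r[1L] * (p[2L] - q[2L]))
    if (abs(d) < 1e-14 * (1 + max(abs(c(p, q, r))))^2) {
      # collinear: widest two-point circle
      cands <- list(circ2(p, q), circ2(p, r), circ2(q, r))
      return(cands[[which.max(vapply(cands, `[[`, numeric(1), "radius"))]])
    }
    p2 <- sum(p^2); q2 <- sum(q^2); r2 <- sum(r^2)
    ux <- (p2 * (q[2L] - r[2L]) + q2 * (r[2L] - p[2L]) +
           r2 * (p[2L] - q[2L])) / d
    uy <- (p2 * (r[1L] - q[1L]) + q2 * (p[1L] - r[1L]) +
           r2 * (q[1L] - p[1L])) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((p - ctr)^2)))
  }
  circ <- list(center = as.numeric(pts[1L, ]), radius = 0)
  for (i in 2:n) {
    pi_ <- pts[i, ]
    if (inside(circ, pi_)) next
    circ <- list(center = pi_, radius = 0)
    for (j in seq_len(i - 1L)) {
      pj <- pts[j, ]
      if (inside(circ, pj)) next
      circ <- circ2(pi_, pj)
      for (k in seq_len(j - 1L)) {
        pk <- pts[k, ]
        if (inside(circ, pk)) next
        circ <- circ3(pi_, pj, pk)
      }
    }
  }
  circ
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
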