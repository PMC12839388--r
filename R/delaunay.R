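## Bowyer-Watson Delaunay triangulation in pure R.  Adequate for point
## clouds up to a few thousand points (each insertion scans all live
## triangles, vectorized).  Exactly duplicated points are deterministically
## perturbed; cocircular ties are broken by floating-point evaluation
## order, which is deterministic for a fixed input.

#' Delaunay triangulation of 2D points
#'
#' @param x,y coordinates (or a 2-column matrix as `x`)
#' @return integer matrix, one row per triangle, vertex indices into the
#'   input; attribute `edges`: 2-column matrix of unique edges (including
#'   convex-hull edges of degenerate configurations)
#' @export
delaunay_triangulation <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2L]; x <- x[, 1L] }
  n <- length(x)
  if (n < 2L) {
    out <- matrix(integer(0), 0L, 3L)
    attr(out, "edges") <- matrix(integer(0), 0L, 2L)
    return(out)
  }
  # deterministic perturbation of exact duplicates
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    ext <- max(diff(range(x)), diff(range(y)), 1)
    k <- which(dup)
    x[k] <- x[k] + ext * 1e-9 * seq_along(k)
    y[k] <- y[k] + ext * 1e-9 * seq_along(k) * 0.61803398875
  }
  cx <- mean(range(x)); cy <- mean(range(y))
  big <- 20 * max(diff(range(x)), diff(range(y)), 1)
  px <- c(x, cx - 3 * big, cx + 3 * big, cx)
  py <- c(y, cy - big, cy - big, cy + 3 * big)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  circum <- function(a, b, c) {
    ax <- px[a]; ay <- py[a]; bx <- px[b]; by <- py[b]
    ccx <- px[c]; ccy <- py[c]
    d <- 2 * (ax * (by - ccy) + bx * (ccy - ay) + ccx * (ay - by))
    if (abs(d) < 1e-300) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - ccy) + (bx^2 + by^2) * (ccy - ay) +
             (ccx^2 + ccy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (ccx - bx) + (bx^2 + by^2) * (ax - ccx) +
             (ccx^2 + ccy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }

  cap <- max(64L, 4L * n)
  tri <- matrix(NA_integer_, cap, 3L)
  cc <- matrix(NA_real_, cap, 3L)            # cx, cy, r2
  alive <- logical(cap)
  tri[1L, ] <- c(s1, s2, s3)
  cc[1L, ] <- circum(s1, s2, s3)
  alive[1L] <- TRUE
  ntri <- 1L

  for (i in seq_len(n)) {
    live <- which(alive[seq_len(ntri)])
    d2 <- (px[i] - cc[live, 1L])^2 + (py[i] - cc[live, 2L])^2
    # a point numerically on a circumcircle counts as inside: keeps the
    # cavity valid for cocircular configurations (ties broken the same
    # deterministic way on every run)
    bad <- live[d2 <= cc[live, 3L] * (1 + 1e-9)]
    if (!length(bad)) bad <- live[which.min(d2 - cc[live, 3L])]
    # cavity boundary: edges of bad triangles occurring exactly once
    e <- rbind(tri[bad, c(1L, 2L)], tri[bad, c(2L, 3L)],
               tri[bad, c(3L, 1L)])
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    once <- names(which(table(key) == 1L))
    boundary <- e[key %in% once, , drop = FALSE]
    alive[bad] <- FALSE
    for (k in seq_len(nrow(boundary))) {
      ntri <- ntri + 1L
      if (ntri > cap) {
        cap <- cap * 2L
        tri <- rbind(tri, matrix(NA_integer_, cap - nrow(tri), 3L))
        cc <- rbind(cc, matrix(NA_real_, cap - nrow(cc), 3L))
        alive <- c(alive, logical(cap - length(alive)))
      }
      tri[ntri, ] <- c(boundary[k, ], i)
      cc[ntri, ] <- circum(boundary[k, 1L], boundary[k, 2L], i)
      alive[ntri] <- TRUE
    }
  }

  live <- which(alive[seq_len(ntri)])
  all_tri <- tri[live, , drop = FALSE]
  real <- rowSums(all_tri <= n) == 3L
  # real-real edges, including those only present in super-triangles
  # (hull edges of collinear configurations)
  e <- rbind(all_tri[, c(1L, 2L)], all_tri[, c(2L, 3L)],
             all_tri[, c(3L, 1L)])
  e <- e[e[, 1L] <= n & e[, 2L] <= n, , drop = FALSE]
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  out <- all_tri[real, , drop = FALSE]
  attr(out, "edges") <- e
  attr(out, "perturbed") <- any(dup)
  out
}
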