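## Alpha-filtration persistent homology of 2D point clouds.  The alpha
## parameter is a radius in nm: a growing disc around every point.
## Simplices of the Delaunay triangulation enter the filtration at
## - vertices: 0,
## - edges: half their length when Gabriel (empty diametral disc),
##   otherwise the value of their smallest incident triangle,
## - triangles: their circumradius.
## In general position this filtration has the same persistence diagram
## as the Cech filtration of growing discs.  Dimension-0 features are
## connected components (union-find over edges); dimension-1 features
## are holes (Z2 boundary-matrix reduction of triangle columns).

#' @noRd
circumradius <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-300) return(Inf)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  sqrt((ux - ax)^2 + (uy - ay)^2)
}

#' Alpha-filtration persistence barcode of a 2D point cloud
#'
#' @param x,y coordinates in nm (or a 2-column matrix as `x`)
#' @param alpha_max_nm truncation radius (default 500 nm); intervals are
#'   clipped to `[0, alpha_max_nm]`, and the everlasting component is
#'   reported with death `alpha_max_nm` and `essential = TRUE`
#' @param drop_zero drop zero-persistence intervals (default TRUE)
#' @return a `barcode`: data.frame with columns `dimension` (0 or 1),
#'   `birth_nm`, `death_nm`, `essential`; attributes `n_points`,
#'   `alpha_max_nm`
#' @export
alpha_persistence <- function(x, y = NULL, alpha_max_nm = 500,
                              drop_zero = TRUE) {
  if (is.null(y)) { y <- x[, 2L]; x <- x[, 1L] }
  n <- length(x)
  if (n < 1L) stopf("alpha_persistence needs at least one point")
  check_num(alpha_max_nm, "alpha_max_nm", lower = 1e-9)
  if (n == 1L) {
    return(new_barcode(data.frame(dimension = 0L, birth_nm = 0,
                                  death_nm = alpha_max_nm,
                                  essential = TRUE),
                       n, alpha_max_nm))
  }
  tris <- delaunay_triangulation(x, y)
  edges <- attr(tris, "edges")
  ne <- nrow(edges)
  nt <- nrow(tris)

  tri_val <- if (nt) vapply(seq_len(nt), function(t)
    circumradius(x[tris[t, 1L]], y[tris[t, 1L]],
                 x[tris[t, 2L]], y[tris[t, 2L]],
                 x[tris[t, 3L]], y[tris[t, 3L]]), numeric(1))
  else numeric(0)

  # edge -> incident triangles
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edge_id <- setNames(seq_len(ne), ekey(edges[, 1L], edges[, 2L]))
  tri_edges <- if (nt) matrix(edge_id[c(ekey(tris[, 1L], tris[, 2L]),
                                        ekey(tris[, 2L], tris[, 3L]),
                                        ekey(tris[, 3L], tris[, 1L]))],
                              nt, 3L)
  else matrix(integer(0), 0L, 3L)

  edge_len <- sqrt((x[edges[, 1L]] - x[edges[, 2L]])^2 +
                     (y[edges[, 1L]] - y[edges[, 2L]])^2)
  edge_val <- edge_len / 2
  inc_min <- rep(Inf, ne)
  gabriel <- rep(TRUE, ne)
  if (nt) {
    for (t in seq_len(nt)) {
      vs <- tris[t, ]
      for (k in 1:3) {
        eid <- tri_edges[t, k]
        inc_min[eid] <- min(inc_min[eid], tri_val[t])
        opp <- vs[!(vs %in% edges[eid, ])]
        mx <- (x[edges[eid, 1L]] + x[edges[eid, 2L]]) / 2
        my <- (y[edges[eid, 1L]] + y[edges[eid, 2L]]) / 2
        if ((x[opp] - mx)^2 + (y[opp] - my)^2 < edge_val[eid]^2)
          gabriel[eid] <- FALSE
      }
    }
    edge_val[!gabriel] <- inc_min[!gabriel]
  }

  # ---- dimension 0: union-find over edges in filtration order
  eord <- order(edge_val, seq_len(ne))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  deaths0 <- numeric(0)
  positive <- logical(ne)          # edges creating a 1-cycle
  for (e in eord) {
    ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
    if (ra == rb) positive[e] <- TRUE
    else { parent[ra] <- rb; deaths0 <- c(deaths0, edge_val[e]) }
  }

  # ---- dimension 1: reduce triangle columns over the global edge order
  pairs1 <- NULL
  if (nt) {
    epos <- integer(ne); epos[eord] <- seq_len(ne)  # edge -> order pos
    tord <- order(tri_val, seq_len(nt))
    lowtab <- integer(ne)            # order pos of low edge -> column id
    columns <- vector("list", nt)
    births <- numeric(0); tdeaths <- numeric(0)
    for (t in tord) {
      col <- sort(epos[tri_edges[t, ]])
      repeat {
        if (!length(col)) break
        lw <- col[length(col)]
        other <- lowtab[lw]
        if (other == 0L) break
        col <- sort(c(setdiff(col, columns[[other]]),
                      setdiff(columns[[other]], col)))
      }
      if (length(col)) {
        lw <- col[length(col)]
        lowtab[lw] <- t
        columns[[t]] <- col
        be <- eord[lw]               # the paired (positive) edge
        births <- c(births, edge_val[be])
        tdeaths <- c(tdeaths, tri_val[t])
      }
    }
    pairs1 <- data.frame(birth = births, death = tdeaths)
    # positive edges never filled by a triangle: essential 1-cycles of
    # the truncated filtration
    unpaired <- which(positive)[!(epos[which(positive)] %in%
                                    which(lowtab != 0L))]
    if (length(unpaired))
      pairs1 <- rbind(pairs1, data.frame(birth = edge_val[unpaired],
                                         death = Inf))
  } else if (any(positive)) {
    pairs1 <- data.frame(birth = edge_val[positive], death = Inf)
  }

  bars <- data.frame(dimension = integer(0), birth_nm = numeric(0),
                     death_nm = numeric(0), essential = logical(0))
  if (length(deaths0))
    bars <- rbind(bars, data.frame(dimension = 0L, birth_nm = 0,
                                   death_nm = deaths0,
                                   essential = FALSE))
  bars <- rbind(bars, data.frame(dimension = 0L, birth_nm = 0,
                                 death_nm = Inf, essential = TRUE))
  if (!is.null(pairs1) && nrow(pairs1))
    bars <- rbind(bars, data.frame(dimension = 1L,
                                   birth_nm = pairs1$birth,
                                   death_nm = pairs1$death,
                                   essential = is.infinite(pairs1$death)))
  # truncate to [0, alpha_max]
  bars <- bars[bars$birth_nm < alpha_max_nm, , drop = FALSE]
  bars$death_nm <- pmin(bars$death_nm, alpha_max_nm)
  if (drop_zero) {
    # treat bars shorter than the numeric noise floor of the circumradius
    # computation as zero-persistence (exactly cocircular configurations)
    eps <- 1e-9 * pmax(1, bars$death_nm)
    bars <- bars[bars$death_nm - bars$birth_nm > eps | bars$essential, ,
                 drop = FALSE]
  }
  bars <- bars[order(bars$dimension, bars$birth_nm, bars$death_nm), ,
               drop = FALSE]
  rownames(bars) <- NULL
  new_barcode(bars, n, alpha_max_nm)
}

#' Construct a barcode from explicit persistence intervals
#'
#' Mostly useful for testing similarity measures; analysis code obtains
#' barcodes from [alpha_persistence()].
#'
#' @param dimension integer vector of homology dimensions (0 or 1)
#' @param birth_nm,death_nm interval endpoints (birth <= death;
#'   dimension-0 intervals are born at 0)
#' @param n_points point-cloud size the barcode describes
#' @param alpha_max_nm truncation radius
#' @return a `barcode`
#' @export
barcode <- function(dimension, birth_nm, death_nm, n_points = NA_integer_,
                    alpha_max_nm = max(c(death_nm, 500))) {
  stopifnot(length(dimension) == length(birth_nm),
            length(birth_nm) == length(death_nm))
  if (any(death_nm < birth_nm)) stopf("birth must not exceed death")
  if (any(!dimension %in% c(0L, 1L))) stopf("dimension must be 0 or 1")
  if (any(dimension == 0L & birth_nm != 0))
    stopf("dimension-0 intervals must be born at alpha = 0")
  bars <- data.frame(dimension = as.integer(dimension),
                     birth_nm = as.numeric(birth_nm),
                     death_nm = as.numeric(death_nm),
                     essential = logical(length(dimension)))
  new_barcode(bars, n_points, alpha_max_nm)
}

#' @noRd
new_barcode <- function(bars, n_points, alpha_max_nm) {
  structure(bars, class = c("barcode", "data.frame"),
            n_points = n_points, alpha_max_nm = as.numeric(alpha_max_nm))
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf(
    "barcode: %d points, alpha_max %g nm, %d components, %d holes\n",
    attr(x, "n_points"), attr(x, "alpha_max_nm"),
    sum(x$dimension == 0L), sum(x$dimension == 1L)))
  invisible(x)
}

#' Write / read a barcode as CSV
#'
#' @param barcode a `barcode`
#' @param path file path
#' @return `path` (write) or a `barcode` (read)
#' @export
write_barcode <- function(barcode, path) {
  df <- as.data.frame(barcode)
  df$n_points <- attr(barcode, "n_points")
  df$alpha_max_nm <- attr(barcode, "alpha_max_nm")
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode
#' @export
read_barcode <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",")
  new_barcode(df[, c("dimension", "birth_nm", "death_nm", "essential")],
              df$n_points[1L], df$alpha_max_nm[1L])
}
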