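## Independent brute-force oracles used across the suite.  These are
## deliberately simple O(n^2)/O(n^3) re-derivations from first
## principles, kept free of the package's data structures.

## ---- brute-force DBSCAN ----------------------------------------------
## Full distance-matrix implementation of the textbook definition:
## core = point with >= min_count neighbours within radius (self
## included); clusters = connected components of core points under
## mutual radius-reachability plus their border points; a border point
## reachable from several clusters joins the one discovered first when
## scanning seeds in ascending index order (cluster order = ascending
## minimal core index).
oracle_dbscan <- function(x, y, radius, min_count) {
  n <- length(x)
  if (n == 0L) return(list(labels = integer(0), is_core = logical(0)))
  d <- as.matrix(dist(cbind(x, y)))
  nbr <- d <= radius
  is_core <- rowSums(nbr) >= min_count
  labels <- integer(n)
  comp <- integer(n)          # component id per core point
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || comp[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      reach <- which(is_core & nbr[j, ] & comp == 0L)
      comp[reach] <- cid
      queue <- c(queue, reach)
    }
  }
  labels[is_core] <- comp[is_core]
  for (i in which(!is_core)) {
    cores <- which(is_core & nbr[i, ])
    if (length(cores)) labels[i] <- min(comp[cores])
  }
  list(labels = labels, is_core = is_core)
}

## ---- brute-force Cech persistence (2-skeleton) -----------------------
## Vertices at 0; every pair at half its distance; every triple at its
## minimum-enclosing-ball radius.  H0 by union-find, H1 by Z2 reduction
## of all triangle columns over the global edge order.  Zero-persistence
## pairs are dropped with the same noise floor as the implementation.
oracle_cech_persistence <- function(x, y, alpha_max = Inf) {
  n <- length(x)
  stopifnot(n >= 1L)
  meb_radius <- function(i, j, k) {
    d2 <- c((x[i] - x[j])^2 + (y[i] - y[j])^2,
            (x[j] - x[k])^2 + (y[j] - y[k])^2,
            (x[k] - x[i])^2 + (y[k] - y[i])^2)
    mx <- which.max(d2)
    if (d2[mx] >= sum(d2[-mx])) return(sqrt(d2[mx]) / 2)  # obtuse/right
    den <- 2 * (x[i] * (y[j] - y[k]) + x[j] * (y[k] - y[i]) +
                  x[k] * (y[i] - y[j]))
    ux <- ((x[i]^2 + y[i]^2) * (y[j] - y[k]) +
             (x[j]^2 + y[j]^2) * (y[k] - y[i]) +
             (x[k]^2 + y[k]^2) * (y[i] - y[j])) / den
    uy <- ((x[i]^2 + y[i]^2) * (x[k] - x[j]) +
             (x[j]^2 + y[j]^2) * (x[i] - x[k]) +
             (x[k]^2 + y[k]^2) * (x[j] - x[i])) / den
    sqrt((ux - x[i])^2 + (uy - y[i])^2)
  }
  edges <- if (n >= 2L) t(combn(n, 2L)) else matrix(integer(0), 0L, 2L)
  ne <- nrow(edges)
  edge_val <- sqrt((x[edges[, 1L]] - x[edges[, 2L]])^2 +
                     (y[edges[, 1L]] - y[edges[, 2L]])^2) / 2
  tris <- if (n >= 3L) t(combn(n, 3L)) else matrix(integer(0), 0L, 3L)
  nt <- nrow(tris)
  tri_val <- if (nt) vapply(seq_len(nt), function(t)
    meb_radius(tris[t, 1L], tris[t, 2L], tris[t, 3L]), numeric(1))
  else numeric(0)

  eord <- order(edge_val, seq_len(ne))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  deaths0 <- numeric(0)
  for (e in eord) {
    ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
    if (ra != rb) { parent[ra] <- rb
                    deaths0 <- c(deaths0, edge_val[e]) }
  }

  pairs1 <- data.frame(birth = numeric(0), death = numeric(0))
  if (nt) {
    epos <- integer(ne); epos[eord] <- seq_len(ne)
    eid <- matrix(0L, n, n)
    eid[edges] <- seq_len(ne); eid[edges[, 2:1]] <- seq_len(ne)
    tord <- order(tri_val, seq_len(nt))
    lowtab <- integer(ne)
    cols <- vector("list", nt)
    for (t in tord) {
      col <- sort(epos[c(eid[tris[t, 1L], tris[t, 2L]],
                         eid[tris[t, 2L], tris[t, 3L]],
                         eid[tris[t, 3L], tris[t, 1L]])])
      repeat {
        if (!length(col)) break
        lw <- col[length(col)]
        o <- lowtab[lw]
        if (o == 0L) break
        col <- sort(c(setdiff(col, cols[[o]]), setdiff(cols[[o]], col)))
      }
      if (length(col)) {
        lw <- col[length(col)]
        lowtab[lw] <- t
        cols[[t]] <- col
        pairs1 <- rbind(pairs1,
                        data.frame(birth = edge_val[eord[lw]],
                                   death = tri_val[t]))
      }
    }
  }
  bars <- rbind(
    if (length(deaths0))
      data.frame(dimension = 0L, birth = 0, death = deaths0,
                 essential = FALSE),
    data.frame(dimension = 0L, birth = 0, death = Inf,
               essential = TRUE),
    if (nrow(pairs1))
      data.frame(dimension = 1L, birth = pairs1$birth,
                 death = pairs1$death, essential = FALSE))
  bars <- bars[bars$birth < alpha_max, , drop = FALSE]
  bars$death <- pmin(bars$death, alpha_max)
  eps <- 1e-9 * pmax(1, bars$death)
  bars <- bars[bars$death - bars$birth > eps | bars$essential, ,
               drop = FALSE]
  bars <- bars[order(bars$dimension, bars$birth, bars$death), ,
               drop = FALSE]
  rownames(bars) <- NULL
  bars
}

## ---- nearest-neighbour oracle ----------------------------------------
oracle_nn_dist <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i)
    min(sqrt((b[, 1L] - a[i, 1L])^2 + (b[, 2L] - a[i, 2L])^2)),
    numeric(1))
}

## ---- shared fixtures -------------------------------------------------
tiny_orte <- function(n = 50L, seed = 1L, xmax = 1000, ymax = 1000) {
  set.seed(seed)
  orte_matrix(runif(n, 0.5, 2), runif(n, 0, xmax), runif(n, 0, ymax),
              rep(15, n))
}

quick_scene_params <- function(...) {
  # small nucleus keeps mask rasterization and sampling fast in tests
  defaults <- list(nucleus_radius_nm = 1500, events_per_focus_ch1 = 150L,
                   events_per_focus_ch2 = 150L,
                   background_density_ch1 = 20,
                   background_density_ch2 = 20)
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}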