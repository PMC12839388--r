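## DBSCAN nanocluster analysis of localization tables (defaults: radius
## 200 nm, minimum 30 signals per cluster, self included in the
## neighbour count) and per-nucleus cluster morphometrics: convex hulls,
## hull areas in um^2, tag densities.

#' DBSCAN parameters
#'
#' @param radius_nm neighbourhood radius (default 200 nm)
#' @param min_count minimum neighbours (self included) for a core point
#'   (default 30)
#' @return a `cluster_params` list
#' @export
cluster_params <- function(radius_nm = 200, min_count = 30L) {
  check_num(radius_nm, "radius_nm", lower = 1e-9)
  check_num(min_count, "min_count", lower = 1)
  structure(list(radius_nm = radius_nm, min_count = as.integer(min_count)),
            class = "cluster_params")
}

#' @noRd
grid_neighbours <- function(x, y, radius) {
  # cell-list neighbour search: returns a function i -> indices within
  # radius of point i (self included)
  cell_x <- floor(x / radius); cell_y <- floor(y / radius)
  key <- paste(cell_x, cell_y)
  buckets <- split(seq_along(x), key)
  r2 <- radius^2
  function(i) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(cell_x[i] + dx, cell_y[i] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    sort(cand[d2 <= r2])
  }
}

#' DBSCAN clustering of 2D points
#'
#' Standard DBSCAN semantics: a core point has at least `min_count`
#' neighbours within `radius_nm` (itself included); clusters are
#' connected components of core points under mutual reachability plus
#' their border points.  Clusters are discovered by scanning points in
#' ascending index order and fully expanded before the next seed, so a
#' border point reachable from several clusters deterministically joins
#' the cluster discovered first.
#'
#' @param x,y coordinates in nm (or a 2-column matrix as `x`)
#' @param params a [cluster_params()]
#' @return list with `labels` (integer vector, 0 = noise), `is_core`
#'   (logical), `n_clusters`
#' @export
dbscan_points <- function(x, y = NULL, params = cluster_params()) {
  if (is.null(y)) { y <- x[, 2L]; x <- x[, 1L] }
  n <- length(x)
  labels <- integer(n)
  if (n == 0L)
    return(list(labels = labels, is_core = logical(0), n_clusters = 0L))
  nbr <- grid_neighbours(x, y, params$radius_nm)
  neigh <- lapply(seq_len(n), nbr)
  is_core <- lengths(neigh) >= params$min_count
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- neigh[[i]]
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]; head <- head + 1L
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (is_core[j]) queue <- c(queue, neigh[[j]])
      }
    }
  }
  list(labels = labels, is_core = is_core, n_clusters = cl)
}

#' Morphometric properties of one cluster
#'
#' Convex hull of the member coordinates, hull area via the shoelace
#' formula (um^2), and tag density (count / area).  Fewer than 3
#' non-collinear members give area 0 and a missing density.
#'
#' @param members integer row indices of the cluster members
#' @param x,y full coordinate vectors in nm
#' @return list: `members`, `n`, `hull` (matrix of hull vertices, nm),
#'   `area_um2`, `density_per_um2`
#' @export
cluster_properties <- function(members, x, y) {
  hx <- x[members]; hy <- y[members]
  hull_idx <- if (length(members) >= 3L) grDevices::chull(hx, hy)
              else seq_along(members)
  area_nm2 <- polygon_area(hx[hull_idx], hy[hull_idx])
  area_um2 <- area_nm2 / 1e6
  density <- if (area_um2 > 0) length(members) / area_um2 else NA_real_
  list(members = members, n = length(members),
       hull = cbind(x = hx[hull_idx], y = hy[hull_idx]),
       area_um2 = area_um2, density_per_um2 = density)
}

#' Cluster an orte matrix and compute per-cluster morphometrics
#'
#' @param orte an [orte_matrix()]
#' @param params a [cluster_params()]
#' @return list with `clusters` (list of [cluster_properties()]
#'   results), `labels`, `is_core`, `noise` (row indices)
#' @export
cluster_orte <- function(orte, params = cluster_params()) {
  db <- dbscan_points(orte$x_nm, orte$y_nm, params)
  clusters <- lapply(seq_len(db$n_clusters), function(k)
    cluster_properties(which(db$labels == k), orte$x_nm, orte$y_nm))
  list(clusters = clusters, labels = db$labels, is_core = db$is_core,
       noise = which(db$labels == 0L))
}

#' Per-nucleus summary over labels and masks
#'
#' Computes, for every channel and for both masking methods (whole
#' nucleus, damage-focus regions), the panels of a cluster-morphometry
#' figure: number of detected events, event density (tags/um^2), number
#' of clusters, tags inside clusters, mean cluster area (um^2) and mean
#' tag density within clusters (per-cluster densities averaged
#' unweighted).
#'
#' @param orte_list named list of [orte_matrix()] objects (one per
#'   channel/label), unmasked
#' @param nucleus_mask,foci_mask [binary_mask()] objects
#' @param params a [cluster_params()]
#' @return data.frame with one row per label x mask
#' @export
summarize_nucleus <- function(orte_list, nucleus_mask, foci_mask,
                              params = cluster_params()) {
  stopifnot(is.list(orte_list), length(names(orte_list)) ==
              length(orte_list))
  masks <- list(nucleus = nucleus_mask, foci = foci_mask)
  rows <- list()
  for (lab in names(orte_list)) {
    for (mk in names(masks)) {
      mask <- masks[[mk]]
      sub <- apply_mask(orte_list[[lab]], mask)
      area <- mask_area(mask)
      cl <- cluster_orte(sub, params)
      n_in <- sum(cl$labels != 0L)
      areas <- vapply(cl$clusters, `[[`, numeric(1), "area_um2")
      dens <- vapply(cl$clusters, `[[`, numeric(1), "density_per_um2")
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, mask = mk,
        n_events = nrow(sub),
        event_density_per_um2 = if (area > 0) nrow(sub) / area
                                else NA_real_,
        n_clusters = length(cl$clusters),
        tags_in_clusters = n_in,
        frac_tags_in_clusters = if (nrow(sub) > 0) n_in / nrow(sub)
                                else NA_real_,
        mean_cluster_area_um2 = if (length(areas)) mean(areas)
                                else NA_real_,
        mean_cluster_density_per_um2 =
          if (any(!is.na(dens))) mean(dens, na.rm = TRUE) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
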