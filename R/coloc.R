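## Point-based two-channel co-localization: an event of channel A is
## co-localized when its nearest neighbour in channel B lies within a
## distance threshold (analysis set 95 / 50 / 20 nm).  Cluster-level
## statistics: hull-union overlap percentage and second-label density
## inside first-label cluster hulls (hull unions raster-approximated).

#' Co-localization parameters
#'
#' @param threshold_nm nearest-neighbour distance limit (95, 50 and
#'   20 nm form the standard analysis set; any positive value allowed)
#' @return a `coloc_params` list
#' @export
coloc_params <- function(threshold_nm = 95) {
  check_num(threshold_nm, "threshold_nm", lower = 1e-9)
  structure(list(threshold_nm = threshold_nm), class = "coloc_params")
}

#' Nearest-neighbour co-localization between two channels
#'
#' Directional by definition (A -> B); both directions are reported.
#'
#' @param orteA,orteB [orte_matrix()] objects in the same frame,
#'   identically masked
#' @param params a [coloc_params()]
#' @return a `coloc_result`: list with `threshold_nm` and per-direction
#'   entries `a_to_b` / `b_to_a`, each holding `flags` (logical per
#'   point), `nn_dist_nm`, `n`, `n_coloc`, `fraction_pct`
#' @export
colocalize_points <- function(orteA, orteB, params = coloc_params()) {
  if (nrow(orteA) == 0L) stopf("channel A is empty")
  direction <- function(a, b) {
    n <- nrow(a)
    if (nrow(b) == 0L) {
      warnf("co-localization target channel empty; fraction set to 0")
      return(list(flags = rep(FALSE, n), nn_dist_nm = rep(Inf, n),
                  n = n, n_coloc = 0L, fraction_pct = 0))
    }
    nn <- nn_brute(cbind(a$x_nm, a$y_nm), cbind(b$x_nm, b$y_nm))
    flags <- nn$dist <= params$threshold_nm
    list(flags = flags, nn_dist_nm = nn$dist, n = n,
         n_coloc = sum(flags), fraction_pct = 100 * mean(flags))
  }
  structure(list(threshold_nm = params$threshold_nm,
                 a_to_b = direction(orteA, orteB),
                 b_to_a = if (nrow(orteB) > 0L) direction(orteB, orteA)
                          else NULL),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("co-localization @ %g nm: A->B %.1f%% (%d/%d)",
              x$threshold_nm, x$a_to_b$fraction_pct, x$a_to_b$n_coloc,
              x$a_to_b$n))
  if (!is.null(x$b_to_a))
    cat(sprintf(", B->A %.1f%% (%d/%d)", x$b_to_a$fraction_pct,
                x$b_to_a$n_coloc, x$b_to_a$n))
  cat("\n")
  invisible(x)
}

#' @noRd
rasterize_hulls <- function(clusters, xlim, ylim, resolution) {
  # logical raster of the union of convex hulls; cell centres tested
  nx <- max(1L, ceiling((xlim[2L] - xlim[1L]) / resolution))
  ny <- max(1L, ceiling((ylim[2L] - ylim[1L]) / resolution))
  gx <- xlim[1L] + (seq_len(nx) - 0.5) * resolution
  gy <- ylim[1L] + (seq_len(ny) - 0.5) * resolution
  inside <- matrix(FALSE, ny, nx)
  for (cl in clusters) {
    h <- cl$hull
    if (nrow(h) < 3L) next
    cx0 <- which(gx >= min(h[, 1L]) - resolution &
                 gx <= max(h[, 1L]) + resolution)
    cy0 <- which(gy >= min(h[, 2L]) - resolution &
                 gy <= max(h[, 2L]) + resolution)
    if (!length(cx0) || !length(cy0)) next
    px <- rep(gx[cx0], each = length(cy0))
    py <- rep(gy[cy0], times = length(cx0))
    ok <- points_in_convex_polygon(px, py, h)
    if (any(ok))
      inside[cy0, cx0] <- inside[cy0, cx0] |
        matrix(ok, length(cy0), length(cx0))
  }
  list(inside = inside, cell_area_nm2 = resolution^2)
}

#' @noRd
points_in_convex_polygon <- function(px, py, hull) {
  # convex hull vertices in boundary order; a point is inside when it
  # lies on the polygon's side of every edge (boundary counts as inside)
  n <- nrow(hull)
  j <- c(2:n, 1L)
  area2 <- sum(hull[, 1L] * hull[j, 2L] - hull[j, 1L] * hull[, 2L])
  orient <- sign(area2)
  if (orient == 0) return(rep(FALSE, length(px)))  # degenerate hull
  ex <- hull[j, 1L] - hull[, 1L]
  ey <- hull[j, 2L] - hull[, 2L]
  inside <- rep(TRUE, length(px))
  for (k in seq_len(n)) {
    cr <- ex[k] * (py - hull[k, 2L]) - ey[k] * (px - hull[k, 1L])
    inside <- inside & (orient * cr >= 0)
  }
  inside
}

#' Overlap percentage of two cluster-hull unions
#'
#' `100 * area(union(A) intersect union(B)) / area(union(A))`, with
#' areas approximated on a raster of configurable resolution.
#'
#' @param clustersA,clustersB lists of [cluster_properties()] results
#' @param resolution_nm raster cell size (default 5 nm)
#' @return overlap percentage, or `NA` when the A hull union has zero
#'   area
#' @export
cluster_overlap <- function(clustersA, clustersB, resolution_nm = 5) {
  ha <- do.call(rbind, lapply(clustersA, `[[`, "hull"))
  hb <- do.call(rbind, lapply(clustersB, `[[`, "hull"))
  if (is.null(ha) || nrow(ha) < 3L) return(NA_real_)
  pts <- rbind(ha, if (!is.null(hb)) hb)
  xlim <- range(pts[, 1L]) + c(-resolution_nm, resolution_nm)
  ylim <- range(pts[, 2L]) + c(-resolution_nm, resolution_nm)
  ra <- rasterize_hulls(clustersA, xlim, ylim, resolution_nm)
  na <- sum(ra$inside)
  if (na == 0L) return(NA_real_)
  if (is.null(hb) || nrow(hb) < 3L) return(0)
  rb <- rasterize_hulls(clustersB, xlim, ylim, resolution_nm)
  100 * sum(ra$inside & rb$inside) / na
}

#' Density of second-channel events inside first-channel cluster hulls
#'
#' Count of B events falling inside the union of the A cluster hulls,
#' divided by the raster-approximated union area in um^2.
#'
#' @param orteB an [orte_matrix()]
#' @param clustersA list of [cluster_properties()] results
#' @param resolution_nm raster cell size for the union area (default
#'   5 nm)
#' @return list with `n_inside`, `union_area_um2`, `density_per_um2`
#'   (`NA` on zero union area)
#' @export
density_in_clusters <- function(orteB, clustersA, resolution_nm = 5) {
  ha <- do.call(rbind, lapply(clustersA, `[[`, "hull"))
  if (is.null(ha) || nrow(ha) < 3L)
    return(list(n_inside = 0L, union_area_um2 = 0,
                density_per_um2 = NA_real_))
  xlim <- range(ha[, 1L]) + c(-resolution_nm, resolution_nm)
  ylim <- range(ha[, 2L]) + c(-resolution_nm, resolution_nm)
  ra <- rasterize_hulls(clustersA, xlim, ylim, resolution_nm)
  area_um2 <- sum(ra$inside) * ra$cell_area_nm2 / 1e6
  if (area_um2 == 0)
    return(list(n_inside = 0L, union_area_um2 = 0,
                density_per_um2 = NA_real_))
  inside <- rep(FALSE, nrow(orteB))
  for (cl in clustersA) {
    if (nrow(cl$hull) < 3L) next
    inside <- inside | points_in_convex_polygon(orteB$x_nm, orteB$y_nm,
                                                cl$hull)
  }
  list(n_inside = sum(inside), union_area_um2 = area_um2,
       density_per_um2 = sum(inside) / area_um2)
}

#' Chance-co-localization control by uniform resampling
#'
#' Replaces channel-B positions by uniform draws over the nucleus mask
#' (same event count), providing the baseline used in
#' irradiated-vs-control comparisons.
#'
#' @param orteB an [orte_matrix()]
#' @param nucleus_mask a [binary_mask()]
#' @param seed RNG seed
#' @return an [orte_matrix()] with resampled coordinates
#' @export
resample_channel <- function(orteB, nucleus_mask, seed = 1L) {
  set.seed(derive_seed(seed, "resample"))
  n <- nrow(orteB)
  p <- sample_in_mask(n, nucleus_mask)
  orte_matrix(orteB$amplitude, p[, 1L], p[, 2L], orteB$loc_error_nm,
              channel = attr(orteB, "channel"), source = "resampled")
}
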