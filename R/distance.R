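## Ripley-style pairwise-distance frequency histograms: the relative
## abundance of all unordered point-to-point distances up to a maximum
## range.  Clustering appears as low-distance peaks; complete spatial
## randomness in a window rises near-linearly at short range.  A raw
## Ripley K estimate (no edge correction) is provided as a secondary
## output.

#' Pairwise point-to-point distance frequency histogram
#'
#' All unordered pairs with distance <= `max_distance_nm` are binned into
#' half-open bins `[a, b)` of width `bin_width_nm` (a distance exactly
#' equal to `max_distance_nm` is placed in the last bin); frequencies are
#' normalized by the number of such pairs.
#'
#' @param x,y coordinates in nm (or a 2-column matrix as `x`)
#' @param bin_width_nm bin width (default 10 nm)
#' @param max_distance_nm histogram range (default 1000 nm)
#' @return a `distance_histogram`: list with `breaks_nm`, `rel_freq`,
#'   `counts`, `n_points`, `n_pairs`, `max_distance_nm`
#' @export
pairwise_distance_histogram <- function(x, y = NULL, bin_width_nm = 10,
                                        max_distance_nm = 1000) {
  if (is.null(y)) { y <- x[, 2L]; x <- x[, 1L] }
  check_num(bin_width_nm, "bin_width_nm", lower = 1e-9)
  check_num(max_distance_nm, "max_distance_nm", lower = bin_width_nm)
  n <- length(x)
  if (n < 2L) stopf("insufficient points for a distance histogram (n=%d)",
                    n)
  d <- as.vector(dist(cbind(x, y)))
  d <- d[d <= max_distance_nm]
  nbins <- ceiling(max_distance_nm / bin_width_nm)
  idx <- pmin(floor(d / bin_width_nm) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  n_pairs <- length(d)
  rel <- if (n_pairs > 0) counts / n_pairs else rep(0, nbins)
  structure(list(breaks_nm = seq(0, nbins * bin_width_nm,
                                 by = bin_width_nm),
                 rel_freq = rel, counts = counts, n_points = n,
                 n_pairs = n_pairs, max_distance_nm = max_distance_nm),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf(
    "distance histogram: %d points, %d pairs <= %g nm, %d bins\n",
    x$n_points, x$n_pairs, x$max_distance_nm, length(x$rel_freq)))
  invisible(x)
}

#' Pool distance histograms across nuclei
#'
#' Combines per-nucleus histograms on a shared binning, weighting each
#' nucleus by its pair count (set `weight = "equal"` for unweighted
#' averaging of the relative frequencies).
#'
#' @param hists list of `distance_histogram` objects with identical bins
#' @param weight `"pairs"` (default) or `"equal"`
#' @return a pooled `distance_histogram`
#' @export
pool_distance_histograms <- function(hists, weight = c("pairs", "equal")) {
  weight <- match.arg(weight)
  stopifnot(length(hists) >= 1L)
  b <- hists[[1L]]$breaks_nm
  for (h in hists)
    if (!isTRUE(all.equal(h$breaks_nm, b)))
      stopf("histograms have differing bins")
  if (weight == "pairs") {
    counts <- Reduce(`+`, lapply(hists, `[[`, "counts"))
    n_pairs <- sum(vapply(hists, `[[`, numeric(1), "n_pairs"))
    rel <- if (n_pairs > 0) counts / n_pairs else counts * 0
  } else {
    rel <- Reduce(`+`, lapply(hists, `[[`, "rel_freq")) / length(hists)
    counts <- NA_integer_
    n_pairs <- sum(vapply(hists, `[[`, numeric(1), "n_pairs"))
  }
  structure(list(breaks_nm = b, rel_freq = rel, counts = counts,
                 n_points = sum(vapply(hists, `[[`, numeric(1),
                                       "n_points")),
                 n_pairs = n_pairs,
                 max_distance_nm = hists[[1L]]$max_distance_nm),
            class = "distance_histogram")
}

#' Detect peaks in a distance histogram
#'
#' The relative frequencies are smoothed with a centred moving average;
#' peaks are local maxima whose topographic prominence is at least
#' `min_prominence` times the global maximum of the smoothed curve.
#' Full width at half maximum is measured on the smoothed curve by
#' linear interpolation (NA when the half level is not crossed within
#' the analyzed range).
#'
#' @param hist a `distance_histogram`
#' @param smoothing_window moving-average window in bins (odd; default 3)
#' @param min_prominence minimum prominence as a fraction of the global
#'   maximum (default 0.05)
#' @return a `peak_annotation` data.frame: `position_nm`, `height`,
#'   `fwhm_nm`; attribute `spacing_nm` holds successive peak-position
#'   differences
#' @export
detect_peaks <- function(hist, smoothing_window = 3L,
                         min_prominence = 0.05) {
  stopifnot(inherits(hist, "distance_histogram"))
  if (smoothing_window %% 2 == 0) stopf("smoothing_window must be odd")
  yv <- hist$rel_freq
  nb <- length(yv)
  half <- (smoothing_window - 1L) %/% 2L
  sm <- vapply(seq_len(nb), function(i)
    mean(yv[max(1L, i - half):min(nb, i + half)]), numeric(1))
  centers <- (hist$breaks_nm[-1L] + hist$breaks_nm[-(nb + 1L)]) / 2
  gmax <- max(sm)
  empty <- data.frame(position_nm = numeric(0), height = numeric(0),
                      fwhm_nm = numeric(0))
  attr(empty, "spacing_nm") <- numeric(0)
  class(empty) <- c("peak_annotation", "data.frame")
  if (gmax <= 0) return(empty)
  # local maxima (first bin of a plateau); endpoints excluded
  is_peak <- logical(nb)
  if (nb >= 3L)
    for (i in 2:(nb - 1L))
      is_peak[i] <- sm[i] > sm[i - 1L] && sm[i] >= sm[i + 1L]
  cand <- which(is_peak)
  if (!length(cand)) return(empty)
  prominence <- vapply(cand, function(i) {
    # lowest descent towards a higher bin on each side (global max:
    # towards the range ends)
    left_min <- sm[i]; j <- i
    while (j > 1L && sm[j - 1L] <= sm[i]) {
      j <- j - 1L; left_min <- min(left_min, sm[j])
    }
    if (j == 1L && sm[j] <= sm[i]) left_min <- min(sm[1:i])
    right_min <- sm[i]; j <- i
    while (j < nb && sm[j + 1L] <= sm[i]) {
      j <- j + 1L; right_min <- min(right_min, sm[j])
    }
    if (j == nb && sm[j] <= sm[i]) right_min <- min(sm[i:nb])
    sm[i] - max(left_min, right_min)
  }, numeric(1))
  ok <- prominence >= min_prominence * gmax
  cand <- cand[ok]
  if (!length(cand)) return(empty)
  fwhm <- vapply(cand, function(i) {
    hlev <- sm[i] / 2
    xl <- NA_real_; xr <- NA_real_
    j <- i
    while (j > 1L) {
      if (sm[j - 1L] < hlev) {
        xl <- centers[j - 1L] + (centers[j] - centers[j - 1L]) *
          (hlev - sm[j - 1L]) / (sm[j] - sm[j - 1L])
        break
      }
      j <- j - 1L
    }
    j <- i
    while (j < nb) {
      if (sm[j + 1L] < hlev) {
        xr <- centers[j] + (centers[j + 1L] - centers[j]) *
          (sm[j] - hlev) / (sm[j] - sm[j + 1L])
        break
      }
      j <- j + 1L
    }
    if (is.na(xl) || is.na(xr)) NA_real_ else xr - xl
  }, numeric(1))
  out <- data.frame(position_nm = centers[cand], height = sm[cand],
                    fwhm_nm = fwhm)
  out <- out[order(out$position_nm), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "spacing_nm") <- diff(out$position_nm)
  class(out) <- c("peak_annotation", "data.frame")
  out
}

#' Raw Ripley K estimate (no edge correction)
#'
#' `K(r) = A / (n (n - 1)) * #[ordered pairs with distance <= r]` for a
#' window of area `A` (um^2 input, computed in nm^2).
#'
#' @param x,y coordinates in nm (or a 2-column matrix as `x`)
#' @param r_nm vector of radii in nm
#' @param area_um2 observation-window area in um^2
#' @return data.frame with `r_nm` and `k_nm2`
#' @export
ripley_k <- function(x, y = NULL, r_nm, area_um2) {
  if (is.null(y)) { y <- x[, 2L]; x <- x[, 1L] }
  n <- length(x)
  if (n < 2L) stopf("insufficient points for Ripley K (n=%d)", n)
  d <- as.vector(dist(cbind(x, y)))
  area_nm2 <- area_um2 * 1e6
  k <- vapply(r_nm, function(r) 2 * sum(d <= r), numeric(1)) *
    area_nm2 / (n * (n - 1))
  data.frame(r_nm = r_nm, k_nm2 = k)
}
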