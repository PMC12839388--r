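## Ground-truth synthetic scenes: a disc nucleus of ~30 um^2 containing
## one or two DNA-damage foci, each a Thomas-type Gaussian cluster of
## labelling events in two channels, plus uniform background events.  A
## configurable fraction of channel-2 focus events is planted within a
## small displacement of a channel-1 event ("co-localized").  Everything
## is reproducible from a single integer seed.

#' Parameters of a synthetic two-channel nuclear scene
#'
#' Defaults emulate the experimental regime of low-LET beta-irradiated
#' PBMC nuclei: a ~30 um^2 nucleus, two damage foci, localization
#' precision 17 nm (channel 1 / Cy3) and 15 nm (channel 2 / Cy5).
#'
#' @param nucleus_radius_nm nucleus disc radius (default 3090 nm, i.e.
#'   area ~30 um^2)
#' @param n_foci number of damage foci (typically 1 or 2)
#' @param focus_sigma_nm isotropic Gaussian spread of focus events
#' @param events_per_focus_ch1,events_per_focus_ch2 emitters per focus
#' @param background_density_ch1,background_density_ch2 uniform
#'   background emitters per um^2
#' @param coloc_fraction fraction in [0, 1] of channel-2 focus events
#'   planted next to a channel-1 focus event
#' @param coloc_displacement_sigma_nm isotropic Gaussian displacement of
#'   planted channel-2 events from their channel-1 partner
#' @param loc_error_ch1_nm,loc_error_ch2_nm localization error sigma per
#'   channel
#' @param mask_pixel_nm raster pixel size of the ground-truth masks
#' @param focus_mask_radius_nm radius of the ground-truth focus-mask
#'   discs; `NULL` (default) calibrates it so the foci mask covers ~6%
#'   of the nucleus area
#' @param seed integer RNG seed
#' @return a validated `scene_params` list
#' @export
scene_params <- function(nucleus_radius_nm = 3090,
                         n_foci = 2L,
                         focus_sigma_nm = 50,
                         events_per_focus_ch1 = 300L,
                         events_per_focus_ch2 = 300L,
                         background_density_ch1 = 50,
                         background_density_ch2 = 50,
                         coloc_fraction = 0.5,
                         coloc_displacement_sigma_nm = 10,
                         loc_error_ch1_nm = 17,
                         loc_error_ch2_nm = 15,
                         mask_pixel_nm = 20,
                         focus_mask_radius_nm = NULL,
                         seed = 1L) {
  check_num(nucleus_radius_nm, "nucleus_radius_nm", lower = 1e-6)
  check_num(n_foci, "n_foci", lower = 0)
  check_num(focus_sigma_nm, "focus_sigma_nm", lower = 1e-6)
  check_num(events_per_focus_ch1, "events_per_focus_ch1", lower = 0)
  check_num(events_per_focus_ch2, "events_per_focus_ch2", lower = 0)
  check_num(background_density_ch1, "background_density_ch1", lower = 0)
  check_num(background_density_ch2, "background_density_ch2", lower = 0)
  check_num(coloc_fraction, "coloc_fraction", lower = 0, upper = 1)
  check_num(coloc_displacement_sigma_nm, "coloc_displacement_sigma_nm",
            lower = 1e-9)
  check_num(loc_error_ch1_nm, "loc_error_ch1_nm", lower = 0)
  check_num(loc_error_ch2_nm, "loc_error_ch2_nm", lower = 0)
  check_num(mask_pixel_nm, "mask_pixel_nm", lower = 1e-3)
  check_num(seed, "seed", lower = 0)
  nucleus_area_um2 <- pi * nucleus_radius_nm^2 / 1e6
  if (is.null(focus_mask_radius_nm)) {
    # ~6% coverage of the nucleus split across the foci
    focus_mask_radius_nm <- if (n_foci > 0)
      sqrt(0.06 * pi * nucleus_radius_nm^2 / (n_foci * pi)) else
      3 * focus_sigma_nm
  }
  check_num(focus_mask_radius_nm, "focus_mask_radius_nm", lower = 1e-6)
  structure(list(nucleus_radius_nm = nucleus_radius_nm,
                 n_foci = as.integer(n_foci),
                 focus_sigma_nm = focus_sigma_nm,
                 events_per_focus_ch1 = as.integer(events_per_focus_ch1),
                 events_per_focus_ch2 = as.integer(events_per_focus_ch2),
                 background_density_ch1 = background_density_ch1,
                 background_density_ch2 = background_density_ch2,
                 coloc_fraction = coloc_fraction,
                 coloc_displacement_sigma_nm = coloc_displacement_sigma_nm,
                 loc_error_ch1_nm = loc_error_ch1_nm,
                 loc_error_ch2_nm = loc_error_ch2_nm,
                 mask_pixel_nm = mask_pixel_nm,
                 focus_mask_radius_nm = focus_mask_radius_nm,
                 nucleus_area_um2 = nucleus_area_um2,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' @noRd
disc_mask <- function(center_x, center_y, radius, pixel, width_nm,
                      height_nm, kind) {
  ncols <- ceiling(width_nm / pixel)
  nrows <- ceiling(height_nm / pixel)
  cx <- (seq_len(ncols) - 0.5) * pixel
  cy <- (seq_len(nrows) - 0.5) * pixel
  inside <- matrix(FALSE, nrows, ncols)
  for (k in seq_along(center_x)) {
    dx2 <- outer(rep(1, nrows), (cx - center_x[k])^2)
    dy2 <- outer((cy - center_y[k])^2, rep(1, ncols))
    inside <- inside | (dx2 + dy2 <= radius[min(k, length(radius))]^2)
  }
  binary_mask(inside, pixel, 0, 0, kind = kind)
}

#' @noRd
sample_in_mask <- function(n, mask, max_tries = 200L) {
  # uniform over the inside region of a raster mask, by rejection
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  w <- ncol(mask$inside) * mask$pixel_size_nm
  h <- nrow(mask$inside) * mask$pixel_size_nm
  out <- matrix(NA_real_, n, 2L)
  need <- seq_len(n)
  for (t in seq_len(max_tries)) {
    m <- length(need)
    if (!m) break
    x <- runif(m, 0, w); y <- runif(m, 0, h)
    ok <- mask_contains(mask, x, y)
    out[need[ok], ] <- cbind(x[ok], y[ok])
    need <- need[!ok]
  }
  if (length(need)) stopf("rejection sampling in mask failed")
  colnames(out) <- c("x", "y")
  out
}

#' @noRd
resample_outside <- function(pos, mask, regen, max_tries = 500L) {
  # redraw rows of pos falling outside the mask (truncated distribution)
  bad <- which(!mask_contains(mask, pos[, 1L], pos[, 2L]))
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > max_tries) stopf("truncated sampling failed to converge")
    pos[bad, ] <- regen(length(bad))
    bad <- bad[!mask_contains(mask, pos[bad, 1L], pos[bad, 2L])]
  }
  pos
}

#' Generate a ground-truth two-channel scene
#'
#' Focus centers are drawn uniformly inside the nucleus disc (with a
#' 3-sigma margin from the boundary) subject to a pairwise separation of
#' at least `4 * focus_sigma_nm`; focus events are isotropic Gaussians
#' around the centers, truncated to the nucleus mask; background events
#' are uniform over the nucleus mask with Poisson-distributed counts.  A
#' `coloc_fraction` subset of channel-2 focus events (rounded count per
#' focus) is planted at a uniformly chosen channel-1 event of the same
#' focus plus an isotropic Gaussian displacement.
#'
#' @param params a [scene_params()]
#' @return a `ground_truth_scene` list with focus centers, per-channel
#'   true positions (with focus labels, 0 = background), a planted
#'   co-localization flag for channel 2, and nucleus / foci masks
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(derive_seed(params$seed, "scene"))
  R <- params$nucleus_radius_nm
  sgm <- params$focus_sigma_nm
  field <- 2 * (R + 10 * params$mask_pixel_nm)
  cx0 <- field / 2; cy0 <- field / 2
  nucleus_mask <- disc_mask(cx0, cy0, R, params$mask_pixel_nm,
                            field, field, kind = "nucleus")

  # --- focus centers: uniform in the margin disc, min separation 4 sigma
  margin <- 3 * sgm
  if (params$n_foci > 0 && R - margin <= 0)
    stopf("nucleus too small to place foci (radius %g <= margin %g)",
          R, margin)
  sep <- 4 * sgm
  centers <- matrix(numeric(0), 0L, 2L)
  tries <- 0L
  while (nrow(centers) < params$n_foci) {
    tries <- tries + 1L
    if (tries > 5000L)
      stopf("failed to place %d foci at separation >= %g nm in nucleus",
            params$n_foci, sep)
    r <- (R - margin) * sqrt(runif(1)); a <- runif(1, 0, 2 * pi)
    cand <- c(cx0 + r * cos(a), cy0 + r * sin(a))
    if (!nrow(centers) ||
        all(sqrt(rowSums(sweep(centers, 2L, cand)^2)) >= sep))
      centers <- rbind(centers, cand)
  }
  rownames(centers) <- NULL

  foci_mask <- if (params$n_foci > 0)
    disc_mask(centers[, 1L], centers[, 2L],
              rep(params$focus_mask_radius_nm, params$n_foci),
              params$mask_pixel_nm, field, field, kind = "foci")
  else binary_mask(matrix(FALSE, nrow(nucleus_mask$inside),
                          ncol(nucleus_mask$inside)),
                   params$mask_pixel_nm, kind = "foci")
  # ground-truth inclusion: foci mask restricted to the nucleus
  foci_mask$inside <- foci_mask$inside & nucleus_mask$inside

  draw_channel <- function(n_per_focus, bg_density) {
    pos <- matrix(numeric(0), 0L, 2L); lab <- integer(0)
    for (k in seq_len(params$n_foci)) {
      if (n_per_focus == 0L) next
      gen <- function(m) cbind(rnorm(m, centers[k, 1L], sgm),
                               rnorm(m, centers[k, 2L], sgm))
      p <- resample_outside(gen(n_per_focus), nucleus_mask, gen)
      pos <- rbind(pos, p); lab <- c(lab, rep(k, n_per_focus))
    }
    n_bg <- rpois(1L, bg_density * params$nucleus_area_um2)
    if (n_bg > 0L) {
      p <- sample_in_mask(n_bg, nucleus_mask)
      pos <- rbind(pos, p); lab <- c(lab, rep(0L, n_bg))
    }
    list(pos = pos, label = lab)
  }

  ch1 <- draw_channel(params$events_per_focus_ch1,
                      params$background_density_ch1)
  ch2 <- draw_channel(params$events_per_focus_ch2,
                      params$background_density_ch2)

  # --- plant co-localized channel-2 focus events next to channel-1 events
  is_coloc <- rep(FALSE, nrow(ch2$pos))
  if (params$coloc_fraction > 0 && params$n_foci > 0 &&
      params$events_per_focus_ch2 > 0 && params$events_per_focus_ch1 > 0) {
    n_plant <- round(params$coloc_fraction * params$events_per_focus_ch2)
    for (k in seq_len(params$n_foci)) {
      idx2 <- which(ch2$label == k)
      idx1 <- which(ch1$label == k)
      plant <- idx2[seq_len(min(n_plant, length(idx2)))]
      if (!length(plant)) next
      partners <- idx1[sample.int(length(idx1), length(plant),
                                  replace = TRUE)]
      gen <- function(m, base) base +
        cbind(rnorm(m, 0, params$coloc_displacement_sigma_nm),
              rnorm(m, 0, params$coloc_displacement_sigma_nm))
      base <- ch1$pos[partners, , drop = FALSE]
      p <- gen(length(plant), base)
      bad <- which(!mask_contains(nucleus_mask, p[, 1L], p[, 2L]))
      t2 <- 0L
      while (length(bad)) {
        t2 <- t2 + 1L
        if (t2 > 500L) stopf("co-localization planting failed")
        p[bad, ] <- gen(length(bad), base[bad, , drop = FALSE])
        bad <- bad[!mask_contains(nucleus_mask, p[bad, 1L],
                                  p[bad, 2L])]
      }
      ch2$pos[plant, ] <- p
      is_coloc[plant] <- TRUE
    }
  }

  structure(list(params = params,
                 field_nm = field,
                 focus_centers = centers,
                 true_positions_ch1 = data.frame(x = ch1$pos[, 1L],
                                                 y = ch1$pos[, 2L],
                                                 label = ch1$label),
                 true_positions_ch2 = data.frame(x = ch2$pos[, 1L],
                                                 y = ch2$pos[, 2L],
                                                 label = ch2$label,
                                                 is_coloc = is_coloc),
                 nucleus_mask = nucleus_mask,
                 foci_mask = foci_mask),
            class = "ground_truth_scene")
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf(paste0("ground-truth scene: %d foci, %d ch1 / %d ch2 true",
                     " positions, nucleus %.1f um^2, foci mask %.1f%%\n"),
              nrow(x$focus_centers), nrow(x$true_positions_ch1),
              nrow(x$true_positions_ch2), mask_area(x$nucleus_mask),
              100 * mask_area(x$foci_mask) / mask_area(x$nucleus_mask)))
  invisible(x)
}

#' Sample an orte matrix from a ground-truth scene
#'
#' Each true position emits a geometric- (default, memoryless
#' off-switching; support >= 1) or Poisson-distributed number of blink
#' events; every blink is the true position plus isotropic Gaussian
#' localization noise with the channel's error sigma.  The recorded
#' `loc_error_nm` column is the noise sigma used.
#'
#' @param scene a [generate_scene()] result
#' @param channel 1 or 2
#' @param mean_blinks_per_emitter mean blink count (>= 1 for geometric)
#' @param blink_distribution `"geometric"` or `"poisson"`
#' @param amplitude_meanlog,amplitude_sdlog lognormal amplitude model
#' @param seed optional seed override (default derived from the scene)
#' @return an [orte_matrix()] with attribute `emitter` (row index of the
#'   true position each blink came from)
#' @export
sample_localizations <- function(scene, channel = 1L,
                                 mean_blinks_per_emitter = 1,
                                 blink_distribution = c("geometric",
                                                        "poisson"),
                                 amplitude_meanlog = log(1000),
                                 amplitude_sdlog = 0.3,
                                 seed = NULL) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  blink_distribution <- match.arg(blink_distribution)
  if (mean_blinks_per_emitter < 1 && blink_distribution == "geometric")
    stopf("mean_blinks_per_emitter must be >= 1 for the geometric model")
  if (is.null(seed))
    seed <- derive_seed(scene$params$seed, "blinks", channel)
  set.seed(seed)
  true <- if (channel == 1L) scene$true_positions_ch1 else
    scene$true_positions_ch2
  loc_error <- if (channel == 1L) scene$params$loc_error_ch1_nm else
    scene$params$loc_error_ch2_nm
  n <- nrow(true)
  blinks <- if (n == 0L) integer(0)
  else if (blink_distribution == "geometric")
    rgeom(n, prob = 1 / mean_blinks_per_emitter) + 1L
  else rpois(n, mean_blinks_per_emitter)
  emitter <- rep(seq_len(n), blinks)
  m <- length(emitter)
  x <- true$x[emitter] + rnorm(m, 0, loc_error)
  y <- true$y[emitter] + rnorm(m, 0, loc_error)
  amp <- exp(rnorm(m, amplitude_meanlog, amplitude_sdlog))
  out <- orte_matrix(amp, x, y, rep(loc_error, m),
                     channel = paste0("ch", channel),
                     source = "synthetic")
  attr(out, "emitter") <- emitter
  out
}
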