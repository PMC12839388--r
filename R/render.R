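## Synthetic frame-stack renderer: distributes blink events uniformly
## over frames and renders each as a pixel-integrated 2D Gaussian PSF
## plus uniform background, Poisson-sampled per pixel (EMCCD gain-register
## noise, drift and chromatic aberration are out of scope).

#' Render a synthetic acquisition from a ground-truth scene
#'
#' Each emitter of the chosen channel produces a number of blinks; every
#' blink is assigned to exactly one frame uniformly at random and drawn
#' as an integrated Gaussian spot of `photons_per_blink` expected photons.
#' Pixel values are Poisson samples of spot + background intensity.
#'
#' @param scene a [generate_scene()] result
#' @param channel 1 or 2
#' @param n_frames number of frames (acquisition default 2000)
#' @param pixel_size_nm camera pixel size in the object plane
#' @param psf_sigma_nm Gaussian PSF sigma
#' @param photons_per_blink expected photons per blink
#' @param background_photons expected background photons per pixel/frame
#' @param mean_blinks_per_emitter mean blinks per emitter
#' @param blink_distribution `"geometric"` or `"poisson"`
#' @param seed optional seed override (default derived from the scene)
#' @return a `frame_stack`: list with `frames` (3D integer array
#'   `[frame, row, col]`), `pixel_size_nm`, and `ground_truth` (one row
#'   per rendered blink: frame, x/y in nm, emitter index)
#' @export
render_frames <- function(scene, channel = 1L, n_frames = 2000L,
                          pixel_size_nm = 100, psf_sigma_nm = 150,
                          photons_per_blink = 5000,
                          background_photons = 10,
                          mean_blinks_per_emitter = 1,
                          blink_distribution = c("geometric", "poisson"),
                          seed = NULL) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  blink_distribution <- match.arg(blink_distribution)
  check_num(n_frames, "n_frames", lower = 1)
  check_num(pixel_size_nm, "pixel_size_nm", lower = 1e-3)
  check_num(psf_sigma_nm, "psf_sigma_nm", lower = 1e-3)
  if (is.null(seed))
    seed <- derive_seed(scene$params$seed, "render", channel)
  set.seed(seed)
  true <- if (channel == 1L) scene$true_positions_ch1 else
    scene$true_positions_ch2
  n <- nrow(true)
  blinks <- if (n == 0L) integer(0)
  else if (blink_distribution == "geometric")
    rgeom(n, prob = 1 / mean_blinks_per_emitter) + 1L
  else rpois(n, mean_blinks_per_emitter)
  emitter <- rep(seq_len(n), blinks)
  bx <- true$x[emitter]; by <- true$y[emitter]
  frame_of <- if (length(emitter))
    sample.int(n_frames, length(emitter), replace = TRUE) else integer(0)

  npx <- ceiling(scene$field_nm / pixel_size_nm)
  # clip blinks outside the field of view
  inside <- bx >= 0 & bx < npx * pixel_size_nm &
            by >= 0 & by < npx * pixel_size_nm
  n_clip <- sum(!inside)
  if (n_clip > 0)
    warnf("render_frames: %d blink(s) outside the field of view clipped",
          n_clip)
  keep <- which(inside)

  frames <- array(0L, dim = c(n_frames, npx, npx))
  edges <- seq(0, npx * pixel_size_nm, by = pixel_size_nm)
  half_extent <- 4 * psf_sigma_nm
  by_frame <- split(keep, frame_of[keep])
  for (fr in seq_len(n_frames)) {
    lam <- matrix(background_photons, npx, npx)
    ids <- by_frame[[as.character(fr)]]
    for (i in ids) {
      c0 <- max(1L, floor((bx[i] - half_extent) / pixel_size_nm) + 1L)
      c1 <- min(npx, floor((bx[i] + half_extent) / pixel_size_nm) + 1L)
      r0 <- max(1L, floor((by[i] - half_extent) / pixel_size_nm) + 1L)
      r1 <- min(npx, floor((by[i] + half_extent) / pixel_size_nm) + 1L)
      fx <- pnorm(edges[(c0 + 1L):(c1 + 1L)], bx[i], psf_sigma_nm) -
            pnorm(edges[c0:c1], bx[i], psf_sigma_nm)
      fy <- pnorm(edges[(r0 + 1L):(r1 + 1L)], by[i], psf_sigma_nm) -
            pnorm(edges[r0:r1], by[i], psf_sigma_nm)
      lam[r0:r1, c0:c1] <- lam[r0:r1, c0:c1] +
        photons_per_blink * outer(fy, fx)
    }
    frames[fr, , ] <- rpois(npx * npx, as.vector(lam))
  }
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 ground_truth = data.frame(frame = frame_of[keep],
                                           x = bx[keep], y = by[keep],
                                           emitter = emitter[keep]),
                 n_clipped = n_clip),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame stack: %d frames of %d x %d px @ %g nm, %d blinks\n",
              d[1L], d[2L], d[3L], x$pixel_size_nm,
              nrow(x$ground_truth)))
  invisible(x)
}

#' Write a frame stack as multi-page 16-bit TIFF
#'
#' @param stack a `frame_stack`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_frame_stack <- function(stack, path) {
  fr <- pmin(stack$frames, 65535L)
  write_tiff(fr, path, bits = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into a frame stack
#'
#' @param path TIFF path
#' @param pixel_size_nm pixel size to record on the stack
#' @return a `frame_stack` (without ground truth)
#' @export
read_frame_stack <- function(path, pixel_size_nm) {
  pages <- read_tiff(path)
  d <- dim(pages[[1L]])
  frames <- array(0L, dim = c(length(pages), d[1L], d[2L]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 ground_truth = NULL, n_clipped = 0L),
            class = "frame_stack")
}
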