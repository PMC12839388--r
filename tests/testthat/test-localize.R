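# Rendering and localization are validated jointly: the renderer's
# ground-truth blink table provides the truth the fitter must recover.

make_single_spot <- function(x0, y0, psf = 130, photons = 5000, bg = 5,
                             px = 100, W = 15) {
  edges <- seq(0, W * px, by = px)
  fx <- pnorm(edges[-1], x0, psf) - pnorm(edges[-(W + 1)], x0, psf)
  fy <- pnorm(edges[-1], y0, psf) - pnorm(edges[-(W + 1)], y0, psf)
  list(lambda = photons * outer(fy, fx) + bg, px = px)
}

test_that("renderer reproduces background statistics and blink bookkeeping", {
  sc0 <- generate_scene(scene_params(n_foci = 0L,
                                     background_density_ch1 = 0,
                                     background_density_ch2 = 0,
                                     nucleus_radius_nm = 1000,
                                     seed = 1))
  st <- render_frames(sc0, n_frames = 5L, pixel_size_nm = 100,
                      background_photons = 10)
  expect_identical(nrow(st$ground_truth), 0L)
  m <- mean(st$frames)
  se <- sqrt(10 / length(st$frames))
  expect_lt(abs(m - 10), 3 * se)

  # one emitter, one blink, bright and noise-free background:
  # brightest pixel contains the true position
  sc1 <- generate_scene(scene_params(n_foci = 1L,
                                     events_per_focus_ch1 = 1L,
                                     background_density_ch1 = 0,
                                     background_density_ch2 = 0,
                                     nucleus_radius_nm = 1000,
                                     seed = 2))
  st1 <- render_frames(sc1, n_frames = 1L, pixel_size_nm = 100,
                       photons_per_blink = 2e5, background_photons = 0)
  idx <- which(st1$frames[1, , ] == max(st1$frames[1, , ]),
               arr.ind = TRUE)[1, ]
  tx <- st1$ground_truth$x[1]; ty <- st1$ground_truth$y[1]
  expect_equal(floor(tx / 100) + 1, unname(idx[2]),
               ignore_attr = TRUE)
  expect_equal(floor(ty / 100) + 1, unname(idx[1]),
               ignore_attr = TRUE)

  # allocation bookkeeping: every blink lands in exactly one frame
  sc2 <- generate_scene(scene_params(n_foci = 2L,
                                     events_per_focus_ch1 = 25L,
                                     background_density_ch1 = 0,
                                     background_density_ch2 = 0,
                                     nucleus_radius_nm = 1000,
                                     seed = 3))
  st2 <- render_frames(sc2, n_frames = 200L, pixel_size_nm = 100)
  expect_identical(nrow(st2$ground_truth), 50L)
  expect_true(all(st2$ground_truth$frame %in% 1:200))
})

test_that("spot detection finds rendered spots and nothing on flat frames", {
  expect_identical(nrow(detect_spots(matrix(7, 30, 30))), 0L)

  s <- make_single_spot(750, 750, photons = 1e4, bg = 0)
  fr <- matrix(s$lambda, nrow(s$lambda))     # noise-free
  cand <- detect_spots(fr)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$row, which.max(apply(fr, 1, max)))

  # 20 well-separated spots: all found within one pixel
  set.seed(4)
  px <- 100; W <- 60
  gx <- rep(seq(5.5, 55.5, length.out = 5), 4) * px
  gy <- rep(seq(5.5, 55.5, length.out = 4), each = 5) * px
  edges <- seq(0, W * px, by = px)
  lam <- matrix(2, W, W)
  for (i in 1:20) {
    fx <- pnorm(edges[-1], gx[i], 130) - pnorm(edges[-(W + 1)], gx[i], 130)
    fy <- pnorm(edges[-1], gy[i], 130) - pnorm(edges[-(W + 1)], gy[i], 130)
    lam <- lam + 5000 * outer(fy, fx)
  }
  fr20 <- matrix(rpois(W * W, as.vector(lam)), W, W)
  cand20 <- detect_spots(fr20)
  expect_identical(nrow(cand20), 20L)
  for (i in 1:20) {
    d <- sqrt((cand20$col - gx[i] / px - 0.5)^2 +
                (cand20$row - gy[i] / px - 0.5)^2)
    expect_lte(min(d), 1)
  }
})

test_that("detection is translation-equivariant for whole-pixel shifts", {
  s <- make_single_spot(720, 680, photons = 8000, bg = 3, W = 20)
  fr <- round(s$lambda)               # noise-free expectation image
  shifted <- matrix(3, 20, 20)          # fill with background level
  shifted[4:20, 2:20] <- fr[1:17, 1:19] # shift +3 rows, +1 col
  c1 <- detect_spots(fr); c2 <- detect_spots(shifted)
  expect_identical(nrow(c1), 1L)
  expect_identical(c2$row, c1$row + 3L)
  expect_identical(c2$col, c1$col + 1L)
})

test_that("Gaussian fitting recovers sub-pixel positions and flags edges", {
  # noiseless spot at a known sub-pixel position
  s <- make_single_spot(761.3, 742.8, photons = 1e4, bg = 2)
  fr <- s$lambda                         # expectation, no Poisson draw
  cand <- detect_spots(fr)
  f <- fit_gaussian2d(fr, cand[1, ], detection_params(), 100)
  expect_true(is.data.frame(f))
  expect_lt(abs(f$x_nm - 761.3), 1)
  expect_lt(abs(f$y_nm - 742.8), 1)

  # candidate at the frame edge is rejected with reason "edge"
  fe <- fit_gaussian2d(fr, data.frame(row = 2L, col = 8L),
                       detection_params(), 100)
  expect_false(is.data.frame(fe))
  expect_identical(attr(fe, "reason"), "edge")
})

test_that("recorded loc_error matches Monte-Carlo precision at 5000 photons", {
  set.seed(6)
  errs2 <- c(); est <- c()
  for (m in 1:150) {
    x0 <- runif(1, 700, 800); y0 <- runif(1, 700, 800)
    s <- make_single_spot(x0, y0, photons = 5000, bg = 5)
    fr <- matrix(rpois(length(s$lambda), as.vector(s$lambda)),
                 nrow(s$lambda))
    cand <- detect_spots(fr)
    f <- fit_gaussian2d(fr, cand[1, ], detection_params(), 100)
    if (!is.data.frame(f)) next
    errs2 <- c(errs2, ((f$x_nm - x0)^2 + (f$y_nm - y0)^2) / 2)
    est <- c(est, f$loc_error_nm)
  }
  expect_gt(length(errs2), 140)
  rms <- sqrt(mean(errs2))
  expect_lt(abs(rms - mean(est)) / mean(est), 0.25)
})

test_that("localize_stack is deterministic and handles empty stacks", {
  empty <- structure(list(frames = array(0L, c(0, 8, 8)),
                          pixel_size_nm = 100, ground_truth = NULL,
                          n_clipped = 0L), class = "frame_stack")
  expect_identical(nrow(localize_stack(empty)), 0L)

  sc <- generate_scene(scene_params(n_foci = 1L,
                                    events_per_focus_ch1 = 10L,
                                    background_density_ch1 = 0,
                                    background_density_ch2 = 0,
                                    nucleus_radius_nm = 1000, seed = 8))
  st <- render_frames(sc, n_frames = 30L, pixel_size_nm = 100,
                      photons_per_blink = 5000, background_photons = 3)
  o1 <- localize_stack(st); o2 <- localize_stack(st)
  expect_identical(o1, o2)
  expect_gt(nrow(o1), 0L)
})

test_that("frame stacks round-trip through multi-page TIFF", {
  sc <- generate_scene(scene_params(n_foci = 1L,
                                    events_per_focus_ch1 = 5L,
                                    background_density_ch1 = 0,
                                    background_density_ch2 = 0,
                                    nucleus_radius_nm = 800, seed = 9))
  st <- render_frames(sc, n_frames = 4L, pixel_size_nm = 100)
  f <- tempfile(fileext = ".tif")
  write_frame_stack(st, f)
  back <- read_frame_stack(f, 100)
  expect_identical(back$frames, st$frames)
})
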