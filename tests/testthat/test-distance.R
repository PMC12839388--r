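test_that("distance histogram bins pair distances as specified", {
  # two points 100 nm apart: unit mass in bin [100, 110)
  h <- pairwise_distance_histogram(c(0, 100), c(0, 0), 10, 500)
  expect_equal(sum(h$rel_freq), 1)
  expect_equal(h$rel_freq[11], 1)

  # equilateral triangle, side 50: all mass in the bin containing 50
  x <- c(0, 50, 25); y <- c(0, 0, 25 * sqrt(3))
  h2 <- pairwise_distance_histogram(x, y, 10, 500)
  expect_equal(h2$rel_freq[6], 1)
  expect_identical(h2$n_pairs, 3L)

  expect_error(pairwise_distance_histogram(1, 1, 10, 500),
               "insufficient")
})

test_that("histogram is invariant under rigid motions and duplication", {
  set.seed(1)
  x <- runif(300, 0, 2000); y <- runif(300, 0, 2000)
  h <- pairwise_distance_histogram(x, y)
  th <- 0.7
  xr <- x * cos(th) - y * sin(th) + 500
  yr <- x * sin(th) + y * cos(th) - 900
  hr <- pairwise_distance_histogram(xr, yr)
  expect_equal(hr$counts, h$counts)

  # doubling every point changes only the zero bin: every original pair
  # appears four times, plus 300 zero-distance self pairs
  hd <- pairwise_distance_histogram(c(x, x), c(y, y))
  expect_equal(hd$counts[-1], 4 * h$counts[-1])
  expect_equal(hd$counts[1], 4 * h$counts[1] + 300)
})

test_that("CSR points give a near-linear rising histogram", {
  set.seed(2)
  r <- 3090 * sqrt(runif(2000)); a <- runif(2000, 0, 2 * pi)
  h <- pairwise_distance_histogram(r * cos(a), r * sin(a), 10, 500)
  mids <- (h$breaks_nm[-1] + h$breaks_nm[-length(h$breaks_nm)]) / 2
  fit <- lm(h$rel_freq ~ mids)
  expect_gte(summary(fit)$r.squared, 0.98)
})

test_that("peak detection finds constructed peaks and ignores monotone rises", {
  # monotone increasing: no peaks
  hm <- structure(list(breaks_nm = seq(0, 500, 10),
                       rel_freq = seq_len(50) / sum(seq_len(50)),
                       counts = seq_len(50), n_points = 100L,
                       n_pairs = sum(seq_len(50)),
                       max_distance_nm = 500),
                  class = "distance_histogram")
  expect_identical(nrow(detect_peaks(hm)), 0L)

  # two Gaussian bumps at 80 and 250 nm: peaks within one bin, spacing
  # 170 +/- bin width
  mids <- seq(5, 495, 10)
  f <- 0.6 * exp(-(mids - 80)^2 / (2 * 20^2)) +
       0.4 * exp(-(mids - 250)^2 / (2 * 25^2))
  hb <- structure(list(breaks_nm = seq(0, 500, 10), rel_freq = f / sum(f),
                       counts = round(1e4 * f), n_points = 500L,
                       n_pairs = round(sum(1e4 * f)),
                       max_distance_nm = 500),
                  class = "distance_histogram")
  pk <- detect_peaks(hb)
  expect_identical(nrow(pk), 2L)
  expect_lt(abs(pk$position_nm[1] - 80), 10 + 1e-9)
  expect_lt(abs(pk$position_nm[2] - 250), 10 + 1e-9)
  expect_lt(abs(attr(pk, "spacing_nm") - 170), 10 + 1e-9)
  expect_true(all(is.finite(pk$fwhm_nm)))
})

test_that("single-cluster scenes peak near the analytic pair-distance mode", {
  # pair differences of an isotropic Gaussian (sigma) are Gaussian with
  # sigma * sqrt(2) per axis, so pair distances are Rayleigh with mode
  # sigma * sqrt(2); the histogram peak must sit within 20% of the mode
  # computed from the analytic density (numeric oracle)
  sigma_eff <- sqrt(50^2 + 17^2)        # focus spread + blink noise
  dgrid <- seq(0.1, 500, 0.1)
  dens <- dgrid * exp(-dgrid^2 / (4 * sigma_eff^2))
  mode_analytic <- dgrid[which.max(dens)]
  sp <- scene_params(n_foci = 1L, events_per_focus_ch1 = 400L,
                     background_density_ch1 = 0,
                     background_density_ch2 = 0,
                     nucleus_radius_nm = 1500, seed = 5)
  sc <- generate_scene(sp)
  o <- sample_localizations(sc, 1L)
  h <- pairwise_distance_histogram(o$x_nm, o$y_nm, 10, 500)
  pk <- detect_peaks(h)
  expect_gte(nrow(pk), 1L)
  main <- pk$position_nm[which.max(pk$height)]
  expect_lt(abs(main - mode_analytic) / mode_analytic, 0.2)
})

test_that("peak position grows with the focus spread", {
  peak_for <- function(sigma, seeds) {
    mean(vapply(seeds, function(s) {
      sc <- generate_scene(scene_params(n_foci = 1L,
                                        events_per_focus_ch1 = 300L,
                                        background_density_ch1 = 0,
                                        background_density_ch2 = 0,
                                        focus_sigma_nm = sigma,
                                        nucleus_radius_nm = 1500,
                                        seed = s))
      o <- sample_localizations(sc, 1L)
      h <- pairwise_distance_histogram(o$x_nm, o$y_nm, 10, 800)
      pk <- detect_peaks(h)
      pk$position_nm[which.max(pk$height)]
    }, numeric(1)))
  }
  seeds <- 1:10
  p1 <- peak_for(30, seeds); p2 <- peak_for(60, seeds)
  p3 <- peak_for(100, seeds)
  expect_lt(p1, p2)
  expect_lt(p2, p3)
})

test_that("Ripley K matches the closed form for two points", {
  # two points at distance d in area A: K(r >= d) = A, K(r < d) = 0
  k <- ripley_k(c(0, 100), c(0, 0), r_nm = c(50, 150), area_um2 = 30)
  expect_equal(k$k_nm2, c(0, 30e6))
})

test_that("pooled histograms combine nuclei by pair count", {
  h1 <- pairwise_distance_histogram(c(0, 100), c(0, 0), 10, 500)
  x <- c(0, 50, 25); y <- c(0, 0, 25 * sqrt(3))
  h2 <- pairwise_distance_histogram(x, y, 10, 500)
  pooled <- pool_distance_histograms(list(h1, h2))
  expect_equal(pooled$n_pairs, 4L)
  expect_equal(pooled$rel_freq[6], 3 / 4)   # triangle's three 50s
  expect_equal(pooled$rel_freq[11], 1 / 4)  # pair's 100
  eqw <- pool_distance_histograms(list(h1, h2), weight = "equal")
  expect_equal(eqw$rel_freq[6], 0.5)
})
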