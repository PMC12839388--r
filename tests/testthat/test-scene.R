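# quick_scene_params (helper) shrinks the nucleus and counts so the
# generator's distributional properties can be exercised cheaply.

test_that("scene generation conserves counts and honours invariants", {
  # empty scene
  sp0 <- scene_params(n_foci = 0L, background_density_ch1 = 0,
                      background_density_ch2 = 0, seed = 1)
  sc0 <- generate_scene(sp0)
  expect_identical(nrow(sc0$true_positions_ch1), 0L)
  expect_identical(nrow(sample_localizations(sc0, 1L)), 0L)

  # exact focus counts, all inside the nucleus, foci mask within nucleus
  sp <- scene_params(n_foci = 2L, events_per_focus_ch1 = 300L,
                     background_density_ch1 = 0,
                     background_density_ch2 = 0, seed = 2)
  sc <- generate_scene(sp)
  expect_identical(nrow(sc$true_positions_ch1), 600L)
  expect_true(all(mask_contains(sc$nucleus_mask,
                                sc$true_positions_ch1$x,
                                sc$true_positions_ch1$y)))
  expect_true(all(sc$nucleus_mask$inside[sc$foci_mask$inside]))
  # focus centres respect the 4-sigma separation
  d <- dist(sc$focus_centers)
  expect_true(all(d >= 4 * sp$focus_sigma_nm))
})

test_that("background counts follow the Poisson sampling oracle", {
  # density 50/um^2 over ~30 um^2 -> mean 1500; 200 seeds
  counts <- vapply(1:200, function(s) {
    sc <- generate_scene(scene_params(n_foci = 0L,
                                      background_density_ch1 = 50,
                                      background_density_ch2 = 0,
                                      seed = s))
    nrow(sc$true_positions_ch1)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 1500), 3 * sqrt(1500) / sqrt(200))
})

test_that("scenes and orte matrices are bit-identical for a fixed seed", {
  sp <- quick_scene_params(seed = 11)
  s1 <- generate_scene(sp); s2 <- generate_scene(sp)
  expect_identical(s1, s2)
  expect_identical(sample_localizations(s1, 2L),
                   sample_localizations(s2, 2L))
})

test_that("localization sampling reproduces the error model", {
  # zero noise, one blink each: orte equals true positions
  sp <- quick_scene_params(loc_error_ch1_nm = 0, seed = 3)
  sc <- generate_scene(sp)
  o <- sample_localizations(sc, 1L)
  expect_identical(o$x_nm, sc$true_positions_ch1$x)
  expect_identical(o$y_nm, sc$true_positions_ch1$y)

  # 15 nm errors at n ~ 1e4: per-axis RMS within 2%
  spl <- scene_params(n_foci = 0L, background_density_ch2 = 334,
                      background_density_ch1 = 0, seed = 4)
  scl <- generate_scene(spl)
  ol <- sample_localizations(scl, 2L)
  em <- attr(ol, "emitter")
  expect_gt(nrow(ol), 9000)
  rms_x <- sqrt(mean((ol$x_nm - scl$true_positions_ch2$x[em])^2))
  rms_y <- sqrt(mean((ol$y_nm - scl$true_positions_ch2$y[em])^2))
  expect_lt(abs(rms_x - 15) / 15, 0.02)
  expect_lt(abs(rms_y - 15) / 15, 0.02)

  # recorded error column carries the channel defaults (17 / 15 nm)
  sc2 <- generate_scene(quick_scene_params(seed = 5))
  expect_identical(unique(sample_localizations(sc2, 1L)$loc_error_nm), 17)
  expect_identical(unique(sample_localizations(sc2, 2L)$loc_error_nm), 15)

  # blink-count conservation: orte rows = sum of blink draws
  ob <- sample_localizations(sc2, 1L, mean_blinks_per_emitter = 3)
  expect_identical(nrow(ob), length(attr(ob, "emitter")))
  expect_gt(nrow(ob), nrow(sc2$true_positions_ch1))
})

test_that("focus spread is recovered by the maximum-likelihood oracle", {
  sp <- scene_params(n_foci = 1L, events_per_focus_ch1 = 10000L,
                     background_density_ch1 = 0,
                     background_density_ch2 = 0, focus_sigma_nm = 50,
                     seed = 6)
  sc <- generate_scene(sp)
  r2 <- (sc$true_positions_ch1$x - sc$focus_centers[1, 1])^2 +
    (sc$true_positions_ch1$y - sc$focus_centers[1, 2])^2
  sigma_hat <- sqrt(mean(r2) / 2)     # ML for isotropic Gaussian radius
  expect_lt(abs(sigma_hat - 50) / 50, 0.05)
})

test_that("planted channel-2 events sit near channel-1 partners", {
  sp <- quick_scene_params(coloc_fraction = 0.6,
                           coloc_displacement_sigma_nm = 10, seed = 7)
  sc <- generate_scene(sp)
  planted <- sc$true_positions_ch2[sc$true_positions_ch2$is_coloc, ]
  expect_equal(nrow(planted), 2 * round(0.6 * 150))
  nnd <- oracle_nn_dist(cbind(planted$x, planted$y),
                        cbind(sc$true_positions_ch1$x,
                              sc$true_positions_ch1$y))
  expect_true(all(nnd < 60))          # ~5 sigma of the displacement
})

test_that("impossible focus placement fails explicitly", {
  expect_error(
    generate_scene(scene_params(nucleus_radius_nm = 500,
                                focus_sigma_nm = 150, n_foci = 2L,
                                seed = 1)),
    "place")
})
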