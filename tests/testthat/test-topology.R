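test_that("alpha persistence matches closed forms on simple configurations", {
  # isolated points far apart: n components, no holes within alpha_max
  x <- c(0, 5000, 10000); y <- c(0, 0, 8000)
  b <- alpha_persistence(x, y, alpha_max_nm = 500)
  expect_identical(sum(b$dimension == 0L), 3L)
  expect_identical(sum(b$dimension == 1L), 0L)
  expect_identical(sum(b$essential & b$dimension == 0L), 1L)
  expect_true(all(b$birth_nm[b$dimension == 0L] == 0))

  # two points at distance d merge at d/2
  b2 <- alpha_persistence(c(0, 100), c(0, 0), alpha_max_nm = 500)
  expect_equal(b2$death_nm[b2$dimension == 0L & !b2$essential], 50)

  # 20 points on a circle of radius 200: exactly one hole, death = R
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  b3 <- alpha_persistence(200 * cos(th), 200 * sin(th),
                          alpha_max_nm = 500)
  holes <- b3[b3$dimension == 1L, ]
  expect_identical(nrow(holes), 1L)
  expect_equal(holes$death_nm, 200, tolerance = 1e-9)
  expect_equal(holes$birth_nm, 200 * sin(pi / 20), tolerance = 1e-9)

  # single point
  b4 <- alpha_persistence(5, 7, alpha_max_nm = 100)
  expect_identical(nrow(b4), 1L)
  expect_error(alpha_persistence(numeric(0), numeric(0)), "at least")
})

test_that("dimension-0 bar count equals the point count", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(5:60, 1)
    b <- alpha_persistence(runif(n, 0, 500), runif(n, 0, 500),
                           alpha_max_nm = 1e5)
    expect_identical(sum(b$dimension == 0L), n)
    expect_identical(sum(b$essential & b$dimension == 0L), 1L)
  }
})

test_that("alpha persistence equals brute-force Cech persistence", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(4:12, 1)
    x <- runif(n, 0, 500); y <- runif(n, 0, 500)
    b <- alpha_persistence(x, y, alpha_max_nm = 1e5)
    o <- oracle_cech_persistence(x, y, alpha_max = 1e5)
    got <- as.data.frame(b)[, c("dimension", "birth_nm", "death_nm")]
    got <- got[order(got$dimension, got$birth_nm, got$death_nm), ]
    expect_identical(nrow(got), nrow(o))
    expect_lt(max(abs(got$birth_nm - o$birth)), 1e-9)
    expect_lt(max(abs(got$death_nm - o$death)), 1e-9)
  }
})

test_that("barcodes survive CSV round trips", {
  set.seed(3)
  b <- alpha_persistence(runif(30, 0, 800), runif(30, 0, 800), 500)
  f <- tempfile(fileext = ".csv")
  write_barcode(b, f)
  back <- read_barcode(f)
  expect_equal(as.data.frame(back), as.data.frame(b),
               ignore_attr = TRUE)
  expect_identical(attr(back, "alpha_max_nm"), attr(b, "alpha_max_nm"))
})

test_that("barcode Jaccard similarity obeys the paper's identities", {
  set.seed(4)
  b <- alpha_persistence(runif(40, 0, 600), runif(40, 0, 600), 500)
  expect_identical(jaccard_barcodes(b, b, 0L), 1)
  expect_identical(jaccard_barcodes(b, b, 1L), 1)

  # disjoint interval supports: S = 0
  b1 <- barcode(c(1L, 1L), c(5, 10), c(20, 40), alpha_max_nm = 500)
  b2 <- barcode(1L, 100, 200, alpha_max_nm = 500)
  expect_identical(jaccard_barcodes(b1, b2, 1L), 0)

  # hand-computed: [0,2] vs [1,3] -> 1/3
  h1 <- barcode(1L, 0, 2, alpha_max_nm = 500)
  h2 <- barcode(1L, 1, 3, alpha_max_nm = 500)
  expect_equal(jaccard_barcodes(h1, h2, 1L), 1 / 3)

  # both empty in a dimension -> 1; exactly one empty -> 0
  e <- barcode(integer(0), numeric(0), numeric(0), alpha_max_nm = 500)
  expect_identical(jaccard_barcodes(e, e, 1L), 1)
  expect_identical(jaccard_barcodes(e, h1, 1L), 0)

  # mismatched alpha_max is an error
  expect_error(jaccard_barcodes(h1, barcode(1L, 1, 3,
                                            alpha_max_nm = 300), 1L),
               "alpha_max")
})

test_that("greedy matching normalizes by the larger bar count", {
  # two identical bars vs one: best match 1, S = 1/2
  b1 <- barcode(c(1L, 1L), c(0, 0), c(10, 10), alpha_max_nm = 500)
  b2 <- barcode(1L, 0, 10, alpha_max_nm = 500)
  expect_equal(jaccard_barcodes(b1, b2, 1L), 0.5)
})

test_that("similarity is symmetric and bounded on random barcodes", {
  set.seed(5)
  bcs <- lapply(1:6, function(i)
    alpha_persistence(runif(30, 0, 700), runif(30, 0, 700), 500))
  for (i in 1:5) for (j in (i + 1):6) for (dm in c(0L, 1L)) {
    s_ij <- jaccard_barcodes(bcs[[i]], bcs[[j]], dm)
    s_ji <- jaccard_barcodes(bcs[[j]], bcs[[i]], dm)
    expect_identical(s_ij, s_ji)
    expect_gte(s_ij, 0); expect_lte(s_ij, 1)
  }
})

test_that("first-generation heatmaps are symmetric with unit diagonal", {
  set.seed(6)
  bcs <- lapply(1:4, function(i)
    alpha_persistence(runif(25, 0, 600), runif(25, 0, 600), 500))
  hm <- first_generation_heatmap(bcs, 0L)
  expect_identical(dim(hm$values), c(4L, 4L))
  expect_true(isSymmetric(hm$values))
  expect_equal(unname(diag(hm$values)), rep(1, 4))

  two <- first_generation_heatmap(list(bcs[[1]], bcs[[1]]), 0L)
  expect_equal(unname(two$values), matrix(1, 2, 2))
})

test_that("heatmap blocks reproduce hand-computed similarities", {
  bA <- barcode(1L, 0, 2, alpha_max_nm = 500)
  bB <- barcode(1L, 1, 3, alpha_max_nm = 500)
  bC <- barcode(1L, 100, 200, alpha_max_nm = 500)
  hm <- first_generation_heatmap(list(A = bA, B = bB, C = bC), 1L)
  expected <- matrix(c(1, 1 / 3, 0, 1 / 3, 1, 0, 0, 0, 1),
                     3, 3, dimnames = list(c("A", "B", "C"),
                                           c("A", "B", "C")))
  expect_equal(hm$values, expected)
})

test_that("second-generation cells are means of first-generation blocks", {
  g1 <- list("X|X" = matrix(c(1, 0.2, 0.2, 1), 2, 2),
             "X|Y" = matrix(c(0.2, 0.4), 1, 2),
             "Y|Y" = matrix(c(1, 0.4, 0.4, 1), 2, 2))
  g2 <- second_generation_heatmap(g1, c("X", "Y"), 0L)
  expect_equal(g2$values["X", "X"], 0.2)
  expect_equal(g2$values["Y", "Y"], 0.4)
  expect_equal(g2$values["X", "Y"], 0.3)
  expect_equal(g2$values["Y", "X"], 0.3)

  # constant gen-1 maps give a constant gen-2
  gc <- list("X|X" = matrix(c(1, 0.7, 0.7, 1), 2, 2),
             "X|Y" = matrix(0.7, 2, 2),
             "Y|Y" = matrix(c(1, 0.7, 0.7, 1), 2, 2))
  g2c <- second_generation_heatmap(gc, c("X", "Y"), 0L)
  expect_equal(unname(g2c$values[1, ]), c(0.7, 0.7))

  # missing pair reported missing
  g2m <- second_generation_heatmap(g1["X|X"], c("X", "Y"), 0L)
  expect_true(is.na(g2m$values["X", "Y"]))
})

test_that("component similarity exceeds hole similarity on a cohort", {
  # holes are fewer and born later, so their barcode overlap is weaker;
  # assessed as a cohort-level mean over seeds (scaled-down cohort)
  set.seed(7)
  bcs <- lapply(1:10, function(s) {
    sc <- generate_scene(quick_scene_params(seed = s))
    o <- apply_mask(sample_localizations(sc, 1L), sc$foci_mask)
    pts <- cbind(o$x_nm, o$y_nm)
    if (nrow(pts) > 150) pts <- pts[sort(sample.int(nrow(pts), 150)), ]
    alpha_persistence(pts, alpha_max_nm = 500)
  })
  hm0 <- first_generation_heatmap(bcs, 0L)$values
  hm1 <- first_generation_heatmap(bcs, 1L)$values
  off <- row(hm0) != col(hm0)
  expect_gt(mean(hm0[off]), mean(hm1[off]))
})
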