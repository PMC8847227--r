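test_that("NBD arithmetic, symmetry and degenerate pixels", {
  vals <- array(0, dim = c(1, 3, 2))
  vals[1, 1, ] <- c(0.1, 0.5)  # (0.5 - 0.1)/(0.6)
  vals[1, 2, ] <- c(0.3, 0.3)  # 0
  vals[1, 3, ] <- c(0, 0)      # undefined
  cube <- hyper_cube(vals, c(474, 898))
  nbd <- compute_nbd(cube, band_pair(cube, 898, 474))
  expect_equal(nbd$values[1, 1], 0.4 / 0.6)
  expect_equal(nbd$values[1, 2], 0)
  expect_true(is.na(nbd$values[1, 3]))
  expect_error(band_pair(cube, 474, 898), "lambda1 > lambda2")
})

test_that("NBD of any nonnegative cube lies in [-1, 1] where defined", {
  for (seed in 1:5) {
    cube <- toy_cube(6, 6, 8, seed = seed)
    nbd <- compute_nbd(cube, band_pair(cube, cube$wavelengths[7],
                                       cube$wavelengths[2]))
    v <- nbd$values[is.finite(nbd$values)]
    expect_true(all(v >= -1 & v <= 1))
  }
})

test_that("otsu contrast: two-valued data scores 1, constants error", {
  v <- c(rep(0, 17), rep(1, 47))
  expect_equal(otsu_contrast(v)$score, 1)
  expect_error(otsu_contrast(rep(0.3, 10)), "constant")
})

test_that("otsu contrast equals brute-force threshold search", {
  for (seed in 1:8) {
    set.seed(seed)
    v <- c(rnorm(32, 0, 0.5), rnorm(32, 2, 0.7))
    got <- otsu_contrast(v)
    want <- oracle_otsu(v)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
  }
})

test_that("otsu score is invariant under affine rescaling", {
  set.seed(4)
  v <- c(runif(40), runif(30, 2, 3))
  s0 <- otsu_contrast(v)$score
  expect_equal(otsu_contrast(3.7 * v - 11)$score, s0, tolerance = 1e-10)
  expect_equal(otsu_contrast(-2 * v + 5)$score, s0, tolerance = 1e-10)
})

test_that("band-pair selection matches the exhaustive oracle", {
  # cube where one band carries the class signal, the rest are noise
  set.seed(2)
  L <- 10; P <- 12; B <- 6
  vals <- array(runif(L * P * B, 0.2, 0.4), dim = c(L, P, B))
  fg <- matrix(FALSE, L, P); fg[3:7, 4:9] <- TRUE
  sig <- 4  # signal band index
  vals[, , sig][fg] <- vals[, , sig][fg] + 0.5
  cube <- hyper_cube(vals, seq(450, 950, length.out = B))
  got <- select_band_pair(cube, stride = 1)
  expect_true(sig %in% c(got$pair$band1, got$pair$band2))
  want <- oracle_band_pair(cube)
  expect_equal(got$pair$lambda1, want$l1)
  expect_equal(got$pair$lambda2, want$l2)
  expect_equal(got$score$score, want$score, tolerance = 1e-12)
})

test_that("band-pair selection equals the oracle on random cubes", {
  for (seed in 1:5) {
    cube <- toy_cube(8, 9, 7, seed = seed + 20)
    got <- select_band_pair(cube, stride = 1)
    want <- oracle_band_pair(cube)
    expect_equal(c(got$pair$lambda1, got$pair$lambda2),
                 c(want$l1, want$l2))
  }
})

test_that("stride-1 search never scores below a strided search", {
  cube <- toy_cube(8, 8, 12, seed = 31)
  s1 <- select_band_pair(cube, stride = 1)$score$score
  s3 <- select_band_pair(cube, stride = 3)$score$score
  expect_gte(s1, s3)
})

test_that("intermodes threshold of two delta peaks is their midpoint", {
  v <- c(rep(0, 120), rep(0.8, 90))
  th <- intermode_threshold(v)
  expect_equal(th$threshold, 0.4)
  expect_equal(th$smoothing_iterations, 0)
  expect_error(intermode_threshold(rep(1, 5)), "constant")
})

test_that("intermodes threshold equals the naive smoothing oracle", {
  set.seed(17)
  n_cases <- 100
  checked <- 0
  for (i in seq_len(n_cases)) {
    mix <- c(rnorm(150, 0, runif(1, 0.3, 1)),
             rnorm(150, runif(1, 2.5, 5), runif(1, 0.3, 1)))
    want <- oracle_intermodes(mix, bins = 64)
    if (is.null(want)) next
    got <- intermode_threshold(mix, bins = 64)
    expect_identical(got$smoothing_iterations, want$iterations)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gte(checked, 95)
})

test_that("synthetic scenes segment with high IoU and correct count", {
  fx <- leaf_scene(n = 8, seed = 3)
  sc <- fx$scene
  seg <- segment_scene(sc$cube, c(900, 470))
  truth <- sc$labels > 0
  iou <- sum(seg$mask & truth) / sum(seg$mask | truth)
  expect_gte(iou, 0.95)
  expect_equal(nrow(seg$region_table), 8)
  # regions partition the mask
  expect_equal(sum(seg$region_table$area), sum(seg$mask))
})

test_that("area filtering removes specks and labels run in raster order", {
  vals <- array(0.1, dim = c(40, 40, 2))
  big1 <- matrix(FALSE, 40, 40); big1[5:15, 5:15] <- TRUE
  big2 <- matrix(FALSE, 40, 40); big2[25:35, 20:30] <- TRUE
  speck <- matrix(FALSE, 40, 40); speck[20, 38] <- TRUE
  for (m in list(big1, big2, speck))
    vals[, , 2][m] <- 0.9   # high NBD foreground
  cube <- hyper_cube(vals, c(500, 900))
  seg <- segment_scene(cube, c(900, 500), min_area = 50,
                       morph_radius = 0)
  expect_equal(nrow(seg$region_table), 2)
  # raster order: big1 starts on an earlier line
  expect_lt(seg$region_table$line_min[1], seg$region_table$line_min[2])
  expect_false(any(seg$mask & speck))
})

test_that("8-connected components are one region across diagonals", {
  vals <- array(0.1, dim = c(12, 12, 2))
  diag_m <- matrix(FALSE, 12, 12)
  for (i in 1:10) diag_m[i, i] <- TRUE  # diagonal chain
  vals[, , 2][diag_m] <- 0.9
  cube <- hyper_cube(vals, c(500, 900))
  seg <- segment_scene(cube, c(900, 500), min_area = 1,
                       morph_radius = 0)
  expect_equal(nrow(seg$region_table), 1)
})

test_that("reference panel localization works in both modes", {
  fx <- leaf_scene(n = 4, seed = 9)
  sc <- fx$scene
  seg <- segment_scene(sc$cube, c(900, 470))
  # roi mode: the configured rectangle is returned
  ref <- locate_reference(sc$cube, seg, mode = "roi",
                          roi = list(rows = c(6, 24), cols = c(1, 220)))
  expect_equal(ref$mask, sc$reference_mask)
  expect_error(locate_reference(sc$cube, seg, mode = "roi",
                                roi = list(rows = c(500, 520),
                                           cols = c(1, 10))),
               "outside")
  # flatness mode: the flat panel beats every leaf on spectrum CV
  fl <- locate_reference(sc$cube, seg, mode = "flatness")
  expect_false(is.null(fl))
  expect_gt(sum(fl$mask & sc$reference_mask) / sum(fl$mask), 0.95)
  leaf_cv <- sapply(seq_len(4), function(i) {
    s <- mean_spectrum(sc$cube, seg$regions, id = i)$mean
    sd(s) / mean(s)
  })
  expect_true(all(fl$cv < leaf_cv))
  # no panel in the scene -> none found
  fx2 <- leaf_scene(n = 4, seed = 10, reference = FALSE)
  seg2 <- segment_scene(fx2$scene$cube, c(900, 470))
  expect_null(locate_reference(fx2$scene$cube, seg2,
                               mode = "flatness"))
})
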