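test_that("deterministic vegetation curve has the expected shape", {
  m <- quiet_model()
  wl <- seq(400, 1000, length.out = 462)
  r <- vegetation_spectrum(m, wl)
  expect_true(all(r >= 0 & r <= 1))
  # chlorophyll dip: local minimum at the 670 nm band over 650-690
  win <- which(wl >= 650 & wl <= 690)
  expect_equal(which.min(r[win]),
               which(win == which.min(abs(wl - 670))))
  # NIR plateau reached beyond the red edge
  r900 <- r[which.min(abs(wl - 900))]
  expect_lt(abs(r900 - m$nir_plateau) / m$nir_plateau, 0.05)
  # green bump visible relative to the surrounding visible range
  expect_gt(r[which.min(abs(wl - 550))], r[which.min(abs(wl - 480))])
})

test_that("spectrum draws are deterministic under a seed", {
  m <- spectral_class_model()
  wl <- seq(400, 1000, length.out = 60)
  expect_identical(vegetation_spectrum(m, wl, seed = 42),
                   vegetation_spectrum(m, wl, seed = 42))
  expect_false(identical(vegetation_spectrum(m, wl, seed = 1),
                         vegetation_spectrum(m, wl, seed = 2)))
})

test_that("invalid class models are rejected", {
  expect_error(spectral_class_model(nir_plateau = 0.05),
               "nir_plateau")
  expect_error(spectral_class_model(chl_absorption = c(0.5, 670, 20)),
               "dip depth")
  expect_error(spectral_class_model(within_class_sd = -1), "sd")
  m <- quiet_model()
  expect_error(vegetation_spectrum(m, c(600, 500)), "ascending")
  expect_error(vegetation_spectrum(m, c(300, 600)), "350")
})

test_that("sampling design reports the study plant totals", {
  d <- build_sampling_design()
  expect_equal(d$plants_per_cultivar, 20)
  expect_equal(d$total_plants, 100)
  expect_equal(sum(d$cells$n[d$cells$organ == "leaf"]), 400)
  d1 <- build_sampling_design(cultivars = 1, dates = 1, replicates = 1)
  expect_equal(d1$total_plants, 1)
  expect_error(build_sampling_design(replicates = 0), "positive")
})

test_that("generated dataset row counts match the design cells", {
  d <- build_sampling_design()
  ds <- generate_spectra_dataset(d, seed = 1,
                                 wavelengths = seq(400, 1000,
                                                   length.out = 15))
  meta <- spectra_meta(ds$table)
  expect_equal(nrow(meta), sum(d$cells$n))
  # Table-1 anchor cell: CW flowers at the first date
  expect_equal(sum(meta$cultivar == "CW" & meta$stage == 1 &
                     meta$organ == "flower"), 24)
  # every cell matches
  for (i in seq_len(nrow(d$cells))) {
    cell <- d$cells[i, ]
    expect_equal(sum(meta$cultivar == cell$cultivar &
                       meta$stage == cell$stage &
                       meta$organ == cell$organ), cell$n)
  }
})

test_that("empirical class means converge to the model curves", {
  # 10,000 draws of one class; per-wavelength mean within 3 SE
  d <- build_sampling_design(cultivars = "CW", dates = 1,
                             replicates = 4,
                             counts = list(leaf = matrix(10000, 1, 1)))
  wl <- seq(400, 1000, length.out = 60)
  cls <- hemp_class_models("CW", 1, "leaf")
  ds <- generate_spectra_dataset(d, classes = cls, seed = 99,
                                 wavelengths = wl)
  mu_hat <- colMeans(spectra_matrix(ds$table))
  mu <- hempspec:::class_mean_curve(cls[["CW|1|leaf"]], wl)
  se <- mu * cls[["CW|1|leaf"]]$within_class_sd / sqrt(10000)
  expect_true(all(abs(mu_hat - mu) < 3 * se))
})

test_that("separation zero collapses all classes onto one curve", {
  d <- build_sampling_design(cultivars = c("CW", "BX"), dates = 2,
                             replicates = 2,
                             counts = list(leaf = matrix(4, 2, 2),
                                           flower = matrix(4, 2, 2)))
  wl <- seq(400, 1000, length.out = 20)
  ds0 <- generate_spectra_dataset(d, separation = 0, seed = 5,
                                  wavelengths = wl)
  ds1 <- generate_spectra_dataset(d, separation = 1, seed = 5,
                                  wavelengths = wl)
  X0 <- spectra_matrix(ds0$table)
  X1 <- spectra_matrix(ds1$table)
  gm0 <- sapply(split(seq_len(nrow(X0)), ds0$labels$organ),
                function(i) colMeans(X0[i, , drop = FALSE]))
  gm1 <- sapply(split(seq_len(nrow(X1)), ds1$labels$organ),
                function(i) colMeans(X1[i, , drop = FALSE]))
  # organ means nearly coincide at separation 0, far apart at 1
  expect_lt(max(abs(gm0[, 1] - gm0[, 2]) / gm0[, 1]), 0.1)
  expect_gt(max(abs(gm1[, 1] - gm1[, 2]) / gm1[, 1]), 0.2)
})

test_that("rendered scenes honour the zero-noise reference contract", {
  cls <- list(leaf = quiet_model(label = "leaf"))
  des <- scene_design(
    objects = scene_objects_grid("leaf"),
    noise = list(additive_sd = 0, multiplicative_sd = 0),
    illumination = list(amplitude = 0, line_amplitude = 0), seed = 1)
  sc <- render_scene(des, cls)
  ref_vals <- apply(sc$cube$values, 3, function(pl) pl[sc$reference_mask])
  expect_true(all(ref_vals == 0.20))
})

test_that("ground-truth labels conserve object areas and seeds fix bits", {
  fx <- leaf_scene(n = 5, seed = 11)
  sc <- fx$scene
  counts <- tabulate(sc$labels[sc$labels > 0], nbins = 5)
  expect_equal(counts, sc$objects$area_px)
  # no overlap with the reference
  expect_false(any(sc$labels > 0 & sc$reference_mask))
  sc2 <- render_scene(fx$design, fx$classes)
  expect_identical(sc$cube$values, sc2$cube$values)
})

test_that("overlapping objects are a design error", {
  cls <- list(leaf = quiet_model(label = "leaf"))
  objs <- list(list(shape = "ellipse", center = c(80, 100),
                    radii = c(12, 12), label = "leaf"),
               list(shape = "ellipse", center = c(85, 104),
                    radii = c(12, 12), label = "leaf"))
  des <- scene_design(objects = objs)
  expect_error(render_scene(des, cls), "overlaps")
})
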