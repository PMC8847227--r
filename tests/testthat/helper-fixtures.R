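# Small fixtures built in code: toy cubes, quiet class models, scenes.

toy_cube <- function(lines = 2, pixels = 2, bands = 3,
                     wavelengths = seq(500, 900, length.out = bands),
                     fill = NULL, seed = 1) {
  if (is.null(fill)) {
    set.seed(seed)
    fill <- array(runif(lines * pixels * bands, 0.05, 0.9),
                  dim = c(lines, pixels, bands))
  }
  hyper_cube(fill, wavelengths, scan_id = "toy")
}

quiet_model <- function(...) spectral_class_model(within_class_sd = 0, ...)

# One-leaf-class scene with n disjoint ellipses; noise/illumination
# configurable.
leaf_scene <- function(n = 8, seed = 3, noise = list(additive_sd = 0.002,
                                                     multiplicative_sd = 0.02),
                       illumination = list(amplitude = 0.15,
                                           line_amplitude = 0),
                       reference = TRUE, sd_within = 0.05) {
  cls <- list("leaf" = spectral_class_model(within_class_sd = sd_within,
                                            label = "leaf"))
  des <- scene_design(
    objects = scene_objects_grid(rep("leaf", n)),
    reference = if (reference) list(rows = c(6, 24), cols = c(1, 220),
                                    reflectance = 0.20) else NULL,
    noise = noise, illumination = illumination, seed = seed)
  list(scene = render_scene(des, cls), design = des, classes = cls)
}

# Two-organ spectra set at study-like separation.
organ_dataset <- function(n_per_class = 40, wavelengths = seq(400, 1000,
                                                              length.out = 80),
                          separation = 1, seed = 1) {
  d <- build_sampling_design(
    cultivars = "CW", dates = 1, replicates = 4,
    counts = list(leaf = matrix(n_per_class, 1, 1),
                  flower = matrix(n_per_class, 1, 1)))
  generate_spectra_dataset(d, separation = separation, seed = seed,
                           wavelengths = wavelengths)
}
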