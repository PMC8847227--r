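## Synthetic hyperspectral scenes and spectra with the statistical
## structure the analysis assumes: vegetation-like reflectance curves
## (visible pigment absorption, green bump, chlorophyll dip near 670 nm,
## logistic red edge into an NIR plateau), a flat tray background, a
## spectrally flat 20% reference panel, smooth multiplicative
## illumination unevenness, and the greenhouse sampling design
## (5 cultivars x 5 dates x leaf/flower).

#' Spectral class model for vegetation-like reflectance
#'
#' Parametric mean reflectance curve of one sample class plus its
#' within-class spread. The curve is a visible baseline with a green
#' reflectance bump and a chlorophyll absorption dip, blended into a
#' near-infrared plateau through a logistic red edge.
#'
#' @param visible_baseline Reflectance fraction in the visible range.
#' @param green_peak `c(amplitude, center_nm, width_nm)` of the green
#'   reflectance bump (center near 550 nm).
#' @param chl_absorption `c(depth, center_nm, width_nm)` of the
#'   chlorophyll absorption dip (center near 670 nm).
#' @param red_edge `c(center_nm, slope_nm)` of the logistic transition
#'   into the NIR plateau (inflection near 700-720 nm).
#' @param nir_plateau Reflectance fraction beyond the red edge.
#' @param within_class_sd Multiplicative per-wavelength spread of
#'   individual samples around the class mean curve.
#' @param label Optional list/character naming the class
#'   (cultivar, stage, organ).
#' @return An object of class `spectral_class_model`.
#' @export
spectral_class_model <- function(visible_baseline = 0.06,
                                 green_peak = c(0.05, 550, 40),
                                 chl_absorption = c(0.045, 670, 20),
                                 red_edge = c(720, 7),
                                 nir_plateau = 0.45,
                                 within_class_sd = 0.05,
                                 label = NULL) {
  m <- structure(
    list(visible_baseline = visible_baseline, green_peak = green_peak,
         chl_absorption = chl_absorption, red_edge = red_edge,
         nir_plateau = nir_plateau, within_class_sd = within_class_sd,
         label = label),
    class = "spectral_class_model")
  if (visible_baseline < 0 || visible_baseline > 1 ||
      nir_plateau < 0 || nir_plateau > 1 || green_peak[1] < 0 ||
      green_peak[1] > 1 || chl_absorption[1] < 0)
    stop("reflectance fractions must lie in [0, 1]", call. = FALSE)
  if (chl_absorption[1] >= visible_baseline + green_peak[1])
    stop("chlorophyll dip depth must be < visible baseline + green peak",
         call. = FALSE)
  if (nir_plateau <= visible_baseline)
    stop("vegetation-like model requires nir_plateau > visible baseline",
         call. = FALSE)
  if (within_class_sd < 0)
    stop("within_class_sd must be >= 0", call. = FALSE)
  m
}

## Deterministic class mean curve on a wavelength grid.
class_mean_curve <- function(model, wavelengths) {
  stopifnot(inherits(model, "spectral_class_model"))
  vis <- model$visible_baseline +
    model$green_peak[1] *
    exp(-(wavelengths - model$green_peak[2])^2 /
          (2 * model$green_peak[3]^2))
  w <- stats::plogis((wavelengths - model$red_edge[1]) / model$red_edge[2])
  r <- (1 - w) * vis + w * model$nir_plateau -
    model$chl_absorption[1] *
    exp(-(wavelengths - model$chl_absorption[2])^2 /
          (2 * model$chl_absorption[3]^2))
  pmin(pmax(r, 0), 1)
}

#' Draw a vegetation reflectance spectrum
#'
#' Evaluates the class mean curve on a wavelength grid and, when the
#' model's `within_class_sd` is positive, applies independent
#' multiplicative Gaussian spread per wavelength. With `within_class_sd
#' = 0` the result is the deterministic mean curve.
#'
#' @param model A [spectral_class_model()].
#' @param wavelengths Ascending wavelengths in nm, within 350-1100 nm.
#' @param seed Optional integer seed for the draw.
#' @return Reflectance vector in `[0, 1]`, one value per wavelength.
#' @export
vegetation_spectrum <- function(model, wavelengths, seed = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly ascending", call. = FALSE)
  if (min(wavelengths) < 350 || max(wavelengths) > 1100)
    stop("wavelengths must lie within 350-1100 nm", call. = FALSE)
  mu <- class_mean_curve(model, wavelengths)
  if (model$within_class_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    mu <- mu * (1 + stats::rnorm(length(mu), 0, model$within_class_sd))
  }
  pmin(pmax(mu, 0), 1)
}

## ---------------------------------------------------------------------
## Class model sets for the hemp study design
## ---------------------------------------------------------------------

.cultivar_effects <- list(  # fixed small per-cultivar parameter factors
  CW   = c(chl = 1.000, nir = 1.000, green = 1.000),
  BX   = c(chl = 1.030, nir = 0.990, green = 1.020),
  FL58 = c(chl = 0.970, nir = 1.010, green = 0.980),
  FL70 = c(chl = 1.020, nir = 1.015, green = 1.030),
  TJ   = c(chl = 0.980, nir = 0.985, green = 1.010)
)

#' Class models for cultivar x stage x organ combinations
#'
#' Builds one [spectral_class_model()] per combination. Effects are
#' parameter offsets relative to a common base model: organs differ by a
#' large NIR plateau and red-edge slope shift (mirroring the clear
#' leaf/flower separation in PC space), stages by a monotone decrease in
#' chlorophyll dip depth with a matching NIR increase (senescence), and
#' cultivars by small fixed parameter factors (their clusters overlap).
#' All effects scale linearly with `separation`; at 0 every class shares
#' the base curve.
#'
#' @param cultivars Character vector of cultivar names. Names outside the
#'   built-in five get deterministic small effects derived from their
#'   position in the vector.
#' @param stages Integer vector of growth stage indices (1 = earliest).
#' @param organs Subset of `c("leaf", "flower")`.
#' @param separation Non-negative scale on all between-class mean
#'   differences (1 = default study-like effects).
#' @param base Base [spectral_class_model()].
#' @return Named list of models, names `"cultivar|stage|organ"`.
#' @export
hemp_class_models <- function(cultivars = c("CW", "BX", "FL58", "FL70", "TJ"),
                              stages = 1:5,
                              organs = c("leaf", "flower"),
                              separation = 1,
                              base = spectral_class_model()) {
  stopifnot(separation >= 0)
  organs <- match.arg(organs, c("leaf", "flower"), several.ok = TRUE)
  sc <- function(f) 1 + separation * (f - 1)  # scale a factor toward 1
  models <- list()
  for (cv in cultivars) {
    eff <- .cultivar_effects[[cv]]
    if (is.null(eff)) {
      i <- match(cv, cultivars)
      eff <- c(chl = 1 + 0.03 * sin(i), nir = 1 + 0.015 * cos(i),
               green = 1 + 0.02 * sin(2 * i))
    }
    for (st in stages) {
      t <- st - 1
      for (org in organs) {
        chl <- base$chl_absorption
        chl[1] <- chl[1] * sc(eff[["chl"]]) * (1 - 0.08 * separation * t)
        nir <- base$nir_plateau * sc(eff[["nir"]]) *
          (1 + 0.05 * separation * t)
        edge <- base$red_edge
        if (org == "flower") {
          nir <- nir * (1 + 0.30 * separation)
          edge[2] <- edge[2] * (1 + 0.40 * separation)
        }
        green <- base$green_peak
        green[1] <- green[1] * sc(eff[["green"]])
        models[[paste(cv, st, org, sep = "|")]] <- spectral_class_model(
          visible_baseline = base$visible_baseline,
          green_peak = green, chl_absorption = chl, red_edge = edge,
          nir_plateau = min(nir, 0.95),
          within_class_sd = base$within_class_sd,
          label = list(cultivar = cv, stage = st, organ = org))
      }
    }
  }
  models
}

## ---------------------------------------------------------------------
## Sampling design
## ---------------------------------------------------------------------

#' Leaf and flower counts of the greenhouse sampling design
#'
#' Per cultivar x sampling date counts of scanned leaves and flowers for
#' the five cultivars (CW, BX, FL58, FL70, TJ) over five dates: 16
#' leaves per cell throughout; flowers 24 for CW, 21-22 for BX, 16-17
#' for FL58 and 16 for FL70 and TJ.
#'
#' @return List of two 5x5 integer matrices (`leaf`, `flower`), rows =
#'   cultivars, columns = dates.
#' @export
hemp_design_counts <- function() {
  cvs <- c("CW", "BX", "FL58", "FL70", "TJ")
  leaf <- matrix(16L, 5, 5, dimnames = list(cvs, NULL))
  flower <- rbind(
    CW   = c(24L, 24L, 24L, 24L, 24L),
    BX   = c(22L, 21L, 21L, 22L, 21L),
    FL58 = c(16L, 17L, 16L, 16L, 16L),
    FL70 = c(16L, 16L, 16L, 16L, 16L),
    TJ   = c(16L, 16L, 16L, 16L, 16L))
  list(leaf = leaf, flower = flower)
}

#' Build a sampling design
#'
#' Describes how many leaf and flower samples are scanned per cultivar
#' and sampling date (growth stage), and reports the plant totals implied
#' by the replicated harvest layout: `dates x replicates` plants per
#' cultivar.
#'
#' @param cultivars Cultivar names, or a count (names generated).
#' @param dates Date/stage labels, or a count.
#' @param replicates Plants harvested per cultivar per date.
#' @param counts List with integer matrices `leaf` and `flower`
#'   (cultivar x date). Defaults to [hemp_design_counts()] for the
#'   standard 5 x 5 design, otherwise 16 per cell.
#' @return An object of class `sampling_design` with fields `cultivars`,
#'   `dates`, `replicates`, `counts`, `cells` (long-format data frame),
#'   `plants_per_cultivar` and `total_plants`.
#' @export
build_sampling_design <- function(cultivars = c("CW", "BX", "FL58",
                                                "FL70", "TJ"),
                                  dates = 5, replicates = 4,
                                  counts = NULL) {
  if (is.numeric(cultivars) && length(cultivars) == 1L)
    cultivars <- paste0("C", seq_len(cultivars))
  if (is.numeric(dates) && length(dates) == 1L)
    dates <- seq_len(dates)
  n <- length(cultivars); m <- length(dates); r <- as.integer(replicates)
  if (n < 1L || m < 1L || r < 1L)
    stop("cultivar, date and replicate counts must be positive",
         call. = FALSE)
  if (is.null(counts)) {
    counts <- if (n == 5L && m == 5L &&
                  all(cultivars == c("CW", "BX", "FL58", "FL70", "TJ")))
      hemp_design_counts()
    else
      list(leaf = matrix(16L, n, m), flower = matrix(16L, n, m))
  }
  for (org in names(counts)) {
    cm <- counts[[org]]
    if (!all(dim(cm) == c(n, m)))
      stop("counts$", org, " must be a ", n, "x", m, " matrix",
           call. = FALSE)
    if (any(cm != round(cm)) || any(cm <= 0))
      stop("sample counts must be positive integers", call. = FALSE)
  }
  cells <- do.call(rbind, lapply(names(counts), function(org) {
    data.frame(cultivar = rep(cultivars, times = m),
               stage = rep(seq_len(m), each = n),
               date = rep(dates, each = n),
               organ = org, n = as.vector(counts[[org]]),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(cultivars = cultivars, dates = dates, replicates = r,
         counts = counts, cells = cells,
         plants_per_cultivar = m * r, total_plants = n * m * r),
    class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf(
    "sampling_design: %d cultivars x %d dates x %d replicates\n",
    length(x$cultivars), length(x$dates), x$replicates))
  cat(sprintf("plants per cultivar: %d; total plants: %d; samples: %d\n",
              x$plants_per_cultivar, x$total_plants, sum(x$cells$n)))
  invisible(x)
}

#' Generate a spectra dataset from a sampling design
#'
#' Draws one spectrum per designed sample. Class mean curves are taken
#' from `classes` and shrunk toward (or stretched away from) their grand
#' mean by `separation`; individual samples scatter around their class
#' mean with the model's multiplicative within-class spread. At
#' `separation = 0` every class shares one distribution.
#'
#' @param design A [build_sampling_design()] result.
#' @param classes Named list of class models as from [hemp_class_models()]
#'   (names `"cultivar|stage|organ"`); built automatically if `NULL`.
#' @param separation Non-negative scale on between-class mean differences
#'   (in units of the built-in class effects; 1 = study-like defaults).
#' @param seed Integer seed.
#' @param wavelengths Wavelength grid in nm; default the study's 462
#'   bands over 400-1000 nm.
#' @return List with `table` (a [spectra_table()]) and `labels` (data
#'   frame of cultivar/stage/organ per row).
#' @export
generate_spectra_dataset <- function(design, classes = NULL,
                                     separation = 1, seed = 1,
                                     wavelengths = seq(400, 1000,
                                                       length.out = 462)) {
  stopifnot(inherits(design, "sampling_design"), separation >= 0)
  if (is.null(classes))
    classes <- hemp_class_models(design$cultivars,
                                 seq_along(design$dates),
                                 unique(design$cells$organ))
  curves <- vapply(classes, class_mean_curve,
                   numeric(length(wavelengths)),
                   wavelengths = wavelengths)
  grand <- rowMeans(curves)
  curves <- grand + separation * (curves - grand)
  set.seed(seed)
  rows <- vector("list", nrow(design$cells))
  meta <- vector("list", nrow(design$cells))
  for (i in seq_len(nrow(design$cells))) {
    cell <- design$cells[i, ]
    key <- paste(cell$cultivar, cell$stage, cell$organ, sep = "|")
    if (!key %in% colnames(curves))
      stop("no class model for cell ", key, call. = FALSE)
    mu <- curves[, key]
    sdw <- classes[[key]]$within_class_sd
    k <- cell$n
    eps <- matrix(stats::rnorm(k * length(mu), 0, sdw), k)
    rows[[i]] <- pmin(pmax(rep(mu, each = k) * (1 + eps), 1e-8), 1)
    rep_id <- rep_len(seq_len(design$replicates), k)
    meta[[i]] <- data.frame(
      sample_id = sprintf("%s_s%s_%s_%02d", cell$cultivar, cell$stage,
                          cell$organ, seq_len(k)),
      scan_id = sprintf("%s_s%s_%s_r%d", cell$cultivar, cell$stage,
                        cell$organ, rep_id),
      cultivar = cell$cultivar, stage = cell$stage, organ = cell$organ,
      replicate = rep_id, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  tab <- spectra_table(meta, do.call(rbind, rows), wavelengths)
  list(table = tab,
       labels = meta[, c("cultivar", "stage", "organ")])
}

## ---------------------------------------------------------------------
## Scene rendering
## ---------------------------------------------------------------------

#' Scene design for synthetic rendering
#'
#' Describes the layout of one synthetic scan: image size, plant objects
#' (ellipses or blob unions of ellipses) with class labels, a spectrally
#' flat grey reference panel, a flat tray background, a smooth
#' multiplicative illumination field and sensor noise.
#'
#' @param lines,pixels Image size.
#' @param objects List of objects, each a list with `shape` ("ellipse" or
#'   "blob"), `center` `c(line, pixel)`, `radii` `c(r_line, r_pixel)` and
#'   `label` (class key `"cultivar|stage|organ"` or a list). See
#'   [scene_objects_grid()] for an automatic disjoint layout.
#' @param reference `NULL`, or a list with `rows` `c(from, to)`, `cols`
#'   `c(from, to)` and `reflectance` (nominal 0.20). The default spans
#'   the full scan width so that column-wise flat-fielding is possible.
#' @param background Tray reflectance (spectrally flat).
#' @param illumination List: `amplitude` (multiplicative unevenness, 0.15
#'   = +/-15%), `line_amplitude` (optional along-track component,
#'   default 0: a line-scan lamp profile is fixed along the scan line and
#'   constant over time).
#' @param noise List: `additive_sd` (sensor), `multiplicative_sd`
#'   (per-pixel gain).
#' @param wavelengths Wavelength grid of the rendered cube.
#' @param seed Integer seed.
#' @return An object of class `scene_design`.
#' @export
scene_design <- function(lines = 160, pixels = 220, objects = list(),
                         reference = list(rows = c(6, 24),
                                          cols = c(1, pixels),
                                          reflectance = 0.20),
                         background = 0.10,
                         illumination = list(amplitude = 0.15,
                                             line_amplitude = 0),
                         noise = list(additive_sd = 0.002,
                                      multiplicative_sd = 0.02),
                         wavelengths = seq(400, 1000, length.out = 60),
                         seed = 1) {
  if (is.null(illumination$line_amplitude))
    illumination$line_amplitude <- 0
  structure(
    list(lines = as.integer(lines), pixels = as.integer(pixels),
         objects = objects, reference = reference,
         background = background, illumination = illumination,
         noise = noise, wavelengths = as.numeric(wavelengths),
         seed = as.integer(seed)),
    class = "scene_design")
}

#' Disjoint grid layout of scene objects
#'
#' Places one object per class label on a regular grid below the
#' reference strip, guaranteeing pairwise disjoint shapes.
#'
#' @param labels Character vector of class keys, one object each
#'   (recycled object ids distinguish repeats of one class).
#' @param lines,pixels Scene size.
#' @param top First image line available for objects (below the panel).
#' @param shape `"ellipse"` or `"blob"` (blob = union of overlapping
#'   ellipses), recycled over objects.
#' @param radii Base object radii `c(r_line, r_pixel)`.
#' @return List of object descriptors for [scene_design()].
#' @export
scene_objects_grid <- function(labels, lines = 160, pixels = 220,
                               top = 30, shape = "ellipse",
                               radii = c(11, 14)) {
  k <- length(labels)
  shape <- rep_len(shape, k)
  ncol_ <- ceiling(sqrt(k))
  nrow_ <- ceiling(k / ncol_)
  ys <- seq(top + radii[1] + 6, lines - radii[1] - 6,
            length.out = nrow_)
  xs <- seq(radii[2] + 8, pixels - radii[2] - 8, length.out = ncol_)
  objs <- vector("list", k)
  for (i in seq_len(k)) {
    r <- (i - 1) %/% ncol_ + 1; c <- (i - 1) %% ncol_ + 1
    objs[[i]] <- list(shape = shape[i],
                      center = c(ys[r], xs[c]), radii = radii,
                      label = labels[i])
  }
  objs
}

ellipse_mask <- function(lines, pixels, center, radii, angle = 0) {
  l <- matrix(seq_len(lines), lines, pixels) - center[1]
  p <- matrix(seq_len(pixels), lines, pixels, byrow = TRUE) - center[2]
  if (angle != 0) {
    ca <- cos(angle); sa <- sin(angle)
    l2 <- ca * l + sa * p; p2 <- -sa * l + ca * p
    l <- l2; p <- p2
  }
  (l / radii[1])^2 + (p / radii[2])^2 <= 1
}

object_mask <- function(obj, lines, pixels) {
  if (identical(obj$shape, "blob")) {
    ## union of three overlapping ellipses — a compact flower-like blob
    m <- ellipse_mask(lines, pixels, obj$center, obj$radii * 0.8)
    off <- rbind(c(-0.45, 0.35), c(0.4, -0.3))
    for (i in 1:2)
      m <- m | ellipse_mask(lines, pixels,
                            obj$center + off[i, ] * obj$radii,
                            obj$radii * 0.65)
    m
  } else {
    ellipse_mask(lines, pixels, obj$center, obj$radii,
                 angle = if (is.null(obj$angle)) 0 else obj$angle)
  }
}

illumination_field <- function(design) {
  P <- design$pixels; L <- design$lines
  xp <- 2 * (seq_len(P) - 1) / max(P - 1, 1) - 1
  col_prof <- 1 + design$illumination$amplitude * (0.5 - xp^2) * 2
  fld <- matrix(col_prof, L, P, byrow = TRUE)
  la <- design$illumination$line_amplitude
  if (la > 0) {
    xl <- 2 * (seq_len(L) - 1) / max(L - 1, 1) - 1
    fld <- fld * (1 + la * (0.5 - xl^2) * 2)
  }
  fld
}

#' Render a synthetic hyperspectral scene
#'
#' Renders a cube as `illumination(line, pixel) * reflectance(band) *
#' (1 + multiplicative noise) + additive noise`, clipped at 0. Each
#' object draws its own sample-level spectrum from its class model;
#' reference pixels carry the flat nominal reflectance before
#' illumination.
#'
#' @param design A [scene_design()].
#' @param classes Named list of [spectral_class_model()]s covering every
#'   object label in the design.
#' @param seed Seed; defaults to the design's.
#' @return List: `cube` (a [hyper_cube()]), `labels` (integer ground
#'   truth, 0 = background, objects numbered in layout order),
#'   `reference_mask` (logical matrix), `objects` (metadata frame with
#'   id, shape, class label fields and rendered pixel area).
#' @export
render_scene <- function(design, classes, seed = design$seed) {
  stopifnot(inherits(design, "scene_design"))
  set.seed(seed)
  L <- design$lines; P <- design$pixels
  wl <- design$wavelengths; B <- length(wl)
  labels <- matrix(0L, L, P)
  occupied <- matrix(FALSE, L, P)
  ref_mask <- matrix(FALSE, L, P)
  if (!is.null(design$reference)) {
    r <- design$reference
    ref_mask[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2]] <- TRUE
    occupied <- occupied | ref_mask
  }
  refl <- array(design$background, dim = c(L, P, B))
  if (!is.null(design$reference)) {
    idx <- which(ref_mask)
    for (b in seq_len(B))
      refl[idx + (b - 1L) * L * P] <- design$reference$reflectance
  }
  meta <- NULL
  for (i in seq_along(design$objects)) {
    obj <- design$objects[[i]]
    m <- object_mask(obj, L, P)
    if (any(m & occupied))
      stop("scene design error: object ", i,
           " overlaps another object or the reference", call. = FALSE)
    occupied <- occupied | m
    labels[m] <- i
    key <- if (is.list(obj$label))
      paste(obj$label$cultivar, obj$label$stage, obj$label$organ,
            sep = "|") else as.character(obj$label)
    model <- classes[[key]]
    if (is.null(model))
      stop("no class model for object label '", key, "'", call. = FALSE)
    spec <- vegetation_spectrum(model, wl)
    idx <- which(m)
    for (b in seq_len(B)) refl[idx + (b - 1L) * L * P] <- spec[b]
    lab <- if (is.list(obj$label)) obj$label else {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      list(cultivar = parts[1], stage = parts[2], organ = parts[3])
    }
    meta <- rbind(meta, data.frame(
      id = i, shape = obj$shape, cultivar = lab$cultivar,
      stage = lab$stage, organ = lab$organ, area_px = sum(m),
      stringsAsFactors = FALSE))
  }
  illum <- illumination_field(design)
  cube_vals <- refl * as.vector(illum)  # recycles over bands
  if (design$noise$multiplicative_sd > 0)
    cube_vals <- cube_vals *
      (1 + array(stats::rnorm(L * P * B, 0,
                              design$noise$multiplicative_sd),
                 dim = c(L, P, B)))
  if (design$noise$additive_sd > 0)
    cube_vals <- cube_vals +
      array(stats::rnorm(L * P * B, 0, design$noise$additive_sd),
            dim = c(L, P, B))
  cube_vals <- pmax(cube_vals, 0)
  list(cube = hyper_cube(cube_vals, wl,
                         scan_id = sprintf("scene_seed%d", seed)),
       labels = labels, reference_mask = ref_mask, objects = meta,
       illumination = illum)
}
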