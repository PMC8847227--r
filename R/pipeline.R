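## End-to-end orchestration: simulate -> segment -> extract -> explore
## -> train, as one reproducible run driven by a config list (or YAML
## file). A single config seed fans out to fixed per-stage offsets so
## stages are independently re-runnable yet jointly deterministic. The
## package's function layer is the interface; run_pipeline() is the
## entry point a shell wrapper would call.

#' Default pipeline configuration
#'
#' A compact end-to-end run: two cultivars at one growth stage, both
#' organs, six samples per scene, cultivar classification without
#' per-replicate tuning. Every field can be overridden via `modify`.
#'
#' @param out_dir Output directory.
#' @param modify Named list of overrides merged over the defaults
#'   (two levels deep).
#' @return Config list for [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = tempfile("hempspec_run_"),
                                    modify = list()) {
  cfg <- list(
    out_dir = out_dir,
    seed = 17L,
    separation = 1,
    design = list(cultivars = c("CW", "BX"), stages = 1L,
                  organs = c("leaf", "flower"), objects_per_cell = 6L),
    scene = list(lines = 150L, pixels = 200L, n_bands = 40L,
                 noise = list(additive_sd = 0.002,
                              multiplicative_sd = 0.02),
                 illumination = list(amplitude = 0.15,
                                     line_amplitude = 0)),
    segmentation = list(stride = 2L, min_area = 50L, morph_radius = 1L,
                        bins = 256L),
    classification = list(label_col = "cultivar", reps = 5L,
                          ratio = 0.75, tune = FALSE, gamma = 0.005,
                          delta = 1, budget = 15L, k = 5L,
                          subset = list()),
    explore = list(grouping = c("cultivar", "organ"),
                   n_components = 2L))
  for (k in names(modify)) {
    if (is.list(modify[[k]]) && is.list(cfg[[k]]))
      for (k2 in names(modify[[k]])) cfg[[k]][[k2]] <- modify[[k]][[k2]]
    else cfg[[k]] <- modify[[k]]
  }
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$out_dir)) stop("config needs out_dir", call. = FALSE)
  lc <- cfg$classification$label_col
  if (!lc %in% c("cultivar", "stage", "organ"))
    stop("unknown label column '", lc,
         "'; must be cultivar, stage or organ", call. = FALSE)
  for (f in cfg$files)
    if (!file.exists(f))
      stop("referenced file does not exist: ", f, call. = FALSE)
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Executes simulate, segment, extract, explore and train in order,
#' writing per-stage outputs under the configured directory and a run
#' manifest (inputs, seeds, per-stage outputs, wall time) as JSON.
#' Re-running with an identical config reproduces identical numeric
#' outputs. A stage failure aborts with a stage-named error.
#'
#' @param config Config list (see [default_pipeline_config()]) or path
#'   to a YAML file with the same structure.
#' @return The manifest list, invisibly; the heavyweight in-memory
#'   results are attached as `attr(, "results")`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  t0 <- Sys.time()
  stage <- function(name, fn) {
    ts <- Sys.time()
    out <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      outputs = out$outputs,
      seconds = as.numeric(difftime(Sys.time(), ts, units = "secs")))
    out$value
  }

  ## -- simulate ------------------------------------------------------
  sim <- stage("simulate", function() {
    d <- config$design
    classes <- hemp_class_models(d$cultivars, d$stages, d$organs,
                                 separation = config$separation)
    cells <- expand.grid(cultivar = d$cultivars, stage = d$stages,
                         organ = d$organs, stringsAsFactors = FALSE)
    scene_dir <- file.path(config$out_dir, "scenes")
    dir.create(scene_dir, showWarnings = FALSE)
    scenes <- vector("list", nrow(cells))
    outs <- character(0)
    for (i in seq_len(nrow(cells))) {
      key <- paste(cells$cultivar[i], cells$stage[i], cells$organ[i],
                   sep = "|")
      wl <- seq(400, 1000, length.out = config$scene$n_bands)
      des <- scene_design(
        lines = config$scene$lines, pixels = config$scene$pixels,
        objects = scene_objects_grid(
          rep(key, d$objects_per_cell),
          lines = config$scene$lines, pixels = config$scene$pixels),
        noise = config$scene$noise,
        illumination = config$scene$illumination,
        wavelengths = wl, seed = config$seed + 100L + i)
      sc <- render_scene(des, classes)
      sc$cube$scan_id <- sprintf("scan%02d_%s_s%s_%s", i,
                                 cells$cultivar[i], cells$stage[i],
                                 cells$organ[i])
      base <- file.path(scene_dir, sc$cube$scan_id)
      write_cube(sc$cube, base)
      write_label_image(sc$labels, paste0(base, "_labels.tif"))
      outs <- c(outs, paste0(base, ".hdr"))
      sc$design <- des
      sc$cell <- cells[i, ]
      scenes[[i]] <- sc
    }
    list(value = scenes, outputs = outs)
  })

  ## -- segment -------------------------------------------------------
  seg <- stage("segment", function() {
    sg <- config$segmentation
    pair <- select_band_pair(sim[[1]]$cube, stride = sg$stride)$pair
    results <- lapply(sim, function(sc)
      segment_scene(sc$cube, pair, bins = sg$bins,
                    min_area = sg$min_area,
                    morph_radius = sg$morph_radius))
    rep_file <- file.path(config$out_dir, "segmentation.json")
    jsonlite::write_json(list(
      pair = list(lambda1 = pair$lambda1, lambda2 = pair$lambda2),
      thresholds = vapply(results, `[[`, numeric(1), "threshold"),
      regions = vapply(results, function(r) nrow(r$region_table),
                       integer(1))), rep_file, auto_unbox = TRUE,
      digits = NA)
    list(value = list(pair = pair, results = results),
         outputs = rep_file)
  })

  ## -- extract -------------------------------------------------------
  tab <- stage("extract", function() {
    extractions <- lapply(seq_along(sim), function(i) {
      sc <- sim[[i]]; res <- seg$results[[i]]
      ref <- sc$design$reference
      spectra <- extract_spectra(
        sc$cube, res$regions,
        locate_reference(sc$cube, res, mode = "roi",
                         roi = list(rows = ref$rows,
                                    cols = ref$cols))$mask)
      ## map each segmented region to the ground-truth object it covers
      meta <- do.call(rbind, lapply(seq_len(max(res$regions)),
                                    function(j) {
        truth <- sc$labels[res$regions == j]
        truth <- truth[truth > 0]
        if (!length(truth))
          stop("region ", j, " of scan ", sc$cube$scan_id,
               " maps to no ground-truth object", call. = FALSE)
        obj <- as.integer(names(which.max(table(truth))))
        data.frame(sample_id = sprintf("%s_obj%02d", sc$cube$scan_id,
                                       obj),
                   cultivar = sc$objects$cultivar[obj],
                   stage = sc$objects$stage[obj],
                   organ = sc$objects$organ[obj],
                   replicate = obj, stringsAsFactors = FALSE)
      }))
      list(spectra = spectra, meta = meta)
    })
    tab <- assemble_spectra_table(extractions)
    f <- file.path(config$out_dir, "spectra.csv")
    write_spectra_table(tab, f)
    list(value = tab, outputs = f)
  })

  ## -- explore -------------------------------------------------------
  stage("explore", function() {
    pc <- pca_explore(tab, n_components = config$explore$n_components)
    gm <- group_mean_spectra(tab, config$explore$grouping)
    f1 <- file.path(config$out_dir, "pca_scores.csv")
    f2 <- file.path(config$out_dir, "group_mean_spectra.csv")
    utils::write.csv(data.frame(sample_id = rownames(pc$scores),
                                pc$scores,
                                check.names = FALSE), f1,
                     row.names = FALSE)
    utils::write.csv(data.frame(group = rownames(gm$mean), gm$mean,
                                check.names = FALSE), f2,
                     row.names = FALSE)
    list(value = pc, outputs = c(f1, f2))
  })

  ## -- train ---------------------------------------------------------
  report <- stage("train", function() {
    cl <- config$classification
    keep <- rep(TRUE, nrow(tab))
    meta <- spectra_meta(tab)
    for (f in names(cl$subset))
      keep <- keep & meta[[f]] %in% cl$subset[[f]]
    sub <- filter_spectra(tab, keep)
    y <- spectra_meta(sub)[[cl$label_col]]
    rep_ <- repeated_holdout(spectra_matrix(sub), y, reps = cl$reps,
                             ratio = cl$ratio,
                             base_seed = config$seed + 500L,
                             tune = cl$tune, gamma = cl$gamma,
                             delta = cl$delta, budget = cl$budget,
                             k = cl$k)
    conf <- pooled_confusion(rep_)
    f1 <- file.path(config$out_dir, "report.json")
    f2 <- file.path(config$out_dir, "confusion.csv")
    jsonlite::write_json(list(
      label = cl$label_col, accuracy = rep_$accuracy,
      mean_accuracy = rep_$mean_accuracy,
      se_accuracy = rep_$se_accuracy,
      params = rep_$params), f1, auto_unbox = TRUE, digits = NA)
    utils::write.csv(conf$proportions, f2)
    list(value = rep_, outputs = c(f1, f2))
  })

  manifest$wall_seconds <- as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  attr(manifest, "results") <- list(scenes = sim, segmentation = seg,
                                    table = tab, report = report)
  invisible(manifest)
}

#' Enumerate the classification scenario matrix
#'
#' Builds the list of classification runs implied by the factorial
#' design: cultivar classification per stage for leaf, flower and both;
#' cultivar classification pooled over stages (leaf, flower, both);
#' stage classification per cultivar x organ; organ classification per
#' cultivar x stage. Scenarios whose filtered table has fewer than two
#' label classes are dropped with a warning.
#'
#' @param table A [spectra_table()] (used for the available factor
#'   levels and for filtering feasibility).
#' @return List of scenario descriptors: `name`, `label_col`, `subset`
#'   (named list of metadata filters).
#' @export
scenario_matrix <- function(table) {
  meta <- spectra_meta(table)
  cultivars <- sort(unique(meta$cultivar))
  stages <- sort(unique(meta$stage))
  organs <- sort(unique(meta$organ))
  runs <- list()
  add <- function(name, label_col, subset) {
    keep <- rep(TRUE, nrow(meta))
    for (f in names(subset)) keep <- keep & meta[[f]] %in% subset[[f]]
    if (length(unique(meta[[label_col]][keep])) < 2L) {
      warning("scenario '", name,
              "' has < 2 classes after filtering; skipped",
              call. = FALSE)
      return(invisible(NULL))
    }
    runs[[length(runs) + 1L]] <<- list(name = name,
                                       label_col = label_col,
                                       subset = subset)
  }
  for (st in stages) {
    for (org in organs)
      add(sprintf("cultivar_stage%s_%s", st, org), "cultivar",
          list(stage = st, organ = org))
    add(sprintf("cultivar_stage%s_both", st), "cultivar",
        list(stage = st))
  }
  for (org in organs)
    add(sprintf("cultivar_pooled_%s", org), "cultivar",
        list(organ = org))
  add("cultivar_pooled_both", "cultivar", list())
  for (cv in cultivars) for (org in organs)
    add(sprintf("stage_%s_%s", cv, org), "stage",
        list(cultivar = cv, organ = org))
  for (cv in cultivars) for (st in stages)
    add(sprintf("organ_%s_stage%s", cv, st), "organ",
        list(cultivar = cv, stage = st))
  runs
}
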