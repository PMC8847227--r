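## Mean-spectrum extraction per segmented region and standardization
## against the in-scan grey reference panel. Two reference-ratio forms
## are provided: the mean-spectrum ratio (sample mean divided by the
## panel mean, the quantity plotted as relative reflectance in a.u.) and
## a column-wise flat-field (each pixel column divided by the panel rows
## of the same column) which additionally cancels illumination
## unevenness along the scan line when the panel spans the full width.

#' Mean spectrum of a region
#'
#' @param cube A [hyper_cube()].
#' @param mask Logical matrix (line x pixel) selecting the region, or an
#'   integer matrix together with `id`.
#' @param id Region id when `mask` is a labeled matrix.
#' @return An object of class `region_spectrum`: list with `mean`
#'   (per-band arithmetic mean over region pixels), `n_pixels`,
#'   `wavelengths` and `scan_id`.
#' @export
mean_spectrum <- function(cube, mask, id = NULL) {
  if (!is.null(id)) mask <- mask == id
  mask <- mask & TRUE
  n <- sum(mask)
  if (n < 1L) stop("empty region", call. = FALSE)
  d <- dim(cube)
  idx <- which(mask)
  m <- vapply(seq_len(d[3]),
              function(b) mean(cube$values[idx + (b - 1L) * d[1] * d[2]]),
              numeric(1))
  structure(list(mean = m, n_pixels = n,
                 wavelengths = cube$wavelengths, scan_id = cube$scan_id),
            class = "region_spectrum")
}

#' Ratio spectra against a reference spectrum
#'
#' Divides each sample mean spectrum element-wise by the reference mean
#' spectrum of the same scan, yielding relative reflectance in arbitrary
#' units (the panel's nominal 20% is deliberately not multiplied back
#' in).
#'
#' @param samples A `region_spectrum` or list of them.
#' @param reference A `region_spectrum`, strictly positive at every band.
#' @return List of ratio spectra (`region_spectrum` objects flagged
#'   `relative = TRUE`), or a single one if `samples` was one.
#' @export
ratio_to_reference <- function(samples, reference) {
  single <- inherits(samples, "region_spectrum")
  if (single) samples <- list(samples)
  bad <- which(reference$mean <= 0)
  if (length(bad))
    stop("reference spectrum non-positive at wavelength(s) ",
         paste(format(reference$wavelengths[bad]), collapse = ", "),
         " nm", call. = FALSE)
  out <- lapply(samples, function(s) {
    if (length(s$mean) != length(reference$mean))
      stop("sample and reference are on different wavelength grids",
           call. = FALSE)
    s$mean <- s$mean / reference$mean
    s$relative <- TRUE
    s
  })
  if (single) out[[1]] else out
}

#' Extract reference-ratioed spectra from a segmented scan
#'
#' For every labeled region, computes the mean relative-reflectance
#' spectrum against the in-scan reference panel. The panel region is
#' eroded by `erode_px` to drop its bright edge pixels. With `columnwise
#' = TRUE` (default) each pixel column of the cube is divided by the
#' panel's mean spectrum of the same column before averaging, which
#' cancels multiplicative illumination unevenness along the scan line
#' exactly; columns the panel does not cover fall back to the panel's
#' global mean spectrum.
#'
#' @param cube A [hyper_cube()].
#' @param regions Labeled region matrix (e.g. from [segment_scene()]).
#' @param reference_mask Logical matrix of panel pixels.
#' @param columnwise Use column-matched flat-fielding.
#' @param erode_px Erosion radius applied to the panel mask.
#' @return List of `region_spectrum` objects (relative reflectance), one
#'   per region id.
#' @export
extract_spectra <- function(cube, regions, reference_mask,
                            columnwise = TRUE, erode_px = 2L) {
  d <- dim(cube)
  ref <- reference_mask
  if (erode_px > 0L) {
    kern <- EBImage::makeBrush(2L * erode_px + 1L, shape = "disc")
    er <- EBImage::erode(reference_mask * 1, kern) > 0.5
    if (any(er)) ref <- er
  }
  nreg <- max(regions)
  if (nreg < 1L) stop("no regions to extract", call. = FALSE)
  if (!any(ref)) stop("empty reference mask", call. = FALSE)
  if (columnwise) {
    ## panel mean spectrum per pixel column: cols x bands
    cols_cov <- which(colSums(ref) > 0)
    refspec <- matrix(NA_real_, d[2], d[3])
    for (b in seq_len(d[3])) {
      plane <- cube$values[, , b]
      plane[!ref] <- NA
      refspec[cols_cov, b] <- colMeans(plane[, cols_cov, drop = FALSE],
                                       na.rm = TRUE)
    }
    global <- colMeans(refspec[cols_cov, , drop = FALSE])
    if (length(cols_cov) < d[2])
      refspec[-cols_cov, ] <- matrix(global, d[2] - length(cols_cov),
                                     d[3], byrow = TRUE)
    if (any(refspec <= 0))
      stop("reference spectrum non-positive in at least one column",
           call. = FALSE)
    lapply(seq_len(nreg), function(i) {
      w <- which(regions == i, arr.ind = TRUE)
      if (nrow(w) == 0L) stop("empty region ", i, call. = FALSE)
      px <- cube$values[cbind(rep(w[, 1], d[3]), rep(w[, 2], d[3]),
                              rep(seq_len(d[3]), each = nrow(w)))]
      px <- matrix(px, nrow(w), d[3])
      ratio <- px / refspec[w[, 2], , drop = FALSE]
      structure(list(mean = colMeans(ratio), n_pixels = nrow(w),
                     wavelengths = cube$wavelengths,
                     scan_id = cube$scan_id, relative = TRUE,
                     region_id = i),
                class = "region_spectrum")
    })
  } else {
    refs <- mean_spectrum(cube, ref)
    sams <- lapply(seq_len(nreg), function(i)
      mean_spectrum(cube, regions, id = i))
    out <- ratio_to_reference(sams, refs)
    for (i in seq_along(out)) out[[i]]$region_id <- i
    out
  }
}

#' Assemble a spectra table from scan extractions
#'
#' Combines per-scan region spectra with per-region sample metadata into
#' one table. Every region must be mapped; all scans must share one
#' wavelength grid; duplicate sample ids are rejected.
#'
#' @param extractions List of per-scan entries, each a list with
#'   `spectra` (list of `region_spectrum`, as from [extract_spectra()])
#'   and `meta` (data frame with one row per region in region-id order:
#'   `sample_id`, `cultivar`, `stage`, `organ`, `replicate`; `scan_id`
#'   defaults to the spectra's).
#' @return A [spectra_table()].
#' @export
assemble_spectra_table <- function(extractions) {
  rows <- list(); metas <- list(); wl <- NULL
  for (e in extractions) {
    if (length(e$spectra) != nrow(e$meta))
      stop("mapping error: ", length(e$spectra), " regions but ",
           nrow(e$meta), " metadata rows for scan ",
           e$spectra[[1]]$scan_id, call. = FALSE)
    for (i in seq_along(e$spectra)) {
      s <- e$spectra[[i]]
      if (is.null(wl)) wl <- s$wavelengths
      else if (length(wl) != length(s$wavelengths) ||
               any(wl != s$wavelengths))
        stop("wavelength grid mismatch across scans", call. = FALSE)
      rows[[length(rows) + 1L]] <- s$mean
      m <- e$meta[i, , drop = FALSE]
      if (is.null(m$scan_id)) m$scan_id <- s$scan_id
      metas[[length(metas) + 1L]] <- m
    }
  }
  meta <- do.call(rbind, metas)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id across scans: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "), call. = FALSE)
  spectra_table(meta, do.call(rbind, rows), wl)
}
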