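#' Hyperspectral datacube
#'
#' Container for a line-scan hyperspectral reflectance datacube. Values are
#' held in a 3-D array with canonical axis order (line, pixel, band),
#' whatever the on-disk interleave was, together with the wavelength (nm)
#' of every band.
#'
#' @param values Numeric 3-D array, dimensions (line, pixel, band). All
#'   values must be finite and non-negative.
#' @param wavelengths Numeric vector of band-center wavelengths in nm,
#'   strictly increasing, one per band.
#' @param scan_id Opaque scan identifier (character scalar).
#' @param pixel_area_mm2 Optional ground area covered by one pixel, in mm^2
#'   (the benchtop system this emulates resolves about 0.5 mm^2/pixel).
#'
#' @return An object of class `hyper_cube` with fields `values`,
#'   `wavelengths`, `scan_id`, `pixel_area_mm2`.
#' @export
hyper_cube <- function(values, wavelengths, scan_id = "scan",
                       pixel_area_mm2 = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array (line, pixel, band)", call. = FALSE)
  storage.mode(values) <- "double"
  wavelengths <- as.numeric(wavelengths)
  cube <- structure(
    list(values = values, wavelengths = wavelengths,
         scan_id = as.character(scan_id)[1L],
         pixel_area_mm2 = pixel_area_mm2),
    class = "hyper_cube")
  validate_cube(cube)
  cube
}

#' Validate a hyperspectral cube
#'
#' Checks the `hyper_cube` invariants: the wavelength vector has one entry
#' per band and is strictly increasing, and the cube holds no NaN/Inf or
#' negative values.
#'
#' @param cube A `hyper_cube`.
#' @return The cube, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_cube <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  if (length(cube$wavelengths) != d[3L])
    stop(sprintf("wavelength count (%d) != band count (%d)",
                 length(cube$wavelengths), d[3L]), call. = FALSE)
  if (any(!is.finite(cube$wavelengths)) ||
      any(diff(cube$wavelengths) <= 0))
    stop("wavelengths must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(cube$values)))
    stop("cube contains non-finite values", call. = FALSE)
  if (any(cube$values < 0))
    stop("cube contains negative reflectance values", call. = FALSE)
  invisible(cube)
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "hyper_cube '%s': %d lines x %d pixels x %d bands (%.1f-%.1f nm)\n",
    x$scan_id, d[1L], d[2L], d[3L],
    min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

#' Index of the band nearest a wavelength
#'
#' @param cube A `hyper_cube`.
#' @param wavelength Target wavelength in nm.
#' @param exact If `TRUE`, the wavelength must match a band center to
#'   within `tol` nm, otherwise an error is thrown.
#' @param tol Matching tolerance in nm used when `exact = TRUE`.
#' @return Integer band index.
#' @export
band_index <- function(cube, wavelength, exact = FALSE, tol = 1e-6) {
  i <- which.min(abs(cube$wavelengths - wavelength))
  if (exact && abs(cube$wavelengths[i] - wavelength) > tol)
    stop(sprintf("wavelength %g nm not present in cube", wavelength),
         call. = FALSE)
  i
}

#' Single-band image
#'
#' @param cube A `hyper_cube`.
#' @param band Band index or, if `wavelength = TRUE`, a wavelength in nm
#'   resolved to the nearest band.
#' @param wavelength Interpret `band` as nm rather than an index.
#' @return Matrix (line x pixel) of reflectance at that band.
#' @export
band_image <- function(cube, band, wavelength = FALSE) {
  if (wavelength) band <- band_index(cube, band)
  m <- cube$values[, , band, drop = FALSE]
  dim(m) <- dim(cube$values)[1:2]
  m
}
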