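## Spectra tables: one row per sample region, a fixed metadata prefix
## (sample_id, scan_id, cultivar, stage, organ, replicate) and one column
## per wavelength. On disk these are plain CSV with the nm values as
## wavelength column headers.

.meta_cols <- c("sample_id", "scan_id", "cultivar", "stage", "organ",
                "replicate")

#' Spectra table
#'
#' Builds a samples-by-wavelengths table of (relative) reflectance spectra
#' together with sample metadata.
#'
#' @param meta Data frame with columns `sample_id`, `scan_id`, `cultivar`,
#'   `stage`, `organ`, `replicate` (missing ones are filled with `NA`).
#' @param values Numeric matrix, rows matching `meta`, one column per
#'   wavelength; all values finite and positive.
#' @param wavelengths Wavelengths in nm, strictly increasing, one per
#'   column of `values`.
#' @return An object of class `spectra_table`: a data frame of metadata
#'   plus wavelength columns, with the numeric wavelength grid in
#'   `attr(, "wavelengths")`.
#' @export
spectra_table <- function(meta, values, wavelengths) {
  values <- as.matrix(values)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(values) != length(wavelengths))
    stop("value columns != wavelength count", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (nrow(values) != nrow(meta))
    stop("metadata rows != spectra rows", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("spectra must be finite and > 0", call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  for (m in .meta_cols) if (is.null(meta[[m]])) meta[[m]] <- NA
  meta <- meta[.meta_cols]
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in spectra table", call. = FALSE)
  colnames(values) <- format(wavelengths, trim = TRUE, digits = 10)
  out <- cbind(meta, as.data.frame(values, check.names = FALSE))
  attr(out, "wavelengths") <- wavelengths
  class(out) <- c("spectra_table", "data.frame")
  out
}

#' Spectral matrix of a spectra table
#'
#' @param table A `spectra_table`.
#' @return Numeric matrix (samples x wavelengths), row names = sample ids.
#' @export
spectra_matrix <- function(table) {
  m <- as.matrix(table[, setdiff(names(table), .meta_cols), drop = FALSE])
  rownames(m) <- table$sample_id
  m
}

#' Metadata of a spectra table
#'
#' @param table A `spectra_table`.
#' @return Data frame with the metadata prefix columns.
#' @export
spectra_meta <- function(table) {
  out <- as.data.frame(table)[, .meta_cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wavelength grid of a spectra table
#'
#' @param table A `spectra_table`.
#' @return Numeric vector of wavelengths in nm.
#' @export
table_wavelengths <- function(table) attr(table, "wavelengths")

#' Write a spectra table to CSV
#'
#' @param table A `spectra_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spectra_table <- function(table, path) {
  stopifnot(inherits(table, "spectra_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a spectra table from CSV
#'
#' Metadata columns are matched by name (any column order is accepted);
#' every remaining column whose header parses as a number is taken as a
#' wavelength column, sorted ascending.
#'
#' @param path CSV path.
#' @return A `spectra_table`.
#' @export
read_spectra_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  wl_cols <- names(df)[suppressWarnings(!is.na(as.numeric(names(df))))]
  if (length(wl_cols) == 0L)
    stop("no wavelength columns found in ", path, call. = FALSE)
  wl <- as.numeric(wl_cols)
  o <- order(wl)
  meta <- df[, intersect(names(df), .meta_cols), drop = FALSE]
  spectra_table(meta, as.matrix(df[, wl_cols[o], drop = FALSE]), wl[o])
}

#' Row-subset of a spectra table
#'
#' Filters rows by metadata values while preserving the class and the
#' wavelength attribute.
#'
#' @param table A `spectra_table`.
#' @param keep Logical vector of rows to keep.
#' @return A `spectra_table`.
#' @export
filter_spectra <- function(table, keep) {
  spectra_table(spectra_meta(table)[keep, , drop = FALSE],
                spectra_matrix(table)[keep, , drop = FALSE],
                table_wavelengths(table))
}
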