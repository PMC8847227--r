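## Exploratory views of a spectra table: PCA score summaries and group
## mean spectra (the standard first look before any supervised model).

#' PCA of a spectra table
#'
#' Principal components of the spectral matrix, mean-centered per
#' wavelength (spectra share units, so no scaling by default; a scaling
#' flag is available). The sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param table A [spectra_table()] or numeric matrix.
#' @param n_components Components to keep (default all).
#' @param scale. Also scale columns to unit variance.
#' @return Object of class `pca_result`: `scores` (samples x
#'   components), `loadings`, `variance_fraction` (non-increasing,
#'   summing to 1 over all components), `variance_percent`.
#' @export
pca_explore <- function(table, n_components = NULL, scale. = FALSE) {
  X <- if (inherits(table, "spectra_table")) spectra_matrix(table)
       else as.matrix(table)
  if (nrow(X) < 2L) stop("need >= 2 rows for PCA", call. = FALSE)
  max_comp <- min(nrow(X) - 1L, ncol(X))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp)
    stop("n_components exceeds min(rows - 1, columns) = ", max_comp,
         call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  frac_all <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(n_components)
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  for (j in keep) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(scores = scores, loadings = loadings,
         variance_fraction = frac_all[keep],
         variance_percent = 100 * frac_all[keep],
         all_variance_fraction = frac_all),
    class = "pca_result")
}

#' Group mean spectra
#'
#' Wavelength-wise mean and standard deviation per group of samples,
#' grouped by one or more metadata fields; group order is the sorted
#' label order.
#'
#' @param table A [spectra_table()].
#' @param grouping Character vector of metadata field names (subset of
#'   sample_id/scan_id/cultivar/stage/organ/replicate).
#' @return List with `mean` and `sd` (groups x wavelengths matrices,
#'   rownames = group labels joined by "|"), `n` (group sizes) and
#'   `wavelengths`.
#' @export
group_mean_spectra <- function(table, grouping) {
  meta <- spectra_meta(table)
  missing_f <- setdiff(grouping, names(meta))
  if (length(missing_f))
    stop("unknown grouping field(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  X <- spectra_matrix(table)
  key <- do.call(paste, c(meta[grouping], sep = "|"))
  labs <- sort(unique(key))
  mu <- t(vapply(labs, function(l)
    colMeans(X[key == l, , drop = FALSE]), numeric(ncol(X))))
  sdv <- t(vapply(labs, function(l) {
    rows <- X[key == l, , drop = FALSE]
    if (nrow(rows) < 2L) rep(NA_real_, ncol(X))
    else apply(rows, 2, stats::sd)
  }, numeric(ncol(X))))
  rownames(mu) <- rownames(sdv) <- labs
  list(mean = mu, sd = sdv,
       n = as.integer(table(factor(key, labs))),
       wavelengths = table_wavelengths(table))
}

#' Plot group mean spectra
#'
#' Simple base-graphics overlay of the group mean curves.
#'
#' @param gms A [group_mean_spectra()] result.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_group_mean_spectra <- function(gms, ...) {
  graphics::matplot(gms$wavelengths, t(gms$mean), type = "l", lty = 1,
                    xlab = "wavelength (nm)",
                    ylab = "relative reflectance (a.u.)", ...)
  graphics::legend("topleft", legend = rownames(gms$mean),
                   col = seq_len(nrow(gms$mean)), lty = 1, cex = 0.7)
}
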