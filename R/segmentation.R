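## Segmentation of plant material from a scan: a contrast-optimized
## normalized band difference (NBD) image, global thresholding at the
## intermodes point of its histogram, morphological refinement, and
## 8-connected region labeling. The band pair is chosen once, on a
## calibration cube, by exhaustively scoring every ordered pair with the
## Otsu between/total variance ratio, and reused batch-wide.

#' Band pair for a normalized band difference image
#'
#' @param cube A [hyper_cube()].
#' @param lambda1 Higher wavelength (nm), e.g. near-infrared.
#' @param lambda2 Lower wavelength (nm), e.g. blue.
#' @return An object of class `band_pair` with wavelengths and band
#'   indices resolved against the cube grid.
#' @export
band_pair <- function(cube, lambda1, lambda2) {
  if (lambda1 <= lambda2)
    stop("band pair requires lambda1 > lambda2", call. = FALSE)
  i1 <- band_index(cube, lambda1)
  i2 <- band_index(cube, lambda2)
  structure(list(lambda1 = cube$wavelengths[i1],
                 lambda2 = cube$wavelengths[i2],
                 band1 = i1, band2 = i2),
            class = "band_pair")
}

#' Normalized band difference image
#'
#' Computes `(R_lambda1 - R_lambda2) / (R_lambda1 + R_lambda2)` per
#' pixel. Pixels whose denominator does not exceed `eps` are flagged
#' undefined (`NA`) rather than propagating division artifacts; all
#' defined values lie in `[-1, 1]` for a non-negative cube.
#'
#' @param cube A [hyper_cube()].
#' @param pair A [band_pair()] (or `c(lambda1, lambda2)`).
#' @param eps Denominator guard; default `1e-6` of the cube's dynamic
#'   range.
#' @return An object of class `nbd_image`: list with `values` (matrix,
#'   `NA` = undefined) and `pair`.
#' @export
compute_nbd <- function(cube, pair, eps = NULL) {
  if (is.numeric(pair)) pair <- band_pair(cube, pair[1], pair[2])
  r1 <- band_image(cube, pair$band1)
  r2 <- band_image(cube, pair$band2)
  if (is.null(eps)) eps <- 1e-6 * max(cube$values)
  den <- r1 + r2
  v <- (r1 - r2) / den
  v[den <= eps] <- NA_real_
  structure(list(values = v, pair = pair), class = "nbd_image")
}

#' Otsu contrast of an image or value vector
#'
#' Scores how well a single threshold separates the values into two
#' classes: the maximal ratio of between-class variance to total variance
#' over a 256-candidate threshold grid spanning the value range. The
#' score lies in `[0, 1]` and is invariant under affine rescaling.
#'
#' @param image Numeric matrix/vector (`NA`s ignored).
#' @param n_candidates Number of candidate thresholds.
#' @return List with `threshold` (argmax candidate, lowest on ties) and
#'   `score`.
#' @export
otsu_contrast <- function(image, n_candidates = 256L) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L)
    stop("otsu contrast undefined for a constant image", call. = FALSE)
  tot <- stats::var(v) * (length(v) - 1) / length(v)  # population
  cand <- seq(min(v), max(v), length.out = n_candidates)
  v <- sort(v)
  n <- length(v)
  cs <- cumsum(v)
  ## count of values <= each candidate
  k <- findInterval(cand, v)
  w0 <- k / n
  m0 <- ifelse(k > 0, cs[pmax(k, 1)] / pmax(k, 1), 0)
  m1 <- ifelse(k < n, (cs[n] - ifelse(k > 0, cs[pmax(k, 1)], 0)) /
                 (n - k), 0)
  bc <- w0 * (1 - w0) * (m0 - m1)^2
  bc[k == 0 | k == n] <- 0  # one-sided splits carry no contrast
  i <- which.max(bc)  # which.max returns the first (lowest) on ties
  list(threshold = cand[i], score = min(bc[i] / tot, 1))
}

#' Select the contrast-optimal band pair
#'
#' Evaluates the Otsu contrast of the NBD image for every ordered band
#' pair (higher wavelength first) on a strided band grid and returns the
#' argmax. Ties are broken toward the larger `lambda1`, then the smaller
#' `lambda2`. The selected pair is intended to be chosen on one
#' calibration cube and reused for every scan of the batch.
#'
#' @param cube A [hyper_cube()] with at least 2 bands (after striding).
#' @param stride Band subsampling step (>= 1).
#' @param eps Passed to [compute_nbd()].
#' @return List with `pair` ([band_pair()]), `score` (list threshold /
#'   score of the winning pair), and `scores` (matrix of contrast scores,
#'   rows = lambda1 index, cols = lambda2 index on the strided grid).
#' @export
select_band_pair <- function(cube, stride = 1L, eps = NULL) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  bands <- seq(1L, dim(cube)[3L], by = stride)
  if (length(bands) < 2L)
    stop("need at least 2 bands after striding", call. = FALSE)
  nb <- length(bands)
  scores <- matrix(NA_real_, nb, nb,
                   dimnames = list(cube$wavelengths[bands],
                                   cube$wavelengths[bands]))
  best <- list(score = -Inf, i = NA, j = NA, threshold = NA)
  for (hi in 2:nb) for (lo in 1:(hi - 1)) {
    pair <- structure(list(lambda1 = cube$wavelengths[bands[hi]],
                           lambda2 = cube$wavelengths[bands[lo]],
                           band1 = bands[hi], band2 = bands[lo]),
                      class = "band_pair")
    nbd <- compute_nbd(cube, pair, eps = eps)
    v <- nbd$values[is.finite(nbd$values)]
    if (length(unique(v)) < 2L) next
    oc <- otsu_contrast(v)
    scores[hi, lo] <- oc$score
    better <- oc$score > best$score ||
      (oc$score == best$score &&
         (bands[hi] > best$i || (bands[hi] == best$i &&
                                   bands[lo] < best$j)))
    if (better)
      best <- list(score = oc$score, i = bands[hi], j = bands[lo],
                   threshold = oc$threshold)
  }
  if (!is.finite(best$score))
    stop("no band pair produced a non-constant NBD image", call. = FALSE)
  list(pair = structure(list(lambda1 = cube$wavelengths[best$i],
                             lambda2 = cube$wavelengths[best$j],
                             band1 = best$i, band2 = best$j),
                        class = "band_pair"),
       score = list(threshold = best$threshold, score = best$score),
       scores = scores)
}

## One pass of 3-point moving-average smoothing; the window extends past
## the histogram ends with zero counts. Summands run left to right so a
## naive loop reproduces the result bit for bit.
smooth3 <- function(h) {
  n <- length(h)
  if (n < 2L) return(h)
  (c(0, h[-n]) + h + c(h[-1], 0)) / 3
}

## Positions (bin centers) of strict local maxima after collapsing
## equal-count plateaus; a boundary run with a single lower neighbour
## counts as a peak.
histogram_peaks <- function(counts, centers) {
  r <- rle(counts)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- numeric(0)
  for (i in seq_len(k)) {
    left <- if (i > 1L) r$values[i - 1L] else -Inf
    right <- if (i < k) r$values[i + 1L] else -Inf
    if (r$values[i] > left && r$values[i] > right)
      peaks <- c(peaks, mean(centers[starts[i]:ends[i]]))
  }
  peaks
}

#' Intermodes threshold of a value distribution
#'
#' Histograms the values, smooths the histogram iteratively with a
#' 3-point moving average (window zero-padded past the ends) until it is
#' bimodal (exactly two strict local maxima after collapsing plateaus),
#' and returns the midpoint of the two peak bin centers.
#'
#' @param values Numeric vector (`NA`s ignored), at least 2 distinct.
#' @param bins Histogram bin count over `[min, max]`.
#' @param max_iter Smoothing iteration cap; exceeding it is a
#'   convergence error.
#' @return List with `threshold`, `smoothing_iterations`, `histogram`
#'   (final counts) and `breaks`.
#' @export
intermode_threshold <- function(values, bins = 256L, max_iter = 10000L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L)
    stop("intermodes threshold undefined for constant input",
         call. = FALSE)
  breaks <- seq(min(v), max(v), length.out = bins + 1L)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- as.numeric(
    tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                  bins), nbins = bins))
  it <- 0L
  repeat {
    peaks <- histogram_peaks(counts, centers)
    if (length(peaks) == 2L) break
    if (length(peaks) < 2L)
      stop("histogram collapsed below two modes before bimodality",
           call. = FALSE)
    if (it >= max_iter)
      stop("histogram did not become bimodal within max_iter smoothing ",
           "iterations", call. = FALSE)
    counts <- smooth3(counts)
    it <- it + 1L
  }
  list(threshold = mean(peaks), smoothing_iterations = it,
       histogram = counts, breaks = breaks)
}

## 8-connected labeling of a logical mask, components numbered in raster
## order (column-major: down each pixel column of lines) of their first
## pixel. EBImage's labeller is 4-connected, hence this one.
label_components <- function(mask) {
  L <- nrow(mask); P <- ncol(mask)
  lab <- matrix(0L, L, P)
  nxt <- 0L
  idx <- which(mask)
  ## raster order: line by line, then pixel within a line
  idx <- idx[order((idx - 1L) %% L, (idx - 1L) %/% L)]
  off_l <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  off_p <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  for (s in idx) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    stack <- s
    lab[s] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cl <- (cur - 1L) %% L + 1L
      cp <- (cur - 1L) %/% L + 1L
      nl <- cl + off_l; np <- cp + off_p
      ok <- nl >= 1L & nl <= L & np >= 1L & np <= P
      nb <- (np[ok] - 1L) * L + nl[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- nxt
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' Segment plant material in a scene
#'
#' Thresholds the NBD image at its intermodes point (the upper histogram
#' mode corresponds to vegetation, the lower one to the flat background),
#' refines the mask by morphological opening then closing with a disk
#' structuring element, removes components below a minimum area, and
#' labels the surviving 8-connected regions in raster order.
#'
#' @param cube A [hyper_cube()].
#' @param pair A [band_pair()], `c(lambda1, lambda2)`, or `"auto"` to run
#'   [select_band_pair()] on this cube.
#' @param bins,max_iter Passed to [intermode_threshold()].
#' @param min_area Minimum region area in pixels.
#' @param morph_radius Disk radius (px) of the structuring element; 0
#'   skips morphology.
#' @param stride Band stride for `pair = "auto"`.
#' @return An object of class `segmentation_result`: list with `pair`,
#'   `nbd`, `threshold`, `smoothing_iterations`, `mask`, `regions`
#'   (labeled matrix), `region_table` (id, area, bounding box), and
#'   `reference_region` (`NA` until [locate_reference()] is run).
#' @export
segment_scene <- function(cube, pair, bins = 256L, max_iter = 10000L,
                          min_area = 50L, morph_radius = 1L,
                          stride = 1L) {
  if (identical(pair, "auto"))
    pair <- select_band_pair(cube, stride = stride)$pair
  else if (is.numeric(pair))
    pair <- band_pair(cube, pair[1], pair[2])
  nbd <- compute_nbd(cube, pair)
  th <- intermode_threshold(nbd$values, bins = bins, max_iter = max_iter)
  mask <- !is.na(nbd$values) & nbd$values > th$threshold
  if (morph_radius > 0L) {
    kern <- EBImage::makeBrush(2L * morph_radius + 1L, shape = "disc")
    m <- EBImage::closing(EBImage::opening(mask * 1, kern), kern)
    mask <- m > 0.5
  }
  lab <- label_components(mask)
  if (max(lab) > 0L) {
    areas <- tabulate(lab, nbins = max(lab))
    keep <- which(areas >= min_area)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)  # raster order preserved
    lab <- matrix(ifelse(lab > 0L, relab[pmax(lab, 1L)], 0L),
                  nrow(lab), ncol(lab))
    mask <- lab > 0L
  }
  nreg <- max(lab)
  if (nreg == 0L)
    warning("empty segmentation: no region passed the area filter",
            call. = FALSE)
  region_table <- if (nreg > 0L) {
    do.call(rbind, lapply(seq_len(nreg), function(i) {
      w <- which(lab == i, arr.ind = TRUE)
      data.frame(id = i, area = nrow(w),
                 line_min = min(w[, 1]), line_max = max(w[, 1]),
                 pixel_min = min(w[, 2]), pixel_max = max(w[, 2]))
    }))
  } else {
    data.frame(id = integer(0), area = integer(0),
               line_min = integer(0), line_max = integer(0),
               pixel_min = integer(0), pixel_max = integer(0))
  }
  structure(
    list(pair = pair, nbd = nbd, threshold = th$threshold,
         smoothing_iterations = th$smoothing_iterations, mask = mask,
         regions = lab, region_table = region_table,
         reference_region = NA),
    class = "segmentation_result")
}

#' Locate the grey reference panel
#'
#' Two localization modes. `"roi"`: the reference is the configured
#' rectangle (intersected with the scan). `"flatness"`: candidate regions
#' are the segmented plant regions plus bright connected components
#' outside the plant mask (the flat panel thresholds into the background
#' mode of the NBD histogram, so it is recovered from the intensity image
#' instead); the candidate minimizing the coefficient of variation of its
#' mean spectrum wins, provided its CV is below `flatness_cutoff` —
#' vegetation spectra have high CV, a flat panel's is near zero.
#'
#' @param cube A [hyper_cube()].
#' @param result A [segment_scene()] result.
#' @param mode `"roi"` or `"flatness"`.
#' @param roi For `"roi"`: list with `rows = c(from, to)`,
#'   `cols = c(from, to)`.
#' @param flatness_cutoff Maximum CV for a flatness-mode candidate.
#' @param min_area Minimum candidate area for off-mask components.
#' @return List with `mask` (logical matrix), `region_id` (label id if
#'   the reference coincides with a segmented region, else `NA`) and
#'   `cv`; or `NULL` if no candidate qualifies.
#' @export
locate_reference <- function(cube, result, mode = c("roi", "flatness"),
                             roi = NULL, flatness_cutoff = 0.1,
                             min_area = 50L) {
  mode <- match.arg(mode)
  d <- dim(cube)
  region_cv <- function(mask) {
    s <- mean_spectrum(cube, mask)$mean
    stats::sd(s) / mean(s)
  }
  if (mode == "roi") {
    if (is.null(roi)) stop("roi mode needs a rectangle", call. = FALSE)
    if (roi$rows[1] < 1 || roi$cols[1] < 1 ||
        roi$rows[1] > d[1] || roi$cols[1] > d[2])
      stop("roi lies outside the image", call. = FALSE)
    mask <- matrix(FALSE, d[1], d[2])
    mask[roi$rows[1]:min(roi$rows[2], d[1]),
         roi$cols[1]:min(roi$cols[2], d[2])] <- TRUE
    ids <- unique(result$regions[mask])
    ids <- ids[ids > 0]
    return(list(mask = mask,
                region_id = if (length(ids) == 1L) ids else NA_integer_,
                cv = region_cv(mask)))
  }
  ## flatness mode
  candidates <- list()
  for (i in seq_len(max(result$regions)))
    candidates[[length(candidates) + 1L]] <-
      list(mask = result$regions == i, id = i)
  intensity <- apply(cube$values, c(1, 2), mean)
  bg <- !result$mask
  v <- intensity[bg]
  if (length(unique(v)) >= 2L) {
    ## gate on a clearly bimodal background: unimodal sensor noise
    ## alone reaches Otsu ratios near 0.64, a panel against the tray
    ## scores far higher
    oc <- try(otsu_contrast(v), silent = TRUE)
    if (!inherits(oc, "try-error") && oc$score > 0.85) {
      bright <- bg & intensity > oc$threshold
      lab <- label_components(bright)
      if (max(lab) > 0L) {
        areas <- tabulate(lab, nbins = max(lab))
        for (i in which(areas >= min_area))
          candidates[[length(candidates) + 1L]] <-
            list(mask = lab == i, id = NA_integer_)
      }
    }
  }
  if (!length(candidates)) return(NULL)
  cvs <- vapply(candidates, function(cc) region_cv(cc$mask), numeric(1))
  best <- which.min(cvs)
  if (cvs[best] >= flatness_cutoff) return(NULL)
  list(mask = candidates[[best]]$mask, region_id = candidates[[best]]$id,
       cv = cvs[best])
}
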