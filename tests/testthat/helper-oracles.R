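# Independent reference implementations used to cross-check the package:
# deliberately naive, loop-based, and written without reuse of package
# internals.

# Brute-force Otsu: try every candidate threshold on the raw values.
oracle_otsu <- function(v, n_candidates = 256L) {
  v <- v[is.finite(v)]
  n <- length(v)
  tot <- mean((v - mean(v))^2)
  cand <- seq(min(v), max(v), length.out = n_candidates)
  best <- list(score = -Inf, threshold = NA)
  for (t in cand) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / n
    bc <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bc > best$score) best <- list(score = bc, threshold = t)
  }
  list(threshold = best$threshold, score = min(best$score / tot, 1))
}

# Step-by-step intermodes thresholding: explicit binning, smoothing and
# peak-count loops.
oracle_intermodes <- function(v, bins = 256L, max_iter = 10000L) {
  v <- v[is.finite(v)]
  b <- seq(min(v), max(v), length.out = bins + 1L)
  centers <- numeric(bins)
  h <- numeric(bins)
  for (i in seq_len(bins)) {
    centers[i] <- (b[i] + b[i + 1]) / 2
    h[i] <- if (i < bins) sum(v >= b[i] & v < b[i + 1])
            else sum(v >= b[i] & v <= b[i + 1])
  }
  count_peaks <- function(h) {
    # collapse equal-count plateaus, then count strict maxima
    pos <- list()
    i <- 1L
    while (i <= length(h)) {
      j <- i
      while (j < length(h) && h[j + 1] == h[i]) j <- j + 1
      left <- if (i > 1L) h[i - 1L] else -Inf
      right <- if (j < length(h)) h[j + 1L] else -Inf
      if (h[i] > left && h[i] > right)
        pos[[length(pos) + 1L]] <- mean(centers[i:j])
      i <- j + 1L
    }
    unlist(pos)
  }
  it <- 0L
  repeat {
    pk <- count_peaks(h)
    if (length(pk) == 2L) return(list(threshold = mean(pk),
                                      iterations = it))
    if (it >= max_iter || length(pk) < 2L) return(NULL)
    h2 <- numeric(length(h))
    for (i in seq_along(h)) {
      s <- 0
      for (j in (i - 1L):(i + 1L))
        if (j >= 1L && j <= length(h)) s <- s + h[j]
      h2[i] <- s / 3  # window zero-padded past the ends
    }
    h <- h2
    it <- it + 1L
  }
}

# Exhaustive double-loop band-pair search with the brute-force Otsu
# score and the larger-lambda1 / smaller-lambda2 tie rule.
oracle_band_pair <- function(cube) {
  wl <- cube$wavelengths
  nb <- length(wl)
  best <- NULL
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (wl[i] <= wl[j]) next  # i = lambda1 (higher), j = lambda2
    r1 <- cube$values[, , i]; r2 <- cube$values[, , j]
    den <- r1 + r2
    nbd <- (r1 - r2) / den
    nbd[den <= 1e-6 * max(cube$values)] <- NA
    v <- nbd[is.finite(nbd)]
    if (length(unique(v)) < 2L) next
    sc <- oracle_otsu(v)$score
    take <- is.null(best) || sc > best$score ||
      (sc == best$score && (wl[i] > best$l1 ||
                              (wl[i] == best$l1 && wl[j] < best$l2)))
    if (take) best <- list(score = sc, l1 = wl[i], l2 = wl[j])
  }
  best
}

# Classic-LDA predictions via MASS (reference implementation).
oracle_lda_predict <- function(Xtrain, y, Xtest) {
  fit <- MASS::lda(Xtrain, grouping = y)
  as.character(predict(fit, Xtest)$class)
}
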