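## Repeated-holdout (Monte Carlo) validation of the rLDA classifier:
## many stratified 3:1 splits, per-split hyperparameter tuning by k-fold
## CV on the training part, accuracy mean +/- standard error over
## replicates, pooled row-normalized confusion matrices, and Fisher-LSD
## comparisons between modeling scenarios.

## Stratified train/test split: per class, a seeded shuffle; test size
## round(test_frac * n_c), at least 1 and at most n_c - 2 (training
## keeps >= 2 per class).
holdout_split <- function(y, test_frac, seed) {
  set.seed(seed)
  test <- logical(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    if (length(idx) < 4L)
      stop("class '", cl, "' has fewer than 4 rows; cannot appear in ",
           "both partitions reliably", call. = FALSE)
    nt <- min(max(round(test_frac * length(idx)), 1L), length(idx) - 2L)
    test[idx[sample.int(length(idx))][seq_len(nt)]] <- TRUE
  }
  test
}

#' Repeated-holdout validation of the tuned rLDA pipeline
#'
#' For each replicate `r`: stratified random train/test split (training
#' fraction `ratio`) with seed `base_seed + r`; hyperparameters tuned by
#' k-fold CV on the training part (or fixed values used when `tune =
#' FALSE`); model fit on the standardized training rows; accuracy
#' measured on the held-out rows. Reports the per-replicate accuracies,
#' their mean and standard error (sd / sqrt(reps)), the tuned
#' hyperparameters, and every test prediction for pooling.
#'
#' @param X Raw spectra matrix.
#' @param y Labels (every class >= 4 rows).
#' @param reps Replicate count.
#' @param ratio Training fraction (0.75 = the 3:1 split).
#' @param base_seed Base seed; replicate `r` uses `base_seed + r`.
#' @param tune Tune per replicate; otherwise use `gamma`/`delta`.
#' @param gamma,delta Fixed hyperparameters when `tune = FALSE`.
#' @param budget,k Tuning budget and CV fold count.
#' @return Object of class `replication_report`: `accuracy` (per
#'   replicate), `mean_accuracy`, `se_accuracy` (`NA` for one
#'   replicate), `params` (per-replicate gamma/delta), `records` (data
#'   frame replicate/truth/predicted), `classes`.
#' @export
repeated_holdout <- function(X, y, reps = 30L, ratio = 0.75,
                             base_seed = 0L, tune = TRUE,
                             gamma = 0.005, delta = 1, budget = 30L,
                             k = 10L) {
  X <- as.matrix(X); y <- as.character(y)
  acc <- numeric(reps)
  params <- data.frame(replicate = seq_len(reps), gamma = NA_real_,
                       delta = NA_real_)
  records <- vector("list", reps)
  for (r in seq_len(reps)) {
    test <- holdout_split(y, 1 - ratio, base_seed + r)
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    Xte <- X[test, , drop = FALSE]; yte <- y[test]
    if (tune) {
      tu <- tune_hyperparameters(Xtr, ytr, budget = budget,
                                 seed = base_seed + r, k = k)
      g <- tu$gamma; d <- tu$delta
    } else {
      g <- gamma; d <- delta
    }
    params$gamma[r] <- g; params$delta[r] <- d
    sp <- suppressWarnings(standardize_fit(Xtr))
    m <- rlda_fit(standardize_apply(sp, Xtr), ytr, gamma = g, delta = d)
    pred <- rlda_predict(m, standardize_apply(sp, Xte))
    acc[r] <- mean(pred == yte)
    records[[r]] <- data.frame(replicate = r, truth = yte,
                               predicted = pred,
                               stringsAsFactors = FALSE)
  }
  structure(
    list(accuracy = acc, mean_accuracy = mean(acc),
         se_accuracy = if (reps > 1L) stats::sd(acc) / sqrt(reps)
                       else NA_real_,
         params = params, records = do.call(rbind, records),
         classes = sort(unique(y)), reps = reps, ratio = ratio,
         base_seed = base_seed, tuned = tune),
    class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf(
    "replication_report: %d replicates, mean accuracy %.1f%% (SE %s)\n",
    x$reps, 100 * x$mean_accuracy,
    if (is.na(x$se_accuracy)) "NA"
    else sprintf("%.2f%%", 100 * x$se_accuracy)))
  invisible(x)
}

#' Pooled row-normalized confusion matrix
#'
#' Sums prediction counts over all replicates' test sets, then divides
#' each row (true class) by its total.
#'
#' @param report A [repeated_holdout()] report (or any object with a
#'   `records` data frame of truth/predicted).
#' @return Object of class `confusion_matrix`: list with `counts` and
#'   `proportions` (rows = truth, columns = predicted; rows without
#'   observations are `NaN`-flagged).
#' @export
pooled_confusion <- function(report) {
  rec <- report$records
  if (is.null(rec) || nrow(rec) == 0L)
    stop("no prediction records to pool", call. = FALSE)
  classes <- sort(unique(c(rec$truth, rec$predicted, report$classes)))
  counts <- table(factor(rec$truth, classes),
                  factor(rec$predicted, classes))
  counts <- matrix(as.integer(counts), length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  props <- counts / rowSums(counts)
  structure(list(counts = counts, proportions = props),
            class = "confusion_matrix")
}

#' Fisher's least significant difference comparison of group means
#'
#' One-way ANOVA pooled error variance; pair (i, j) differs when
#' `|mean_i - mean_j| > t(1 - alpha/2, df) * sqrt(MSE (1/n_i + 1/n_j))`.
#' Groups that cannot be separated share a letter in the compact letter
#' display (insert-and-absorb over mean-sorted groups).
#'
#' @param groups Named list of numeric vectors (>= 2 groups; pooled
#'   error needs at least one group with >= 2 values).
#' @param alpha Significance level.
#' @return Object of class `lsd_result`: `means`, `n`, `mse`, `df`,
#'   `lsd` (pairwise threshold matrix), `different` (logical matrix) and
#'   `letters` (compact letter display, groups in input order).
#' @export
fisher_lsd <- function(groups, alpha = 0.05) {
  g <- length(groups)
  if (g < 2L) stop("need >= 2 groups", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_len(g))
  n <- vapply(groups, length, integer(1))
  if (all(n < 2L))
    stop("all groups are singletons; no pooled error df", call. = FALSE)
  means <- vapply(groups, mean, numeric(1))
  df <- sum(n) - g
  if (df < 1L) stop("no error degrees of freedom", call. = FALSE)
  mse <- sum(vapply(groups, function(v)
    sum((v - mean(v))^2), numeric(1))) / df
  tcrit <- stats::qt(1 - alpha / 2, df)
  lsd <- matrix(NA_real_, g, g, dimnames = list(names(groups),
                                                names(groups)))
  for (i in seq_len(g)) for (j in seq_len(g))
    lsd[i, j] <- tcrit * sqrt(mse * (1 / n[i] + 1 / n[j]))
  diffm <- abs(outer(means, means, "-")) > lsd
  diag(diffm) <- FALSE
  ## compact letters: sweep mean-sorted groups, take maximal runs of
  ## mutually non-different groups, absorb nested runs
  ord <- order(-means)
  runs <- list()
  for (i in seq_len(g)) {
    j <- i
    while (j < g && !any(diffm[ord[i:(j + 1)], ord[i:(j + 1)]]))
      j <- j + 1
    runs[[length(runs) + 1L]] <- ord[i:j]
  }
  keep <- rep(TRUE, length(runs))
  for (a in seq_along(runs)) for (b in seq_along(runs))
    if (a != b && keep[a] && keep[b] &&
        all(runs[[a]] %in% runs[[b]])) keep[a] <- FALSE
  runs <- runs[keep]
  letters_out <- rep("", g)
  for (r in seq_along(runs))
    letters_out[runs[[r]]] <- paste0(letters_out[runs[[r]]],
                                     letters[r])
  names(letters_out) <- names(groups)
  structure(
    list(means = means, n = n, mse = mse, df = df, lsd = lsd,
         different = diffm, letters = letters_out, alpha = alpha),
    class = "lsd_result")
}
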