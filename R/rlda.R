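## Regularized linear discriminant analysis for high-dimensional
## spectra. The pooled within-class covariance S is shrunk toward its
## diagonal, S~ = (1 - gamma) S + gamma diag(S), and the per-class
## linear coefficients b_k = S~^{-1} mu_k are hard-thresholded at delta
## (entries with |b| <= delta become exactly 0, acting as wavelength
## selection). Scores are score_k(x) = x' b_k - mu_k' b_k / 2 + log pi_k.
##
## S~ is never formed as a p x p matrix: with class-centered rows Z,
## S = Z'Z / (n - K), and the Woodbury identity solves against
## diag + low-rank at O(p n^2) cost, which is what makes tuning over
## hundreds of wavelength-resolved fits cheap.

#' Fit wavelength-wise standardization on training rows
#'
#' @param X Numeric matrix (rows = samples).
#' @return Object of class `standardization_params` with per-column
#'   `mean` and `sd` (sample convention, denominator n - 1). Columns with
#'   sd below `1e-12` are floored to sd 1 with a warning, so a constant
#'   column maps to zeros.
#' @export
standardize_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need >= 2 training rows", call. = FALSE)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  zero <- sd < 1e-12
  if (any(zero)) {
    warning(sum(zero), " zero-variance wavelength(s); variance floored",
            call. = FALSE)
    sd[zero] <- 1
  }
  structure(list(mean = mu, sd = sd), class = "standardization_params")
}

#' Apply a fitted standardization
#'
#' @param params A [standardize_fit()] result.
#' @param X Rows to transform (training or test).
#' @return Matrix of `(x - mean) / sd` per column.
#' @export
standardize_apply <- function(params, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, params$mean), 2, params$sd, "/")
}

## Solve (Dg + c Z'Z) B = M for p x K M without forming p x p,
## via Woodbury: inv = Dg^-1 - Dg^-1 Z' (I/c + Z Dg^-1 Z')^-1 Z Dg^-1.
woodbury_solve <- function(Z, Dg, cc, M) {
  Dm <- M / Dg                       # Dg^-1 M        (p x K)
  ZD <- Z / rep(Dg, each = nrow(Z))  # Z Dg^-1        (n x p)
  A <- ZD %*% t(Z)                   # Z Dg^-1 Z'     (n x n)
  diag(A) <- diag(A) + 1 / cc
  Dm - t(ZD) %*% solve(A, Z %*% Dm)
}

#' Fit a regularized LDA model
#'
#' @param X Standardized spectra matrix (samples x wavelengths); callers
#'   normally standardize via [standardize_fit()] first and store the
#'   params with the model.
#' @param y Class labels (character/factor), every class with >= 2 rows.
#' @param gamma Covariance regularization in `[0, 1)`.
#' @param delta Coefficient threshold `>= 0`.
#' @param standardization Optional [standardize_fit()] params carried for
#'   prediction-time transformation of raw rows.
#' @return Object of class `rlda_model`: class list (alphabetical),
#'   empirical priors, class means, coefficient matrix (p x K, exact
#'   zeros where pre-threshold magnitude `<= delta`), score intercepts
#'   and bookkeeping fields.
#' @details When `gamma = 0` and the pooled covariance is singular
#'   (fewer samples than wavelengths), a ridge of
#'   `1e-8 * trace(S) / p` stabilizes the solve.
#' @export
rlda_fit <- function(X, y, gamma = 0, delta = 0, standardization = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (gamma < 0 || gamma >= 1) stop("gamma must be in [0, 1)",
                                    call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2L) stop("need >= 2 classes", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  counts <- table(factor(y, classes))
  if (any(counts < 2L))
    stop("every class needs >= 2 rows", call. = FALSE)
  priors <- as.numeric(counts) / n
  M <- matrix(0, K, p)                 # K x p class means
  for (k in seq_len(K))
    M[k, ] <- colMeans(X[y == classes[k], , drop = FALSE])
  Z <- X - M[match(y, classes), , drop = FALSE]
  nu <- n - K                          # pooled covariance df
  D <- colSums(Z^2) / nu               # diag(S), no p x p matrix
  ridge <- 1e-8 * sum(D) / p
  Dg <- gamma * D
  Dg[Dg < ridge] <- ridge              # numerical floor incl. gamma = 0
  B <- woodbury_solve(Z, Dg, (1 - gamma) / nu, t(M))  # p x K
  B[abs(B) <= delta] <- 0
  const <- -0.5 * colSums(t(M) * B) + log(priors)
  structure(
    list(classes = classes, priors = priors, means = M, coef = B,
         const = const, gamma = gamma, delta = delta,
         standardization = standardization, p = p),
    class = "rlda_model")
}

#' Predict classes with a regularized LDA model
#'
#' Scores are linear in the (standardized) spectrum; the argmax class is
#' returned, ties broken toward the alphabetically first class.
#'
#' @param model An [rlda_fit()] result.
#' @param X Rows on the model's wavelength grid. If the model carries
#'   standardization params, raw rows are transformed internally.
#' @param scores Also return the per-class score matrix.
#' @return Character vector of labels, or a list with `labels` and
#'   `scores`.
#' @export
rlda_predict <- function(model, X, scores = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != model$p)
    stop("feature grid mismatch: model has ", model$p, " wavelengths, ",
         "data has ", ncol(X), call. = FALSE)
  if (!is.null(model$standardization))
    X <- standardize_apply(model$standardization, X)
  S <- X %*% model$coef
  S <- sweep(S, 2, model$const, "+")
  ## max.col with first-tie rule; classes are sorted alphabetically
  lab <- model$classes[max.col(S, ties.method = "first")]
  if (scores) list(labels = lab, scores = S) else lab
}

## Stratified fold assignment: within each class, a seeded shuffle is
## dealt round-robin over folds, spreading remainders.
make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation error of an rLDA configuration
#'
#' Standardization is refit inside every fold on that fold's training
#' part only (no leakage).
#'
#' @param X Raw (unstandardized) spectra matrix.
#' @param y Labels.
#' @param gamma,delta Hyperparameters.
#' @param k Fold count.
#' @param seed Seed controlling fold assignment.
#' @return Mean misclassification fraction over folds.
#' @export
cv_error <- function(X, y, gamma = 0, delta = 0, k = 10L, seed = 1L) {
  X <- as.matrix(X); y <- as.character(y)
  fold <- make_folds(y, k, seed)
  errs <- numeric(0)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    if (length(unique(y[tr])) < length(unique(y)) ||
        any(table(y[tr]) < 2L))
      stop("fold construction error: a fold's training part lost a class",
           call. = FALSE)
    sp <- suppressWarnings(standardize_fit(X[tr, , drop = FALSE]))
    m <- rlda_fit(standardize_apply(sp, X[tr, , drop = FALSE]), y[tr],
                  gamma = gamma, delta = delta)
    pred <- rlda_predict(m, standardize_apply(sp, X[te, , drop = FALSE]))
    errs <- c(errs, mean(pred != y[te]))
  }
  mean(errs)
}

#' Tune rLDA hyperparameters by cross-validation
#'
#' Minimizes [cv_error()] over `gamma` in `[0, 0.01]` and `delta` in
#' `[1e-3, 1e3]` (log scale). The default strategy is space-filling
#' initialization (Latin hypercube) followed by local refinement around
#' the incumbent with a shrinking proposal radius; a regular grid
#' fallback is available. Both strategies honour the same contract and
#' evaluation budget.
#'
#' @param X,y Raw spectra and labels.
#' @param budget Total cv_error evaluations (>= 5).
#' @param seed Seed (folds are shared across evaluations, so candidates
#'   compete on identical splits).
#' @param k CV fold count.
#' @param gamma_range,delta_range Search boxes (`delta_range` on the
#'   original scale, searched in log10).
#' @param method `"lhs_refine"` or `"grid"`.
#' @param n_init Latin hypercube points for `"lhs_refine"`.
#' @return List with `gamma`, `delta`, `cv_error` and the evaluation
#'   `trace` data frame.
#' @export
tune_hyperparameters <- function(X, y, budget = 30L, seed = 1L, k = 10L,
                                 gamma_range = c(0, 0.01),
                                 delta_range = c(1e-3, 1e3),
                                 method = c("lhs_refine", "grid"),
                                 n_init = 10L) {
  method <- match.arg(method)
  if (budget < 5L) stop("budget must be >= 5", call. = FALSE)
  lr <- log10(delta_range)
  evals <- data.frame(gamma = numeric(0), delta = numeric(0),
                      error = numeric(0))
  eval1 <- function(g, d) {
    e <- cv_error(X, y, gamma = g, delta = d, k = k, seed = seed)
    evals[nrow(evals) + 1L, ] <<- c(g, d, e)
    e
  }
  if (method == "grid") {
    ng <- max(2L, floor(sqrt(budget)))
    nd <- max(2L, budget %/% ng)
    for (g in seq(gamma_range[1], gamma_range[2], length.out = ng))
      for (d in 10^seq(lr[1], lr[2], length.out = nd))
        if (nrow(evals) < budget) eval1(g, d)
  } else {
    set.seed(seed + 1000L)
    n_init <- min(n_init, budget - 1L)
    H <- lhs::randomLHS(n_init, 2L)
    for (i in seq_len(n_init))
      eval1(gamma_range[1] + H[i, 1] * diff(gamma_range),
            10^(lr[1] + H[i, 2] * diff(lr)))
    radius <- 0.25
    while (nrow(evals) < budget) {
      best <- evals[which.min(evals$error), ]
      g <- best$gamma + stats::rnorm(1, 0, radius * diff(gamma_range))
      d <- log10(best$delta) + stats::rnorm(1, 0, radius * diff(lr))
      g <- min(max(g, gamma_range[1]), gamma_range[2])
      d <- min(max(d, lr[1]), lr[2])
      eval1(g, 10^d)
      radius <- radius * 0.9
    }
  }
  best <- evals[which.min(evals$error), ]
  list(gamma = best$gamma, delta = best$delta, cv_error = best$error,
       trace = evals)
}
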