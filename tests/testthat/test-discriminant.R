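random_instance <- function(seed, n = 45, p = 5, K = 3) {
  set.seed(seed)
  y <- rep(letters[seq_len(K)], length.out = n)
  X <- matrix(rnorm(n * p), n)
  for (k in seq_len(K))
    X[y == letters[k], k] <- X[y == letters[k], k] + 2
  list(X = X, y = y)
}

test_that("standardization centers and scales on training stats only", {
  set.seed(1)
  X <- matrix(rnorm(60), 12)
  sp <- standardize_fit(X)
  Z <- standardize_apply(sp, X)
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-10))
  # a test row equal to the training mean maps to zero
  expect_equal(unname(standardize_apply(sp, t(sp$mean))[1, ]),
               rep(0, 5))
  # constant column: floored variance, zeros out
  Xc <- cbind(X, 7)
  expect_warning(spc <- standardize_fit(Xc), "floored")
  expect_equal(unname(standardize_apply(spc, Xc)[, 6]), rep(0, 12))
})

test_that("rLDA at gamma=0, delta=0 matches classic LDA predictions", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    sp <- standardize_fit(inst$X)
    Xs <- standardize_apply(sp, inst$X)
    set.seed(seed + 500)
    Xnew <- standardize_apply(sp, matrix(rnorm(20 * 5), 20))
    m <- rlda_fit(Xs, inst$y, gamma = 0, delta = 0)
    expect_identical(rlda_predict(m, Xnew),
                     oracle_lda_predict(Xs, inst$y, Xnew))
  }
})

test_that("delta beyond all coefficients leaves a priors-only model", {
  inst <- random_instance(3, n = 40, K = 2)
  y <- c(rep("a", 28), rep("b", 12))  # unbalanced on purpose
  sp <- standardize_fit(inst$X)
  Xs <- standardize_apply(sp, inst$X)
  m0 <- rlda_fit(Xs, y, gamma = 0, delta = 0)
  m <- rlda_fit(Xs, y, gamma = 0, delta = max(abs(m0$coef)) + 1)
  expect_true(all(m$coef == 0))
  expect_true(all(rlda_predict(m, Xs) == "a"))  # the largest class
})

test_that("feature sparsity is monotone non-increasing in delta", {
  inst <- random_instance(8, n = 60, p = 10)
  sp <- standardize_fit(inst$X)
  Xs <- standardize_apply(sp, inst$X)
  deltas <- c(0, 0.01, 0.05, 0.2, 0.5, 1, 5)
  nz <- sapply(deltas, function(d)
    sum(rlda_fit(Xs, inst$y, gamma = 0.005, delta = d)$coef != 0))
  expect_true(all(diff(nz) <= 0))
})

test_that("widely separated classes are learned perfectly", {
  set.seed(5)
  X <- matrix(rnorm(60 * 4), 60)
  y <- rep(c("a", "b"), each = 30)
  X[y == "b", 2] <- X[y == "b", 2] + 10  # +/- 5 sd on one feature
  sp <- standardize_fit(X)
  m <- rlda_fit(standardize_apply(sp, X), y)
  expect_equal(mean(rlda_predict(m, standardize_apply(sp, X)) == y), 1)
})

test_that("exact score ties resolve to the alphabetically first class", {
  X <- matrix(c(-1, 1, 1, -1), 4, 1)
  y <- c("b", "b", "a", "a")  # mirrored classes, identical means
  m <- rlda_fit(X, y, gamma = 0.5, delta = 0)
  expect_true(all(m$coef == 0))
  expect_equal(rlda_predict(m, matrix(c(0.3, -2), 2, 1)),
               c("a", "a"))
})

test_that("batch prediction equals row-by-row prediction", {
  inst <- random_instance(12)
  sp <- standardize_fit(inst$X)
  Xs <- standardize_apply(sp, inst$X)
  m <- rlda_fit(Xs, inst$y, gamma = 0.002, delta = 0.1)
  batch <- rlda_predict(m, Xs)
  single <- vapply(seq_len(nrow(Xs)), function(i)
    rlda_predict(m, Xs[i, , drop = FALSE]), character(1))
  expect_identical(batch, single)
  expect_error(rlda_predict(m, Xs[, 1:3]), "mismatch")
})

test_that("cross-validation error behaves at the extremes", {
  # perfectly separable -> 0
  set.seed(9)
  X <- matrix(rnorm(80 * 3), 80)
  y <- rep(c("a", "b"), each = 40)
  X[y == "b", 1] <- X[y == "b", 1] + 12
  expect_equal(cv_error(X, y, k = 10, seed = 1), 0)
  # random labels, 2 balanced classes, n = 200 -> close to 0.5
  set.seed(10)
  X2 <- matrix(rnorm(200 * 5), 200)
  y2 <- rep(c("a", "b"), 100)
  e <- cv_error(X2, y2, k = 10, seed = 2)
  expect_gt(e, 0.4); expect_lt(e, 0.6)
  # determinism under the seed
  expect_identical(cv_error(X2, y2, k = 10, seed = 7),
                   cv_error(X2, y2, k = 10, seed = 7))
})

test_that("hyperparameter tuning respects ranges and the seed", {
  set.seed(21)
  y <- rep(c("a", "b"), each = 30)
  X <- matrix(rnorm(60 * 5), 60)
  X[y == "b", 2] <- X[y == "b", 2] + 8  # clearly separable
  inst <- list(X = X, y = y)
  tu <- tune_hyperparameters(inst$X, inst$y, budget = 12, seed = 4,
                             k = 5)
  expect_gte(tu$gamma, 0); expect_lte(tu$gamma, 0.01)
  expect_gte(tu$delta, 1e-3); expect_lte(tu$delta, 1e3)
  expect_equal(nrow(tu$trace), 12)
  tu2 <- tune_hyperparameters(inst$X, inst$y, budget = 12, seed = 4,
                              k = 5)
  expect_identical(tu$trace, tu2$trace)
  expect_equal(tu$cv_error, 0)  # separable toy data
  expect_error(tune_hyperparameters(inst$X, inst$y, budget = 3),
               "budget")
})

test_that("repeated holdout reports accuracies, SE and stratification", {
  set.seed(2)
  X <- matrix(rnorm(80 * 6), 80)
  y <- rep(c("a", "b"), each = 40)
  X[y == "b", 3] <- X[y == "b", 3] + 12  # +/- 6 sd
  rep_ <- repeated_holdout(X, y, reps = 8, base_seed = 1, tune = FALSE)
  expect_equal(rep_$mean_accuracy, 1)
  expect_equal(rep_$se_accuracy, 0)
  # test-set class proportions within 1 sample of 25%
  for (r in unique(rep_$records$replicate)) {
    cnt <- table(rep_$records$truth[rep_$records$replicate == r])
    expect_true(all(abs(cnt - 10) <= 1))
  }
  # single replicate: SE undefined
  r1 <- repeated_holdout(X, y, reps = 1, base_seed = 1, tune = FALSE)
  expect_equal(r1$mean_accuracy, r1$accuracy[1])
  expect_true(is.na(r1$se_accuracy))
  # mean/SE recomputable from the per-replicate list
  expect_equal(rep_$mean_accuracy, mean(rep_$accuracy))
  expect_equal(rep_$se_accuracy, sd(rep_$accuracy) / sqrt(8))
  expect_error(repeated_holdout(X[1:6, ], c("a", "a", "a", "b", "b",
                                            "b"), reps = 2,
                                tune = FALSE),
               "fewer than 4")
})

test_that("pooled confusion matrices sum counts and normalize rows", {
  rec <- data.frame(
    replicate = c(1, 1, 1, 2, 2, 2),
    truth = c("a", "a", "b", "a", "b", "b"),
    predicted = c("a", "b", "b", "a", "b", "a"))
  cm <- pooled_confusion(list(records = rec, classes = c("a", "b")))
  expect_equal(cm$counts["a", ], c(a = 2L, b = 1L))
  expect_equal(cm$counts["b", ], c(a = 1L, b = 2L))
  expect_equal(unname(rowSums(cm$proportions)), c(1, 1))
  # all-correct records give the identity
  rec2 <- data.frame(replicate = 1, truth = c("a", "b"),
                     predicted = c("a", "b"))
  cm2 <- pooled_confusion(list(records = rec2, classes = c("a", "b")))
  expect_equal(unname(cm2$proportions), diag(2))
  expect_error(pooled_confusion(list(records = NULL)), "records")
})

test_that("Fisher LSD matches the closed-form t oracle", {
  set.seed(31)
  groups <- list(hi = 0.99 + rnorm(30, 0, 0.004),
                 lo = 0.80 + rnorm(30, 0, 0.004))
  res <- fisher_lsd(groups)
  # independent closed form
  mse <- (sum((groups$hi - mean(groups$hi))^2) +
            sum((groups$lo - mean(groups$lo))^2)) / 58
  lsd <- qt(0.975, 58) * sqrt(mse * (1 / 30 + 1 / 30))
  expect_equal(res$lsd["hi", "lo"], lsd, tolerance = 1e-10)
  expect_true(res$different["hi", "lo"])
  expect_false(res$letters["hi"] == res$letters["lo"])
})

test_that("identical groups share a compact-display letter", {
  g <- list(a = c(0.5, 0.6, 0.55), b = c(0.5, 0.6, 0.55))
  res <- fisher_lsd(g)
  expect_equal(res$letters[["a"]], res$letters[["b"]])
  # all-perfect groups (zero variance) are legal and share a letter
  gz <- list(a = rep(1, 5), b = rep(1, 5))
  expect_equal(unname(fisher_lsd(gz)$letters), c("a", "a"))
  expect_error(fisher_lsd(list(a = 1, b = 2)), "singleton")
})

test_that("three-group letter display separates only the distant group", {
  set.seed(7)
  g <- list(x = rnorm(20, 0.95, 0.01), y = rnorm(20, 0.948, 0.01),
            z = rnorm(20, 0.70, 0.01))
  res <- fisher_lsd(g)
  expect_true(grepl(substr(res$letters[["x"]], 1, 1),
                    res$letters[["y"]]))
  expect_false(res$letters[["z"]] == res$letters[["x"]])
})
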