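test_that("one-hot encoding reflects pattern containment exactly", {
  M <- one_hot_encode(list(c(1, 2, 1)), list(c(1, 2), c(2, 2)),
                      compress = FALSE)
  expect_equal(unname(M[1, ]), c(1L, 0L))
  expect_equal(colnames(M), c("1-2", "2-2"))
})

test_that("encoding a group against its own patterns respects mined support", {
  set.seed(1)
  seqs <- lapply(1:10, function(i) sample.int(3, 30, replace = TRUE))
  spec <- mining_spec(min_support = 0.4, max_length = 4)
  ps <- mine_patterns(seqs, spec)
  M <- one_hot_encode(seqs, ps)
  expect_equal(unname(colSums(M)), ps$support)
  expect_true(all(colSums(M) >= ps$threshold))
})

test_that("degenerate feature inputs are rejected", {
  M <- one_hot_encode(list(c(1, 2)), list())
  expect_equal(ncol(M), 0)
  expect_error(evaluate_classifiers(M, factor(c("A"))), "no features")
  expect_error(one_hot_encode(list(c(1, 2)), list(c(1, 5))),
               "alphabet")
  expect_error(
    evaluate_classifiers(matrix(0:1, 2, 1), factor(c("A", "A"))),
    "two classes")
})

test_that("protocol defaults are the study constants", {
  p <- classification_protocol()
  expect_equal(p$train_fraction, 0.8)
  expect_equal(p$cv_repeats, 100L)
  expect_equal(p$cv_folds, 10L)
  expect_equal(sort(unique(p$rf_grid$ntree)), c(100L, 300L, 500L))
  expect_setequal(p$lda_grid, c("none", "auto"))
})

test_that("a perfectly separating feature yields CV accuracy 1 for both models", {
  set.seed(2)
  X <- cbind(sep = rep(c(0, 1), each = 12),
             noise = rbinom(24, 1, 0.5))
  y <- factor(rep(c("HC", "PD"), each = 12))
  rep <- suppressWarnings(evaluate_classifiers(
    X, y, classification_protocol(cv_repeats = 10, seed = 3)))
  expect_equal(unname(rep$models$rf$cv_mean["accuracy"]), 1)
  expect_equal(unname(rep$models$lda$cv_mean["accuracy"]), 1)
  expect_equal(unname(rep$models$rf$cv_mean["auc"]), 1)
  expect_true(all(rep$models$lda$holdout <= 1, na.rm = TRUE))
})

test_that("reports are reproducible bit-for-bit under a fixed protocol seed", {
  set.seed(4)
  X <- matrix(rbinom(30 * 6, 1, 0.4), 30, 6)
  X[, 1] <- rep(c(0, 1), each = 15)
  y <- factor(rep(c("a", "b"), each = 15))
  prot <- classification_protocol(cv_repeats = 5, seed = 9)
  r1 <- suppressWarnings(evaluate_classifiers(X, y, prot))
  r2 <- suppressWarnings(evaluate_classifiers(X, y, prot))
  expect_identical(r1$models$rf$cv_reps, r2$models$rf$cv_reps)
  expect_identical(r1$models$lda$cv_reps, r2$models$lda$cv_reps)
})

test_that("CV metric means are invariant to feature column order", {
  set.seed(5)
  X <- matrix(rbinom(30 * 4, 1, 0.5), 30, 4)
  X[, 2] <- rep(c(0, 1), each = 15)
  colnames(X) <- paste0("f", 1:4)
  y <- factor(rep(c("a", "b"), each = 15))
  prot <- classification_protocol(cv_repeats = 3, seed = 2)
  r1 <- suppressWarnings(evaluate_classifiers(X, y, prot))
  r2 <- suppressWarnings(evaluate_classifiers(X[, 4:1], y, prot))
  expect_equal(r1$models$lda$cv_mean, r2$models$lda$cv_mean,
               tolerance = 1e-12)
})

test_that("rank AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (i in 1:20) {
    y <- factor(sample(c("n", "p"), 40, replace = TRUE))
    if (length(unique(y)) < 2) next
    pr <- runif(40)
    mine <- dfncpm:::.auc_rank(y, pr, "p")
    ref <- suppressMessages(as.numeric(
      pROC::auc(pROC::roc(response = y, predictor = pr, levels = c("n", "p"),
                          direction = "<"))))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("unregularized LDA matches MASS::lda on well-conditioned data", {
  skip_if_not_installed("MASS")
  set.seed(10)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  y <- factor(rep(c("a", "b"), each = n / 2))
  X[y == "b", ] <- X[y == "b", ] + 0.8
  fit <- dfncpm:::.fit_lda(X, y, "none")
  pred <- dfncpm:::.predict_lda(fit, X, "b")
  ref <- predict(MASS::lda(X, grouping = y), X)
  expect_equal(pred$class, as.character(ref$class))
  expect_equal(unname(pred$prob), unname(ref$posterior[, "b"]),
               tolerance = 1e-6)
})

test_that("a planted informative feature ranks first for both models", {
  set.seed(7)
  n <- 40
  X <- matrix(rbinom(n * 9, 1, 0.5), n, 9)
  y <- factor(rep(c("HC", "PD"), each = n / 2))
  informative <- as.integer(y == "PD")
  flip <- sample(n, 2)
  informative[flip] <- 1L - informative[flip]
  X <- cbind(X, planted = informative)
  colnames(X) <- c(paste0("noise", 1:9), "planted")
  rep <- suppressWarnings(evaluate_classifiers(
    X, y, classification_protocol(cv_repeats = 3, seed = 5)))
  imp <- rank_feature_importance(rep)
  expect_equal(imp$rf$feature[1], "planted")
  expect_equal(imp$lda$feature[1], "planted")
})

test_that("identical features receive near-uniform importance", {
  set.seed(8)
  base <- rbinom(30, 1, 0.5)
  X <- cbind(a = base, b = base, c = base)
  y <- factor(ifelse(base + rbinom(30, 1, 0.2) >= 1, "p", "n"))
  if (length(unique(y)) == 2 && min(table(y)) >= 3) {
    rep <- suppressWarnings(evaluate_classifiers(
      X, y, classification_protocol(cv_repeats = 2, seed = 1)))
    imp <- rank_feature_importance(rep)
    expect_lt(diff(range(imp$rf$importance)), 0.15)
    expect_lt(diff(range(imp$lda$importance)), 1e-6)
  }
})

test_that("small classes shrink the fold count with a warning", {
  set.seed(9)
  X <- matrix(rbinom(12 * 3, 1, 0.5), 12, 3)
  X[, 1] <- rep(c(0, 1), each = 6)
  y <- factor(rep(c("a", "b"), each = 6))
  expect_warning(
    rep <- evaluate_classifiers(X, y,
                                classification_protocol(cv_repeats = 2,
                                                        seed = 1)),
    "reducing CV folds")
  expect_equal(rep$n_folds, 6L)
})
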