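#' One-hot pattern features and cross-validated classification
#'
#' Subjects are encoded by the presence/absence of mined sequential
#' patterns in their dominant-state sequences; random-forest and linear
#' discriminant classifiers are tuned on a held-out-aware split and
#' evaluated by repeated stratified k-fold cross-validation, with
#' feature-importance rankings over the patterns.
#'
#' @name features_and_classify
NULL

#' One-hot encode pattern containment per subject
#'
#' Entry (i, j) is 1 iff pattern j is a subsequence (gaps allowed) of
#' subject i's sequence, compressed with the same convention used at
#' mining time.
#'
#' @param state_sequences list of `state_sequence`s or integer vectors
#' @param patterns a `pattern_set`, or list of integer pattern vectors
#' @param compress apply run-length compression before matching (must
#'   match the mining-time setting; default taken from the pattern set)
#' @return binary matrix, subjects x patterns, pattern strings as colnames
#' @export
one_hot_encode <- function(state_sequences, patterns, compress = NULL) {
  if (inherits(patterns, "pattern_set")) {
    if (is.null(compress)) compress <- patterns$spec$compress_runs
    patterns <- patterns$patterns
  }
  if (is.null(compress)) compress <- TRUE
  if (length(patterns) == 0)
    return(matrix(0L, length(state_sequences), 0))
  seqs <- lapply(state_sequences, function(s)
    if (inherits(s, "state_sequence")) s$labels else as.integer(s))
  alpha_max <- max(unlist(seqs))
  if (any(unlist(patterns) > alpha_max) || any(unlist(patterns) < 1))
    stop("pattern labels outside the sequences' state alphabet")
  if (compress) seqs <- lapply(seqs, compress_runs)
  M <- matrix(0L, length(seqs), length(patterns))
  for (i in seq_along(seqs))
    for (j in seq_along(patterns))
      M[i, j] <- as.integer(contains_pattern(seqs[[i]], patterns[[j]]))
  colnames(M) <- pattern_strings(patterns)
  if (!is.null(names(seqs))) rownames(M) <- names(seqs)
  M
}

#' Classification protocol
#'
#' Defaults: stratified 80/20 train/test split, grid-search tuning with
#' inner cross-validation on the training split, evaluation by 100
#' repetitions of stratified 10-fold cross-validation.
#'
#' @param train_fraction training share of the stratified split
#' @param cv_repeats repetitions of the k-fold evaluation
#' @param cv_folds folds per repetition
#' @param inner_folds folds for hyperparameter tuning
#' @param tune_repeats repetitions of the inner CV whose mean accuracy
#'   scores each grid point (averaging reduces selection noise at small n)
#' @param seed integer seed governing split, tuning and evaluation
#' @param rf_grid data.frame over ntree/max_depth/min_leaf
#' @param lda_grid character vector of shrinkage modes ("none", "auto")
#' @return object of class `classification_protocol`
#' @export
classification_protocol <- function(train_fraction = 0.8,
                                    cv_repeats = 100L, cv_folds = 10L,
                                    inner_folds = 5L, tune_repeats = 5L,
                                    seed = 1L,
                                    rf_grid = expand.grid(
                                      ntree = c(100L, 300L, 500L),
                                      max_depth = c(NA, 4L, 8L),
                                      min_leaf = c(1L, 3L)),
                                    lda_grid = c("none", "auto")) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            cv_repeats >= 1, cv_folds >= 2, inner_folds >= 2,
            tune_repeats >= 1)
  structure(list(train_fraction = train_fraction,
                 cv_repeats = as.integer(cv_repeats),
                 cv_folds = as.integer(cv_folds),
                 inner_folds = as.integer(inner_folds),
                 tune_repeats = as.integer(tune_repeats),
                 seed = as.integer(seed),
                 rf_grid = rf_grid, lda_grid = lda_grid),
            class = "classification_protocol")
}

# ---- model backends -------------------------------------------------------

.fit_rf <- function(x, y, params) {
  x <- as.matrix(x)
  # constant columns carry no splits; an all-constant matrix sends the
  # randomForest C search into an unbounded loop, so drop them up front
  # and fall back to the class prior when nothing variable remains
  keep <- which(apply(x, 2, function(col) any(col != col[1])))
  if (length(keep) == 0)
    return(structure(list(prior = prop.table(table(y)),
                          levels = levels(y)),
                     class = "rf_prior"))
  maxnodes <- if (is.na(params$max_depth)) NULL else
    as.integer(min(2^params$max_depth, nrow(x)))
  fit <- randomForest::randomForest(
    x = x[, keep, drop = FALSE], y = y, ntree = params$ntree,
    maxnodes = maxnodes, nodesize = params$min_leaf)
  fit$keep_cols <- keep
  fit
}

.predict_rf <- function(fit, x, positive) {
  if (inherits(fit, "rf_prior")) {
    n <- nrow(as.matrix(x))
    return(list(prob = rep(unname(fit$prior[positive]), n),
                class = rep(names(fit$prior)[which.max(fit$prior)], n)))
  }
  pr <- stats::predict(fit, as.matrix(x)[, fit$keep_cols, drop = FALSE],
                       type = "prob")
  list(prob = pr[, positive],
       class = colnames(pr)[max.col(pr, ties.method = "first")])
}

# Binary Gaussian LDA on a pooled covariance. shrinkage = "none" adds a
# minimal ridge for invertibility; "auto" applies Schafer-Strimmer-style
# shrinkage of the off-diagonal toward zero (diagonal target), which keeps
# the fit defined when one-hot features are collinear or constant within
# a class.
.fit_lda <- function(x, y, shrinkage = "none") {
  x <- as.matrix(x)
  lev <- levels(y)
  stopifnot(length(lev) == 2)
  x0 <- x[y == lev[1], , drop = FALSE]
  x1 <- x[y == lev[2], , drop = FALSE]
  if (nrow(x0) < 2 || nrow(x1) < 2)
    stop("each class needs at least 2 training observations for LDA")
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  n0 <- nrow(x0); n1 <- nrow(x1); n <- n0 + n1
  Sp <- (crossprod(sweep(x0, 2, mu0)) + crossprod(sweep(x1, 2, mu1))) /
    (n - 2)
  p <- ncol(x)
  if (shrinkage == "auto") {
    lam <- .shrinkage_intensity(rbind(sweep(x0, 2, mu0),
                                      sweep(x1, 2, mu1)))
    target <- diag(diag(Sp), p)
    Sp <- (1 - lam) * Sp + lam * target
    # numerical floor so zero-variance (perfectly separating) features
    # keep the shrunken covariance invertible
    Spr <- Sp + diag(1e-8 * mean(diag(Sp) + 1e-12) + 1e-12, p)
  } else {
    lam <- 0
    Spr <- Sp
    if (rcond(Spr) < 1e-10)
      stop("singular pooled covariance in LDA (shrinkage = none); ",
           "use shrinkage = 'auto'")
  }
  w <- solve(Spr, mu1 - mu0)
  b <- -sum(w * (mu0 + mu1)) / 2 + log(n1 / n0)
  structure(list(w = w, b = b, levels = lev, shrinkage = shrinkage,
                 lambda = lam, pooled_sd = sqrt(diag(Sp))),
            class = "lda_binary")
}

# Ledoit-Wolf-style intensity for shrinking off-diagonal covariances to 0.
# Vectorized: with w_ij(t) = xc_ti * xc_tj, the per-entry variance
# sum_t (w_ij - wbar_ij)^2 equals [crossprod(xc^2)]_ij - n * wbar_ij^2,
# and wbar_ij = (n-1)/n * S_ij.
.shrinkage_intensity <- function(xc) {
  n <- nrow(xc); p <- ncol(xc)
  if (n < 4 || p < 2) return(0)
  S <- crossprod(xc) / (n - 1)
  S2 <- crossprod(xc^2)
  sum_sq <- (sum(S2) - sum(diag(S2))) / 2
  den <- (sum(S^2) - sum(diag(S)^2)) / 2
  num <- n / ((n - 1)^3) * (sum_sq - (n - 1)^2 / n * den)
  if (den <= 0) return(1)
  max(0, min(1, num / den))
}

.predict_lda <- function(fit, x, positive) {
  score <- as.matrix(x) %*% fit$w + fit$b
  prob1 <- stats::plogis(score)[, 1]
  cls <- ifelse(score[, 1] > 0, fit$levels[2], fit$levels[1])
  prob_pos <- if (positive == fit$levels[2]) prob1 else 1 - prob1
  list(prob = prob_pos, class = cls)
}

# ---- metrics --------------------------------------------------------------

# Rank-based (Mann-Whitney) AUC of prob for the positive class
.auc_rank <- function(truth, prob, positive) {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.binary_metrics <- function(truth, pred, prob, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = mean(pred == truth),
    auc = .auc_rank(truth, prob, positive),
    recall = recall, precision = precision, f1 = f1)
}

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin across folds.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.stratified_split <- function(y, train_fraction) {
  train <- integer(0)
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    n_tr <- max(1L, round(train_fraction * length(idx)))
    train <- c(train, idx[seq_len(n_tr)])
  }
  sort(train)
}

# ---- evaluation -----------------------------------------------------------

.fit_predict <- function(model, params, x_tr, y_tr, x_te, positive) {
  if (model == "rf") {
    fit <- .fit_rf(x_tr, y_tr, params)
    .predict_rf(fit, x_te, positive)
  } else {
    fit <- .fit_lda(x_tr, y_tr, params$shrinkage)
    .predict_lda(fit, x_te, positive)
  }
}

.cv_metrics <- function(model, params, x, y, folds, positive) {
  pred <- character(length(y)); prob <- numeric(length(y))
  for (f in sort(unique(folds))) {
    te <- folds == f
    if (length(unique(y[!te])) < 2) return(NULL) # degenerate fold
    out <- tryCatch(
      .fit_predict(model, params, x[!te, , drop = FALSE], y[!te],
                   x[te, , drop = FALSE], positive),
      error = function(e) NULL)
    if (is.null(out)) return(NULL)
    pred[te] <- out$class
    prob[te] <- out$prob
  }
  if (anyNA(pred) || anyNA(prob) || any(pred == "")) return(NULL)
  .binary_metrics(y, pred, prob, positive)
}

#' Tune, evaluate and report binary classifiers
#'
#' Protocol: a seeded stratified train/test split; grid-search tuning by
#' inner stratified cross-validation (accuracy) on the training split;
#' held-out test metrics for the tuned models; then evaluation by
#' repeated stratified k-fold cross-validation over the full cohort with
#' distinct per-repetition seeds, pooling fold predictions within each
#' repetition. Models: random forest ("rf") and binary linear
#' discriminant analysis ("lda").
#'
#' @param features subjects x features matrix (binary pattern encodings
#'   or real-valued dwell measures)
#' @param labels two-level factor (or coercible); the second level is the
#'   positive class
#' @param protocol a `classification_protocol`
#' @return object of class `classification_report`: per model tuned
#'   parameters, held-out metrics, CV metric means/sds, per-repetition
#'   metric draws, final fits on all data; plus `feature_names`,
#'   `positive`, `protocol`
#' @export
evaluate_classifiers <- function(features, labels,
                                 protocol = classification_protocol()) {
  x <- as.matrix(features)
  if (ncol(x) == 0) stop("no features to train on")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need two classes")
  if (nlevels(y) > 2) stop("binary tasks only")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  positive <- levels(y)[2]
  folds_k <- protocol$cv_folds
  if (min(table(y)) < folds_k) {
    folds_k <- max(2L, min(table(y)))
    warning("reducing CV folds to ", folds_k,
            " (smallest class has ", min(table(y)), " subjects)")
  }
  set.seed(protocol$seed)
  train_idx <- .stratified_split(y, protocol$train_fraction)
  x_tr <- x[train_idx, , drop = FALSE]; y_tr <- y[train_idx]
  x_te <- x[-train_idx, , drop = FALSE]; y_te <- y[-train_idx]

  report <- list()
  for (model in c("rf", "lda")) {
    grid <- if (model == "rf") protocol$rf_grid else
      data.frame(shrinkage = protocol$lda_grid, stringsAsFactors = FALSE)
    inner_k <- min(protocol$inner_folds, max(2L, min(table(y_tr))))
    tune_scores <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      acc <- numeric(protocol$tune_repeats)
      for (tr_rep in seq_len(protocol$tune_repeats)) {
        set.seed(protocol$seed + 1000L + tr_rep)  # same folds per config
        fold <- .stratified_folds(y_tr, inner_k)
        m <- .cv_metrics(model, grid[gi, , drop = FALSE], x_tr, y_tr,
                         fold, positive)
        acc[tr_rep] <- if (is.null(m)) -Inf else m[["accuracy"]]
      }
      tune_scores[gi] <- mean(acc)
    }
    best <- grid[which.max(tune_scores), , drop = FALSE]
    # held-out metrics for the tuned model
    set.seed(protocol$seed + 2000L)
    holdout <- tryCatch({
      out <- .fit_predict(model, best, x_tr, y_tr, x_te, positive)
      .binary_metrics(y_te, out$class, out$prob, positive)
    }, error = function(e) rep(NA_real_, 5))
    # repeated stratified k-fold evaluation on the full cohort
    reps <- matrix(NA_real_, protocol$cv_repeats, 5,
                   dimnames = list(NULL, c("accuracy", "auc", "recall",
                                           "precision", "f1")))
    for (r in seq_len(protocol$cv_repeats)) {
      set.seed(protocol$seed + 3000L + r)
      fold <- .stratified_folds(y, folds_k)
      m <- .cv_metrics(model, best, x, y, fold, positive)
      if (!is.null(m)) reps[r, ] <- m
    }
    set.seed(protocol$seed + 4000L)
    if (model == "rf") {
      final_fit <- .fit_rf(x, y, best)
    } else {
      # a shrinkage-free fit tuned on the training split can still be
      # singular on the full cohort; fall back to shrinkage there
      final_fit <- tryCatch(.fit_lda(x, y, best$shrinkage),
                            error = function(e) {
                              best$shrinkage <<- "auto"
                              .fit_lda(x, y, "auto")
                            })
    }
    report[[model]] <- list(
      tuned = best,
      holdout = stats::setNames(holdout, c("accuracy", "auc", "recall",
                                           "precision", "f1")),
      cv_mean = colMeans(reps, na.rm = TRUE),
      cv_sd = apply(reps, 2, stats::sd, na.rm = TRUE),
      cv_reps = reps,
      fit = final_fit)
  }
  structure(list(models = report,
                 feature_names = colnames(x),
                 positive = positive,
                 levels = levels(y),
                 n_folds = folds_k,
                 protocol = protocol),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("classification report (positive class:", x$positive, ")\n")
  for (m in names(x$models)) {
    mm <- x$models[[m]]
    cat(sprintf(
      "  %-4s acc %.3f+-%.3f  auc %.3f  recall %.3f  precision %.3f  f1 %.3f\n",
      m, mm$cv_mean["accuracy"], mm$cv_sd["accuracy"], mm$cv_mean["auc"],
      mm$cv_mean["recall"], mm$cv_mean["precision"], mm$cv_mean["f1"]))
  }
  invisible(x)
}

#' Rank the most discriminative features
#'
#' Random forest: mean impurity-decrease importance across trees. LDA:
#' absolute standardized discriminant coefficients (|w_j| scaled by the
#' pooled within-class sd of feature j). Each ranking is normalized to
#' sum 1 and truncated to the top `top_n`.
#'
#' @param report a `classification_report`
#' @param top_n ranking length
#' @return named list of data.frames (feature, importance) per model
#' @export
rank_feature_importance <- function(report, top_n = 10L) {
  stopifnot(inherits(report, "classification_report"))
  out <- list()
  for (m in names(report$models)) {
    fit <- report$models[[m]]$fit
    if (m == "rf") {
      imp <- stats::setNames(numeric(length(report$feature_names)),
                             report$feature_names)
      if (!inherits(fit, "rf_prior")) {
        imp_raw <- randomForest::importance(fit)[, 1]
        imp[names(imp_raw)] <- imp_raw
      }
    } else {
      imp <- abs(fit$w) * report$models[[m]]$fit$pooled_sd
      names(imp) <- report$feature_names
    }
    if (sum(imp) > 0) imp <- imp / sum(imp)
    else imp <- rep(1 / length(imp), length(imp))
    ord <- order(-imp)
    take <- ord[seq_len(min(top_n, length(imp)))]
    out[[m]] <- data.frame(feature = report$feature_names[take],
                           importance = unname(imp[take]),
                           stringsAsFactors = FALSE)
  }
  out
}
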