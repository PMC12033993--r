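#' Brain-state clustering and dwell-time statistics
#'
#' Pooled FC windows are clustered into k discrete states with a
#' Lloyd-style algorithm. For the city-block metric the centroid update
#' is the coordinate-wise median (k-medians), the L1-optimal centroid;
#' for the euclidean metric it is the mean. States are relabeled in
#' descending order of occupancy so labels are deterministic.
#'
#' @name states
NULL

.dist_to_centroids <- function(X, centroids, distance) {
  k <- nrow(centroids)
  D <- matrix(0, nrow(X), k)
  tX <- t(X)
  for (j in seq_len(k)) {
    if (distance == "cityblock") {
      D[, j] <- colSums(abs(tX - centroids[j, ]))
    } else {
      D[, j] <- colSums((tX - centroids[j, ])^2)
    }
  }
  if (distance == "euclidean") D <- sqrt(D)
  D
}

# k-means++-style seeding under the chosen metric
.seed_centroids <- function(X, k, distance) {
  M <- nrow(X)
  first <- sample.int(M, 1)
  idx <- c(first)
  d_near <- .dist_to_centroids(X, X[first, , drop = FALSE], distance)[, 1]
  while (length(idx) < k) {
    prob <- d_near
    if (sum(prob) <= 0) prob <- rep(1, M)
    nxt <- sample.int(M, 1, prob = prob)
    idx <- c(idx, nxt)
    d_new <- .dist_to_centroids(X, X[nxt, , drop = FALSE], distance)[, 1]
    d_near <- pmin(d_near, d_new)
  }
  X[idx, , drop = FALSE]
}

.update_centroid <- function(Xc, distance) {
  if (distance == "cityblock") apply(Xc, 2, stats::median)
  else colMeans(Xc)
}

#' Cluster pooled FC windows into discrete brain states
#'
#' Runs `n_replicates` Lloyd-style fits from distinct seeded
#' k-means++-style initializations and keeps the replicate with the
#' least total within-cluster distance. An empty cluster is reseeded at
#' the point farthest from its nearest centroid. Final states are
#' relabeled in descending order of occupancy.
#'
#' @param X M x P matrix of pooled FC windows (M >= k)
#' @param k number of states
#' @param distance "cityblock" (k-medians) or "euclidean"
#' @param n_replicates number of restarts
#' @param seed integer seed
#' @param max_iter Lloyd iteration cap per replicate
#' @return object of class `state_model`: `centroids` (k x P), `k`,
#'   `distance`, `objective`, `sizes`, `labels` (training assignment),
#'   `seed`, `cvi_curve` (NULL until `select_k_elbow`)
#' @export
fit_states <- function(X, k = 3L, distance = c("cityblock", "euclidean"),
                       n_replicates = 5L, seed = 1L, max_iter = 100L) {
  distance <- match.arg(distance)
  X <- as.matrix(X)
  M <- nrow(X)
  if (M < k) stop("need at least k = ", k, " windows, got ", M)
  if (k < 1) stop("k must be >= 1")
  best <- NULL
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r - 1L)
    fit <- .lloyd(X, k, distance, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  # relabel states by descending occupancy (ties: original label order)
  ord <- order(-tabulate(best$labels, nbins = k), seq_len(k))
  relab <- integer(k); relab[ord] <- seq_len(k)
  labels <- relab[best$labels]
  centroids <- best$centroids[ord, , drop = FALSE]
  structure(list(k = as.integer(k),
                 centroids = centroids,
                 distance = distance,
                 n_replicates = as.integer(n_replicates),
                 objective = best$objective,
                 sizes = tabulate(labels, nbins = k),
                 labels = labels,
                 seed = as.integer(seed),
                 cvi_curve = NULL),
            class = "state_model")
}

.lloyd <- function(X, k, distance, max_iter) {
  centroids <- .seed_centroids(X, k, distance)
  labels <- rep(0L, nrow(X))
  for (it in seq_len(max_iter)) {
    D <- .dist_to_centroids(X, centroids, distance)
    new_labels <- max.col(-D, ties.method = "first")
    # reseed empty clusters at the point farthest from its nearest centroid
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        far <- which.max(apply(D, 1, min))
        centroids[j, ] <- X[far, ]
        D[, j] <- .dist_to_centroids(X, centroids[j, , drop = FALSE],
                                     distance)[, 1]
        new_labels <- max.col(-D, ties.method = "first")
      }
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k))
      centroids[j, ] <- .update_centroid(X[labels == j, , drop = FALSE],
                                         distance)
  }
  D <- .dist_to_centroids(X, centroids, distance)
  obj <- sum(D[cbind(seq_len(nrow(X)), labels)])
  list(centroids = centroids, labels = labels, objective = obj)
}

#' Choose k with the elbow criterion of a cluster validity index
#'
#' For each k the validity index is the total within-cluster distance
#' divided by the total between-centroid distance (sum of pairwise
#' centroid distances under the model metric). The elbow is the interior
#' k maximizing the positive second difference of the curve. When the
#' maximal second difference is below 10% of the curve's range the
#' returned choice is flagged low-confidence.
#'
#' @param X pooled windows, M x P
#' @param k_range contiguous integer range, min >= 2, length >= 3
#' @inheritParams fit_states
#' @return list: `k_star`, `cvi_curve` (data.frame k/index),
#'   `low_confidence`, `models` (one `state_model` per k)
#' @export
select_k_elbow <- function(X, k_range = 2:6,
                           distance = c("cityblock", "euclidean"),
                           n_replicates = 5L, seed = 1L) {
  distance <- match.arg(distance)
  k_range <- sort(as.integer(k_range))
  if (length(k_range) < 3) stop("k_range must contain at least 3 values")
  if (min(k_range) < 2) stop("k_range minimum must be >= 2")
  if (!all(diff(k_range) == 1L)) stop("k_range must be contiguous")
  models <- lapply(k_range, function(k)
    fit_states(X, k, distance, n_replicates, seed))
  index <- vapply(models, function(m) {
    # mean pairwise centroid distance: normalizing by the pair count keeps
    # the denominator roughly scale-stable in k, so the index inherits the
    # elbow of the within-cluster curve instead of a mechanical k^-2 decay
    n_pairs <- m$k * (m$k - 1) / 2
    between <- sum(.dist_to_centroids(m$centroids, m$centroids,
                                      m$distance)) / 2 / n_pairs
    m$objective / between
  }, numeric(1))
  elbow <- elbow_point(k_range, index)
  list(k_star = elbow$k_star,
       cvi_curve = data.frame(k = k_range, index = index,
                              second_difference = elbow$second_difference),
       low_confidence = elbow$low_confidence,
       models = stats::setNames(models, paste0("k", k_range)))
}

#' Elbow of a validity-index curve
#'
#' The elbow is the interior k with the maximal positive second difference
#' of the index; when that maximum is below 10% of the curve's range the
#' choice is flagged low-confidence (a near-linear curve has no elbow).
#'
#' @param k_range increasing integer vector (length >= 3)
#' @param index validity index per k
#' @return list: `k_star`, `second_difference`, `low_confidence`
#' @export
elbow_point <- function(k_range, index) {
  stopifnot(length(k_range) == length(index), length(k_range) >= 3)
  d2 <- rep(NA_real_, length(k_range))
  for (i in 2:(length(k_range) - 1))
    d2[i] <- index[i - 1] - 2 * index[i] + index[i + 1]
  i_star <- which.max(d2)
  rng <- diff(range(index))
  low_conf <- !is.finite(d2[i_star]) || d2[i_star] < 0.1 * rng
  list(k_star = k_range[i_star], second_difference = d2,
       low_confidence = low_conf)
}

#' Assign windows to their nearest brain state
#'
#' Ties are broken toward the lower state label.
#'
#' @param model a `state_model`
#' @param wfc a `windowed_fc`, or a numeric matrix of FC windows
#' @param tr_seconds repetition time carried into the sequence (taken from
#'   the model call when a bare matrix is given)
#' @return object of class `state_sequence`: `subject_id`, `labels`,
#'   `tr_seconds`, `step_tr`
#' @export
assign_states <- function(model, wfc, tr_seconds = NA_real_) {
  if (inherits(wfc, "windowed_fc")) {
    X <- wfc$fc
    sid <- wfc$subject_id
    step <- wfc$spec$step_tr
  } else {
    X <- as.matrix(wfc)
    sid <- "subject"
    step <- 1L
  }
  if (ncol(X) != ncol(model$centroids))
    stop("FC dimension (", ncol(X), ") does not match model centroids (",
         ncol(model$centroids), ")")
  D <- .dist_to_centroids(X, model$centroids, model$distance)
  labels <- max.col(-D, ties.method = "first")
  structure(list(subject_id = sid, labels = as.integer(labels),
                 tr_seconds = tr_seconds, step_tr = step),
            class = "state_sequence")
}

#' Dwell-time statistics of a state sequence
#'
#' Run-length scan of the label sequence: per-state fraction of windows,
#' mean contiguous run length in windows and seconds, transition count
#' and the empirical transition matrix of adjacent windows. States never
#' visited have fraction 0 and undefined (NA) mean dwell; transition-matrix
#' rows with no outgoing transitions are NA and flagged.
#'
#' @param seq a `state_sequence` or integer vector of labels
#' @param k number of states (default: max label)
#' @param tr_seconds repetition time (for seconds-scale dwell times)
#' @param step_tr window advancement in TR per step
#' @return object of class `dwell_stats`
#' @export
dwell_statistics <- function(seq, k = NULL, tr_seconds = NA_real_,
                             step_tr = 1L) {
  if (inherits(seq, "state_sequence")) {
    if (is.na(tr_seconds)) tr_seconds <- seq$tr_seconds
    step_tr <- seq$step_tr
    labels <- seq$labels
  } else labels <- as.integer(seq)
  if (length(labels) == 0) stop("empty state sequence")
  if (is.null(k)) k <- max(labels)
  runs <- rle(labels)
  n <- length(labels)
  fraction <- tabulate(labels, nbins = k) / n
  mean_dwell <- vapply(seq_len(k), function(s) {
    r <- runs$lengths[runs$values == s]
    if (length(r) == 0) NA_real_ else mean(r)
  }, numeric(1))
  n_runs <- vapply(seq_len(k), function(s)
    sum(runs$values == s), integer(1))
  n_transitions <- sum(diff(labels) != 0)
  TM <- matrix(0, k, k)
  if (n > 1) {
    from <- labels[-n]; to <- labels[-1]
    for (i in seq_along(from)) TM[from[i], to[i]] <- TM[from[i], to[i]] + 1
  }
  out_count <- rowSums(TM)
  no_out <- out_count == 0
  TMn <- TM / ifelse(out_count == 0, NA, out_count)
  structure(list(k = k,
                 fraction_time = fraction,
                 mean_dwell_windows = mean_dwell,
                 mean_dwell_seconds = mean_dwell * step_tr * tr_seconds,
                 n_runs = n_runs,
                 n_transitions = n_transitions,
                 transition_counts = TM,
                 transition_matrix = TMn,
                 no_outgoing = which(no_out),
                 n_windows = n),
            class = "dwell_stats")
}

#' Pooled-variance two-sample t-test
#'
#' Homoscedastic (pooled) two-tailed t-test, evaluated either from two
#' samples or from summary statistics via [ttest_from_summary()]. When
#' the pooled variance is zero: equal means give t = 0, p = 1; unequal
#' means give p = 0 with a warning.
#'
#' @param values_a,values_b numeric samples (each n >= 2)
#' @return list with `t`, `p`, `df`
#' @export
compare_groups_ttest <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 observations")
  ttest_from_summary(mean(values_a), stats::sd(values_a), length(values_a),
                     mean(values_b), stats::sd(values_b), length(values_b))
}

#' @rdname compare_groups_ttest
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summary statistics
#' @export
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("each group needs n >= 2")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 <= 0) {
    if (isTRUE(all.equal(mean_a, mean_b)))
      return(list(t = 0, p = 1, df = df))
    warning("zero pooled variance with unequal means; p = 0")
    return(list(t = sign(mean_a - mean_b) * Inf, p = 0, df = df))
  }
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  t <- (mean_a - mean_b) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, df = df)
}

#' Group comparison table for dwell-time measures
#'
#' Pairwise pooled t-tests between groups for each state's dwell measure,
#' with a Holm-adjusted p-value column alongside the raw one.
#'
#' @param dwell_list named list of `dwell_stats`, one per subject
#' @param groups named character vector subject -> group label
#' @param measure "fraction_time" or "mean_dwell_windows"
#' @return data.frame of pairwise comparisons per state
#' @export
dwell_group_comparison <- function(dwell_list, groups,
                                   measure = c("fraction_time",
                                               "mean_dwell_windows")) {
  measure <- match.arg(measure)
  subjects <- names(dwell_list)
  groups <- groups[subjects]
  k <- dwell_list[[1]]$k
  glabs <- unique(groups)
  rows <- list()
  for (s in seq_len(k)) {
    vals <- vapply(dwell_list, function(d) d[[measure]][s], numeric(1))
    for (a in seq_along(glabs)) for (b in seq_along(glabs)) {
      if (a >= b) next
      va <- vals[groups == glabs[a]]; vb <- vals[groups == glabs[b]]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      if (length(va) < 2 || length(vb) < 2) next
      tt <- compare_groups_ttest(va, vb)
      rows[[length(rows) + 1]] <- data.frame(
        state = s, group_a = glabs[a], group_b = glabs[b],
        mean_a = mean(va), mean_b = mean(vb),
        t = tt$t, p = tt$p, df = tt$df, measure = measure,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Match predicted to reference labels by optimal permutation
#'
#' Exhaustive search over label permutations (k <= 8) maximizing
#' agreement; returns the best agreement rate and the permutation used
#' (Hungarian-matched accuracy for small k).
#'
#' @param predicted,reference integer label vectors of equal length
#' @return list: `agreement`, `permutation` (predicted label -> matched)
#' @export
match_labels <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  k <- max(predicted, reference)
  if (k > 8) stop("permutation matching supported for k <= 8")
  perms <- .permutations(k)
  best <- 0; best_perm <- seq_len(k)
  for (i in seq_len(nrow(perms))) {
    agree <- mean(perms[i, predicted] == reference)
    if (agree > best) { best <- agree; best_perm <- perms[i, ] }
  }
  list(agreement = best, permutation = unname(best_perm))
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}
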