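test_that("k equal to the number of distinct points gives zero within-cluster cost", {
  set.seed(1)
  X <- matrix(rnorm(5 * 3), 5, 3)
  m <- fit_states(X, k = 5, n_replicates = 3, seed = 1)
  expect_equal(m$objective, 0, tolerance = 1e-12)
})

test_that("k-medians on 6 points matches the brute-force optimal 2-partition", {
  set.seed(2)
  X <- matrix(rnorm(12), 6, 2)
  # exhaustive search over all 2-partitions with coordinate-median centroids
  best_cost <- Inf
  for (mask in 1:(2^6 - 2)) {
    lab <- as.integer(intToBits(mask))[1:6]
    if (length(unique(lab)) < 2) next
    cost <- 0
    for (g in 0:1) {
      pts <- X[lab == g, , drop = FALSE]
      ctr <- apply(pts, 2, median)
      cost <- cost + sum(abs(sweep(pts, 2, ctr)))
    }
    best_cost <- min(best_cost, cost)
  }
  m <- fit_states(X, k = 2, n_replicates = 10, seed = 3)
  expect_equal(m$objective, best_cost, tolerance = 1e-10)
})

test_that("default clustering parameters are the study settings", {
  f <- formals(fit_states)
  expect_equal(f$k, 3L)
  expect_equal(eval(f$distance)[1], "cityblock")
  expect_equal(f$n_replicates, 5L)
})

test_that("states are relabeled by descending occupancy", {
  set.seed(4)
  X <- rbind(matrix(rnorm(60, mean = 0), 30, 2),
             matrix(rnorm(20, mean = 10), 10, 2))
  m <- fit_states(X, k = 2, n_replicates = 3, seed = 1)
  expect_true(m$sizes[1] >= m$sizes[2])
  expect_equal(sort(unique(m$labels)), 1:2)
})

test_that("elbow criterion recovers three separable states and flags no-structure data", {
  set.seed(5)
  centers <- matrix(c(0, 0, 8, 0, 0, 8), 3, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(120 * 2, sd = 0.7), 120, 2), 2, -centers[i, ])))
  sel <- select_k_elbow(X, 2:6, n_replicates = 3, seed = 2)
  expect_equal(sel$k_star, 3)
  expect_false(sel$low_confidence)

  blob <- matrix(rnorm(300 * 2), 300, 2)
  sel3 <- select_k_elbow(blob, 2:6, n_replicates = 3, seed = 2)
  expect_true(all(diff(sel3$cvi_curve$index) < 0)) # smooth decay, no kink

  expect_error(select_k_elbow(X, 2:3), "at least 3")
  expect_error(select_k_elbow(X, 1:4), ">= 2")
})

test_that("the elbow rule flags curves without a kink as low-confidence", {
  # near-linear decay: no elbow
  lin <- elbow_point(2:6, c(10, 8.1, 6.05, 4.1, 2.0))
  expect_true(lin$low_confidence)
  # sharp kink at k = 3
  kink <- elbow_point(2:6, c(10, 2, 1.8, 1.6, 1.4))
  expect_equal(kink$k_star, 3)
  expect_false(kink$low_confidence)
})

test_that("state assignment is nearest-centroid with ties to the lower label", {
  m <- structure(list(k = 3, distance = "cityblock",
                      centroids = rbind(c(0, 0), c(1, 1), c(2, 2))),
                 class = "state_model")
  expect_equal(assign_states(m, rbind(c(1, 1)))$labels, 2L)
  # (1, 0) is L1-equidistant (1) from centroids 1 and 2
  expect_equal(assign_states(m, rbind(c(1, 0)))$labels, 1L)
  expect_error(assign_states(m, matrix(0, 1, 3)), "does not match")
})

test_that("dwell statistics match hand counts and boundary cases", {
  d <- dwell_statistics(c(1, 1, 2, 2, 2, 1))
  expect_equal(d$fraction_time, c(0.5, 0.5))
  expect_equal(d$mean_dwell_windows, c(1.5, 3))
  expect_equal(d$n_transitions, 2)

  d2 <- dwell_statistics(rep(2L, 170), k = 3)
  expect_equal(d2$fraction_time, c(0, 1, 0))
  expect_equal(d2$n_transitions, 0)
  expect_true(is.na(d2$mean_dwell_windows[1]))
  expect_equal(d2$n_runs[2], 1L)
  expect_equal(d2$no_outgoing, c(1L, 3L))
})

test_that("dwell statistics satisfy run-scan identities on random sequences", {
  set.seed(6)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    k <- sample(2:4, 1)
    s <- sample.int(k, n, replace = TRUE)
    d <- dwell_statistics(s, k = k)
    expect_equal(sum(d$fraction_time), 1, tolerance = 1e-12)
    expect_equal(d$n_transitions, sum(s[-1] != s[-n]))
    md <- ifelse(is.na(d$mean_dwell_windows), 0, d$mean_dwell_windows)
    expect_equal(sum(md * d$n_runs), n)
    expect_equal(sum(d$transition_counts), d$n_transitions +
                   sum(diff(s) == 0))
  }
})

test_that("dwell seconds scale with TR and window step", {
  d <- dwell_statistics(c(1, 1, 2), k = 2, tr_seconds = 2, step_tr = 1)
  expect_equal(d$mean_dwell_seconds, c(4, 2))
})

test_that("pooled t-test agrees with stats::t.test and handles degenerate input", {
  set.seed(7)
  a <- rnorm(12); b <- rnorm(9, mean = 0.5)
  mine <- compare_groups_ttest(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter))

  same <- rep(1, 5)
  id <- compare_groups_ttest(same, same)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  expect_warning(z <- compare_groups_ttest(rep(1, 3), rep(2, 3)),
                 "zero pooled variance")
  expect_equal(z$p, 0)
  expect_error(compare_groups_ttest(1, c(1, 2)), "at least 2")
})

test_that("summary-statistic t evaluation matches the closed-form pooled formula", {
  # cohort-style summary input: mean +- sd with group sizes
  res <- ttest_from_summary(26.0, 2.3, 22, 22.7, 3.5, 15)
  sp2 <- (21 * 2.3^2 + 14 * 3.5^2) / 35
  t_hand <- (26.0 - 22.7) / sqrt(sp2 * (1 / 22 + 1 / 15))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 35)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 35), tolerance = 1e-12)
})

test_that("group dwell comparison emits raw and Holm-adjusted p-values", {
  set.seed(8)
  seqs <- lapply(1:10, function(i) sample.int(3, 50, replace = TRUE))
  names(seqs) <- paste0("s", 1:10)
  dw <- lapply(seqs, dwell_statistics, k = 3)
  groups <- setNames(rep(c("A", "B"), each = 5), names(seqs))
  tab <- dwell_group_comparison(dw, groups, "fraction_time")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$p_holm >= tab$p))
})

test_that("label matching finds the permutation with maximal agreement", {
  ref <- c(1, 1, 2, 2, 3, 3)
  pred <- c(3, 3, 1, 1, 2, 2)
  m <- match_labels(pred, ref)
  expect_equal(m$agreement, 1)
  expect_equal(m$permutation[pred], ref)
})
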