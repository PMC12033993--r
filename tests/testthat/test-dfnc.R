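test_that("taper weights are symmetric, normalized and match brute-force convolution", {
  w <- build_taper(26, 3)
  expect_length(w, 26)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_lt(max(abs(w - rev(w))), 1e-12)
  expect_true(all(w >= 0))

  set.seed(1)
  for (i in 1:10) {
    width <- sample(2:40, 1)
    sigma <- stats::runif(1, 0.5, 6)
    expect_equal(build_taper(width, sigma), brute_taper(width, sigma),
                 tolerance = 1e-12)
  }
})

test_that("a near-delta Gaussian kernel gives a uniform taper", {
  w <- build_taper(20, 0.01)
  expect_equal(w, rep(1 / 20, 20), tolerance = 1e-8)
})

test_that("window counts follow the T - W convention", {
  expect_equal(sliding_windows(196, 26, 1)$n, 170)
  sw <- sliding_windows(5, 2, 1)
  expect_equal(sw$n, 3)
  expect_equal(sw$starts, 0:2)
  expect_error(sliding_windows(10, 10, 1), "no admissible windows")
  expect_error(sliding_windows(10, 11, 1), "exceeds series length")
})

test_that("uniform-taper pearson FC on one window equals the sample correlation", {
  set.seed(2)
  Tn <- 41; C <- 4
  X <- matrix(rnorm(Tn * C), Tn, C)
  spec <- window_spec(width_tr = 40, taper_sigma_tr = 0.001,
                      fisher_z = FALSE)
  wfc <- estimate_windowed_fc(X, spec)
  R <- cor(X[1:40, ])
  expect_equal(wfc$fc[1, ], t(R)[lower.tri(R)], tolerance = 1e-9)
})

test_that("pearson FC is invariant to affine rescaling of a component", {
  set.seed(3)
  X <- matrix(rnorm(60 * 3), 60, 3)
  spec <- window_spec(width_tr = 20, fisher_z = FALSE)
  a <- estimate_windowed_fc(X, spec)
  X2 <- X
  X2[, 2] <- 5 * X[, 2] - 7
  b <- estimate_windowed_fc(X2, spec)
  expect_equal(a$fc, b$fc, tolerance = 1e-10)
})

test_that("pair ordering is the row-major upper triangle", {
  wfc <- estimate_windowed_fc(matrix(rnorm(40 * 4), 40, 4),
                              window_spec(width_tr = 30))
  expect_equal(wfc$pairs[, "i"], c(0L, 0L, 0L, 1L, 1L, 2L))
  expect_equal(wfc$pairs[, "j"], c(1L, 2L, 3L, 2L, 3L, 3L))
})

test_that("zero-variance columns are reported with subject and window context", {
  X <- matrix(rnorm(50 * 3), 50, 3)
  X[, 2] <- 1
  expect_error(
    estimate_windowed_fc(X, window_spec(width_tr = 20),
                         subject_id = "sub07"),
    "zero-variance column 2 in window 1 .* sub07")
})

test_that("fisher z transform clips at the correlation boundary", {
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
})

test_that("glasso at lambda 0 equals the direct inverse of the tapered covariance", {
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40, 3)
  w <- build_taper(30, 3)
  Xw <- X[1:30, ]
  mu <- colSums(w * Xw)
  Xc <- sweep(Xw, 2, mu)
  S <- crossprod(Xc, w * Xc)
  expect_equal(glasso_fit(S, 0), solve(S), tolerance = 1e-6)
})

test_that("full shrinkage drives all glasso partial correlations to zero", {
  set.seed(5)
  X <- matrix(rnorm(200 * 5), 200, 5) %*%
    chol(make_state_covariances(5, 1, "hyper", seed = 5)[[1]])
  S <- cov(X)
  lam_top <- max(abs(S[upper.tri(S)])) + 0.01
  pc <- partial_correlations(glasso_fit(S, lam_top))
  expect_equal(max(abs(pc[upper.tri(pc)])), 0)
})

test_that("glasso shrinkage of partial correlations is monotone along the lambda path", {
  # mean |off-diagonal| shrinks strictly monotonically; individual entries
  # may fluctuate by a few 1e-3 near the soft threshold (a property of the
  # glasso solution path itself, not of this implementation)
  set.seed(6)
  Sigma <- make_state_covariances(6, 1, "hyper", seed = 6)[[1]]
  X <- matrix(rnorm(300 * 6), 300, 6) %*% chol(Sigma)
  S <- cov(X)
  grid <- exp(seq(log(0.01), log(1), length.out = 10))
  prev <- NULL
  for (lam in grid) {
    pc <- abs(partial_correlations(glasso_fit(S, lam)))
    off <- pc[upper.tri(pc)]
    if (!is.null(prev)) {
      expect_lte(mean(off), mean(prev) + 1e-10)
      expect_true(all(off <= prev + 5e-3))
    }
    prev <- off
  }
})

test_that("glasso estimator runs end to end and records the selected lambda", {
  set.seed(7)
  X <- matrix(rnorm(60 * 4), 60, 4)
  spec <- window_spec(width_tr = 30, estimator = "glasso",
                      lambda_grid = c(0.05, 0.2, 0.6),
                      n_regularization_repeats = 3)
  wfc <- estimate_windowed_fc(X, spec, seed = 1)
  expect_true(wfc$lambda %in% spec$lambda_grid)
  expect_equal(dim(wfc$fc), c(30, 6))
  expect_true(all(is.finite(wfc$fc)))
})

test_that("windowed estimates concentrate as the window grows (noise-free single state)", {
  cfg <- function(T) synthetic_config(
    n_components = 5, n_states = 1, n_volumes = T, noise_sd = 0,
    groups = list(G = list(n_subjects = 1,
                           transition_matrix = matrix(1, 1, 1))),
    profiles = "hyper", seed = 10)
  sim <- simulate_cohort(cfg(3000))
  X <- sim$cohort$subjects[[1]]$timecourses
  Sigma <- sim$truth$covariances[[1]]
  r_true <- t(stats::cov2cor(Sigma))[lower.tri(Sigma)]
  mae <- vapply(c(20, 80, 320), function(W) {
    spec <- window_spec(width_tr = W, taper_sigma_tr = W / 8,
                        fisher_z = FALSE)
    wfc <- estimate_windowed_fc(X, spec)
    mean(abs(sweep(wfc$fc, 2, r_true)))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})
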