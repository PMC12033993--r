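#' Graphical lasso: L1-regularized inverse covariance estimation
#'
#' Block coordinate descent over the columns of the covariance estimate
#' (Friedman-style), with an inner coordinate-descent lasso for each
#' column subproblem. At lambda = 0 the precision matrix is the direct
#' inverse of the input covariance; at lambda >= max |off-diagonal of S|
#' the solution is exactly diagonal, so all partial correlations vanish.
#'
#' @name glasso
NULL

#' Fit a graphical lasso precision matrix
#'
#' Minimizes -log det(Theta) + tr(S Theta) + lambda * ||Theta||_1,off over
#' positive-definite Theta.
#'
#' @param S symmetric covariance matrix (C x C)
#' @param lambda nonnegative L1 penalty on off-diagonal entries
#' @param tol relative convergence tolerance on the working covariance
#' @param max_iter maximum outer sweeps
#' @return precision matrix Theta (C x C, symmetric)
#' @export
glasso_fit <- function(S, lambda, tol = 1e-8, max_iter = 200L) {
  S <- as.matrix(S)
  C <- nrow(S)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    stop("S must be symmetric")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (lambda == 0) {
    Theta <- tryCatch(solve(S), error = function(e)
      stop("covariance is singular; glasso at lambda = 0 requires a ",
           "well-conditioned matrix"))
    return((Theta + t(Theta)) / 2)
  }
  if (C == 1L) return(matrix(1 / S[1, 1], 1, 1))
  W <- S                     # off-diagonal penalty only: diag(W) = diag(S)
  B <- matrix(0, C - 1L, C)           # lasso coefficients per column
  off <- abs(S[upper.tri(S)])
  thr <- tol * max(mean(off), .Machine$double.eps)
  for (iter in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(C)) {
      idx <- setdiff(seq_len(C), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- .lasso_cd(W11, s12, lambda, B[, j])
      B[, j] <- beta
      w12 <- W11 %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)[upper.tri(W)]) < thr) break
  }
  Theta <- matrix(0, C, C)
  for (j in seq_len(C)) {
    idx <- setdiff(seq_len(C), j)
    beta <- B[, j]
    denom <- W[j, j] - sum(W[idx, j] * beta)
    t22 <- 1 / denom
    Theta[j, j] <- t22
    Theta[idx, j] <- -beta * t22
  }
  (Theta + t(Theta)) / 2
}

# Coordinate-descent lasso for 0.5 b' W11 b - s12' b + lambda |b|_1.
.lasso_cd <- function(W11, s12, lambda, beta0,
                      tol = 1e-10, max_iter = 1000L) {
  p <- length(s12)
  beta <- beta0
  grad_cache <- W11 %*% beta
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (k in seq_len(p)) {
      r_k <- s12[k] - grad_cache[k] + W11[k, k] * beta[k]
      bnew <- .soft_threshold(r_k, lambda) / W11[k, k]
      d <- bnew - beta[k]
      if (d != 0) {
        grad_cache <- grad_cache + W11[, k] * d
        beta[k] <- bnew
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) break
  }
  beta
}

.soft_threshold <- function(x, t) sign(x) * max(abs(x) - t, 0)

#' Partial correlations from a precision matrix
#'
#' rho_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj); unit diagonal.
#'
#' @param Theta precision matrix
#' @return partial correlation matrix
#' @export
partial_correlations <- function(Theta) {
  d <- sqrt(diag(Theta))
  R <- -Theta / tcrossprod(d)
  diag(R) <- 1
  R
}

#' Select the glasso regularization strength for one subject
#'
#' For each lambda on the grid, the mean held-out Gaussian log-likelihood
#' log det(Theta) - tr(S_test Theta) is computed over repeated random
#' 80/20 splits of the subject's windows: Theta is fitted to the mean
#' covariance of the training windows and scored on the mean covariance
#' of the held-out windows. The lambda with the best mean score wins.
#' A lambda whose fit fails is dropped with a warning; an error is raised
#' only if every lambda fails.
#'
#' @param window_covs C x C x N_w array of per-window covariances
#' @param lambda_grid candidate penalties
#' @param n_repeats number of random splits
#' @param seed seed for the splits
#' @return selected lambda (scalar)
#' @export
select_glasso_lambda <- function(window_covs, lambda_grid,
                                 n_repeats = 10L, seed = 1L) {
  Nw <- dim(window_covs)[3]
  if (Nw < 2) return(lambda_grid[1])
  set.seed(seed)
  n_train <- max(1L, floor(0.8 * Nw))
  splits <- lapply(seq_len(n_repeats), function(r) sample.int(Nw, n_train))
  scores <- vapply(lambda_grid, function(lam) {
    ll <- vapply(splits, function(tr) {
      te <- setdiff(seq_len(Nw), tr)
      S_tr <- apply(window_covs[, , tr, drop = FALSE], c(1, 2), mean)
      S_te <- apply(window_covs[, , te, drop = FALSE], c(1, 2), mean)
      Theta <- tryCatch(glasso_fit(S_tr, lam), error = function(e) NULL)
      if (is.null(Theta)) return(NA_real_)
      determinant(Theta, logarithm = TRUE)$modulus - sum(S_te * Theta)
    }, numeric(1))
    mean(ll)
  }, numeric(1))
  if (all(is.na(scores)))
    stop("glasso failed to converge at every lambda on the grid")
  if (anyNA(scores))
    warning("dropping ", sum(is.na(scores)),
            " lambda value(s) with failed glasso fits")
  lambda_grid[which.max(scores)]
}
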