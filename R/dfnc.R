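#' Windowed functional connectivity estimation
#'
#' Gaussian-tapered sliding-window FC: each window's columns are centered
#' with the taper weights, a weighted covariance is formed, and either a
#' weighted Pearson correlation or an L1-regularized inverse covariance
#' (graphical lasso, reported as partial correlations) is extracted and
#' vectorized over the upper triangle.
#'
#' @name dfnc
NULL

#' Sliding-window specification
#'
#' Defaults follow common dFNC practice for 2-s TR resting-state data: a
#' 26-TR window advanced 1 TR, tapered by a rectangle convolved with a
#' Gaussian of sigma 3 TR, and Fisher z-transformed connectivity values.
#'
#' @param width_tr window width W in TR units
#' @param step_tr window advancement per step, in TR units
#' @param taper_sigma_tr Gaussian taper standard deviation in TR units
#' @param estimator "pearson" (tapered weighted correlation) or "glasso"
#'   (L1-regularized inverse covariance -> partial correlations)
#' @param lambda_grid regularization grid for the glasso estimator
#' @param n_regularization_repeats number of random 80/20 window splits
#'   used to pick the regularization strength per subject
#' @param fisher_z apply the Fisher z-transform to connectivity values
#' @return object of class `window_spec`
#' @export
window_spec <- function(width_tr = 26L, step_tr = 1L, taper_sigma_tr = 3,
                        estimator = c("pearson", "glasso"),
                        lambda_grid = exp(seq(log(0.01), log(1),
                                              length.out = 10)),
                        n_regularization_repeats = 10L,
                        fisher_z = TRUE) {
  estimator <- match.arg(estimator)
  stopifnot(width_tr >= 1, step_tr >= 1, taper_sigma_tr > 0,
            n_regularization_repeats >= 1)
  if (estimator == "glasso" && length(lambda_grid) == 0)
    stop("lambda_grid must be nonempty for the glasso estimator")
  if (any(lambda_grid < 0)) stop("lambda_grid must be nonnegative")
  structure(list(width_tr = as.integer(width_tr),
                 step_tr = as.integer(step_tr),
                 taper_sigma_tr = taper_sigma_tr,
                 estimator = estimator,
                 lambda_grid = lambda_grid,
                 n_regularization_repeats =
                   as.integer(n_regularization_repeats),
                 fisher_z = fisher_z),
            class = "window_spec")
}

#' Gaussian-tapered window weights
#'
#' A rectangular window of the given width is discretely convolved with a
#' unit-area Gaussian kernel (standard deviation `sigma`, truncated at
#' +/- 4 sigma); the central `width` samples are kept and renormalized to
#' sum 1. As sigma -> 0 the taper approaches the uniform window.
#'
#' @param width window length in samples (>= 1)
#' @param sigma Gaussian standard deviation in samples (> 0)
#' @return nonnegative symmetric weight vector of length `width`, sum 1
#' @export
build_taper <- function(width, sigma) {
  stopifnot(width >= 1, sigma > 0)
  R <- ceiling(4 * sigma)
  kern <- stats::dnorm(seq(-R, R), sd = sigma)
  kern <- kern / sum(kern)
  rect <- rep(1, width)
  # full discrete convolution, length width + 2R
  full <- stats::convolve(rect, rev(kern), type = "open")
  w <- full[(R + 1):(R + width)]
  # enforce exact symmetry against convolution round-off
  w <- (w + rev(w)) / 2
  w / sum(w)
}

#' Sliding-window start indices
#'
#' 0-based, half-open window semantics: window i covers volumes
#' [start_i, start_i + width). Under the adopted convention the final
#' window that would start at T - W is dropped, so a 196-volume series
#' with a 26-TR window advanced 1 TR yields 170 windows.
#'
#' @param n_volumes series length T
#' @param width window width W (<= n_volumes)
#' @param step advancement per window
#' @return list with `n` (window count) and `starts` (0-based integers)
#' @export
sliding_windows <- function(n_volumes, width, step = 1L) {
  if (width > n_volumes)
    stop("window width (", width, ") exceeds series length (", n_volumes, ")")
  stopifnot(step >= 1)
  last <- n_volumes - 1L - width       # last admissible start
  if (last < 0)
    stop("no admissible windows: need n_volumes > width under the ",
         "T - W window-count convention")
  starts <- seq.int(0L, last, by = step)
  list(n = length(starts), starts = as.integer(starts))
}

#' Estimate windowed functional connectivity for one subject
#'
#' For each window the columns are centered with the taper-weighted mean,
#' a taper-weighted covariance is computed, and connectivity is extracted
#' with the chosen estimator. The glasso path selects one regularization
#' strength per subject by repeated 80/20 subsampling of the subject's
#' windows (fit on the mean training-window covariance, score mean
#' held-out covariance by Gaussian log-likelihood), then applies it to
#' every window and reports partial correlations
#' rho_ij = -Theta_ij / sqrt(Theta_ii Theta_jj).
#'
#' @param timecourses T x C numeric matrix (no missing values)
#' @param spec a `window_spec`
#' @param subject_id identifier used in messages and output
#' @param seed seed for the regularization subsampling
#' @return object of class `windowed_fc`: `fc` (N_w x P matrix; P =
#'   C(C-1)/2 row-major upper-triangle pairs, 0-based i < j), `starts`,
#'   `pairs`, `estimator`, `lambda`, `spec`, `subject_id`
#' @export
estimate_windowed_fc <- function(timecourses, spec = window_spec(),
                                 subject_id = "subject", seed = 1L) {
  X <- as.matrix(timecourses)
  if (anyNA(X)) stop("missing values in time courses of ", subject_id)
  Tn <- nrow(X); C <- ncol(X)
  if (C < 2) stop("need at least 2 components")
  win <- sliding_windows(Tn, spec$width_tr, spec$step_tr)
  w <- build_taper(spec$width_tr, spec$taper_sigma_tr)
  covs <- array(0, c(C, C, win$n))
  for (i in seq_len(win$n)) {
    rows <- (win$starts[i] + 1L):(win$starts[i] + spec$width_tr)
    Xw <- X[rows, , drop = FALSE]
    mu <- colSums(w * Xw)
    Xc <- sweep(Xw, 2L, mu)
    S <- crossprod(Xc, w * Xc)
    v <- diag(S)
    if (any(v <= 0)) {
      bad <- which(v <= 0)[1]
      stop(sprintf(
        "zero-variance column %d in window %d (start %d) of subject %s",
        bad, i, win$starts[i], subject_id))
    }
    covs[, , i] <- S
  }
  lambda <- NA_real_
  pairs <- .upper_pairs(C)
  P <- nrow(pairs)
  fc <- matrix(NA_real_, win$n, P)
  if (spec$estimator == "pearson") {
    for (i in seq_len(win$n)) {
      R <- stats::cov2cor(covs[, , i])
      fc[i, ] <- .vec_upper(R, pairs)
    }
  } else {
    lambda <- select_glasso_lambda(covs, spec$lambda_grid,
                                   spec$n_regularization_repeats,
                                   seed = seed)
    for (i in seq_len(win$n)) {
      Theta <- glasso_fit(covs[, , i], lambda)
      fc[i, ] <- .vec_upper(partial_correlations(Theta), pairs)
    }
  }
  if (spec$fisher_z) fc <- fisher_z(fc)
  structure(list(subject_id = subject_id, fc = fc,
                 starts = win$starts, pairs = pairs,
                 estimator = spec$estimator, lambda = lambda,
                 spec = spec),
            class = "windowed_fc")
}

# Row-major upper-triangle pair table (0-based, i < j).
.upper_pairs <- function(C) {
  idx <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cbind(i = idx[, 1] - 1L, j = idx[, 2] - 1L)
}

.vec_upper <- function(M, pairs) {
  M[cbind(pairs[, "i"] + 1L, pairs[, "j"] + 1L)]
}

#' Fisher z-transform with clipping
#'
#' atanh applied after clipping magnitudes at 1 - 1e-7 so that values at
#' the correlation boundary remain finite.
#'
#' @param r numeric vector/matrix of correlations
#' @return transformed values, same shape
#' @export
fisher_z <- function(r) {
  atanh(pmax(pmin(r, 1 - 1e-7), -1 + 1e-7))
}

#' Read a windowed-FC series written by [write_windowed_fc()]
#'
#' @param dir directory holding `<subject_id>_fc.csv` and its JSON sidecar
#' @param subject_id subject identifier
#' @return a `windowed_fc`
#' @export
read_windowed_fc <- function(dir, subject_id) {
  csv <- file.path(dir, paste0(subject_id, "_fc.csv"))
  js <- file.path(dir, paste0(subject_id, "_fc.json"))
  if (!file.exists(csv) || !file.exists(js))
    stop("windowed FC files for ", subject_id, " not found in ", dir)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  fc <- as.matrix(utils::read.csv(csv, header = FALSE))
  dimnames(fc) <- NULL
  pairs <- as.matrix(meta$pairs)
  structure(list(subject_id = meta$subject_id, fc = fc,
                 starts = as.integer(meta$window_starts),
                 pairs = pairs,
                 estimator = meta$estimator,
                 lambda = if (is.null(meta$lambda)) NA_real_ else
                   meta$lambda,
                 spec = do.call(window_spec, meta$spec[
                   setdiff(names(meta$spec), character(0))])),
            class = "windowed_fc")
}

#' Write a windowed-FC series as CSV plus a JSON sidecar
#'
#' @param wfc a `windowed_fc`
#' @param dir output directory
#' @return CSV path, invisibly
#' @export
write_windowed_fc <- function(wfc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(dir, paste0(wfc$subject_id, "_fc.csv"))
  utils::write.table(wfc$fc, f, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(subject_id = wfc$subject_id,
         window_starts = wfc$starts,
         pairs = as.data.frame(wfc$pairs),
         estimator = wfc$estimator,
         lambda = wfc$lambda,
         spec = unclass(wfc$spec)),
    file.path(dir, paste0(wfc$subject_id, "_fc.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(f)
}
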