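#' Synthetic dFNC cohort generation
#'
#' Generates cohorts of multivariate component time courses whose
#' instantaneous covariance switches among a small number of latent
#' connectivity states according to group-specific first-order Markov
#' chains. Every downstream stage (windowed FC, state clustering, pattern
#' mining, classification) can then be validated against the known hidden
#' state paths and generating covariances.
#'
#' @name synthetic
NULL

# Deterministic per-subject substream: subject i draws from the same seed
# regardless of cohort composition.
.subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1299709 + 7919 * as.numeric(i)) %% 2147483647L)
}

#' Construct state covariance (correlation) matrices with named profiles
#'
#' Builds one symmetric positive-definite correlation matrix per latent
#' state. Profiles mirror the qualitative state phenotypes reported for
#' resting-state dFNC: a sparsely connected ("hypo") state, a globally
#' coupled ("hyper") state, and a state with two anticorrelated blocks of
#' networks.
#'
#' @param n_components number of network components C (>= 2)
#' @param n_states number of latent states
#' @param profiles character vector, one of "hypo", "hyper",
#'   "anticorrelated-block" per state (recycled if length 1)
#' @param seed integer seed
#' @return list of `n_states` C x C SPD correlation matrices
#' @export
make_state_covariances <- function(n_components, n_states,
                                   profiles = c("hypo", "hyper",
                                                "anticorrelated-block"),
                                   seed = 1L) {
  if (n_components < 2) stop("n_components must be >= 2")
  if (n_states < 1) stop("n_states must be >= 1")
  profiles <- match.arg(profiles,
                        c("hypo", "hyper", "anticorrelated-block"),
                        several.ok = TRUE)
  if (length(profiles) == 1L) profiles <- rep(profiles, n_states)
  if (length(profiles) != n_states)
    stop("need one profile per state")
  set.seed(seed)
  lapply(profiles, function(p) .state_cov_profile(n_components, p))
}

.state_cov_profile <- function(C, profile) {
  if (profile == "hypo") {
    # near-diagonal: weak random couplings, |r| <= 0.1
    amp <- 0.08
    repeat {
      E <- matrix(0, C, C)
      E[upper.tri(E)] <- stats::runif(C * (C - 1) / 2, -amp, amp)
      E <- E + t(E)
      S <- diag(C) + E
      if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0.05)
        return(S)
      amp <- amp / 2 # retry with smaller jitter; always terminates
    }
  }
  if (profile == "hyper") {
    # one-factor model with positive loadings: SPD by construction,
    # mean off-diagonal correlation ~ 0.55 (>= 0.4)
    l <- sqrt(0.55) + stats::runif(C, -0.04, 0.04)
    S <- tcrossprod(l)
    diag(S) <- 1
    return(S)
  }
  # anticorrelated-block: one-factor model with signed loadings; the two
  # sign blocks are positively coupled within and anticorrelated across
  half <- floor(C / 2)
  sgn <- c(rep(1, C - half), rep(-1, half))
  l <- sgn * (sqrt(0.45) + stats::runif(C, -0.03, 0.03))
  S <- tcrossprod(l)
  diag(S) <- 1
  S
}

#' Simulate a latent state path from a first-order Markov chain
#'
#' The initial state is drawn from the chain's stationary distribution so
#' that occupancy statistics are unbiased from the first volume.
#'
#' @param transition_matrix k x k row-stochastic matrix
#' @param length path length (>= 1)
#' @param seed integer seed
#' @return integer vector of states in 1..k
#' @export
simulate_state_sequence <- function(transition_matrix, length, seed = 1L) {
  P <- as.matrix(transition_matrix)
  .validate_transition_matrix(P)
  if (length < 1) stop("length must be >= 1")
  k <- nrow(P)
  set.seed(seed)
  pi0 <- stationary_distribution(P)
  path <- integer(length)
  path[1] <- sample.int(k, 1, prob = pi0)
  if (length > 1) {
    u <- stats::runif(length - 1)
    cums <- t(apply(P, 1, cumsum))
    for (t in 2:length) {
      path[t] <- findInterval(u[t - 1], cums[path[t - 1], ],
                              left.open = TRUE) + 1L
    }
  }
  path
}

.validate_transition_matrix <- function(P, tol = 1e-8) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("transition matrix must be square")
  if (any(P < -tol) || any(P > 1 + tol))
    stop("transition probabilities must lie in [0, 1]")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol))
    stop("transition matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  invisible(TRUE)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized
#' to sum 1. For reducible chains (e.g. the identity) one valid stationary
#' vector is returned.
#'
#' @param P row-stochastic matrix
#' @return probability vector of length nrow(P)
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the acquisition geometry of a resting-state study with
#' 11 network component time courses of 196 volumes at TR = 2 s, switching
#' among 3 latent connectivity states. The default two-group dynamics give
#' the impaired-like group a strong bias toward the hypo-connected state
#' (elevated self-transition and inflow), a qualitative analogue of
#' impaired cohorts dwelling longer in sparsely connected states.
#'
#' @param n_components number of components C
#' @param n_states number of latent states
#' @param n_volumes volumes per subject T
#' @param tr_seconds repetition time in seconds
#' @param groups named list: for each group label a list with `n_subjects`
#'   and `transition_matrix` (k x k row-stochastic)
#' @param profiles covariance profile per state
#' @param noise_sd isotropic additive Gaussian noise sd
#' @param seed integer master seed
#' @param motif_injection optional list of lists with fields `group`,
#'   `motif` (state labels), `prob` (per-subject insertion probability) and
#'   optionally `hold_volumes` (volumes each motif state is held; default 30)
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(n_components = 11L,
                             n_states = 3L,
                             n_volumes = 196L,
                             tr_seconds = 2.0,
                             groups = default_groups(),
                             profiles = c("hypo", "hyper",
                                          "anticorrelated-block"),
                             noise_sd = 0.2,
                             seed = 1L,
                             motif_injection = NULL) {
  stopifnot(n_components >= 2, n_states >= 1, n_volumes > 0,
            tr_seconds > 0, noise_sd >= 0)
  for (g in groups) {
    .validate_transition_matrix(g$transition_matrix, tol = 1e-12)
    if (nrow(g$transition_matrix) != n_states)
      stop("group transition matrix dimension must equal n_states")
    if (g$n_subjects < 0) stop("n_subjects must be >= 0")
  }
  if (!is.null(motif_injection)) {
    for (m in motif_injection) {
      if (!m$group %in% names(groups)) stop("motif group not in groups")
      if (any(m$motif < 1 | m$motif > n_states))
        stop("motif states out of range")
      if (m$prob < 0 || m$prob > 1) stop("motif prob must be in [0,1]")
    }
  }
  structure(list(n_components = as.integer(n_components),
                 n_states = as.integer(n_states),
                 n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds,
                 groups = groups,
                 profiles = profiles,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 motif_injection = motif_injection),
            class = "synthetic_config")
}

#' Default two-group Markov dynamics
#'
#' A control-like group ("HC") visits all states with moderate persistence
#' (self-transition 0.97 at volume resolution, i.e. mean dwell ~ 33 volumes
#' = 66 s at TR = 2 s) and uniform occupancy; an impaired-like group ("PD")
#' has an elevated self-transition for the hypo-connected state 1 and
#' increased inflow into it, so its occupancy is biased toward state 1.
#'
#' @param n_hc,n_pd subjects per group
#' @return named list of group specifications
#' @export
default_groups <- function(n_hc = 15L, n_pd = 15L) {
  hc <- matrix(c(0.970, 0.015, 0.015,
                 0.015, 0.970, 0.015,
                 0.015, 0.015, 0.970), 3, 3, byrow = TRUE)
  pd <- matrix(c(0.990, 0.005, 0.005,
                 0.040, 0.950, 0.010,
                 0.040, 0.010, 0.950), 3, 3, byrow = TRUE)
  list(HC = list(n_subjects = as.integer(n_hc), transition_matrix = hc),
       PD = list(n_subjects = as.integer(n_pd), transition_matrix = pd))
}

#' Simulate a cohort of state-switching time courses
#'
#' Per subject, row t of the T x C matrix is drawn from a zero-mean
#' multivariate normal with the covariance of the hidden state at volume t,
#' plus isotropic Gaussian noise. Rows are independent given the hidden
#' path; the path is simulated at volume resolution so sliding windows
#' genuinely mix states around transitions. Fully reproducible from the
#' config seed, and subject i is identical regardless of cohort size.
#'
#' @param config a `synthetic_config`
#' @return list with elements `cohort` (class `dfnc_cohort`: subjects with
#'   id, group, tr_seconds, timecourses) and `truth` (class
#'   `dfnc_ground_truth`: state paths, covariances, groups, motif records)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  covs <- make_state_covariances(config$n_components, config$n_states,
                                 config$profiles, seed = config$seed)
  chols <- lapply(covs, chol)
  subjects <- list()
  paths <- list()
  groups_per_subject <- character(0)
  motif_records <- list()
  idx <- 0L
  for (glab in names(config$groups)) {
    g <- config$groups[[glab]]
    if (g$n_subjects == 0L) next
    minj <- NULL
    if (!is.null(config$motif_injection)) {
      for (m in config$motif_injection) if (m$group == glab) minj <- m
    }
    for (j in seq_len(g$n_subjects)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%03d", glab, j)
      sseed <- .subject_seed(config$seed, idx)
      path <- simulate_state_sequence(g$transition_matrix,
                                      config$n_volumes, seed = sseed)
      set.seed(sseed + 1L)
      inserted <- NULL
      if (!is.null(minj) && stats::runif(1) < minj$prob) {
        hold <- if (is.null(minj$hold_volumes)) 30L else
          as.integer(minj$hold_volumes)
        block <- rep(as.integer(minj$motif), each = hold)
        if (length(block) < config$n_volumes) {
          pos <- sample.int(config$n_volumes - length(block) + 1L, 1)
          path[pos:(pos + length(block) - 1L)] <- block
          inserted <- list(subject = sid, position = pos,
                           motif = as.integer(minj$motif))
        }
      }
      Z <- matrix(stats::rnorm(config$n_volumes * config$n_components),
                  config$n_volumes, config$n_components)
      X <- matrix(0, config$n_volumes, config$n_components)
      for (s in seq_len(config$n_states)) {
        rows <- which(path == s)
        if (length(rows))
          X[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[s]]
      }
      if (config$noise_sd > 0)
        X <- X + config$noise_sd *
          matrix(stats::rnorm(length(X)), nrow(X), ncol(X))
      subjects[[sid]] <- list(subject_id = sid, group = glab,
                              tr_seconds = config$tr_seconds,
                              timecourses = X)
      paths[[sid]] <- path
      groups_per_subject[sid] <- glab
      if (!is.null(inserted)) motif_records[[sid]] <- inserted
    }
  }
  cohort <- structure(list(subjects = subjects, config = config),
                      class = "dfnc_cohort")
  truth <- structure(list(state_paths = paths,
                          covariances = covs,
                          groups = groups_per_subject,
                          motifs = motif_records),
                     class = "dfnc_ground_truth")
  list(cohort = cohort, truth = truth)
}

#' @export
print.dfnc_cohort <- function(x, ...) {
  n <- length(x$subjects)
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("dFNC cohort: %d subjects (%s), T = %d, C = %d, TR = %g s\n",
              n, paste(names(tab), tab, sep = "=", collapse = ", "),
              x$config$n_volumes, x$config$n_components,
              x$config$tr_seconds))
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' Per-subject headerless numeric CSV (T rows x C columns), a manifest CSV
#' (subject_id, group, tr_seconds, path) and, when ground truth is given,
#' a JSON file with hidden paths and generating covariances.
#'
#' @param cohort a `dfnc_cohort`
#' @param dir output directory (created if missing)
#' @param truth optional `dfnc_ground_truth`
#' @return path to the manifest CSV, invisibly
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    f <- file.path(dir, paste0(s$subject_id, ".csv"))
    utils::write.table(s$timecourses, f, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    data.frame(subject_id = s$subject_id, group = s$group,
               tr_seconds = s$tr_seconds, path = f,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(state_paths = truth$state_paths,
           covariances = truth$covariances,
           groups = as.list(truth$groups),
           motifs = truth$motifs),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(mf)
}

#' Read a cohort from a manifest CSV
#'
#' @param manifest_path path to a manifest CSV with columns subject_id,
#'   group, tr_seconds, path
#' @return a `dfnc_cohort`
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "tr_seconds", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  missing <- man$path[!file.exists(man$path)]
  if (length(missing))
    stop("manifest references missing files: ",
         paste(missing, collapse = ", "))
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    X <- as.matrix(utils::read.csv(man$path[i], header = FALSE))
    dimnames(X) <- NULL
    list(subject_id = man$subject_id[i], group = man$group[i],
         tr_seconds = man$tr_seconds[i], timecourses = X)
  })
  names(subjects) <- man$subject_id
  structure(list(subjects = subjects, config = NULL),
            class = "dfnc_cohort")
}
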