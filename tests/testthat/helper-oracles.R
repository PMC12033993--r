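# Independent oracles used across the suite. Each is deliberately naive
# (brute force / direct enumeration) and shares no code path with the
# implementation it checks.

# Full discrete convolution of a rectangle with a truncated Gaussian,
# cropped and renormalized -- double loop, no convolve().
brute_taper <- function(width, sigma) {
  R <- ceiling(4 * sigma)
  kern <- exp(-(seq(-R, R))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  rect <- rep(1, width)
  full <- numeric(width + 2 * R)
  for (i in seq_len(width))
    for (j in seq_along(kern))
      full[i + j - 1] <- full[i + j - 1] + rect[i] * kern[j]
  w <- full[(R + 1):(R + width)]
  w / sum(w)
}

# Subsequence containment by exhaustive index search (recursive, no greedy
# shortcut).
brute_contains <- function(sequence, pattern) {
  search <- function(si, pi) {
    if (pi > length(pattern)) return(TRUE)
    if (si > length(sequence)) return(FALSE)
    for (s in si:length(sequence)) {
      if (sequence[s] == pattern[pi] && search(s + 1L, pi + 1L))
        return(TRUE)
    }
    FALSE
  }
  search(1L, 1L)
}

# Brute-force sequential pattern miner: enumerate every distinct
# subsequence of every sequence (index combinations), then count
# sequence-level support. Returns named integer vector keyed by the
# "a-b-c" pattern string.
brute_mine <- function(seqs, threshold, min_length, max_length) {
  per_seq <- lapply(seqs, function(s) {
    keys <- character(0)
    n <- length(s)
    for (l in seq(min_length, min(max_length, n))) {
      idx <- utils::combn(n, l)
      keys <- c(keys, unique(apply(idx, 2, function(ii)
        paste(s[ii], collapse = "-"))))
    }
    unique(keys)
  })
  tab <- table(unlist(per_seq))
  out <- tab[tab >= threshold]
  stats::setNames(as.integer(out), names(out))
}

# Majority hidden state of each sliding window, from a ground-truth
# volume-resolution path (T - W convention, step 1).
window_majority_states <- function(path, width, k) {
  n_w <- length(path) - width
  vapply(seq_len(n_w), function(i)
    which.max(tabulate(path[i:(i + width - 1)], k)), integer(1))
}

# Pooled per-window ground-truth labels for a whole cohort, in the same
# subject order as `sequences`.
cohort_truth_labels <- function(truth, subject_ids, width, k) {
  unlist(lapply(subject_ids, function(sid)
    window_majority_states(truth$state_paths[[sid]], width, k)))
}

# Small, quick synthetic cohort for pipeline-level tests.
tiny_cohort_config <- function(seed = 1, n_per_group = 3, T = 80) {
  synthetic_config(n_volumes = T, seed = seed,
                   groups = default_groups(n_per_group, n_per_group))
}

# Study condition for the end-to-end discrimination checks: a group-unique
# alternation between the hyper-connected and anticorrelated states,
# always injected, each motif state held longer than one window.
motif_condition <- function(seed) {
  list(
    synthetic = synthetic_config(
      seed = seed, groups = default_groups(25, 25),
      motif_injection = list(list(group = "PD", motif = c(2, 3, 2, 3),
                                  prob = 1.0, hold_volumes = 30))),
    mining = mining_spec(min_support = 0.4, max_length = 4),
    motif = c(2, 3, 2, 3))
}
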