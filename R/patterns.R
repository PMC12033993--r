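#' Sequential pattern mining over state sequences
#'
#' Mines all ordered label tuples (gaps allowed) contained in at least a
#' minimum-support fraction of a group's dominant-state sequences, by
#' depth-first prefix projection with antimonotone support pruning, and
#' partitions the two groups' pattern sets into unique and shared sets
#' (dichotomic pattern mining).
#'
#' @name pattern_mining
NULL

#' Collapse maximal runs of identical labels
#'
#' `[1,1,1,2,2,1] -> [1,2,1]`. Idempotent; the output never has two equal
#' adjacent labels, so patterns express the transition structure of the
#' sequence rather than its dwell durations.
#'
#' @param sequence nonempty integer label vector
#' @return compressed integer vector
#' @export
compress_runs <- function(sequence) {
  if (length(sequence) == 0) stop("empty sequence")
  rle(as.integer(sequence))$values
}

#' Subsequence containment with gaps allowed
#'
#' TRUE iff `pattern` occurs in `sequence` in order, not necessarily
#' contiguously. Greedy leftmost matching, which is exact for
#' subsequence containment.
#'
#' @param sequence integer label vector
#' @param pattern nonempty integer label vector
#' @return logical scalar
#' @export
contains_pattern <- function(sequence, pattern) {
  if (length(pattern) == 0) stop("empty pattern")
  i <- 1L
  np <- length(pattern)
  for (s in sequence) {
    if (s == pattern[i]) {
      if (i == np) return(TRUE)
      i <- i + 1L
    }
  }
  FALSE
}

#' Mining specification
#'
#' @param min_support minimum fraction of a group's sequences that must
#'   contain a pattern, in (0, 1]
#' @param min_length minimum pattern length (a single state is not a
#'   sequential pattern, so the default is 2)
#' @param max_length maximum pattern length
#' @param compress_runs collapse dwell runs before mining (default TRUE)
#' @return object of class `mining_spec`
#' @export
mining_spec <- function(min_support = 0.05, min_length = 2L,
                        max_length = 10L, compress_runs = TRUE) {
  stopifnot(min_support > 0, min_support <= 1,
            min_length >= 1, min_length <= max_length)
  structure(list(min_support = min_support,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 compress_runs = isTRUE(compress_runs)),
            class = "mining_spec")
}

#' Mine frequent sequential patterns from a group of sequences
#'
#' Returns exactly the patterns p with `min_length <= |p| <= max_length`
#' contained (gaps allowed) in at least `ceiling(min_support * n)` of the
#' n sequences. Support is sequence-level: a sequence counts once however
#' many occurrences it holds. Enumeration is depth-first prefix
#' projection; supports are exact; output is ordered by length then
#' lexicographically.
#'
#' @param sequences list of integer label vectors (or `state_sequence`s)
#' @param spec a `mining_spec`
#' @return object of class `pattern_set`: `patterns` (list of integer
#'   vectors), `support` (integer vector), `n_sequences`, `threshold`,
#'   `spec`
#' @export
mine_patterns <- function(sequences, spec = mining_spec()) {
  stopifnot(inherits(spec, "mining_spec"))
  seqs <- lapply(sequences, function(s)
    if (inherits(s, "state_sequence")) s$labels else as.integer(s))
  if (length(seqs) == 0) stop("no sequences to mine")
  if (any(vapply(seqs, length, 1L) == 0)) stop("empty sequence in input")
  if (spec$compress_runs) seqs <- lapply(seqs, compress_runs)
  n <- length(seqs)
  threshold <- as.integer(ceiling(spec$min_support * n))
  if (threshold < 1)
    stop("support threshold below one sequence; increase min_support")
  alphabet <- sort(unique(unlist(seqs)))
  acc_items <- list(); acc_support <- integer(0)
  # projections: per live sequence, (sequence index, next search position)
  recurse <- function(prefix, proj_seq, proj_pos, parent_support) {
    for (a in alphabet) {
      new_seq <- integer(0); new_pos <- integer(0)
      for (t in seq_along(proj_seq)) {
        s <- seqs[[proj_seq[t]]]
        p0 <- proj_pos[t]
        if (p0 > length(s)) next
        hit <- which(s[p0:length(s)] == a)
        if (length(hit)) {
          new_seq <- c(new_seq, proj_seq[t])
          new_pos <- c(new_pos, p0 + hit[1])
        }
      }
      supp <- length(new_seq)
      # antimonotonicity: an extension can never gain support
      stopifnot(supp <= parent_support)
      if (supp >= threshold) {
        pat <- c(prefix, a)
        if (length(pat) >= spec$min_length) {
          acc_items[[length(acc_items) + 1L]] <<- pat
          acc_support[length(acc_support) + 1L] <<- supp
        }
        if (length(pat) < spec$max_length)
          recurse(pat, new_seq, new_pos, supp)
      }
    }
  }
  recurse(integer(0), seq_len(n), rep(1L, n), n)
  ord <- order(lengths(acc_items),
               vapply(acc_items, function(p)
                 paste(sprintf("%09d", p), collapse = ","), ""))
  structure(list(patterns = acc_items[ord],
                 support = acc_support[ord],
                 n_sequences = n,
                 threshold = threshold,
                 spec = spec),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf(
    "pattern_set: %d patterns from %d sequences (threshold %d/%d, %s)\n",
    length(x$patterns), x$n_sequences, x$threshold, x$n_sequences,
    if (x$spec$compress_runs) "runs compressed" else "raw sequences"))
  invisible(x)
}

#' Render patterns as strings
#'
#' State labels joined with "-", e.g. `c(2, 1, 2)` becomes `"2-1-2"`.
#'
#' @param patterns list of integer vectors, or a `pattern_set`
#' @return character vector
#' @export
pattern_strings <- function(patterns) {
  if (inherits(patterns, "pattern_set")) patterns <- patterns$patterns
  vapply(patterns, paste, "", collapse = "-")
}

#' Dichotomic partition of two groups' pattern sets
#'
#' Patterns mined per group under the same specification are split by
#' exact item-tuple equality into those unique to group A, unique to
#' group B, and shared. The partition identity
#' |unique_A| + |unique_B| + |shared| = |A union B| is asserted on every
#' run.
#'
#' @param patterns_a,patterns_b `pattern_set`s mined with identical specs
#' @return object of class `dpm_result`: `unique_a`, `unique_b`, `shared`
#'   (data.frames with pattern, support_a, support_b), `counts`
#' @export
dichotomic_split <- function(patterns_a, patterns_b) {
  stopifnot(inherits(patterns_a, "pattern_set"),
            inherits(patterns_b, "pattern_set"))
  if (!identical(unclass(patterns_a$spec), unclass(patterns_b$spec)))
    stop("pattern sets were mined under different specifications")
  key_a <- pattern_strings(patterns_a)
  key_b <- pattern_strings(patterns_b)
  sup_a <- stats::setNames(patterns_a$support, key_a)
  sup_b <- stats::setNames(patterns_b$support, key_b)
  only_a <- setdiff(key_a, key_b)
  only_b <- setdiff(key_b, key_a)
  both <- intersect(key_a, key_b)
  mk <- function(keys) data.frame(
    pattern = keys,
    support_a = unname(sup_a[keys]),
    support_b = unname(sup_b[keys]),
    stringsAsFactors = FALSE)
  res <- structure(list(unique_a = mk(only_a),
                        unique_b = mk(only_b),
                        shared = mk(both),
                        counts = c(unique_a = length(only_a),
                                   unique_b = length(only_b),
                                   shared = length(both),
                                   total = length(union(key_a, key_b)))),
                   class = "dpm_result")
  stopifnot(sum(res$counts[c("unique_a", "unique_b", "shared")]) ==
              res$counts["total"])
  res
}

#' @export
print.dpm_result <- function(x, ...) {
  cat(sprintf(
    "dichotomic pattern partition: %d unique to A, %d unique to B, %d shared (%d total)\n",
    x$counts["unique_a"], x$counts["unique_b"], x$counts["shared"],
    x$counts["total"]))
  invisible(x)
}

#' Serialize a pattern set or DPM result to JSON
#'
#' @param x a `pattern_set` or `dpm_result`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_patterns_json <- function(x, path) {
  if (inherits(x, "pattern_set")) {
    obj <- list(
      patterns = lapply(seq_along(x$patterns), function(i)
        list(items = x$patterns[[i]], support = x$support[i])),
      n_sequences = x$n_sequences, threshold = x$threshold,
      spec = unclass(x$spec))
  } else if (inherits(x, "dpm_result")) {
    obj <- list(unique_a = x$unique_a, unique_b = x$unique_b,
                shared = x$shared, counts = as.list(x$counts))
  } else stop("unsupported object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
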