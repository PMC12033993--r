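test_that("run compression collapses dwell runs and is idempotent", {
  expect_equal(compress_runs(c(1, 1, 1, 2, 2, 1)), c(1, 2, 1))
  expect_equal(compress_runs(rep(3, 10)), 3L)
  set.seed(1)
  for (i in 1:50) {
    s <- sample.int(3, sample(1:30, 1), replace = TRUE)
    cs <- compress_runs(s)
    expect_false(any(cs[-1] == cs[-length(cs)]))
    expect_identical(compress_runs(cs), cs)
  }
  expect_error(compress_runs(integer(0)), "empty")
})

test_that("subsequence containment agrees with exhaustive index search", {
  expect_true(contains_pattern(c(2, 2, 1, 1, 2), c(2, 1, 2)))
  expect_false(contains_pattern(c(1, 2, 3), c(3, 1)))
  set.seed(2)
  for (i in 1:300) {
    s <- sample.int(3, sample(1:10, 1), replace = TRUE)
    p <- sample.int(3, sample(1:4, 1), replace = TRUE)
    expect_identical(contains_pattern(s, p), brute_contains(s, p))
  }
})

test_that("miner reproduces the worked three-sequence example exactly", {
  seqs <- list(c(1, 2, 1), c(1, 1, 2), c(2, 1))
  spec <- mining_spec(min_support = 2 / 3, compress_runs = FALSE)
  ps <- mine_patterns(seqs, spec)
  expect_equal(ps$threshold, 2L)
  got <- setNames(ps$support, pattern_strings(ps))
  expect_equal(got[order(names(got))],
               c("1-1" = 2L, "1-2" = 2L, "2-1" = 2L))
})

test_that("full support keeps only patterns contained in every sequence", {
  seqs <- list(c(1, 2, 3), c(1, 3, 2, 3), c(2, 1, 2, 3))
  ps <- mine_patterns(seqs, mining_spec(min_support = 1,
                                        compress_runs = FALSE))
  for (p in ps$patterns)
    for (s in seqs) expect_true(contains_pattern(s, p))
  has <- function(p) any(vapply(ps$patterns, identical, TRUE, y = p))
  expect_true(has(c(1L, 3L)))
  expect_false(has(c(3L, 1L))) # sequence [1,2,3] has no 1 after its 3
})

test_that("miner equals the brute-force enumerator on randomized instances", {
  set.seed(3)
  for (i in 1:60) {
    n <- sample(2:10, 1)
    seqs <- lapply(seq_len(n), function(j)
      sample.int(3, sample(2:12, 1), replace = TRUE))
    min_sup <- runif(1, 0.1, 0.8)
    max_len <- sample(3:6, 1)
    spec <- mining_spec(min_support = min_sup, min_length = 2,
                        max_length = max_len, compress_runs = FALSE)
    ps <- mine_patterns(seqs, spec)
    got <- setNames(ps$support, pattern_strings(ps))
    want <- brute_mine(seqs, ceiling(min_sup * n), 2, max_len)
    expect_identical(got[order(names(got))], want[order(names(want))],
                     info = sprintf("instance %d", i))
  }
})

test_that("every mined pattern satisfies its own support via containment", {
  set.seed(4)
  seqs <- lapply(1:12, function(i) sample.int(3, 40, replace = TRUE))
  spec <- mining_spec(min_support = 0.25, max_length = 5)
  ps <- mine_patterns(seqs, spec)
  comp <- lapply(seqs, compress_runs)
  for (j in seq_along(ps$patterns)) {
    n_contain <- sum(vapply(comp, contains_pattern, TRUE,
                            pattern = ps$patterns[[j]]))
    expect_equal(n_contain, ps$support[j])
    expect_gte(n_contain, ps$threshold)
  }
})

test_that("dichotomic split is exact set algebra with the partition identity", {
  mk <- function(pats, sup) structure(
    list(patterns = pats, support = sup, n_sequences = 10,
         threshold = 2L, spec = mining_spec()), class = "pattern_set")
  A <- mk(list(c(1L, 2L), c(2L, 1L), c(1L, 3L)), c(5L, 4L, 3L))
  B <- mk(list(c(2L, 1L), c(3L, 1L)), c(6L, 2L))
  res <- dichotomic_split(A, B)
  expect_setequal(res$unique_a$pattern, c("1-2", "1-3"))
  expect_equal(res$unique_b$pattern, "3-1")
  expect_equal(res$shared$pattern, "2-1")
  expect_equal(res$shared$support_a, 4L)
  expect_equal(res$shared$support_b, 6L)
  expect_equal(unname(res$counts["total"]), 4L)

  same <- dichotomic_split(A, A)
  expect_equal(nrow(same$unique_a), 0)
  expect_equal(nrow(same$unique_b), 0)
  expect_equal(unname(same$counts["shared"]), 3L)

  B2 <- mk(list(c(2L, 1L)), 3L)
  B2$spec <- mining_spec(min_support = 0.2)
  expect_error(dichotomic_split(A, B2), "different specifications")
})

test_that("partition identity holds for mined pattern sets on random data", {
  set.seed(5)
  for (i in 1:20) {
    sa <- lapply(1:6, function(j) sample.int(3, 30, replace = TRUE))
    sb <- lapply(1:6, function(j) sample.int(3, 30, replace = TRUE))
    spec <- mining_spec(min_support = 0.5, max_length = 4)
    res <- dichotomic_split(mine_patterns(sa, spec),
                            mine_patterns(sb, spec))
    expect_length(intersect(res$unique_a$pattern, res$unique_b$pattern), 0)
    expect_length(intersect(res$unique_a$pattern, res$shared$pattern), 0)
    expect_length(intersect(res$unique_b$pattern, res$shared$pattern), 0)
    expect_equal(unname(sum(res$counts[1:3])), unname(res$counts["total"]))
  }
})

test_that("pattern sets serialize to JSON and back", {
  seqs <- list(c(1, 2, 1, 3), c(1, 3, 2), c(2, 1, 3))
  ps <- mine_patterns(seqs, mining_spec(min_support = 0.6,
                                        compress_runs = FALSE))
  f <- withr::local_tempfile(fileext = ".json")
  write_patterns_json(ps, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(back$patterns), length(ps$patterns))
  expect_equal(back$threshold, ps$threshold)
})
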