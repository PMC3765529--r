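test_that("index engines reproduce the worked-example matches", {
  S <- worked_example_sequence()
  q <- worked_example_pattern()
  esa <- build_esa(S)
  for (fn in list(lesa_align, lgslink_align)) {
    m <- fn(q, esa, K = 5, d = 1)
    expect_equal(min(m$start), 16L)
    expect_equal(nrow(fn(q, esa, K = 1, d = 1)), 0L)
  }
})

test_that("suffix-link traversal marks and chains the expected ranks", {
  S <- worked_example_sequence()
  q <- worked_example_pattern()
  esa <- build_esa(S)
  m <- lgslink_align(q, esa, K = 1, d = 1, diagnostics = TRUE)
  ev <- attr(m, "events")
  # traversal starts at rank 1 (suffix S_14)
  expect_equal(ev$rank[ev$type == 1L][1L], 1L)
  # after the first early stop, the suffixes S_11 and S_7 are marked
  first_stop <- which(ev$type == 4L)[1L]
  marks <- ev$rank[ev$type == 3L & seq_len(nrow(ev)) > first_stop]
  expect_equal(marks[1:2], c(esa$isuf[11L], esa$isuf[7L]))
  # the suffix-link chain visits ranks 12, 8, 4, 18, 19 and then stops
  # because the next suffix is shorter than m - d
  expect_equal(ev$rank[ev$type == 2L], c(12L, 8L, 4L, 18L, 19L))
})

test_that("no rank is processed twice and marked ranks never match", {
  S <- worked_example_sequence()
  q <- worked_example_pattern()
  esa <- build_esa(S)
  for (K in c(1, 5)) {
    m <- lgslink_align(q, esa, K = K, d = 1, diagnostics = TRUE)
    ev <- attr(m, "events")
    processed <- ev$rank[ev$type %in% c(1L, 2L)]
    expect_false(any(duplicated(processed)))
    # substring/prefix-marked ranks provably contain no match
    for (rk in ev$rank[ev$type == 3L]) {
      sp <- esa$suf[rk]
      pdepth <- min(length(q) + 1L, esa$n - sp + 1L)
      if (pdepth < length(q) - 1L) next
      fr <- dp_final_row(semiglobal_dp(q, substr(S, sp, sp + pdepth - 1L)))
      lo <- length(q) - 1L
      for (pp in lo:pdepth) {
        ok <- fr["cost", pp + 1L] > K + 1e-9 || fr["indels", pp + 1L] > 1 + 1e-9
        expect_true(ok, info = paste("rank", rk, "length", pp))
      }
    }
  }
})

test_that("all four engines report identical match sets on random instances", {
  for (seed in 1:30) {
    inst <- random_search_instance(seed + 100L, nmax = 400L)
    esa <- build_esa(inst$s)
    keys <- c(
      match_key(scan_align(inst$q, inst$s, inst$K, inst$d)),
      match_key(lscan_align(inst$q, inst$s, inst$K, inst$d)),
      match_key(lesa_align(inst$q, esa, inst$K, inst$d)),
      match_key(lgslink_align(inst$q, esa, inst$K, inst$d)))
    expect_equal(length(unique(keys)), 1L, info = paste("seed", seed))
  }
})

test_that("index search is complete against the naive windowed oracle", {
  for (seed in c(3, 8, 21)) {
    inst <- random_search_instance(seed + 500L, nmin = 80L, nmax = 260L,
                                   mmax = 9L)
    oracle <- windowed_oracle_search(inst$q, inst$s, inst$K, inst$d)
    esa <- build_esa(inst$s)
    for (m in list(lesa_align(inst$q, esa, inst$K, inst$d),
                   lgslink_align(inst$q, esa, inst$K, inst$d))) {
      expect_equal(match_key(m),
                   match_key(oracle[order(oracle$start, oracle$length), ]),
                   info = paste("seed", seed))
    }
  }
})

test_that("skipping reduces the computed cells on the worked example", {
  S <- worked_example_sequence()
  q <- worked_example_pattern()
  esa <- build_esa(S)
  scan_cells <- attr(scan_align(q, S, K = 1, d = 1), "cells")
  link_cells <- attr(lgslink_align(q, esa, K = 1, d = 1), "cells")
  expect_lt(link_cells, scan_cells)
})

test_that("patterns longer than any suffix yield an empty result", {
  esa <- build_esa("ACGU")
  q <- rssp(strrep("N", 10L), strrep(".", 10L))
  expect_warning(m <- lesa_align(q, esa, K = 3, d = 1), "shorter")
  expect_equal(nrow(m), 0L)
})
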