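branched_pattern <- function() rssp("AAUACUUAGUAUCUAUCUGU", "..(.(...).(....)..).")

test_that("region decomposition reproduces the four condition classes", {
  regs <- decompose_regions(branched_pattern())
  key <- function(cond) {
    r <- regs[regs$condition == cond, ]
    paste(r$x, r$y, sep = "-", collapse = " ")
  }
  expect_equal(key(1L), "1-2 4-4 6-8 12-15")
  expect_equal(key(2L), "4-10 4-18 1-20")
  expect_equal(key(3L), "5-9 11-16 3-19")
  expect_equal(key(4L), "4-9 4-16 1-19")
})

test_that("the hairpin pattern decomposes into its four regions", {
  regs <- decompose_regions(rssp("AAGUUUC", "..(...)"))
  expect_equal(paste(regs$x, regs$y, regs$condition),
               c("1 2 1", "4 6 1", "3 7 3", "1 7 4"))
})

test_that("regions map to rows and recurrences", {
  q <- branched_pattern()
  regs <- decompose_regions(q)
  pick <- function(x, y) regs[regs$x == x & regs$y == y, ][1L, ]
  r1 <- rows_for_region(pick(6, 8), q)
  expect_equal(r1$rows, 6:8); expect_equal(r1$rule, "unpaired")
  r3 <- rows_for_region(pick(5, 9), q)
  expect_equal(r3$rows, 9L); expect_equal(r3$rule, "arc")
  r2 <- rows_for_region(pick(4, 10), q)
  expect_equal(r2$rows, 10L); expect_equal(r2$rule, "unpaired")
  r4 <- rows_for_region(regs[regs$x == 4 & regs$y == 9, ], q)
  expect_equal(r4$rows, 5L); expect_equal(r4$rule, "merged")
})

test_that("region structure covers the pattern and orders dependencies", {
  for (seed in 1:25) {
    q <- random_rssp(sample_1(seed, 4:16), seed = seed)
    regs <- decompose_regions(q)
    # the last region in top-down order is the unique outermost one
    expect_equal(regs$x[nrow(regs)], 1L)
    expect_equal(regs$y[nrow(regs)], length(q))
    # rows partition: every unpaired and closing position owned exactly once
    rows <- unlist(lapply(seq_len(nrow(regs)), function(r) {
      if (regs$condition[r] > 2L) return(NULL)  # arc rows tracked separately
      rows_for_region(regs[r, ], q)$rows
    }))
    sch <- strsplit(q$struct, "")[[1L]]
    expect_setequal(rows, which(sch == "."))
    expect_false(any(duplicated(rows)))
    # dependencies precede their dependents in top-down order
    deps <- region_dependencies(regs)
    for (r in seq_along(deps)) {
      if (length(deps[[r]]) > 0L) expect_true(all(deps[[r]] < r))
    }
  }
})

test_that("index resorting starts at the left-most free region clearing the band", {
  q <- rssp("AAGUUUC", "..(...)")
  sorted <- sort_regions_for_index(decompose_regions(q), d = 1)
  expect_equal(c(sorted$x[1L], sorted$y[1L]), c(4L, 6L))
  # flat pattern with a single region: fall back to the top-down order
  flat <- decompose_regions(rssp("ACGUA", "....."))
  expect_identical(sort_regions_for_index(flat, d = 0), flat)
  # resorting preserves dependency order
  for (seed in 26:40) {
    q <- random_rssp(sample_1(seed, 6:16), seed = seed)
    regs <- sort_regions_for_index(decompose_regions(q), d = 1)
    deps <- region_dependencies(regs)
    for (r in seq_along(deps)) {
      if (length(deps[[r]]) > 0L) expect_true(all(deps[[r]] < r))
    }
  }
})

test_that("the band test reproduces the worked-example stop", {
  q <- rssp("AAGUUUC", "..(...)")
  # the example-sequence suffix starting at 14: every placement of the
  # sub-region Q[4..5] on its band costs more than K = 1 at d = 1
  st <- semiglobal_dp(q, "ACCACCCU")
  expect_true(early_stop_exceeded(st, list(x = 4L, y = 5L, condition = 1L),
                                  K = 1, d = 1))
  # a perfect-match window never stops
  st0 <- semiglobal_dp(q, "AAGUUUCA")
  regs <- decompose_regions(q)
  for (r in seq_len(nrow(regs))) {
    expect_false(early_stop_exceeded(st0, regs[r, ], K = 0, d = 1))
  }
})

test_that("a positive band test implies every candidate length exceeds K", {
  checked <- 0L
  for (seed in 1:200) {
    q <- random_rssp(sample_1(seed, 4:9), seed = 1000L + seed)
    d <- sample_1(seed, 0:2)
    K <- sample_1(seed + 3L, 0:3)
    t <- random_sequence(length(q) + d, seed = 2000L + seed)
    st <- semiglobal_dp(q, t)
    regs <- decompose_regions(q)
    fr <- dp_final_row(st)
    lo <- max(1L, length(q) - d)
    for (r in seq_len(nrow(regs))) {
      if (early_stop_exceeded(st, regs[r, ], K, d)) {
        checked <- checked + 1L
        for (pp in lo:nchar(t)) expect_gt(fr["cost", pp + 1L], K)
      }
    }
  }
  expect_gt(checked, 20L)  # the property was actually exercised
})
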