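test_that("chi evaluates class membership of target characters", {
  q <- rssp("AAGUUUC", "..(...)")
  expect_equal(chi(rssp("N", "."), "G", 1, 1), 0L)
  expect_equal(chi(q, "CACCCUC", 2, 2), 0L)  # A vs A
  expect_equal(chi(q, "CACCCUC", 3, 3), 1L)  # G vs C
  expect_equal(chi(q, "CXCCCUC", 2, 2), 1L)  # non-base never matches
})

test_that("comp_bases evaluates ordered complementarity", {
  expect_equal(comp_bases("AU", 1, 2), 0L)
  expect_equal(comp_bases("GU", 1, 2), 0L)  # wobble
  expect_equal(comp_bases("CC", 1, 2), 1L)
  wc <- base_pair_rules(cbind(c("A", "U", "C", "G"), c("U", "A", "G", "C")))
  expect_equal(comp_bases("GU", 1, 2, wc), 1L)
})

test_that("row_fn maps positions to their storage rows", {
  q3 <- rssp("AAUACUUAGUAUCUAUCUGU", "..(.(...).(....)..).")
  expect_equal(row_fn(q3, 9), 5L)   # closing index maps to its left partner
  expect_equal(row_fn(q3, 5), 0L)   # left index followed by unpaired maps to 0
  expect_equal(row_fn(q3, 2), 2L)   # unpaired position maps to itself
  expect_equal(row_fn(q3, 0), 0L)
})

test_that("worked distances match the brute-force definition", {
  q <- rssp("AAGUUUC", "..(...)")
  expect_equal(ss_edit_dist(q, "CACCCUC"), 5)
  expect_equal(brute_force_dist(q, "CACCCUC"), 5)
  expect_equal(ss_edit_dist(q, "AAGUUUC"), 0)   # perfect realization
  expect_equal(ss_edit_dist(q, "AAGUAUC"), 1)   # one loop mismatch
  cm <- cost_model(mismatch = 3, indel = 5)
  expect_equal(ss_edit_dist(q, "AAGAUUC", cm), 3)  # single unpaired mismatch
  # forced single operations
  expect_equal(brute_force_dist(rssp("A", "."), "C"), 1)
  expect_equal(brute_force_dist(rssp("AC", ".."), "A"), 1)
  expect_error(brute_force_dist(rssp(strrep("A", 9), strrep(".", 9)), "A"),
               "m <= 8")
})

test_that("final row of the first matrix holds every prefix distance", {
  q <- random_rssp(7, seed = 5)
  t <- random_sequence(9, seed = 6)
  fr <- dp_final_row(semiglobal_dp(q, t))
  for (j in 1:9) {
    expect_equal(unname(fr["cost", j + 1L]), ss_edit_dist(q, substr(t, 1, j)))
  }
})

test_that("DP equals the enumeration oracle on random instances", {
  set.seed(11)
  for (it in 1:150) {
    q <- random_rssp(sample(2:6, 1L), seed = it, ambig = 0.3)
    t <- random_sequence(sample(1:8, 1L), seed = 5000L + it)
    cm <- cost_model(sample(1:3, 1L), sample(1:3, 1L), sample(1:3, 1L),
                     sample(1:3, 1L), sample(1:3, 1L))
    a <- ss_edit_dist(q, t, cm, with_indels = TRUE)
    b <- brute_force_dist(q, t, cm, with_indels = TRUE)
    expect_equal(unname(a), unname(b),
                 info = paste(q$pattern, q$struct, t))
  }
})

test_that("distances are non-negative and zero only for realizations", {
  set.seed(3)
  for (it in 1:40) {
    q <- random_rssp(sample(3:8, 1L), seed = 300L + it)
    t <- random_sequence(length(q), seed = 900L + it)
    expect_gte(ss_edit_dist(q, t), 0)
    r <- realize_pattern(q, seed = it)
    expect_equal(ss_edit_dist(q, unclass(r)), attr(r, "residual_cost"))
  }
})

test_that("diagonal cells are non-decreasing for unpaired patterns", {
  q <- rssp("NACGUA", "......")
  t <- random_sequence(8, seed = 42)
  st <- semiglobal_dp(q, t)
  mats <- dp_matrices(st)
  lay <- st$layout
  for (k in seq_along(mats)) {
    cm <- mats[[k]]$cost
    if (ncol(cm) < 2L) next  # the empty-suffix matrix has only column 0
    for (i in 1:(length(q) - 1L)) {
      r1 <- lay$slot_main[i] + 1L; r2 <- lay$slot_main[i + 1L] + 1L
      for (j in seq_len(ncol(cm) - 1L)) {
        expect_gte(cm[r2, j + 1L], cm[r1, j])
      }
    }
  }
})

test_that("cell accounting reproduces the window-shift and lcp-reuse counts", {
  q <- rssp("AAGUUUC", "..(...)")   # m = 7, d = 1: window length 8
  st <- semiglobal_dp(q, "ACCCUCUU")
  expect_equal(unname(count_cells(st)), c(252, 0, 252))
  dp_shift(st, "A")
  expect_equal(unname(count_cells(st)), c(56, 196, 252))
  st2 <- semiglobal_dp(q, "ACCCUCUU")
  dp_reuse_prefix(st2, "ACCCACCA", shared = 4)
  expect_equal(unname(count_cells(st2)), c(182, 70, 252))
})

test_that("window shifts reproduce from-scratch matrices cell by cell", {
  set.seed(8)
  for (it in 1:15) {
    q <- random_rssp(sample(4:8, 1L), seed = 40L + it)
    s <- random_sequence(length(q) + 6L, seed = 80L + it)
    w <- length(q) + 1L
    st <- semiglobal_dp(q, substr(s, 1, w), reserve = w)
    for (p in 2:(nchar(s) - w + 1L)) {
      dp_shift(st, substr(s, p + w - 1L, p + w - 1L))
      fresh <- semiglobal_dp(q, substr(s, p, p + w - 1L))
      mo <- dp_matrices(st); mf <- dp_matrices(fresh)
      for (k in seq_along(mf)) {
        expect_equal(mo[[k]]$cost, mf[[k]]$cost)
        expect_equal(mo[[k]]$indels, mf[[k]]$indels)
      }
    }
  }
})

test_that("traceback returns an alignment scoring the reported distance", {
  set.seed(21)
  for (it in 1:200) {
    q <- random_rssp(sample(3:9, 1L), seed = 600L + it)
    tn <- max(1L, length(q) + sample(-2:2, 1L))
    t <- random_sequence(tn, seed = 1600L + it)
    st <- semiglobal_dp(q, t)
    fr <- dp_final_row(st)
    ec <- sample(seq_len(tn), 1L)
    al <- traceback_alignment(st, ec)
    expect_equal(al$cost, unname(fr["cost", ec + 1L]))
    expect_equal(al$indels, unname(fr["indels", ec + 1L]))
    # every pattern and target position appears in exactly one edge
    expect_equal(sort(unname(c(al$matches[, 1L], al$pattern_gaps))),
                 seq_len(length(q)))
    expect_equal(sort(unname(c(al$matches[, 2L], al$insertions))),
                 seq_len(ec))
    # match edges strictly monotone in both coordinates
    if (nrow(al$matches) > 1L) {
      expect_true(all(diff(al$matches[, 1L]) > 0))
      expect_true(all(diff(al$matches[, 2L]) > 0))
    }
  }
})

test_that("alignments render as pattern/structure/bars/target blocks", {
  q <- rssp("AAGUUUC", "..(...)")
  st <- semiglobal_dp(q, "CACCCUC")
  out <- format(traceback_alignment(st))
  lines <- strsplit(out, "\n")[[1L]]
  expect_equal(length(lines), 5L)
  expect_match(lines[1L], "AAGUUUC")
  expect_match(lines[2L], "\\.\\.\\(\\.\\.\\.\\)")
  expect_match(lines[4L], "CACCCUC")
  expect_match(lines[5L], "cost = 5")
  al0 <- traceback_alignment(semiglobal_dp(q, "AAGUUUC"))
  expect_equal(al0$cost, 0)
  expect_equal(nrow(al0$matches), 7L)
})
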