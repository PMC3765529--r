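test_that("IUPAC classes expand to the standard base sets", {
  expect_setequal(iupac_class("N"), c("A", "C", "G", "U"))
  expect_identical(iupac_class("A"), "A")
  expect_setequal(iupac_class("R"), c("A", "G"))
  expect_setequal(iupac_class("B"), c("C", "G", "U"))
  expect_identical(iupac_class("T"), "U")
  for (x in c("A", "C", "G", "U", "R", "Y", "M", "K", "W", "S", "B", "D",
              "H", "V", "N")) {
    cls <- iupac_class(x)
    expect_gt(length(cls), 0L)
    expect_true(all(cls %in% c("A", "C", "G", "U")))
  }
  expect_error(iupac_class("X"), "X")
})

test_that("pair_table matches brackets and rejects unbalanced input", {
  expect_equal(unname(pair_table("..(...)")), matrix(c(3L, 7L), 1L))
  got <- pair_table("..(.(...).(....)..).")
  expect_setequal(paste(got[, 1L], got[, 2L]), c("5 9", "11 16", "3 19"))
  expect_error(pair_table("(()"), "position 1")
  expect_error(pair_table("())"), "position 3")
  expect_error(pair_table("..x."), "invalid structure character")
})

test_that("structure string rendering inverts pair_table", {
  for (st in c("..(...)", "((..))", ".....", "(.(..).)..", "..(.(...).(....)..).")) {
    expect_identical(structure_string(pair_table(st), nchar(st)), st)
  }
})

test_that("pattern files parse records in order with per-pattern thresholds", {
  txt <- c("# two stems", ">hp1", "AAGUUUC", "..(...)", "cost=5", "indels=1",
           ">hp2", "NNNCCC", "......")
  sd <- read_patterns(txt, cost = 2, indels = 0)
  expect_s3_class(sd, "ssd")
  expect_equal(vapply(sd$patterns, function(q) q$name, ""), c("hp1", "hp2"))
  expect_equal(sd$patterns[[1L]]$cost, 5)
  expect_equal(sd$patterns[[1L]]$indels, 1L)
  expect_equal(sd$patterns[[2L]]$cost, 2)   # command-line default retained
  expect_equal(nrow(sd$patterns[[1L]]$pairs), 1L)
  expect_error(read_patterns(c(">x", "ACGU")), "structure")
  expect_error(read_patterns(c(">x", "ACGU", "...")), "length")
  expect_error(read_patterns(c(">x", "ACGU", "....", "limit=3")), "unknown key")
  expect_error(read_patterns(c(">x", "ACXU", "....")), "X")
})

test_that("minus-strand transformation reverse-complements pattern and rules", {
  q <- rssp("AAGUUUC", "..(...)")
  qr <- reverse_complement_pattern(q)
  expect_identical(qr$pattern, "GAAACUU")
  expect_identical(qr$struct, "(...)..")
  # involution
  back <- reverse_complement_pattern(qr)
  expect_identical(back$pattern, q$pattern)
  expect_identical(back$struct, q$struct)
  # ambiguity classes complement class-wise
  qn <- reverse_complement_pattern(rssp("RYN", "..."))
  expect_identical(qn$pattern, "NRY")
  # wobble rules become (C,A),(A,C)
  wob <- base_pair_rules(cbind(c("G", "U"), c("U", "G")))
  cw <- complement_rules(wob)
  expect_setequal(paste(cw[, 1L], cw[, 2L]), c("C A", "A C"))
})

test_that("cost model defaults and validation", {
  cm <- cost_model()
  expect_equal(unlist(cm[c("mismatch", "indel", "arc_breaking", "arc_altering",
                           "arc_removing")]),
               c(mismatch = 1, indel = 1, arc_breaking = 1, arc_altering = 1,
                 arc_removing = 2))
  expect_error(cost_model(mismatch = -1), "non-negative")
})

test_that("base-pair rules default to canonical + wobble and parse from files", {
  rules <- base_pair_rules()
  expect_equal(nrow(rules), 6L)
  expect_true(all(c("A U", "U A", "C G", "G C", "G U", "U G") %in%
                    paste(rules[, 1L], rules[, 2L])))
  f <- withr::local_tempfile(lines = c("# WC only", "A U", "U A", "c g", "G C"))
  r2 <- read_bp_rules(f)
  expect_equal(nrow(r2), 4L)
  expect_error(base_pair_rules(cbind("A", "X")), "A, C, G, U")
})

test_that("targets are normalized and read from FASTA", {
  expect_identical(normalize_sequence("acgt"), "ACGU")
  f <- withr::local_tempfile(lines = c(">chr1 some desc", "ACGTACGT", ">chr2", "uuuu"))
  seqs <- read_target_fasta(f)
  expect_identical(unname(seqs), c("ACGUACGU", "UUUU"))
  expect_identical(names(seqs), c("chr1", "chr2"))
  empty <- withr::local_tempfile(lines = character(0L))
  expect_error(read_target_fasta(empty))
})
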