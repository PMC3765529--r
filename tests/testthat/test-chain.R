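mk_frags <- function(starts, ends, weights, patterns, seqid = "s",
                     strand = "+") {
  data.frame(seqid = seqid, start = starts, end = ends,
             length = ends - starts + 1L, strand = strand, pattern = patterns,
             cost = 0, indels = 0, weight = weights, stringsAsFactors = FALSE)
}

two_pattern_ssd <- function() {
  ssd(list(rssp("AAAA", "....", name = "A"), rssp("CCCC", "....", name = "B")))
}

test_that("fragment weights derive from the maximal pattern weight", {
  q <- rssp("AAGUUUC", "..(...)")
  expect_equal(max_pattern_weight(q), 9)        # 7 * 1 + 1 * 2
  expect_equal(fragment_weight(q, 0), 9)
  expect_equal(fragment_weight(q, 5), 4)
  expect_warning(w0 <- fragment_weight(q, 9), "non-positive")
  expect_equal(w0, 0)
})

test_that("global chains pick the unique colinear cover", {
  sd <- two_pattern_ssd()
  fr <- mk_frags(c(10L, 50L, 30L), c(20L, 60L, 40L), c(5, 4, 3),
                 c("A", "A", "B"))
  ch <- global_chains(fr, sd)
  expect_equal(unique(ch$score), 8)
  expect_equal(ch$pattern[order(ch$pattern_index)], c("A", "B"))
  expect_equal(ch$start[order(ch$pattern_index)], c(10L, 30L))
  # fragments out of order on the target: no global chain
  bad <- mk_frags(c(30L, 10L), c(40L, 20L), c(3, 3), c("A", "B"))
  expect_equal(nrow(global_chains(bad, sd)), 0L)
  # a one-pattern SSD turns every fragment into its own chain
  one <- ssd(list(rssp("AAAA", "....", name = "A")))
  solo <- global_chains(mk_frags(c(5L, 40L), c(10L, 45L), c(7, 6), "A"), one)
  expect_equal(sort(unique(solo$score)), c(6, 7))
})

test_that("local chains are maximal and respect the score threshold", {
  sd <- two_pattern_ssd()
  fr <- mk_frags(c(10L, 50L, 30L), c(20L, 60L, 40L), c(5, 4, 3),
                 c("A", "A", "B"))
  lc <- local_chains(fr, sd, min_score = 0)
  scores <- unique(lc$score)
  expect_true(8 %in% scores)            # the extended pair chain is reported
  expect_false(5 %in% scores)           # its dominated singleton is not
  expect_true(4 %in% scores)            # the unextendable singleton survives
  expect_equal(nrow(local_chains(fr, sd, min_score = 100)), 0L)
  # one colinear fragment per pattern: local and global coincide
  fr2 <- mk_frags(c(10L, 30L), c(20L, 40L), c(5, 3), c("A", "B"))
  expect_equal(local_chains(fr2, sd)[, -1L], global_chains(fr2, sd)[, -1L])
})

test_that("chain scores equal exhaustive colinear-subset enumeration", {
  set.seed(99)
  for (it in 1:25) {
    np <- sample(2:4, 1L)
    k <- sample(4:12, 1L)
    starts <- sort(sample.int(300L, k))
    lens <- sample(5:20, k, replace = TRUE)
    fr <- mk_frags(starts, starts + lens, sample(1:9, k, replace = TRUE),
                   LETTERS[sample.int(np, k, replace = TRUE)])
    sd <- ssd(lapply(LETTERS[1:np], function(nm) {
      rssp("AAAA", "....", name = nm)
    }))
    fr$pattern_index <- match(fr$pattern, LETTERS[1:np])
    ref_g <- enumerate_chains(fr, np, global = TRUE)
    got_g <- global_chains(fr, sd)
    if (is.infinite(ref_g$best)) {
      expect_equal(nrow(got_g), 0L)
    } else {
      expect_equal(max(got_g$score), ref_g$best)
      # every reported chain's score is the sum of its member weights
      for (ci in unique(got_g$chain)) {
        rows <- got_g[got_g$chain == ci, ]
        expect_equal(rows$score[1L], sum(rows$weight))
        expect_true(all(diff(rows$pattern_index) > 0))
        expect_true(all(rows$end[-nrow(rows)] < rows$start[-1L]))
      }
      # all co-optimal chains are reported
      top <- got_g[got_g$score == ref_g$best, ]
      got_sets <- unique(lapply(split(seq_len(nrow(top)), top$chain),
                                function(i) sort(paste(top$start[i], top$pattern[i]))))
      ref_sets <- unique(lapply(ref_g$sets, function(set) {
        sort(paste(fr$start[set], fr$pattern[set]))
      }))
      expect_setequal(vapply(got_sets, paste, "", collapse = "|"),
                      vapply(ref_sets, paste, "", collapse = "|"))
    }
    ref_l <- enumerate_chains(fr, np, global = FALSE)
    got_l <- local_chains(fr, sd)
    expect_equal(max(got_l$score), ref_l$best)
  }
})

test_that("adding a fragment never decreases the best global chain score", {
  sd <- two_pattern_ssd()
  fr <- mk_frags(c(10L, 30L), c(20L, 40L), c(5, 3), c("A", "B"))
  base <- max(global_chains(fr, sd)$score)
  more <- rbind(fr, mk_frags(5L, 8L, 9, "A"))
  expect_gte(max(global_chains(more, sd)$score), base)
})

test_that("chains never mix sequences or strands", {
  sd <- two_pattern_ssd()
  fr <- rbind(mk_frags(10L, 20L, 5, "A", seqid = "s1"),
              mk_frags(30L, 40L, 3, "B", seqid = "s2"))
  expect_equal(nrow(global_chains(fr, sd)), 0L)
  fr2 <- rbind(mk_frags(10L, 20L, 5, "A", strand = "+"),
               mk_frags(30L, 40L, 3, "B", strand = "-"))
  expect_equal(nrow(global_chains(fr2, sd)), 0L)
})

test_that("the overlap filter keeps the best match per overlapping set", {
  m <- mk_frags(c(1L, 5L), c(10L, 12L), c(9, 4), "A")
  expect_equal(overlap_filter(m)$weight, 9)
  disjoint <- mk_frags(c(1L, 20L), c(10L, 30L), c(9, 4), "A")
  expect_equal(nrow(overlap_filter(disjoint)), 2L)
  dup <- mk_frags(c(1L, 1L), c(10L, 10L), c(5, 5), "A")
  expect_equal(nrow(overlap_filter(dup)), 1L)
  # different patterns never shadow one another
  mixed <- mk_frags(c(1L, 5L), c(10L, 12L), c(9, 4), c("A", "B"))
  expect_equal(nrow(overlap_filter(mixed)), 2L)
})

test_that("planted SSD instances are recovered as one full global chain", {
  sd <- ssd(list(rssp("AAGNNNUUC", "..((...))", name = "s1", cost = 2, indels = 1),
                 rssp("GGWWSNCC", "((....))", name = "s2", cost = 2, indels = 1)))
  set.seed(5)
  bg <- random_sequence(300, seed = 50)
  s1 <- unclass(realize_pattern(sd$patterns[[1L]], seed = 51))
  s2 <- unclass(realize_pattern(sd$patterns[[2L]], seed = 52))
  s <- paste0(substr(bg, 1, 100), s1, substr(bg, 101, 200), s2,
              substr(bg, 201, 300))
  names(s) <- "planted"
  res <- search_patterns(sd, s, algorithm = "lscan", chain = "global")
  top <- res$chains[res$chains$chain == 1L, ]
  expect_equal(top$pattern[order(top$pattern_index)], c("s1", "s2"))
  expect_true(101L %in% res$matches$start[res$matches$pattern == "s1"])
  expect_true((100L + nchar(s1) + 100L + 1L) %in%
                res$matches$start[res$matches$pattern == "s2"])
})
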