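# Seeded synthetic data: random sequences and patterns, pattern realizations,
# planted (mutated) instances with recorded ground truth.

# run expr under a local RNG stream; the caller's RNG state is untouched
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Random background sequence
#'
#' Uniform over `A C G U` by default, with a GC-bias knob.
#'
#' @param n Length.
#' @param seed Seed (explicit argument; the global RNG state is preserved).
#' @param gc GC content in `[0, 1]`.
#' @return A sequence string.
#' @export
random_sequence <- function(n, seed, gc = 0.5) {
  .with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  })
}

#' Random RSSP
#'
#' Draws a pattern of length `m` with up to `max_pairs` nested base pairs
#' (stems with optional bulges and dangling ends, exercising all recurrence
#' cases) and IUPAC ambiguity codes at the requested rate.
#'
#' @param m Pattern length.
#' @param seed Seed.
#' @param max_pairs Maximum number of base pairs.
#' @param ambig Probability of an ambiguity code per position.
#' @return An [rssp()].
#' @export
random_rssp <- function(m, seed, max_pairs = max(0L, (m - 3L) %/% 3L),
                        ambig = 0.2) {
  .with_seed(seed, {
    sch <- rep(".", m)
    npairs <- if (max_pairs > 0L) sample(0:max_pairs, 1L) else 0L
    placed <- 0L
    guard <- 0L
    while (placed < npairs && guard < 50L) {
      guard <- guard + 1L
      a <- sample.int(m, 1L)
      b <- a + 3L + sample(0:max(0L, m - a - 3L), 1L)
      if (b > m || sch[a] != "." || sch[b] != ".") next
      sch2 <- sch; sch2[a] <- "("; sch2[b] <- ")"
      pt <- tryCatch(pair_table(paste(sch2, collapse = "")),
                     error = function(e) NULL)
      if (is.null(pt)) next
      ok <- TRUE
      if (nrow(pt) > 1L) for (r1 in seq_len(nrow(pt) - 1L)) {
        for (r2 in (r1 + 1L):nrow(pt)) {
          i1 <- pt[r1, 1L]; j1 <- pt[r1, 2L]; i2 <- pt[r2, 1L]; j2 <- pt[r2, 2L]
          if ((i1 < i2 && i2 < j1 && j1 < j2) || (i2 < i1 && i1 < j2 && j2 < j1)) {
            ok <- FALSE
          }
        }
      }
      if (!ok) next
      sch <- sch2
      placed <- placed + 1L
    }
    syms <- ifelse(runif(m) < ambig,
                   sample(c("N", "R", "Y", "S", "W"), m, replace = TRUE),
                   sample(c("A", "C", "G", "U"), m, replace = TRUE))
    rssp(paste(syms, collapse = ""), paste(sch, collapse = ""),
         name = paste0("rand", seed))
  })
}

#' Realize a pattern as a concrete sequence
#'
#' Draws each unpaired position uniformly from its IUPAC class; for each base
#' pair, draws a complementary pair consistent with both classes when one
#' exists. If class and complementarity conflict, the left partner is drawn
#' from its class and the right from the left's complement partners (taking a
#' mismatch if it falls outside the right class) or, lacking any rule partner,
#' from its own class (breaking the arc); the residual cost is recorded.
#'
#' @param q An [rssp()].
#' @param seed Seed.
#' @param costs,rules Scoring context for the recorded residual cost.
#' @return A sequence string with attribute `residual_cost` (0 when a
#'   consistent draw succeeded).
#' @export
realize_pattern <- function(q, seed, costs = cost_model(),
                            rules = base_pair_rules()) {
  .with_seed(seed, {
    m <- length(q)
    syms <- strsplit(q$pattern, "")[[1L]]
    out <- character(m)
    residual <- 0
    for (i in seq_len(m)) out[i] <- sample(iupac_class(syms[i]), 1L)
    if (nrow(q$pairs) > 0L) for (r in seq_len(nrow(q$pairs))) {
      a <- q$pairs[r, 1L]; b <- q$pairs[r, 2L]
      ca <- iupac_class(syms[a]); cb <- iupac_class(syms[b])
      cand <- rules[rules[, 1L] %in% ca & rules[, 2L] %in% cb, , drop = FALSE]
      if (nrow(cand) > 0L) {
        pick <- cand[sample.int(nrow(cand), 1L), ]
        out[a] <- pick[1L]; out[b] <- pick[2L]
      } else {
        out[a] <- sample(ca, 1L)
        partners <- rules[rules[, 1L] == out[a], 2L]
        if (length(partners) > 0L) {
          out[b] <- sample(partners, 1L)
          residual <- residual + costs$mismatch  # right base outside its class
        } else {
          out[b] <- sample(cb, 1L)
          residual <- residual + costs$arc_breaking
        }
      }
    }
    structure(paste(out, collapse = ""), residual_cost = residual)
  })
}

#' Plant mutated pattern instances in a random background
#'
#' Embeds `n_sites` realizations of the pattern, each perturbed by randomly
#' chosen edit operations (unpaired-base mismatch, insertion, deletion, arc
#' breaking, arc altering, arc removing -- realized as the corresponding
#' sequence changes) whose summed cost stays within `op_budget` and whose
#' indel count stays within `indel_budget`. Operations hit distinct positions
#' and never the site boundaries, so the reported distance at a planted start
#' never exceeds the applied cost, and searching with `K = op_budget`,
#' `d = indel_budget` recovers every site.
#'
#' @param q An [rssp()].
#' @param background_length Total background length (sites are inserted in
#'   addition to this).
#' @param n_sites Number of planted instances.
#' @param op_budget Maximum summed operation cost per site.
#' @param indel_budget Maximum indels per site.
#' @param seed Seed.
#' @param costs,rules Scoring context.
#' @param gc Background GC content.
#' @return List with `seq` (named sequence string) and `truth` (data.frame:
#'   `name`, `start`, `end`, `applied_cost`, `applied_indels`, `ops`).
#' @export
plant_mutated <- function(q, background_length, n_sites, op_budget,
                          indel_budget, seed, costs = cost_model(),
                          rules = base_pair_rules(), gc = 0.5) {
  m <- length(q)
  if (n_sites * (m + indel_budget) > background_length) {
    stop("sites do not fit: increase background_length or reduce n_sites")
  }
  .with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
    gaps <- background_length %/% (n_sites + 1L)
    pieces <- character(0L)
    truth <- NULL
    pos <- 0L
    for (s in seq_len(n_sites)) {
      bg <- paste(sample(names(p), gaps, replace = TRUE, prob = p), collapse = "")
      site <- .mutate_site(q, op_budget, indel_budget, costs, rules)
      pieces <- c(pieces, bg, site$seq)
      start <- pos + gaps + 1L
      pos <- pos + gaps + nchar(site$seq)
      truth <- rbind(truth, data.frame(
        name = q$name, start = start, end = pos,
        applied_cost = site$cost, applied_indels = site$indels,
        ops = paste(site$ops, collapse = ","), stringsAsFactors = FALSE))
    }
    pieces <- c(pieces,
                paste(sample(names(p), gaps, replace = TRUE, prob = p),
                      collapse = ""))
    seqs <- paste(pieces, collapse = "")
    names(seqs) <- paste0("planted_", q$name)
    list(seq = seqs, truth = truth)
  })
}

# apply random edit operations to one realization (uses the current RNG)
.mutate_site <- function(q, op_budget, indel_budget, costs, rules) {
  m <- length(q)
  base <- realize_pattern(q, seed = sample.int(1e7, 1L), costs = costs,
                          rules = rules)
  residual <- attr(base, "residual_cost")
  chars <- strsplit(unclass(base), "")[[1L]]
  partner <- .q_partner(q)
  sch <- strsplit(q$struct, "")[[1L]]
  syms <- strsplit(q$pattern, "")[[1L]]
  deleted <- logical(m)
  inserts <- vector("list", m)  # insertions after position i
  used <- logical(m)            # positions already hit by an operation
  cost <- residual; indels <- 0L; ops <- character(0L)
  candidates <- sample(c("mismatch", "insertion", "deletion", "arc_breaking",
                         "arc_altering", "arc_removing"))
  n_ops <- sample(0:3, 1L)
  guard <- 0L
  while (n_ops > 0L && guard < 40L) {
    guard <- guard + 1L
    op <- sample(candidates, 1L)
    if (op == "mismatch") {
      if (costs$mismatch > op_budget - cost) next
      free <- which(sch == "." & !used)
      if (length(free) == 0L) next
      i <- if (length(free) == 1L) free else sample(free, 1L)
      off <- setdiff(.BASES, iupac_class(syms[i]))
      if (length(off) == 0L) next
      chars[i] <- if (length(off) == 1L) off else sample(off, 1L)
      used[i] <- TRUE
      cost <- cost + costs$mismatch
    } else if (op == "insertion") {
      if (costs$indel > op_budget - cost || indels + 1L > indel_budget) next
      if (m < 2L) next
      i <- sample(seq_len(m - 1L), 1L)  # never before position 1 / after m
      inserts[[i]] <- c(inserts[[i]], sample(.BASES, 1L))
      cost <- cost + costs$indel; indels <- indels + 1L
    } else if (op == "deletion") {
      if (costs$indel > op_budget - cost || indels + 1L > indel_budget) next
      free <- which(sch == "." & !used & seq_len(m) > 1L & seq_len(m) < m)
      if (length(free) == 0L) next
      i <- if (length(free) == 1L) free else sample(free, 1L)
      deleted[i] <- TRUE; used[i] <- TRUE
      cost <- cost + costs$indel; indels <- indels + 1L
    } else {
      arcs <- which(partner > seq_len(m))
      arcs <- arcs[!used[arcs] & !used[partner[arcs]]]
      if (op != "arc_breaking") {
        arcs <- arcs[arcs > 1L & partner[arcs] < m]
      }
      if (length(arcs) == 0L) next
      a <- if (length(arcs) == 1L) arcs else sample(arcs, 1L)
      b <- partner[a]
      if (op == "arc_breaking") {
        noncomp <- setdiff(iupac_class(syms[b]),
                           rules[rules[, 1L] == chars[a], 2L])
        extra <- 0
        if (length(noncomp) == 0L) {
          noncomp <- setdiff(.BASES, rules[rules[, 1L] == chars[a], 2L])
          extra <- costs$mismatch
        }
        if (length(noncomp) == 0L) next
        if (costs$arc_breaking + extra > op_budget - cost) next
        chars[b] <- if (length(noncomp) == 1L) noncomp else sample(noncomp, 1L)
        cost <- cost + costs$arc_breaking + extra
      } else if (op == "arc_altering") {
        cc <- costs$arc_altering + costs$indel
        if (cc > op_budget - cost || indels + 1L > indel_budget) next
        side <- sample(c(a, b), 1L)
        deleted[side] <- TRUE
        cost <- cost + cc; indels <- indels + 1L
      } else {
        cc <- costs$arc_removing + 2 * costs$indel
        if (cc > op_budget - cost || indels + 2L > indel_budget) next
        deleted[a] <- TRUE; deleted[b] <- TRUE
        cost <- cost + cc; indels <- indels + 2L
      }
      used[a] <- TRUE; used[b] <- TRUE
    }
    ops <- c(ops, op)
    n_ops <- n_ops - 1L
  }
  out <- character(0L)
  for (i in seq_len(m)) {
    if (!deleted[i]) out <- c(out, chars[i])
    if (!is.null(inserts[[i]])) out <- c(out, inserts[[i]])
  }
  list(seq = paste(out, collapse = ""), cost = cost, indels = indels, ops = ops)
}
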