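# Shared generators and oracles for the test suite. All fixtures are built in
# code under fixed seeds.

# canonical key of a match set (order-free comparison across engines)
match_key <- function(m) {
  o <- order(m$start, m$length)
  paste(m$start[o], m$length[o], m$cost[o], m$indels[o], sep = ":",
        collapse = ";")
}

# one randomized search instance: pattern with hairpins/bulges/dangling ends,
# background sequence, thresholds
random_search_instance <- function(seed, nmin = 100L, nmax = 500L,
                                   mmin = 5L, mmax = 14L, kmax = 4L,
                                   dmax = 2L) {
  q <- random_rssp(sample_1(seed * 7L + 1L, mmin:mmax), seed = seed)
  n <- sample_1(seed * 7L + 2L, nmin:nmax)
  s <- random_sequence(n, seed = seed * 7L + 3L,
                       gc = 0.35 + 0.3 * ((seed %% 3L) / 2))
  list(q = q, s = s,
       K = sample_1(seed * 7L + 4L, 0:kmax),
       d = sample_1(seed * 7L + 5L, 0:dmax))
}

# deterministic single draw without touching the global RNG
sample_1 <- function(seed, values) {
  values[(seed * 2654435761) %% length(values) + 1L]
}

# naive windowed search: full DP per window, no reuse, no skipping
windowed_oracle_search <- function(q, s, K, d, costs = cost_model(),
                                   rules = base_pair_rules()) {
  s <- normalize_sequence(s)
  n <- nchar(s)
  m <- length(q)
  lo <- max(1L, m - d)
  out <- NULL
  if (n < lo) return(data.frame(start = integer(0L), length = integer(0L),
                                cost = numeric(0L), indels = numeric(0L)))
  for (p in 1:(n - lo + 1L)) {
    window <- substr(s, p, min(p + m + d - 1L, n))
    fr <- dp_final_row(semiglobal_dp(q, window, costs, rules))
    for (pp in lo:min(nchar(window), m + d)) {
      if (fr["cost", pp + 1L] <= K + 1e-9 && fr["indels", pp + 1L] <= d + 1e-9) {
        out <- rbind(out, c(p, pp, fr["cost", pp + 1L], fr["indels", pp + 1L]))
      }
    }
  }
  if (is.null(out)) out <- matrix(numeric(0L), 0L, 4L)
  out <- as.data.frame(out)
  names(out) <- c("start", "length", "cost", "indels")
  out
}

# exhaustive colinear-chain enumeration for small fragment sets
enumerate_chains <- function(frags, np, global) {
  k <- nrow(frags)
  best <- -Inf
  best_sets <- list()
  sets <- unlist(lapply(seq_len(k), function(sz) {
    utils::combn(k, sz, simplify = FALSE)
  }), recursive = FALSE)
  for (set in sets) {
    fr <- frags[set, , drop = FALSE]
    o <- order(fr$pattern_index)
    fr <- fr[o, , drop = FALSE]
    if (any(duplicated(fr$pattern_index))) next
    if (global && !identical(fr$pattern_index, seq_len(np))) next
    if (nrow(fr) > 1L) {
      ok <- all(diff(fr$start) > 0) && all(fr$end[-nrow(fr)] < fr$start[-1L])
      if (!ok) next
    }
    sc <- sum(fr$weight)
    if (sc > best + 1e-9) {
      best <- sc
      best_sets <- list(sort(set[o]))
    } else if (abs(sc - best) < 1e-9) {
      best_sets <- c(best_sets, list(sort(set[o])))
    }
  }
  list(best = best, sets = best_sets)
}

worked_example_sequence <- function() "CCACCCCCCACCCACCACCCUCUU"
worked_example_pattern <- function() {
  rssp("AAGUUUC", "..(...)", name = "hairpin", cost = 5, indels = 1)
}
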