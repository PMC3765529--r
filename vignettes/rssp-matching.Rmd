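---
title: "Approximate RNA sequence-structure pattern matching: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximate RNA sequence-structure pattern matching: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsspsearch)
```

## The problem and the model

Functional RNAs conserve base-paired secondary structure better than primary
sequence, so motif search must score both levels. `rsspsearch` matches an
*RNA sequence-structure pattern* (RSSP) `Q = (P, R)` — an IUPAC sequence
pattern `P` and an equally long, non-crossing dot-bracket string `R` —
against substrings of a target sequence `S` (DNA or RNA; `T` is read as `U`,
and any other character mismatches every class and pairs with nothing).

An alignment of the complete pattern and a substring (semi-global alignment)
is a set of match edges, strictly monotone in both coordinates, plus gap
edges for the unmatched positions. Its cost adds

* ω~m~ per match edge whose target base lies outside the pattern position's
  IUPAC class,
* ω~d~ per inserted or deleted base, at any position, and
* one arc penalty per base pair `(k1, k2)`: ω~b~ (*arc breaking*) when both
  partners are matched but the target bases are not complementary under the
  active base-pairing rules, ω~a~ (*arc altering*) when exactly one partner is
  deleted, ω~r~ (*arc removing*) when both are.

`dist(Q, T)` is the minimum cost over all alignments. A substring `S[p..q]`
is reported as a match when `dist(Q, S[p..q]) <= K`, the number of indels in
an optimal alignment is at most `d`, and `m - d <= q - p + 1 <= m + d`.

One modelling point deserves emphasis because the operation definitions can
be read two ways: here the base operations apply at *every* position and the
arc penalties are add-ons. A deleted arc partner therefore costs
ω~d~ + ω~a~ in total, a removed arc ω~r~ + 2ω~d~. This reading keeps the
default ω~r~ = 2 coherent (removing an arc costs exactly twice altering it)
and it is the convention under which the package's running example — the
24-nt sequence `CCACCCCCCACCCACCACCCUCUU` searched with
`(AAGUUUC, ..(...))` at `K = 5, d = 1` — yields its leftmost match at
position 16. Under the alternative reading (arc penalties replacing the
deletion cost) a cheaper arc-altering alignment would already match at
position 2. The brute-force oracle ([brute_force_dist()]) scores alignments
directly from these definitions by enumeration and pins the DP down on
hundreds of randomized instances, including random operation costs.

### Indel gating

The match definition bounds both the cost and the indel count. Every DP cell
therefore carries the pair *(cost, minimum indels among minimum-cost
alignments)*, minimised lexicographically; a candidate match is reported when
the cost is at most `K` *and* that indel count is at most `d`. This is exact
and avoids a per-candidate traceback. One consequence worth knowing: for arc
patterns a window can be rejected at any `K` because its only minimum-cost
alignments run through more than `d` indels (arc altering can undercut arc
breaking); for unpaired patterns a gapless alignment is always co-optimal and
only `K` gates reporting.

## The matrix family and column reuse

For a window text `T` of length `m' = m + d` the DP computes `m' + 1` matrix
families, one per suffix `T_k` plus one for the empty suffix; column `j` of
matrix `k` covers `T[k..k+j-1]`. The final row of the first matrix holds
`dist(Q, T[1..j])` for every prefix length, so all candidate lengths of one
start position come from a single computation.

Storage is by pattern position: each unpaired position owns a row holding
the prefix value of its structural segment; each arc-closing position owns a
row with the pure arc substructure value; and where material precedes an arc
inside its segment, a separate *merged* row holds the combination
`min over j' { prefix(j') + arc(k + j', j - j') }` (the split-column
recurrence). Left arc partners own no row — their cost is folded into the
arc row — which is why the matrices are not defined for every subinterval.
The column indexing of the paired-base recurrence follows the
convention "the left partner consumes `T[k]`, the right partner
`T[k+j-1]`"; the enumeration oracle validates the convention.

Two reuse schemes avoid recomputation:

* **window shift** (`scan`, and `dp_shift()` on a state): a one-position
  shift makes each matrix the previous window's next-deeper matrix, so only
  the last column of every matrix is new;
* **shared prefix** (`lesa`/`lgslink`, and `dp_reuse_prefix()`): if two texts
  share a prefix of length `l`, columns `j <= l - k + 1` of matrix `k` are
  identical.

`count_cells()` reports the accounting in the convention of `m` pattern rows
per matrix and columns `1..m'-k+1`: with `m = 7, d = 1` a full window costs
252 cells, a shift recomputes 56 (22%), and a suffix sharing a 4-prefix still
recomputes 182 (72%) — the gap that motivates the suffix-link engine.

## Regions and the early-stop band test

`decompose_regions()` splits the pattern into regions that never partially
overlap: maximal unpaired runs after an opening bracket or at the 5' end
(condition 1), trailing unpaired runs preceded by complete arcs in the same
segment (condition 2), the arcs themselves (condition 3), and
"prefix-plus-arc" regions where material precedes an arc in its segment
(condition 4). Their order by right end is exactly the top-down computation
order of the DP rows, so dependencies always precede dependents.

After each computed row (sub-region `Q[x..i]`) the band test probes the cells
`dist(Q[x..i], T_{x+d'}[1..l+z])` for every start shift
`d' in [-d, min(d, x)]` and every `z in [|d'|-d, d-|d'|]`. If all probed
cells exceed `K`, no alignment of the full pattern within the indel budget
can pass through the region, and the window (or suffix) is skipped.

Two numerical choices here are deliberate:

* the band is the *full* inclusive range of `z`, not only the extreme
  diagonals; probing only the extremes misses gapless region placements when
  `d >= 1` and would discard true matches (observed on randomized instances);
* probe columns are clipped to the columns that exist, and out-of-range
  probes count as exceeding. On short tail windows (length below `m + d`)
  this keeps the test sound: the clipped probes cover exactly the shorter
  placements that remain feasible.

Soundness is asserted property-style: whenever the test fires, the full
distances of every candidate length exceed `K`, and across engines the match
sets never change — only the instrumented cell counts do.

## Index-based search

`build_esa()` constructs the enhanced suffix array of `S$`: `suf` (the ranks
of all `n + 1` suffixes, the terminator sorting *after* every base), `lcp`,
and the inverse permutation `isuf`. The terminator-last order has a useful
consequence: a short suffix sorts after all its extensions, so a rank range
sharing a full reading depth is always homogeneous. The terminator is
virtual — no symbol is added to the alphabet — and `lcp` is stored as plain
integers. Construction is prefix doubling (`O(n log^2 n)`), with correctness
defined by the sortedness/lcp invariants, which the tests check against
naive sorting; lcp values come from the standard rank-order scan.

`lesa_align()` walks ranks top-down with reading depth
`p_i = min(m + d, |suffix|)`, reusing columns covered by the lcp with the
last computed suffix for regions already computed there (regions from the
first failed one on are recomputed fully). When the whole reading depth is
shared, no cell is computed at all: the predecessor's outcome transfers to
the entire rank range sharing that prefix — matches are emitted at all those
suffix starts, or the range is skipped. After an early stop on sub-region
`[x..y]`, every rank sharing the prefix `T[1..y+d]` is skipped too.

`lgslink_align()` adds two uses of generalized suffix links
(`link(i, x') = isuf[suf[i] + x']`):

* **substring skipping**: after a stop on `[x..y]` with `x - d > 1`, the
  failing evidence is the substring `W = T[x-d..y+d]`. The rank of the
  suffix starting with `W` is found by one link jump, the maximal rank
  interval sharing `|W|` is collected, and every suffix containing `W` at
  offset `x - d - 1` is marked in the bit array `vtab` — those ranks are
  eliminated without being visited;
* **suffix-link chains**: after processing a rank, the suffix one character
  shorter is processed immediately (one link jump), reusing all matrices but
  their last column, until the next suffix is too short or already marked.
  Processed and skipped ranks are marked, so no rank is handled twice.

After a chain the matrices belong to the chain's tail, not to the last
top-down rank; the lcp-reuse bookkeeping is then reset conservatively
(next processed suffix recomputes everything) rather than tracked across the
jump. This favours correctness over a marginal reuse and is one reason the
engines' cell counts — not their match sets — are the only thing that
differs.

## Chaining

For descriptors of multiply-branched RNAs, an ordered list of RSSPs (an SSD)
is searched pattern by pattern and the matches are combined by colinear
chaining per sequence and strand. A match of cost `c` becomes a fragment of
weight `m ω~m~ + bps ω~r~ - c`; since matches satisfy `c <= K`, configuring
`K` below the maximal pattern weight guarantees the positive weights the
chaining requires (a warning flags violations). The chain score is the plain
sum of fragment weights — no gap penalty; nothing in the match model
justifies one, and the plain sum keeps scores interpretable as "total
conservation credit". Chains are found by an `O(k^2)` sparse DP over
fragments sorted by start; consecutive fragments must not overlap on the
target. Global chains use every SSD pattern exactly once in order; local
chains may use any non-empty subsequence, and only maximal chains are
reported (positive weights make every extension score higher, so a chain
with a colinear successor is suppressed). All co-optimal chains are
backtracked, then lower-scoring ones down to `min_score`, capped by
`max_chains`. An optional overlap filter removes matches overlapped by a
higher-weight match of the same pattern (ties keep the lower start, then the
shorter interval).

## Strands, coordinates, input formats

The index is built for the plus strand only. Minus-strand search reverses
and complements the pattern class-wise, swaps the brackets, and complements
the base-pairing rules (wobble `(G,U),(U,G)` becomes `(C,A),(A,C)`); applying
the transformation twice is the identity. Matches are always reported in
plus-strand coordinates, 1-based inclusive, with a strand column; a BED
writer (0-based half-open) is provided. By default every qualifying
(start, length) pair is reported; `best_per_start` collapses to the
minimum-cost (tie: shortest) interval per start — both behaviours exist
because per-position reporting is what downstream chaining wants, while
per-start reporting reads better for humans.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `cost` (K) | maximum edit cost of a match | 0 (per pattern) | in cost units; keep below `m ω~m~ + bps ω~r~` for chaining |
| `indels` (d) | maximum indels of a match; also bounds match length to `m ± d` | 0 | window length is `m + d` |
| ω~m~, ω~d~ | base mismatch / indel cost | 1, 1 | non-negative reals; defaults are the small-integer scheme used throughout |
| ω~b~, ω~a~, ω~r~ | arc breaking / altering / removing | 1, 1, 2 | add-ons per base pair |
| base-pair rules | allowed ordered pairs | WC + wobble | any subset of {A,C,G,U}²; order respected |
| `gc` (fixtures) | background GC content | 0.5 | uniform background otherwise |

## The synthetic-data generators

`random_sequence()`, `random_rssp()`, `realize_pattern()` and
`plant_mutated()` take explicit seeds and never touch the global RNG.
`plant_mutated()` draws a perfect realization of the pattern (unpaired
positions from their classes, arcs from the complementarity rules; class
conflicts fall back to a class-respecting draw whose residual cost is
recorded), applies randomly chosen edit operations on distinct positions —
never at the site boundaries — within an operation-cost and an indel budget,
and embeds the sites in uniform background with recorded coordinates. By
construction the planted alignment costs exactly the applied cost, so the
distance at a planted start is at most the applied cost and a search with
`K =` budget, `d =` indel budget recovers every site (sensitivity 1.0), which
the tests assert for all four engines.

What the generator emulates is deliberately narrow: independent uniform
background, isolated motif instances, independent edits. Real genomes have
skewed composition, repeats (which the index engines exploit, so realistic
speedups will differ), overlapping and clustered motifs, and correlated
compensatory mutations that preserve pairing. Passing the planted-recovery
tests therefore demonstrates correctness of the match semantics, not
field sensitivity or specificity of any particular pattern.

## Problem sizes in the test suite

The suite runs entirely on synthetic data built at test time: oracle
equivalence on 500 instances with `m <= 6`, texts up to 8 (the enumeration
oracle is exponential); four-way engine equivalence on 100 instances with
targets of 150–600 nt and patterns of 5–14 nt; suffix-array invariants
against naive sorting up to 200 nt; chaining against exhaustive enumeration
up to 12 fragments. These sizes exercise every code path (all four region
conditions, wobble rules, ambiguity codes, tail windows, chain ties) while
keeping the default run in tens of seconds.

## Known limitations

* Pseudoknots (crossing structures) cannot be expressed in dot-bracket input
  and are rejected.
* Scoring is the unit-cost edit scheme; there is no RIBOSUM-style
  substitution scoring and no thermodynamics.
* Execution is single-threaded (`--threads` is accepted for compatibility).
* The index build is `O(n log^2 n)` and in-memory; `lcp` uses full-width
  integers rather than a byte table with an exception list.
* Local chaining reports maximal chains under plain-sum scoring; if a gap
  penalty between fragments is wanted it must be imposed downstream.
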