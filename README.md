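# rsspsearch

Approximate matching of RNA sequence-structure patterns (RSSPs) in nucleotide
sequences.

Homology search for non-coding RNAs cannot rely on sequence alone: family
members often conserve their base-paired secondary structure far better than
their primary sequence. `rsspsearch` is for people who describe an RNA motif
as a pattern — an IUPAC sequence string plus a dot-bracket structure string —
and want every place in a target sequence (or genome-scale FASTA) where that
motif occurs approximately, with mutations allowed on both the sequence and
the structure level.

## The model

An RSSP `Q = (P, R)` of length *m* couples a sequence pattern *P* over the
IUPAC alphabet with a non-crossing structure string *R* over `. ( )`. A
*match* of `Q` in a target `S` is a substring `S[p..q]` whose semi-global
sequence-structure alignment with the complete pattern has edit cost

&nbsp;&nbsp;&nbsp;&nbsp;`dist(Q, S[p..q]) ≤ K` with at most `d` indels, and
`m − d ≤ q − p + 1 ≤ m + d`.

The edit operations are base mismatch (ω<sub>m</sub>) and base indel
(ω<sub>d</sub>) at any position, plus one arc penalty per base pair: *arc
breaking* (ω<sub>b</sub>, both partners aligned but the target bases not
complementary), *arc altering* (ω<sub>a</sub>, one partner deleted) and *arc
removing* (ω<sub>r</sub>, both deleted). Defaults:
ω<sub>d</sub> = ω<sub>m</sub> = ω<sub>b</sub> = ω<sub>a</sub> = 1,
ω<sub>r</sub> = 2. Base-pairing rules default to Watson-Crick plus wobble and
can be any ordered subset of {A,C,G,U}².

Four engines compute the identical match set:

| engine    | idea |
|-----------|------|
| `scan`    | sliding window of length *m + d*; one matrix family per window, only the last column of every matrix recomputed per shift |
| `lscan`   | adds region-wise computation of the pattern (dangling ends, loops, arcs, …) with an early-stop band test: if every alignment of a region already exceeds *K*, the window is skipped |
| `lesa`    | traverses the enhanced suffix array (suf, lcp) of the target; shared prefixes let whole rank ranges be decided at once and matrix columns be reused |
| `lgslink` | adds generalized suffix links (via suf⁻¹): suffixes containing a failing substring anywhere are eliminated, and suffix-link chains reuse the matrices of the previous suffix up to the last column |

Matches of several ordered patterns (a secondary structure descriptor, SSD)
are combined by global or local colinear chaining; a match of cost *c* enters
a chain with weight ω\*<sub>Q</sub> − c where
ω\*<sub>Q</sub> = m·ω<sub>m</sub> + bps·ω<sub>r</sub>, and a chain's score is
the sum of its fragment weights.

## A worked example

The 24-nt sequence and hairpin pattern below are the package's running
example (the pattern asks for two unpaired bases, a G≡C-closed arc and a UUU
loop; threshold `cost = 5`, one indel allowed):

```r
library(rsspsearch)
q <- rssp("AAGUUUC", "..(...)", name = "hairpin", cost = 5, indels = 1)
S <- c(example = "CCACCCCCCACCCACCACCCUCUU")
res <- search_patterns(q, S, algorithm = "lgslink")
res$matches
#>     seqid start end length strand pattern cost indels weight
#> 1 example    16  22      7      + hairpin    5      0      4
#> 2 example    17  22      6      + hairpin    5      1      4
```

Two matches are reported, both ending at position 22: the full-length window
starting at 16 (cost 5: three unpaired mismatches, the arc broken by the
non-complementary C…C with one class mismatch on G) and its one-deletion
variant starting at 17. `weight = 4` is the chaining weight 9 − 5. The
alignment of the first match:

```r
match_alignment(q, S, res$matches[1, ])
#> AAGUUUC
#> ..(...)
#>  |   ||
#> CACCCUC
#> cost = 5, indels = 0
```

At `K = d = 1` the same search reports nothing — and the accelerated engines
prove it while computing only a fraction of the matrix cells (see
`attr(, "cells")` on any result).

Command-line use mirrors the R API
(`inst/cli/rsspsearch.R {index|search|fixtures}`):

```sh
Rscript inst/cli/rsspsearch.R index  --fasta target.fa --out idx
Rscript inst/cli/rsspsearch.R search --patterns motif.txt --fasta target.fa \
    --algorithm lgslink --index idx.manifest --strand both --chain global
```

Pattern files are records of a `>name` line, a sequence line, a structure
line and optional `cost=`/`indels=` lines; `#` starts a comment.

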