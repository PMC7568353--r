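---
title: "Reference pangenome graphs: model, mapping and construction methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference pangenome graphs: model, mapping and construction methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangraphr)
```

# The data model

A pangenome graph here is a bidirected sequence graph: vertices
(*segments*) carry DNA, and each edge (*link*) endpoint carries an
orientation, so a link can be traversed forward-forward, forward-reverse,
and so on. The rGFA dialect adds three tags to every segment — `SN` (the
stable sequence it derives from), `SO` (its 0-based offset on that
sequence) and `SR` (rank: 0 on the linear reference backbone, higher for
sample-derived material). Two consequences make this a usable *reference*
structure:

* every base in the graph has a unique **stable coordinate**
  (`chr1:9`-style), obtained by adding the within-segment offset to `SO`,
  which survives graph transformations such as segment splits;
* distinct regions of one stable sequence may never collapse onto one
  segment (validated after every parse, split and augmentation), so the
  inverse lookup from stable coordinate to segment is unambiguous.

Internally all coordinates are 0-based and half-open. GAF declares its
query start "0-based, closed" and its end "open"; we read that pair as the
ordinary half-open interval and render it unchanged on output.

Mappings are written as GAF: 12 tab-delimited columns extending PAF, with
column 6 an oriented path matching
`([><][^\s><]+(:\d+-\d+)?)+|([^\s><]+)`. Paths come in segment
coordinates (`>s1>s2>s3`) or stable coordinates; abutting same-strand
stable intervals merge (`>chr1:0-5>chr1:5-8` becomes `>chr1:0-8`), and a
path confined to one stable sequence reduces to the bare name, at which
point the line is valid PAF. For reverse-oriented elements we merge when
the intervals abut in descending coordinate order; the convention is
chosen so that reversing a walk reverses the converted element list — the
format itself does not spell this case out.

Column 7 of a non-reduced record is the total bp length of the path
(consistent with columns 8-9 indexing into the path); only reduced
records carry the full stable-sequence length there.

# Mapping: seeding and chaining

**Seeding.** Minimizers (default k = 19, window = 10) are collected per
segment. The hash is an invertible multiply-mod-4^k mix of the 2-bit
canonical encoding, so every index hit is an exact k-mer match; k-mers
containing N and strand-symmetric palindromes are skipped. Hashes whose
posting lists exceed 250 entries are dropped (repeat masking). Because
minimizers are never selected across segment junctions, variation sitting
on a junction of many short segments cannot be seeded — the known
limitation of this mapping approach, and the reason dense small-variant
graphs are out of scope.

**Linear chaining.** An anchor `(x, y, w)` matches a closed w-long
interval ending at `x` on a segment with one ending at `y` on the query.
Within each segment/strand run, the chain score is

    f(i) = max( max_j { f(j) + a(j,i) - b(j,i) }, w_i )

with `a = min(min(dy, dx), w_i)` matching bases and the gap cost
`b = c1*g + c2*min(dx, dy) + log2(g)` for gap `g = |dy - dx|`, zero when
`g = 0` and infinite beyond `G` (default 100 kb). The coefficients are
`c1 = exp(-d k)` and `c2 = 0.05 exp(-d k)` with an expected divergence
d = 0.01. The exact predecessor search is restricted to a `G' = 10 kb`
window; in parallel, a candidate optimal under the *linear* cost
`c1*(dx + dy)` over the full `G` window is retrieved from a dynamic
range-min-query structure, and whichever wins under the full cost becomes
the predecessor. With `G' = G` the combination provably returns the exact
optimum, which the test suite asserts against a quadratic oracle.

The RMQ structure is an AVL tree over `(y, s)` pairs in which every
subtree holds a pointer to its minimum-`s` node; insert, delete and
range-minimum are O(log m). The linear-cost recurrence is folded into it
by storing `-(f'(j) + w_j + c1 (x_j + y_j))` keyed by `y_j` and evicting
anchors that fall behind the `G` window. The printed recurrence for the
linear-cost score has no explicit base case; we take
`f'(i) = max(0, ...)` so that a chain's score is `f'(i) + w_i`, matching
the bookkeeping of the stored key. Ties among equal-scoring predecessors
break toward the smaller gap, then the later anchor, so output is
deterministic.

Chains are recovered by backtracking from high scores, dropping chains
scoring under 40 or with fewer than 3 anchors (artifact parameters; the
method's sources do not state them).

**Graph chaining.** Linear chains ignore topology; a second DP joins
them. Chain `L_j` precedes `L_i` when it ends earlier on the query and a
walk connects them in the graph; we enumerate up to the 16 shortest walks
(uniform-cost search, segment revisits allowed, pruned at `G`) and use
the one whose graph length is closest to the query distance, measured
anchor-end to anchor-start. The DP is the chain recurrence again with
`omega(L_i)` in place of per-anchor scores. The printed form of this
recurrence adds the predecessor's `omega` rather than the current
chain's; read literally it never counts the final chain and double-counts
the first, so we implement the standard form `g(i) =
max(max_j{g(j) + omega(L_i) - beta(j,i)}, omega(L_i))` — the
brute-force oracle in the tests uses the same corrected recurrence.
Mapping quality is computed minimap2-style from the best and second-best
graph-chain scores, capped at 60. There is no base-level alignment during
mapping: the graphs this tool builds encode structural variants, so path
choice is rarely decided at base resolution.

# Incremental construction

For each assembly in turn: map every contig to the current graph, label
graph chains primary when under half their query span overlaps a
higher-scoring primary chain (an overlap quantification the sources leave
open; 50% is the minimap2 convention), and keep **orthogonal regions** —
parts of the query inside a primary chain longer than 100 kb and not
intersecting another primary chain longer than 20 kb. This avoids
augmenting from paralogs.

Along each primary chain the adjacent-anchor divergence score is

    h_i = -10                      if dx = dy <= w_{i+1}
        = eta * max(dx, dy)        otherwise

with `eta` the anchor density (anchors per query bp) averaged over all
primary graph chains — we compute it as one global ratio, total anchors
over total spanned bp, the simplest reading of "averaged". The -10 is
deliberately insensitive; downstream verification does the real
filtering. All maximal positive-scoring runs of `h` are found with the
Ruzzo-Tompa algorithm in linear time. Each such region, spelled from the
chain's walk with one flanking anchor of context on each side, is
verified by global affine-gap base alignment (match/mismatch/open/extend
= 2/-4/-6/-2): the region is retained if the alignment contains an indel
run of at least 100 bp or a 100-column window of aligned bases with
identity below 80%. Identity windows are computed over aligned base
pairs, not gap columns — otherwise any indel above ~25 bp would trigger
the identity branch and the 100 bp SV floor below would be meaningless.
Regions smaller than 100 bp on both sides are skipped without aligning
(they can satisfy neither branch).

Retained events pass the SV filter — length within 100 bp-100 kb, host
alignment at least 100 kb — and are inserted: the backbone is split at
both breakpoints (leftmost-aligned indel placement; deterministic), a new
segment carrying the query subsequence is added with `SN` = contig name,
`SO` = query offset, `SR` = the assembly's 1-based index, and links
attach it between the flanks; pure deletions add only a flank-to-flank
link. Splitting never moves a stable coordinate, so augmentation is
monotone and coordinate-preserving. Events whose breakpoints do not land
on forward rank-0 segments are skipped with a message: inversion
augmentation is out of scope here (the bidirected model itself supports
it), as is augmentation from reverse-strand chains.

Within one assembly, all contigs are mapped against the same snapshot of
the graph and events are applied afterwards, so contig order cannot
change discovery.

# Bubbles and blacklists

A **variation** is a minimal subgraph with a single source and single
sink, both on the rank-0 backbone, whose interior has no edge to the
outside; each source-to-sink path is an allele. The scan walks the
backbone in stable order and grows each candidate locus until the
furthest backbone segment reachable through alternative material
stabilises; alleles are enumerated by depth-first search (cap 64,
duplicates collapsed with a warning), and side branches that never rejoin
are reported as tips rather than alleles.

Blacklist regions — reference intervals where SV-induced misalignment
inflates small-variant errors — are computed as `I0 ∪ I(0, 0.99) ∖
I(0.998, 1)`: variation intervals padded by 50 bp (`I0`, unmerged at this
stage), united with reference intervals covered by inserted-sequence
alignments at identity at most 0.99, minus intervals covered at 0.998 or
better. We bind the union before the subtraction (the formula's
left-to-right reading), take identity stratum bounds as inclusive, take
`I0` per variation rather than per allele, and define identity as PAF
matches over block length; alignments under mapping quality 5 are
dropped. Interval algebra is delegated to IRanges; results are sorted,
disjoint, half-open BED.

# Synthetic data

The generator emulates the study conditions the pipeline targets: a
random megabase-scale reference; haplotypes carrying implanted
insertions/deletions of 100 bp-10 kb (log-uniform, evenly strided with at
least twice-the-maximum-length spacing so events cannot interact) plus
optional VNTR expansions of a 10-100 bp motif; 1% SNP divergence; and
exponential-length long reads (15 kb mean, 5% errors at a 4:3:3
sub:ins:del mix). Everything is seeded and bit-reproducible, and truth
records reconstruct the assembly exactly (a tested invariant).

What it does *not* emulate: real repeat structure (segmental
duplications, satellite arrays), assembly errors, biased error profiles,
and inter-sample haplotype sharing. Passing the simulation round-trip
therefore demonstrates the machinery — seeding, chaining, verification,
augmentation, bubble calling — under clean conditions, not performance on
real genomes; the population-scale statistics published for assembly
cohorts are inherently out of desk-scale reach.

# Problem sizes and numerical choices

The test suite exercises the construction round-trip at a 1 Mb reference
with two haplotypes of 20 SVs each (about a minute of compute), property
checks against brute-force oracles at n ≤ 200 anchors / ≤ 50 scores /
≤ 12 chains, and 10^4-operation RMQ workloads; these sizes were chosen to
make every oracle exhaustively checkable. Scores are plain doubles;
`log2(1)` contributes exactly 0 to the gap cost; infinite penalties are
rejection sentinels, never stored; and alignment above a 200 kb cap falls
back to proportional chunking with a warning (at the sizes the SV filter
admits this does not trigger).
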