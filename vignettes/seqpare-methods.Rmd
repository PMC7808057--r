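---
title: "Comparing genomic interval sets with a mutual-best-match Jaccard index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing genomic interval sets with a mutual-best-match Jaccard index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqpare)
```

## The problem

Functional-genomics assays (ChIP-seq peaks, ATAC-seq accessibility, CpG
islands, gene annotations, ...) are routinely summarised as *interval sets*:
collections of `(chromosome, start, end)` spans, usually shipped as BED
files. Searching a public repository means asking, for a query set, which
deposited sets are most *similar* — and that requires a number that actually
measures similarity.

The scoring used by popular interval-database search tools derives from
Fisher's exact test on a 2×2 table built from the cross-set intersection
count `n`. That construction has structural problems:

* the fourth cell needs a **universe size** (the number of intervals that
  exist "in neither set"), which is not objectively defined for a genome;
* intervals span 1 to ~10^5 bases, so two essentially unrelated intervals
  that touch by a few bases count exactly as much as two identical ones;
* one broad interval can contain many narrow ones, so `n` can *exceed* the
  set sizes `N1`, `N2`, driving the `N1 − n` and `N2 − n` cells negative and
  leaving both the p-value and the odds ratio undefined without an ad-hoc
  clamping convention;
* p-values on large sets saturate around 10^-200 and stop discriminating.

This package implements a single self-consistent index instead, along with
the Fisher baseline itself (including the clamping convention) so the two
can be compared on the same inputs.

## The index

For two intervals with lengths $l_1$, $l_2$ overlapping by $o$ bases, the
per-pair similarity is the Jaccard index of the spans,

$$s = \frac{o}{l_1 + l_2 - o} \in [0, 1],$$

with $s = 1$ exactly for coincident intervals. The *total effective
overlap* of two sets is

$$O = \sum_{\text{MBM pairs}} s,$$

summed over **mutual-best-matching (MBM) pairs**: pairs in which each
interval is the other's best-scoring intersecting partner. The selection is
greedy and strict — repeatedly take the remaining intersection pair with the
highest $s$, then discard every pair sharing one of its intervals — so each
interval is used at most once, $|\text{pairs}| \le \min(N_1, N_2)$, and
$0 \le O \le \min(N_1, N_2)$. The set-level index is then

$$S = \frac{O}{N_1 + N_2 - O} \in [0, 1],$$

a Jaccard-style ratio of effective overlap to effective union: $S = 0$ iff
no cross-set pair overlaps, and $S = 1$ forces $N_1 = N_2 = O$, i.e. a
perfect interval-by-interval correspondence. Because best matches are
mutual, $O$ — and hence $S$ — is symmetric in the two sets. A set compared
with itself scores exactly 1 through the ordinary code path: every
interval's mutual best match in the copy is itself, with $s = 1$.

`compare_sets()` runs this pipeline; `enumerate_intersections()`,
`select_mbm_pairs()` and `seqpare_index()` expose the stages.

```{r}
fx <- make_figure1_fixture("b")
enumerate_intersections(fx$set1, fx$set2)
compare_sets(fx$set1, fx$set2)
```

## Conventions and numerical choices

**Coordinates.** BED semantics throughout: 0-based, half-open
`[start, end)`, length `end − start ≥ 1`. "Intersect" means an overlap of
at least one base; abutting intervals do not intersect. Chromosome names
are opaque strings (`chr1` ≠ `1`).

**Degenerate records.** Zero-length records (`end == start`) can never
overlap anything under half-open semantics; they would only inflate `N`, so
`read_bed()` drops them with a warning. `end < start` marks a corrupt file
and is a hard error. Duplicate and nested intervals are retained, never
merged: `N` is the raw record count, and within-set containment is exactly
what makes the intersection count exceed `N` in self-comparisons — a real
structural feature the Fisher baseline trips over.

**Tie-breaking.** When several intersection pairs share the maximal $s$,
candidates are ordered by ($s$ descending, set-1 index ascending, set-2
index ascending) and the first is taken. The greedy rule itself does not
prescribe an order among equal-$s$ pairs, and while the worked examples are
tie-order-invariant, invariance in general is not established — so the
package fixes one deterministic order and exposes the chosen pairs via
`compare_sets(..., detail = TRUE)` for inspection.

**Floating point.** $s$ and $O$ accumulate in double precision. Identity
and symmetry are exact in this arithmetic (sums of identical terms in
identical order), and the test suite asserts them with exact equality;
derived rationals such as $S = 1/14$ are asserted at tolerance $10^{-12}$.

**Empty sets.** One empty set forces $O = 0$, so $S = 0$. Two empty sets
make the index 0/0; the package defines $S = 0$ there — reporting perfect
similarity on no evidence would be the more surprising choice — and emits a
message.

**The overlap index.** Cross-set pairs are enumerated per chromosome with a
start-sorted array augmented by a running maximum of interval ends
(`maxend[k] = max(end[1..k])`). Both query boundaries come from binary
search (`findInterval`): hits for a probe `[qs, qe)` lie among positions
with `start < qe` and `maxend > qs`, then a vectorised filter removes
candidates whose own end is too small — nested intervals make the candidate
range a superset of the hits, never a subset. This is a deliberately
single-component simplification of augmented-interval-list indexing;
correctness is pinned to an exhaustive $O(N_1 N_2)$ all-pairs oracle
(`brute_force_intersections()`), which the property tests hold element-for-
element equal to the indexed enumeration across hundreds of random set
pairs with mixed densities, duplicates and nesting.

## The Fisher baseline

`build_contingency(n, N1, N2, universe)` assembles the table
`(n, N1−n, N2−n, m)`. The universe size is a **required argument**: the
tools that use this baseline either leave the universe to the user (where
it is not objectively defined) or estimate it internally by an unpublished
rule, so the package refuses to guess. When `n > N1` or `n > N2`, the
negative cells are clamped — to 0 for the p-value path, to 1 for the
odds-ratio path — following the convention of the GIGGLE search tool, with
flags recording that clamping occurred; `m` is computed from the clamped
cells and floored at zero with a loud warning. The two-sided p-value is the
standard sum of hypergeometric point probabilities no larger than the
observed table's (computed by `stats::fisher.test()` on the clamped cells;
the test suite checks it against an independent brute-force tail
enumeration). The odds ratio is the sample cross-product ratio
$(n \cdot m) / ((N_1−n)(N_2−n))$, reported as `Inf` when a non-overlap cell
is zero — which happens for *any* comparison of identical small sets, one
of the baseline's inconsistencies the toy geometries demonstrate:

```{r}
fa <- make_figure1_fixture("a")  # two identical sets
fb <- make_figure1_fixture("b")  # three very different intervals each
p_a <- fisher_p(build_contingency(count_intersections(fa$set1, fa$set2),
                                  2, 2, universe = 100))
p_b <- fisher_p(build_contingency(count_intersections(fb$set1, fb$set2),
                                  3, 3, universe = 100))
c(p_identical = p_a, p_different = p_b)  # the DIFFERENT sets look "better"
c(S_identical = compare_sets(fa$set1, fa$set2)$S,
  S_different = compare_sets(fb$set1, fb$set2)$S)
```

## The toy geometries

No coordinates are published for the illustrative panels, only length
ratios (1:5, 1:3:5, 2:3:4) and the resulting quantities.
`make_figure1_fixture()` uses minimal integer geometries derived to satisfy
every printed value at once; the derivations are spelled out in its
documentation (for instance, an $s = 1/9$ between two length-5 intervals
forces an overlap of exactly one base, and $S = 1/14$ with $O = 2/5$ forces
$N_1 + N_2 = 6$). Panel "c" is not reconstructed — only its intersection
count is published, which under-determines the geometry — and its
containment behaviour is covered by panel "d" and the random suites. The
tests assert each panel's printed quantities, so any coordinate drift would
fail loudly.

## What the synthetic generators emulate — and what they do not

`random_interval_set()` draws starts uniformly over a span and lengths
uniformly over a range, optionally across several chromosomes; at the
defaults (span 10^5, lengths 1–1000) duplicates and nesting occur
naturally, as in real tracks where broad domains contain narrow peaks.
`perturb_set()` drops, shifts and resizes intervals to produce families of
progressively less similar copies; the test suite asserts a non-increasing
similarity trend over shift magnitudes spanning four orders. Both are
bit-reproducible under a caller-supplied seed and restore the global RNG
state.

Real genomic tracks are *not* uniform: interval density follows chromatin
and assembly structure, lengths are heavy-tailed, and related assays
co-localise. Passing the property suites therefore demonstrates the
metric's algebraic laws (range, symmetry, exact self-identity, the
matching's exclusivity, oracle equivalence of the enumeration) on adverse
random geometry — not that any particular biological pair of tracks will
score highly. The published search over 100 UCSC annotation tracks, with
its real-data similarities and GIGGLE's internally estimated universe, is
outside what can be recomputed from synthetic data; the search *workflow*
(one comparison per database file, deterministic ranking, rank-1
self-retrieval with $S = 1$) is what the suites pin down, using 20 seeded
databases of 5–50 sets with up to 5,000 intervals each over a 10^6-base,
3-chromosome layout — sparse enough to resemble genomic track density while
keeping the full suite around a minute.

## Known limitations

* Greedy MBM selection is the defining procedure, not an approximation
  target: a maximum-weight bipartite matching could yield a larger $O$, but
  would be a different metric.
* Whether greedy $O$ is invariant to the order in which equal-$s$ ties are
  consumed is not established in general; the deterministic tie-break makes
  results reproducible rather than settling that question.
* The index weights every interval equally regardless of length; two sets
  differing only in a handful of megabase-scale domains can score close to
  sets differing in many small peaks.
* No genome-assembly awareness: chromosome names are not validated or
  normalised, and strand is ignored.
* The search scans the database per query; there is no persistent on-disk
  index.
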