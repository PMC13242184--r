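---
title: "Effective sequence counts for multiple sequence alignments: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective sequence counts for multiple sequence alignments: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neffr)
```

## The statistic

A multiple sequence alignment (MSA) with $N$ rows and $L$ columns often
contains heavy redundancy: iterative homology search returns many
near-identical hits, so $N$ alone says little about the evolutionary
information the alignment carries. The *number of effective sequences*
corrects for this. Every sequence $n$ is assigned a weight

$$w_n = \frac{1}{1 + \sum_{m \ne n} \mathbb{1}\left[S_{m,n} \ge \theta\right]},$$

the reciprocal of the number of sequences (including itself) whose pairwise
similarity to it reaches the threshold $\theta$, and

$$\mathrm{NEFF} = \frac{1}{L}\sum_{n=1}^{N} w_n .$$

A cluster of $k$ mutually similar sequences contributes $k \cdot 1/k = 1$
to the unnormalized sum, so the statistic behaves like a soft cluster
count. The Iverson bracket is inclusive ($\ge \theta$), and the default
$\theta = 0.8$ is the value used throughout the contact- and
structure-prediction literature; downstream accuracy of MSA-based
predictors is known to correlate with this quantity.

`compute_neff()` returns both the normalized value and the raw weight sum.
Three normalizations are offered via `norm`: `"by_length"` ($1/L$, the
default, with $L$ the post-preprocessing column count — under default
query-gap removal this is exactly the query's residue count),
`"by_sqrt_length"` ($1/\sqrt{L}$), and `"none"`. The raw sum always lies
in $[1, N]$.

## Pairwise similarity: symmetric and asymmetric

The similarity axis has two standard constructions, both provided:

* **Symmetric** (default): the fraction of columns at which the two rows
  carry the same code, a gap aligned to a gap counting as a match, divided
  by the common alignment length. $S_{i,j} = S_{j,i}$.
* **Asymmetric**: the directional identity into row $j$ divides the
  columns where the codes agree *and $j$ is non-gap* by $j$'s non-gap
  length. Code agreement implies both rows are non-gap there, so the
  numerator is shared between the two directions while the denominators
  differ. A row with no residues at all has similarity 0 into it (flagged,
  not an error). The weight of row $n$ uses the similarities *into* $n$.

These are the constructions used by the established tools on each side of
the axis; neither is given a formula in most tool descriptions, so the
exact divisor conventions above are this package's pinned choice and are
echoed in every result object.

## Preprocessing

Three filters are applied to the encoded matrix in a fixed, documented
order — depth cap, query-gap removal, gappy-column removal — because the
order changes the result (a depth cap changes gap fractions; query-gap
removal changes the columns the gap filter sees):

1. **Depth cap** (`depth`, off by default): keep the first `depth` rows,
   always retaining the query.
2. **Query gaps** (`keep_query_gaps = FALSE` by default): drop every
   column where the query row holds a gap. These columns arise from
   insertions in other sequences; removing them makes $L$ the query
   length.
3. **Gappy columns** (`gap_cutoff`, default 1.0 = disabled): drop columns
   whose gap fraction over the remaining rows *strictly exceeds* the
   cutoff. The strict comparison means the default 1.0 can never trigger,
   making the filter opt-in.

Per-residue values and the normalization factor are always computed on the
post-preprocessing matrix, with `column_map` translating back to original
column coordinates.

## Numerical choices

Similarities are ratios of integer counts. The threshold comparison is
performed in floating point, but the optimized C++ kernel first converts
$\theta$ into the smallest integer match count $t$ with $t/d \ge \theta$
for the relevant denominator $d$ (verified against the same
double-precision comparison), after which thresholding is exact integer
arithmetic — the kernel agrees *exactly*, not just within tolerance, with
a literal naive $O(N^2L)$ double loop, and the test suite asserts this
identity on hundreds of random alignments across all option combinations.
The symmetric path additionally early-exits a pair once its mismatch
budget $L - t$ is exhausted, which keeps deep alignments (thousands of
rows) in the low seconds on one CPU.

## Alphabets, non-standard residues, validation

Three alphabets are supported: protein (20 standard letters), DNA
(`ACGT`) and RNA (`ACGU`). The non-standard sets are `B J O U X Z` for
protein and the IUPAC ambiguity letters plus `X` for nucleotides — the
permitted-set contents are a design decision here, chosen as the defensible
IUPAC closure. Two policies govern them: `as_standard` (default; each
keeps its own code, preserving information) and `as_gap` (all map to the
gap code, the convention of several older tools). `*` and anything else is
rejected outright rather than silently dropped. `validate_msa()` checks
format structure, row-length consistency and the permitted character set
without modifying the input, reporting 1-based line numbers.

## Formats

Seven alignment formats are read and written: FASTA, A2M, A3M, Stockholm,
ALN, Clustal and PFAM. A2M/A3M carry alignment-state semantics in case
(uppercase/`-` = match, lowercase/`.` = insertion; A3M omits the `.`
placeholders so raw row lengths differ); `resolve_insertions()` produces a
column-aligned view either by removing insertion states (default — the
match-column view is what the effective-count computation consumes) or by
expanding each insertion run into full columns, left-aligned and padded.
Where a dialect is underspecified in the wild, the package pins a minimal
one: ALN is bare aligned rows (ids are synthesized on read and dropped
with a warning on write), PFAM is a one-line-per-record Stockholm body.
Stockholm annotation lines (`#=GF/GC/GS/GR`) pass through reading, merging
and Stockholm/PFAM writing verbatim; lossy targets warn about exactly what
they drop. Merging multiple MSAs deduplicates on the gap-normalized,
uppercased sequence string only — ids are deliberately ignored, since the
same sequence is routinely hit under different database identifiers — and
by default insists that all inputs share one query (overridable), a
safety check rather than a hard semantic requirement.

## Multimer alignments

Concatenated multimer MSAs (the paired alignments used by
complex-structure predictors) are segmented by *explicit chain lengths*;
no attempt is made to infer boundaries from gap structure, which is
ambiguous. A non-query row is *paired* when at least two of its chain
segments contain residues, otherwise unpaired for its single occupied
chain; rows with no residues anywhere are dropped with a warning. NEFF is
reported for the full width, for the query-plus-paired block, and per
chain over the rows occupying that chain (rows all-gap in a chain carry no
signal for it and would only distort weights). For homomers an option
stacks the chain sub-MSAs, deduplicates, and reports one per-entity value.
Pairwise chain-pair statistics for heteromers are out of scope.

## The synthetic generator

`generate_msa()` draws a root sequence, derives `n_clusters` centers by
resampling each column with probability `center_divergence` (default 0.5,
which keeps across-cluster identity far below $\theta = 0.8$ for realistic
lengths), then populates rows by per-column mutation at `mutation_rate`
and per-cell gap injection at `gap_rate`; the query is the gap-free,
unmutated root so that default query-gap removal is a no-op unless gaps
are injected deliberately. With small mutation rates the unnormalized
NEFF concentrates near `n_clusters`, giving tests a known target. The
generator uses R's Mersenne-Twister with an explicit seed and restores the
caller's RNG state.

What it emulates: identity clusters, uniform gap scatter, multimer
paired/unpaired block structure with exact bookkeeping. What it does not:
phylogenetic correlation (no tree), position-specific conservation,
realistic gap runs (real indels are contiguous), or database-scale
redundancy profiles. Passing tests therefore certify the *computation* on
alignments with known structure, not distributional claims about real
MSAs.

## Problem sizes used by the test suite

The suite checks kernel-vs-naive identity on 200 random alignments with
$N \le 50$, $L \le 40$ across all option combinations; invariants
(duplication invariance, row-permutation invariance, monotonicity in
$\theta$ over a 10-point grid, the $[1, N]$ bounds) on dozens of random
fixtures; and one deep alignment of $N = 2000$, $L = 300$ with a 50-row
naive spot check. The acceptance script recomputes headline quantities on
a 500-row, 150-column, 5-cluster alignment. These sizes were chosen so the
full suite runs in well under a minute while still exercising the blocked
kernel path.

## Known limitations

* Entropy-based and clustering-based effective-count variants are not
  implemented; the normalization enum is the only family of alternatives
  offered.
* Alphabet is never auto-detected silently; the caller states it.
* DNA/RNA translation is out of scope (a `U` in a DNA alignment is an
  error, by design).
* Compressed input and PHYLIP/MSF/NEXUS formats are not supported.
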