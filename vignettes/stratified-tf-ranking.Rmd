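---
title: "Ontology-stratified ranking of dominant transcription factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-stratified ranking of dominant transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A DNase-seq or ATAC-seq experiment yields a set of accessible chromatin
regions — thousands of peaks, each a genomic interval. Many transcription
factors (TFs) have predicted binding sites inside those peaks, and the TFs
with the *most* sites are rarely the most informative: ubiquitous,
promiscuous binders dominate any raw abundance count. The question this
package answers is different: *which TFs are functionally dominant* in the
cell state that produced the peaks — that is, which TFs concentrate their
binding sites in the regulatory territory of functionally coherent gene
sets, rather than merely being abundant.

`tfstrata` takes three reference inputs (gene models with canonical TSS
positions, a gene–term annotation table with ontology `is_a` edges, and a
library of per-TF predicted binding-site tracks) plus the query peak set,
and returns a ranked table of TFs with a nonparametric dominance score and
an exact conditional p-value per TF.

## The procedure

**1. Regulatory domains.** Each gene receives a putative cis-regulatory
territory by the basal-plus-extension rule: a strand-aware basal domain
(default 5 kb upstream / 1 kb downstream of the TSS) extended on each
flank up to a maximum (default 1 Mb), stopping at the nearest neighbouring
gene's basal domain, clipped to the chromosome. A term's domain is the
union of its (propagation-closed) genes' domains; `p_π`, the probability
that a uniformly drawn non-gap base lies in the term's domain, is its base
fraction.

**2. Stratum selection.** Query elements are restricted to those
overlapping at least one binding site of any TF (*informative elements*).
Each candidate term — annotating between 2 and 500 genes after upward
propagation — is scored with two GREAT-style tests: a region-based
binomial (are more informative elements inside the term's domain than
`p_π` predicts?) and a gene-based hypergeometric (are the term's genes
over-represented among genes whose domain the query hits, against the
universe of all annotated genes?). The top `K` terms (default 100) ordered
by ascending binomial p-value (hypergeometric, then term id, as
tie-breaks) become the strata `π_1 … π_K`.

**3. TF-by-term enrichment.** For TF *i* and term *j*, with `n_i` the TF's
distinct sites overlapping the query, `k_ij` those also inside the term's
domain, and `N`, `K_j` the same counts for the union of all TF tracks, two
tails are computed per cell: a hypergeometric tail on
`(k_ij, n_i, K_j, N)` and a binomial tail of `k_ij` out of `n_i` at rate
`p_π`. Both are evaluated in log space; a p-value is never reported as
exactly zero (it is floored at the smallest positive double, and all
internal comparisons use the log value, so underflow cannot collapse
ratios).

**4. Adaptive leap threshold.** Within each term, the sorted top 10
p-values `p_1 ≤ … ≤ p_10` define gaps `d_k = −log(p_k / p_{k+1})`
(natural log; the argmax is base-invariant). The threshold is `p_m` at
`m = argmax_k d_k`, taking the smallest index on ties (the most stringent
choice), and every TF in the library with `p ≤ p_m` passes — including
ties beyond the inspected ten. With a single finite p-value a leap is
undefined and the lone TF passes. A TF is *significant* for a term when it
passes both the hypergeometric and the binomial threshold **and** has at
least one site in the term's domain. The last condition is ours: in a
stratum with no signal at all, every p-value ties at exactly 1, the
tie rule alone would keep the whole library, and the deterministic
alphabetical rank tie-break would then hand the lexicographically first
TF a spurious `1/j` from every empty stratum. A TF with zero in-domain
sites cannot be dominant there, so it is excluded before scoring.

**5. Score.** Within each term TFs are ranked (ascending hypergeometric
p, ties by binomial p, then name; see *Open design points*). The partial
score of TF *i* in stratum *j* is `Significant(i,j) / (j · Rank(i,j))`,
and the score is the sum over strata. Earlier strata and better in-term
ranks contribute more; the harmonic weights make the score scale-free, so
the *ranking* of TFs, not the score magnitude, is the product.

**6. Exact conditional p-values.** Under the null that every within-term
ordering of the N TFs is equally likely, a TF's score is a sum of
independent per-term draws: value `1/(j·r)` with probability `1/N` for
each scoring position `r` of term `j`, else 0. The exact distribution is
built by dynamic programming over terms, merging equal cumulative scores
and adding configuration counts; `P(score ≥ x)` is a ratio of
configuration counts over `N^K`. Because scores of different TFs compete
for the same rank positions, the *i*-th ranked TF is tested
conditionally: the *i*−1 better TFs are removed from every term's
ordering, remaining ranks are compacted preserving order, retained
significance flags define the scoring positions, the focal TF's score is
recomputed under compacted ranks, and the null uses N−(i−1) TFs. For
*i* = 1 nothing is removed, so the conditional p-value *is* the marginal
one — asserted bit-exact in the test suite.

## Numerical choices

* **Rational DP.** The summands `1/(j·r)` are rationals. Cumulative
  scores are carried as integer numerators over the least common multiple
  of all summand denominators whenever that lcm stays below 2⁴⁴ (so all
  integer arithmetic remains exact in doubles); merging is then exact
  equality and the DP agrees with exhaustive enumeration *exactly*, not
  within tolerance. When the lcm or the state count (cap 2 × 10⁶)
  exceeds the guard, the DP falls back to merging scores rounded to
  12 decimal digits and says so in a warning; tail comparisons then use a
  10⁻⁹ slack. The default synthetic bundles and all small instances run
  in exact mode.
* **Counting convention.** All `#{·}` quantities are element counts, not
  base counts; element sets are sets (duplicate coordinates collapse), so
  `k_ij ≤ n_i ≤ N` and `k_ij ≤ K_j ≤ N` hold structurally.
* **Coordinates.** BED convention throughout: 0-based half-open on disk
  and in constructors, 1 bp of overlap suffices, overlap is
  strand-agnostic. Chromosome names are compared as exact strings and a
  complete naming mismatch (`chr1` vs `1`) is an error naming the
  offender, never a silent empty result.
* **Determinism.** Every ordering in the pipeline has a total tie-break
  ending in a name or coordinate; identical inputs and seed give
  byte-identical reports. Midpoint trimming uses
  `c = floor((start+end)/2)`, result `[c−floor(L/2), c+ceil(L/2))`.
  Subsampling keeps `round(fraction·n)` elements (half-up); ties at the
  cutoff score are drawn with the run seed.

## Open design points

The per-term rank basis is not dictated by the score definition; we rank
by the hypergeometric p-value (binomial as tie-break) because the
adaptive-threshold construction is phrased around hypergeometric
p-values, and the choice is isolated in `rank_within_terms()`. Term
ordering similarly combines the two term-level tests with the
region-based binomial as the primary key, the display convention of
GREAT-style tools. Conditioning semantics (remove, compact, retain
flags, recompute the observed score) is one consistent reading of
"remove higher-ranked TFs and reapply the recursion"; it lives behind
`conditional_pvalues()` so alternatives can be swapped. Significance
flags are *not* re-derived after removal: the thresholds describe the
full-library evidence, and re-running them on a shrinking library would
let the null drift from the observed masking.

## The synthetic bundle generator

`generate_fixture()` emulates the statistical structure the method
assumes, at desk scale: one 1 Mb chromosome, 60 genes, a two-level
ontology (9 leaves × 5 genes, 3 roots), 20 TFs × 300 sites of 15 bp, and
400 query peaks of 300 bp with a SCORE column. Thirty percent of peaks
are placed inside the *planted* term's domain; the planted TF puts 40% of
its sites in the query and, of those, a `concentration` fraction
(default 0.8) inside the planted term's domain; a *decoy* TF puts 70% of
its sites in the query but uniformly across peaks; the rest are uniform
on the genome. These proportions were fixed from expected-count
arithmetic: the decoy's in-query abundance (~210 of 300 sites) must beat
the planted TF's (~140) so the abundance baseline prefers the decoy,
while the planted TF's in-domain fraction (~0.7 against a background of
~0.35) must dominate the hypergeometric within the planted stratum. At
`concentration = 0` the planted TF becomes functionally uniform — the
negative control in which recovery should fail and the decoy should lead
the abundance-only ranking.

What the generator does **not** emulate: peak-width and site-score
distributions of real data, clustered promoters/CpG islands, assembly
gaps (supported in the pipeline, exercised by micro-fixtures rather than
the bundle), correlated TF families sharing motifs, and read-count noise.
Passing the planted-recovery tests therefore demonstrates that the
statistics behave as designed under the model's own assumptions — not
that the method's biological conclusions transfer to any particular real
dataset.

Test problem sizes are the package's own choices: the planted-recovery
property uses 40 seeds per concentration at the default bundle; the DP is
compared with exhaustive enumeration on 200 random instances with
`N_tf ≤ 5`, `K ≤ 4`; interval algebra is checked against per-base
bit-vectors on 500 random cases over a 10 kb toy genome; the
concentration-monotonicity property uses a reduced bundle (10 TFs × 150
sites, 200 peaks) at 3 grid points × 12 seeds.

## Differential and baseline modes

`run_differential(a, b, …)` subtracts at base level (the portions of A
not covered by B; whole-feature removal is a flag) and runs the full
pipeline on each direction; `combine_region_sets()` supports
multi-replicate contrasts of the form (∩ group 1) ∖ (∪ group 2).
`abundance_ranking()` is the deliberate straw man: binomial tail and fold
of raw in-query site counts at the genomic coverage rate, with no
ontology input — the contrast that shows why stratification matters.

## Known limitations

The gene-level hypergeometric saturates on small dense genomes where the
query hits every gene's domain (it then contributes only tie-breaking);
the score is not comparable across libraries of different size; TFs
sharing near-identical motifs are scored independently (no family or
dimer model); and differential mode ignores read-count evidence — a
region accessible in both samples at very different intensity is treated
as shared.
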