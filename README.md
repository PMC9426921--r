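# tfstrata

Ranks transcription factors (TFs) by **functional dominance** in a set of
accessible chromatin regions (ATAC-seq / DNase-seq peaks), rather than by
raw binding-site abundance.

Sheer-abundance motif counting in open chromatin is dominated by
ubiquitous binders. `tfstrata` instead stratifies the evidence by
function: the query's top enriched ontology terms (found with GREAT-style
binomial and hypergeometric tests over basal-plus-extension gene
regulatory domains) define strata; within each stratum TFs are ranked by
the enrichment of their predicted binding sites; an adaptive p-value leap
threshold masks non-significant TFs; and each TF is scored by

```
score(TF_i) = Σ_j  Significant(i, j) / (j · Rank(i, j))
```

summing over strata `j = 1…K` (default `K = 100`). Significance of the
*i*-th ranked TF is an **exact conditional p-value**: under the null that
every within-term ordering of TFs is equally likely, the score's exact
distribution is computed by dynamic programming (rational arithmetic),
after removing the `i−1` higher-ranked TFs and compacting ranks. The
conditional p-value of the top TF equals its marginal p-value exactly.

The package also provides a differential mode (base-level subtraction
A∖B and B∖A, plus multi-replicate `(∩ group1) ∖ (∪ group2)` contrasts),
an abundance-only binomial-fold baseline for comparison, a robustness
grid (peak subsampling by score, midpoint-preserving trimming, varying
`K`), and a synthetic fixture generator with a planted dominant TF so the
whole pipeline runs and is testable offline.

## Worked example

Everything below is synthetic and self-contained:

```r
library(tfstrata)

dir <- tempfile()
paths <- generate_fixture(fixture_spec(seed = 7), dir)   # planted: TF01,
                                                         # decoy:   TF02
cfg <- run_config(query = paths$query, tfbs_dir = paths$tfbs_dir,
                  genes = paths$genes, annotations = paths$annotations,
                  ontology = paths$ontology,
                  chrom_sizes = paths$chrom_sizes,
                  tf_gene_map = paths$tf_gene_map,
                  out_dir = file.path(dir, "out"))
ranking <- run_single(cfg)
head(as.data.frame(ranking)[, 1:6], 3)
#>   rank   tf     score      cond_p neg_log10_cp n_sites_in_query
#> 1    1 TF01 1.8333333 0.000199866    3.6992611              143
#> 2    2 TF03 0.3787879 0.016171695    1.7912445               38
#> 3    3 TF17 0.3250000 0.036325231    1.4397916               44
```

The planted TF is ranked first with a score an order of magnitude above
the rest: it tops the planted stratum (partial score `1/(1·1) = 1`) and
its parent term. `n_sites_in_query` shows why abundance alone misleads —
the decoy has many more sites in the query:

```r
head(abundance_ranking(read_bed(paths$query), load_tfbs_library(paths$tfbs_dir),
                       read_chrom_sizes(paths$chrom_sizes)), 2)
#>   rank   tf total_sites sites_in_query coverage_fraction       binom_p     fold
#> 1    1 TF02         300            220          0.108042 5.126145e-143 6.787484
#> 2    2 TF01         300            143          0.108042  7.938957e-58 4.411865
```

The abundance-only baseline puts the decoy first; the stratified ranking
does not. `ranking.tsv` and `terms.tsv` in `out_dir` carry the full
report, including each TF's top contributing terms with partial scores
and a closed-loop flag (does a driving term annotate the TF's own gene?).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/tfstrata.R simulate --out fx --seed 7
Rscript inst/cli/tfstrata.R run --config run.yaml
Rscript inst/cli/tfstrata.R diff --config run.yaml --a a.bed --b b.bed
```

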