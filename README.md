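# dedtarget

Consensus transcriptomic target discovery and perturbation-concordance
validation for drug repositioning, at desk scale.

## The problem

When a drug shows therapeutic effect in a multifactorial disease — here
the motivating case is an immunomodulator repositioned for dry eye
disease — its molecular targets are rarely explained by the nominal
mechanism alone. A practical computational strategy is to (i) find the
transcriptional programs that are conserved across heterogeneous disease
models, (ii) intersect the genes driving those programs with the drug's
predicted protein targets, (iii) triage the survivors by structural
binding evidence, and (iv) ask whether silencing each surviving target
*in silico* reproduces the drug's own transcriptomic perturbation.

`dedtarget` implements that pipeline end to end for count-based (bulk
RNA-seq style) data, together with a negative-binomial multi-dataset
simulator with planted ground truth, so every stage is testable without
any external download. It is aimed at computational biologists who want
a transparent, fully seeded re-implementation of this class of analysis
rather than a black-box workflow.

## Methods at the core

- **Per-dataset differential expression.** Genes are kept when their
  group-total count is ≥ 10 in either group; samples are normalized by
  median-of-ratios size factors
  (`s_j = median_g c_{gj} / (∏_k c_{gk})^{1/n}` over all-nonzero genes);
  fold changes are moderated by a prior count,
  `log2FC = log2((μ̄_trt + c) / (μ̄_ctl + c))` with `c = 2`; Welch tests on
  `log2(normalized + c)` are BH-adjusted, and DEGs require
  `|log2FC| > 1` and `padj < 0.05` (both strict).
- **Pre-ranked GSEA.** The weighted Kolmogorov–Smirnov running sum:
  hits add `|s_i|^w / Σ|s|^w` (default `w = 1`), misses subtract
  `1/(N − N_h)`; the ES is the extreme deviation, the leading edge is the
  member subset on the peak side. Significance comes from a gene-
  permutation Monte-Carlo null with a pseudo-count
  (`p = (1 + #{|ES_π| ≥ |ES|, same sign}) / (1 + #same-sign π)`), and
  `NES = ES / mean|ES_π, same sign|`.
- **Cross-dataset consensus.** A pathway is consensus when enriched at
  `p < 0.05` with one direction in ≥ `ceil(0.5 K)` of K datasets (= 4 of
  7). Each leading-edge gene's occurrence frequency is counted over the
  datasets where its pathway was significant; genes with frequency
  `> 0.5` are core leading-edge genes.
- **Target triage.** Predicted drug targets ∩ core genes = key genes;
  docked targets are kept when binding affinity `< −6.5` kcal/mol.
- **Perturbation concordance.** Single-gene knockdowns are simulated by
  a first-order linear co-expression surrogate (or supplied externally
  as profiles); each candidate's profile is correlated (Pearson) with
  the drug profile on the top 20% most drug-altered genes and compared
  with a 100-random-gene null by an unpaired Wilcoxon rank-sum test
  (exact enumeration when the smaller sample ≤ 20 and no ties).
  Pathway-level agreement is an AUROC with the drug's significant
  pathway alterations as labels and the knockdown's signed NES as
  scores; `AUROC = U/(n₊ n₋)` with ties counting ½.

## Worked example

```r
library(dedtarget)

cfg <- simulation_config(n_datasets = 3, n_genes = 400,
                         n_samples_per_group = 5, n_gene_sets = 15,
                         n_active_sets = 4, consensus_support = 2,
                         set_size_range = c(8, 20), n_decoys = 40,
                         seed = 42)
sim <- simulate_study(cfg)

gsea <- lapply(sim$datasets, function(d) {
  res <- differential_expression(filter_low_counts(d, min_count = 10))
  preranked_gsea(rank_genes(res), sim$gene_sets, n_perm = 200, seed = 1)
})
cons <- consensus_pathways(gsea, alpha = 0.05, min_frac = 0.5)
cons
#>   pathway direction support K  datasets
#> 1  SET001        up       2 3 DS01;DS02
#> 2  SET002      down       2 3 DS01;DS03
#> 3  SET003        up       2 3 DS01;DS03
#> 4  SET004      down       2 3 DS02;DS03
#> 5  SET011        up       2 3 DS01;DS03
```

All four planted sets (SET001–SET004) are recovered with their planted
directions at the ≥ 2-of-3 support threshold; SET011 is a chance call.
Concordance validation separates the two planted true targets from the
random-gene null:

```r
report <- concordance_report(
  NULL, sim$profiles[["drug"]], sim$truth$true_targets,
  sim$truth$decoy_genes, n_null = 40, seed = 7,
  kd_fun = function(g) sim$profiles[[paste0("KD:", g)]])
report
#> concordance_report: 2 candidate(s), null n = 40, rank-sum p = 0.00232
#> G000005 G000089
#>   0.846   0.868
```

Both candidate knockdowns correlate with the drug profile at PCC ≈ 0.85
while the null concentrates near 0, and the exact rank-sum p (complete
separation of 2 vs 40) is 0.0023. Docking triage on the bundled
affinity table keeps the three strong binders, strongest first:

```r
dock <- read_docking_table(system.file(
  "extdata", "teriflunomide_docking_affinities.tsv",
  package = "dedtarget"))
filter_by_affinity(dock, threshold = -6.5)
#>   target affinity
#> 1   CTSS    -8.77
#> 2  STAT1    -7.59
#> 3  PTGS1    -6.62
```

The `analysis/` directory holds the same workflow as numbered narrative
drivers (`01_simulate.R` … `06_concordance.R`) that write their tables
under `results/`; run them in order with `Rscript`. The methods
vignette (`vignettes/methods.Rmd`) documents the models, defaults and
design decisions.

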