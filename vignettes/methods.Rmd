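---
title: "Methods: consensus target discovery and perturbation concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus target discovery and perturbation concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dedtarget)
```

This vignette is the package's own account of its models and the design
decisions behind them: what each stage assumes, which parameters matter
and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and where the numerical corners
are.

## Overview

The pipeline asks a drug-repositioning question of count-based
transcriptomic data: which genes both drive the transcriptional programs
conserved across heterogeneous disease models and are plausible physical
targets of the drug — and does silencing those genes *in silico*
reproduce the drug's own perturbation profile? The stages are
per-dataset differential expression, pre-ranked gene-set enrichment with
leading-edge extraction, cross-dataset consensus, target intersection
and docking-affinity triage, and perturbation concordance (correlation
against a random-gene null, plus pathway-level AUROC).

## The synthetic study

Real analyses of this kind integrate public count datasets from several
disease models. The generator (`simulation_config()`, `simulate_study()`)
emulates that setting so the whole pipeline is testable offline,
with every planted value recorded as ground truth.

**Counts.** Each of `n_datasets` (default K = 7, matching the
multi-model integration the pipeline is designed for) is an independent
gamma-Poisson (negative-binomial) draw: per-gene baseline means are
log2-uniform over `baseline_log_mean_range` (default 3–9, spanning
low-expressed to abundant genes), a single dispersion
(`nb_dispersion = 0.1`, a typical bulk RNA-seq scale) is shared, and
per-sample size factors are log-uniform in [0.5, 2] so normalization is
exercised non-trivially. Group effects of `de_log2fc` (default 2) are
applied to the member genes of each *active* gene set in exactly
`consensus_support` datasets (default 5 of 7, comfortably above the
4-of-7 consensus threshold); planted directions alternate up/down across
active sets. Defaults of 2000 genes and 6 samples per group keep a full
seven-dataset study runnable in seconds while leaving Welch tests
adequately powered at effect size 2.

**Gene sets.** `n_gene_sets` (50) sets with sizes in `set_size_range`
(10–40). Active sets draw their members disjointly so planted directions
never collide on a gene; inactive sets are random draws from the
universe, so they behave exactly like the permutation null.

**Perturbation profiles.** Each knockdown profile sets the knocked-down
gene to `kd_primary_log2fc` (default −2, a strong knockdown) on top of a
diffuse background (each gene responds with probability 0.2, effects
N(0, 0.8)). True-target knockdowns additionally carry a
pathway-coherent component: every active set's members receive a common
coefficient of magnitude |N(1, 0.3)| oriented *against* the set's
planted disease direction — the modeling assumption being that true
targets are disease drivers whose silencing, like the drug itself,
counteracts the disease programs. Decoy knockdowns have only the
diffuse background: they are the "not a driver" null, with no coherent
pathway footprint. The drug profile is the arithmetic mean of the true
targets' profiles (mean, not sum, so its effect scale stays comparable
to a single knockdown) plus per-gene N(0, `drug_noise_sd`) noise
(default sd 0.2). `n_decoys` (150) keeps the 100-gene null drawable
with headroom.

**What the generator does not emulate.** Library-size and gene-level
idiosyncrasies of specific public datasets, gene–gene correlation within
a condition, batch structure, single-cell data, and any real biology of
particular gene symbols (identifiers are synthetic `G000001`-style; a
small fixture maps a few to familiar symbols for readable examples).
Passing tests therefore demonstrate statistical correctness and
recovery of planted structure under the stated model — not performance
on real data.

## Differential expression

The count filter retains genes whose *group-total* count reaches 10 in
at least one group. The "either group" (union) reading is the default;
a config switch provides the stricter both-groups (intersection)
variant. Filtering precedes testing, and filtered genes are excluded
from the BH adjustment — the same effect independent filtering has in
standard count-based DE tools.

Size factors are plain median-of-ratios: the reference is the per-gene
geometric mean over samples, restricted to genes with no zero count;
each sample's factor is the median ratio to the reference. When no gene
is all-nonzero the error suggests a pseudo-reference fallback rather
than silently switching.

Fold changes are moderated with a prior count:
`log2((mean normalized treatment + 2)/(mean normalized control + 2))`.
This is a deliberate simplification — a moderated (shrunken) fold
change, named as such in the outputs, not a posterior shrinkage
estimator; it pulls low-count fold changes toward zero, which is all the
downstream ranking and thresholding need. The per-gene test is Welch's
unequal-variance t on `log2(normalized + prior)`; at the simulated
sample sizes its type-I behavior is calibrated (checked by the null
simulations in the test suite). The interface deliberately isolates the
test so a negative-binomial Wald test could be plugged in. Genes with
zero variance in both groups get p = 1 (no evidence) or p = 0 (exact
mean difference with zero noise — only reachable in degenerate
constructed inputs).

DEG calls use strict inequalities (`|log2FC| > 1`, `padj < 0.05`): a
gene at exactly the threshold is excluded. Ranking for enrichment is by
log2FC descending with ties broken lexicographically by identifier, so
ranked lists are reproducible across platforms and runs.

## Pre-ranked enrichment

`enrichment_score()` implements the weighted running sum with hit
increments `|s|^w / Σ|s|^w` (default weight 1) and miss decrements
`1/(N − N_h)`; the ES is the value of maximal absolute deviation, taking
the *first* peak on exact ties. If all member scores are zero at
weight 1 the hit mass degenerates; the walk then falls back to equal
hit increments (the weight-0 walk) rather than dividing by zero.

The permutation null resamples member sets of equal size from the
ranked universe. p-values are same-sign with a pseudo-count,
`(1 + #{|ES_π| ≥ |ES|, same sign})/(1 + #same-sign π)`, so p is never
exactly 0 and never smaller than ~`1/n_perm`; `NES = ES / mean|ES_π|`
over same-sign permutations. The exact multilevel p-value algorithm of
modern GSEA implementations is intentionally not re-implemented: the
pipeline only thresholds at p < 0.05, for which Monte-Carlo permutation
(default 1000, minimum 100) is sufficient at desk scale. Permuted ES
values are computed from hit positions only (between hits the walk is
linear, so extremes occur immediately after or just before a hit),
which keeps a 7-dataset × 50-set × 1000-permutation run in seconds.
Sets are intersected with the ranked universe first; sizes below 2 or
covering the whole universe are skipped with a log message. One test
cross-checks the ES walk against an independent implementation
(`fgsea::calcGseaStat`) when that package is available; the suite's
primary oracle is an exhaustive step-by-step walk.

Over-representation of a query gene list uses the exact upper
hypergeometric tail with BH adjustment.

## Consensus and core genes

A pathway is consensus in a direction when significant (`p < alpha`)
with that NES sign in at least `ceil(min_frac · K)` datasets — the
ceiling convention makes "at least 50% of 7" equal 4. A pathway can
qualify in one direction only: the direction with more supporting
datasets wins, and an exact tie (possible for even K) emits neither,
with a warning.

Occurrence frequency is counted per (pathway, gene) over the
*contributing* datasets only — those where the pathway was significant
in the consensus direction — never over all K. Per gene, the maximum
frequency across its pathways is reported: a gene is core if it is core
for any consensus pathway. (Averaging across pathways was the
alternative; the maximum matches the pooled-list semantics of
this analysis style, where the core list is the union of per-pathway
cores.) Core calls use strict `frequency > 0.5`, so exactly half is
excluded.

## Target triage

Symbols are harmonized by uppercasing only (mouse `Ctss` and human
`CTSS` collapse, with the original spellings kept in an attribute and a
warning on collapses); no orthology mapping is attempted — a documented
limitation. The key-gene set is a plain intersection reported in
lexicographic order; an empty intersection is a result, not an error.
Docking triage keeps affinities strictly below −6.5 kcal/mol (a
hypothetical −6.5 exactly would be excluded, matching the strict "<"
convention used throughout), sorted ascending so the strongest binder
leads.

## Knockdown surrogate

The published engines that predict knockdown transcriptomes are not
re-implemented here; the package provides a deliberately simple,
fully documented surrogate plus a plug-in path. The surrogate fits a
co-expression model on the baseline count datasets: per-dataset Pearson
correlation of log2(normalized + 1) expression, averaged across
datasets, shrunk toward zero by `(1 − shrinkage)` (default 0.5) and
hard-thresholded at `sparsity` (default 0.2). Knockdown propagation is
first-order and linear: the target gets `primary_log2fc` (default −2)
and every other gene `w · primary_log2fc`. Those defaults were chosen
so that unrelated (decoy) knockdowns produce concordances concentrated
near zero while genuinely correlated genes inherit a visible share of
the primary effect. The model is symmetric by construction, so the
effect of knocking down A on B equals that of B on A at equal primary
effects — a useful sanity property, not a biological claim. Any richer
engine (or experimental profiles) can replace it via `load_profiles()`,
which aligns external two-column TSVs to a common universe (missing
genes imputed as 0 with a warning; unknown genes dropped or the
universe extended, per flag).

## Concordance validation

The top-altered subset is ranked by the *drug* profile's |log2FC| by
default — the same `ceil(0.2 N)` genes for every candidate and every
null knockdown, which is what makes the null comparison fair. A
`basis = "union"` flag offers the per-pair alternative (union of the
drug's and the knockdown's own top fractions) for sensitivity analyses.
Candidates are excluded from the null's eligible pool, and the pool
should be restricted to expressed (filter-passing) genes.

The rank-sum comparison is exact — a dynamic-programming enumeration of
the rank-sum distribution — whenever the smaller sample has at most 20
observations and there are no ties, and a normal approximation with tie
and continuity correction otherwise. The exact branch matters: with a
handful of candidates against a 100-gene null, the normal approximation
cannot reach p < 0.001 even under complete separation, while the exact
distribution can.

AUROC labels are built from the drug enrichment (significant at
`alpha` with NES sign matching the panel's direction); scores are the
knockdown's signed NES, negated for the down panel so larger always
predicts positive. The U-statistic form with mean ranks handles ties
(each tied positive–negative pair counts ½). Single-class panels yield
a flagged `NA` rather than a fabricated value.

## Pipeline and reproducibility

`run_pipeline()` executes the stages in order, writes fixed-name TSVs,
and records an MD5 manifest; a rerun with the same config and seed
reproduces the hashes bit for bit. The global seed is expanded into
per-stage child seeds by a deterministic hash of the stage name, so
disabling one stage does not shift the randomness of the others. The
numbered drivers under `analysis/` present the same flow as a readable
narrative. There is no shell CLI beyond these scripts: the functions,
drivers and this vignette are the interface.

## Problem sizes in the test suite

The test suite runs everything at reduced but statistically meaningful
sizes chosen as the package's own operating points: recovery and
calibration use 400–1000 genes, 8–30 gene sets and 200 permutations;
consensus recovery uses the full 7-dataset design at 600 genes over 20
seeded replicates; concordance recovery uses 1000 genes, a 100-gene
null and 20 seeded replicates; the AUROC baseline uses 200 pathways ×
1000 replicates. These sizes keep the Monte-Carlo error far smaller
than the margins being asserted.

## Known limitations

- The Welch-on-log-counts test is a simplification of a count GLM; at
  very small n per group (2–3) it loses power relative to a
  negative-binomial Wald test, though its type-I control holds in the
  simulated regimes.
- The knockdown surrogate is first-order and linear; it cannot express
  saturation, feedback, or directionality of regulation, and its
  concordance values are not comparable to those of any external
  engine — only the validation statistics around it are.
- Symbol harmonization is case-only; cross-species analyses needing
  true orthology must map symbols upstream.
- The consensus rule is a counting rule by design (no effect-size
  meta-analysis); datasets are weighted equally regardless of size or
  quality.
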