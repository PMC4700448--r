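---
title: "lobsuite: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lobsuite: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: what each stage
computes, which assumptions it makes, why the defaults are what they are,
and where the genuinely open design choices were settled. Everything
empirical stated here is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

# The analysis problem

Invasive lobular carcinoma (ILC) cohorts profiled on several molecular
layers — gene expression, targeted DNA sequencing, arm-level copy number,
and reverse-phase protein arrays (RPPA) — support three connected analyses:

1. **Subtype discovery**: are there reproducible expression subtypes, and
   which samples can be assigned to one with confidence?
2. **Subtype characterization**: which pathways, mutations, copy-number
   changes and proteins distinguish the subtypes?
3. **Outcome modelling**: which molecular features predict survival, and can
   a small decision rule stratify patients into prognostic groups?

`lobsuite` implements each stage as a separately testable module and ties
them together with `run_pipeline()`.

# Consensus subtype discovery

## Model and procedure

Expression subtypes are defined by *consensus clustering with feature
resampling*. Given a normalized log-scale gene × sample matrix:

1. keep the `n_features = 1000` genes with the largest median absolute
   deviation (MAD, raw — no 1.4826 consistency factor, since only the
   ranking matters; ties broken lexicographically by gene name);
2. median-centre each gene. Centring is standard practice before
   correlation-based sample clustering: without it, between-sample Pearson
   correlation is dominated by the shared gene-baseline profile and the
   subtype contrast is compressed;
3. for each of `n_iterations = 1000` iterations, draw
   `feature_fraction = 0.9` of the genes without replacement and cluster the
   samples hierarchically (average linkage on Pearson distance
   `1 − r`, `k = 2`);
4. record, for every sample pair, the fraction of iterations in which the
   two samples co-clustered — the **consensus matrix**, whose entries are
   the *pairwise concordances*;
5. recluster the consensus matrix (complete linkage, Euclidean distance,
   two clusters), then *greedily remove* the sample with the lowest mean
   within-cluster concordance from any cluster in which some pair falls
   below `concordance = 0.8`, until both clusters satisfy the all-pairs
   rule. Removed samples are labelled **unassigned**.

The result is a three-way labelling (subtype 1, subtype 2, unassigned) in
which every assigned pair co-clusters in at least 80% of resampled runs.

## Parameter rationale

| parameter | default | why |
|---|---|---|
| `n_features` | 1000 | the conventional top-MAD cut for expression clustering; enough genes to average out noise, few enough that unexpressed genes do not dilute the signal |
| `feature_fraction` | 0.9 | resampling perturbs the feature set just enough to expose unstable sample assignments |
| `n_iterations` | 1000 | binomial SE of a consensus entry is at most `0.5/sqrt(1000) ≈ 0.016`, so entries are stable to ±0.03 at 95% confidence |
| `concordance` | 0.8 | assigned samples must co-cluster in 4 of 5 resampled runs with *every* member of their cluster — a strict, interpretable stability notion |
| `k` | 2 | two subtypes are the object of study; the API accepts other values for de novo reclustering |

Linkage `"ward"` maps to `hclust`'s `"ward.D"` (the D1 criterion).
Tie-breaking within the agglomeration is delegated to `stats::hclust`,
which is deterministic for a fixed input order; `base_cluster()` is
therefore reproducible given the column order. A constant sample vector has
no defined Pearson correlation and raises an error naming the sample.

The greedy removal order (lowest mean within-cluster concordance first) is
a choice: the stability rule only constrains the *final* state. On small
matrices (n ≤ 8) the test suite verifies that the greedy removal set is as
small as any removal set achieving the all-pairs constraint for the same
initial partition.

# Subtype characterization

**Signal-to-noise ranking.** Genes are ranked by
`(μ₁ − μ₂) / (σ₁ + σ₂)` with each class standard deviation floored at
`0.2·|μ|` (and at 0.2 for zero means), the usual guard against
near-constant genes exploding the ratio.

**Gene set enrichment.** The weighted Kolmogorov–Smirnov running sum: hits
increment by `|score|^p / Σ|score|^p` (default `p = 1`), misses decrement by
`1/(N − N_hits)`; the enrichment score (ES) is the extremum of the running
sum. Significance uses **gene-set permutation**: random sets of the same
size drawn from the ranked universe. Phenotype permutation would be
preferable with many samples per class, but subtype sizes in cohorts of
~100 assigned samples make the gene-set null the practical choice. NES
divides the ES by the mean |ES| of same-sign null scores; FDR is
Benjamini–Hochberg across sets. With `p = 0` the ES depends only on hit
positions, hence is invariant under monotone transformations of the scores
(a property the tests exercise).

**Marker tests.** Wilcoxon rank-sum (exact for total n ≤ 20 without ties,
normal approximation with tie correction otherwise; all-tied data returns
p = 1), Fisher's exact test (two-sided conditional hypergeometric; the
reported odds ratio is the *sample* OR with a 0.5 continuity correction on
zero cells, not the conditional MLE), and a one-sided binomial test for
signature overlap whose background rate (the genome-wide differential
expression fraction) is a caller argument, since it depends on the caller's
differential-expression criterion.

**Mutation burden.** Non-silent variants (anything altering the protein
sequence; silent/synonymous and UTR/flank classes are excluded) are counted
per sample and divided by the sequenced capture (`capture_mb = 3.2`). A
sample is *hypermutated* at `rate_threshold = 10` or more variants. Unknown
variant classes are an error under `strict = TRUE` and are otherwise
counted as non-silent with a warning. Pathway collapse marks a sample when
any member gene is mutated and reports observed vs independence-expected
co-mutation counts as a mutual-exclusivity summary.

**Joint factorization.** Expression (restricted to the genes best
correlated with any protein epitope — top 10 by |Pearson r| per epitope,
union over epitopes) and RPPA are each z-scored per feature, scaled to
equal total block variance, stacked, and decomposed by SVD; the top
`k = 5` factors are returned. This is deliberately a plain linear
factorization, not a penalized latent-variable model: it recovers planted
shared sample axes (tests verify correlation > 0.95 with orthogonal planted
factors at n = 200) and provides the EMT-like axis downstream analyses
need, while remaining exactly reproducible. Factor signs are fixed so each
factor correlates positively with its largest-|weight| feature. The
package's EMT score itself is the mean z-score over an EMT signature gene
set — a transparent statistic that tracks the factorization's EMT axis on
synthetic data.

# Cross-cohort validation

The validation cohort is reclustered *de novo* with the same consensus
pipeline; signal-to-noise vectors are computed in both cohorts over shared
genes (exact symbol match; no alias resolution); validation labels are
flipped if needed so the correlation is positive; Pearson and Spearman
correlations are both reported, as the two emphasize the signature tail and
the bulk ranking differently. Association between two labelings of the same
samples uses Fisher's exact test (2×2) or a seeded Monte-Carlo chi-square
(larger tables), with unassigned samples excluded.

# Survival analysis

Kaplan–Meier estimation and log-rank testing wrap the survival package;
the Cox screen fits, per molecular feature, a stratified proportional
hazards model (Breslow ties) with the clinical base covariates, and
compares it to the base model by a likelihood-ratio test on 1 df. Breslow
tie handling is the simplest convention and adequate for continuous
synthetic times. Strata (biobank) absorb baseline-hazard differences
between collection sites — the tests demonstrate that the pooled fit is
biased when the feature is confounded with the stratum while the stratified
fit is not. FDR across features is Benjamini–Hochberg. Per-feature
non-convergence or separation is flagged, never fatal to the screen.
Treatment enters as caller-supplied indicator columns.

# Conditional-inference survival tree

The censored response is transformed to **log-rank scores**
`event_i − Ĥ(t_i)` with `Ĥ` the Nelson–Aalen cumulative hazard; the scores
sum to zero exactly, censoring and ties included. At each node:

1. every feature is tested against the node's scores by the linear
   statistic `T = Σ feature_i·score_i`, standardized by its exact
   permutation moments (`E[T] = Σf·Σs/n`,
   `Var[T] = Σ(f−f̄)²·Σ(s−s̄)²/(n−1)`) with a two-sided normal
   approximation. The normal approximation replaces the exact conditional
   distribution; at the default `minsplit = 20` it is accurate (the tests
   compare it to full permutation enumeration at n ≤ 8 and verify p-value
   calibration at n = 40);
2. p-values are Bonferroni-corrected across features; the node becomes a
   leaf if the smallest corrected p exceeds `alpha = 0.25` or the node has
   fewer than `minsplit = 20` samples;
3. otherwise the winning feature is split at the threshold maximizing the
   two-sample log-rank statistic over all midpoints between consecutive
   distinct values leaving `minbucket = 10` samples on each side (ties take
   the lower threshold; samples equal to the threshold go left);
4. children are fitted recursively; leaves are numbered depth-first.

The split statistic is computed as the standardized sum of the node's
log-rank scores over the left group — the linear-rank form of the log-rank
test — which makes the full threshold scan an O(n log n) cumulative-sum
pass. Splits are therefore invariant to strictly monotone feature
transformations except for the threshold value itself.

Two calibration facts, both measured by the acceptance computations, matter
for interpreting trees grown at the default `alpha = 0.25`:

* a pure-noise node splits with probability close to `alpha` (Bonferroni
  across features controls the per-node family error at `alpha`, not
  below); measured root-only rates on 300-sample pure-noise data are
  0.72–0.80 at `alpha = 0.25` and ~0.94 at `alpha = 0.05`;
* a continuous feature with a smooth effect keeps residual association
  within its children and re-splits readily at so lenient a threshold.

`alpha = 0.25` is thus a *discovery* setting that accepts a substantial
false-split rate in exchange for sensitivity; for confirmatory trees use
`alpha = 0.05`. The leave-one-out partial-likelihood deviance utility
(`loo_tree_deviance()`) is a reporting tool, not a pruning criterion.

# Drug response screen

Drugs measured in at least `min_per_group = 3` cell lines per subtype are
tested by a two-sided Welch t-test on AUC (Welch rather than pooled
variance: group variances from small cell-line panels cannot be assumed
equal), with BH FDR across the retained drugs only (the denominator is the
retained count, never a fixed panel size). Lower AUC means more sensitive;
the reported sensitive subtype is the group with the lower mean. Note that
at FDR 0.25 roughly a quarter of discoveries are expected to be false by
design; with one strong true shift among 20 drugs, the probability that
some null drug is also called is substantial (~0.4 in the acceptance
simulations) — the FDR level controls the expected false-discovery
*proportion*, not the family-wise error.

# The synthetic cohort generator

## What it emulates

`sim_config()` defaults describe a 144-sample ILC-like cohort:

* **Expression**: 2000 genes, baselines N(7, 1.5²) on the log2 scale;
  200 signature genes shifted by `effect_size = 1` residual SD between
  subtypes (half up in each), 44% subtype 1, 27% subtype 2, and 29%
  "mixed" samples carrying no subtype signal — the unassignable fraction.
  Named immune markers (CD4, CD8A, PDCD1, CD274, CTLA4, ...) ride the
  subtype-1 signature and hormone/EMT markers (ESR1, PGR, FN1, COL11A1,
  THBS2, ...) the subtype-2 signature.
* **Mutations**: per-gene Bernoulli draws at the published ILC frequencies
  (CDH1 0.428, PIK3CA 0.348, GATA3/MAP3K1/AKT1 0.051, MAP2K4/NF1/ERBB2
  0.043, TP53 0.036, plus the remaining PI3K members), a negative binomial
  background (mu 4.8, size 6) calibrated so the median non-silent count is
  ~6 (≈1.9 variants/Mb over the 3.2 Mb capture), and a 6% hypermutated
  subset forced to ≥ 10 variants. Background counts of non-hypermutated
  samples are truncated below the threshold so that the latent
  hypermutation flag and the ≥ 10-variant criterion coincide exactly — the
  truth table would otherwise disagree with its own definition.
* **Copy number**: arm-level calls with 1q/8q gains and 11q loss enriched
  in subtype 2 (0.50–0.65 vs 0.20–0.25), 16q loss frequent in both (0.6),
  and low background rates elsewhere.
* **RPPA**: 20 epitopes generated as `r·z(expression of cognate gene) +
  √(1−r²)·noise` with `epitope_gene_corr = 0.7`, plus an **eIF4B** epitope
  drawn independently of the subtypes as a two-component mixture (45% low,
  55% high, component SD 0.35). The bimodality mirrors how the protein is
  used downstream — as a dichotomizing prognostic marker — and gives the
  survival tree a well-defined threshold to find.
* **Survival**: exponential times with log hazard
  `beta_mutrate·1[hypermutated] + beta_eif4b·eIF4B`, defaults 1.3 and 0.7
  (hazard ratios ~3.7 for hypermutation and ~2 between the high and low
  eIF4B modes, the magnitude of effects such a cohort reports);
  administrative uniform censoring calibrated to `censor_frac = 0.35` —
  the simplest mechanism satisfying independent censoring. One sample in
  each cohort is hormone-receptor negative; grade, size, nodal status,
  treatment flags, age and a four-level biobank stratum round out the
  clinical table.

`simulate_validation_pair()` draws two cohorts sharing gene-level
parameters (baselines, signature identities and directions) but with
independent samples and a per-cohort global expression offset — the
structure cross-cohort validation assumes.

## What it does not emulate

No probe-level intensities (except the preprocessing module's own toy
fixtures), no linkage disequilibrium between mutations and expression
subtypes, no copy-number dosage effects on expression, no
proportional-hazards violations, and Gaussian expression noise rather than
the heavier-tailed noise of real arrays. Passing tests therefore
demonstrate the *statistical machinery* — recovery of planted structure at
realistic effect sizes, calibration under the null — not performance on any
real cohort.

## Simulation sizes used by the tests

Module tests run at n = 25–120 samples and a few hundred genes; the
acceptance computations use the generator defaults (and n = 150 × 2000
genes for recovery, n = 300 for tree recovery with a-priori "strong"
effects `beta_mutrate = 3.0`, `beta_eif4b = 0.5`, 500 replicates for type-I
calibration, 50 replicates for tree and drug rates). A power analysis
motivated the strong-effect choice: the node test's *linear* statistic
dilutes a rare binary effect by the uninformative background variation of
the mutation count, so only a dominant hypermutation hazard makes the
mutation-rate feature competitive with a continuous epitope at the root.

# Numerical conventions

* Probe summarization: genes with one probe pass through; multi-probe genes
  use the first principal component of the largest probe subset with mean
  pairwise correlation ≥ 0.3 (exact subset enumeration up to 12 probes,
  greedy drop-worst beyond, fallback to all probes), sign-fixed to
  correlate positively with the probe mean and rescaled to the mean probe
  variance around the mean probe baseline. Missing intensities are
  mean-imputed within a gene for the PC; correlations are
  pairwise-complete.
* Batch adjustment is exact per-gene location/scale standardization to the
  grand mean and pooled within-batch variance — the non-shrunk limit of
  empirical-Bayes batch correction, chosen for exactness and testability.
  Singleton batches are an error; a single batch is the identity.
* Quantile normalization maps every column to the mean of order statistics,
  leaving missing values missing (limma's implementation).
* `assign_stable` relabels clusters so cluster 1 is the larger one.
* All seeded routines restore the caller's RNG state.
* Pipeline stage seeds are `global seed + fixed offset` (simulate 1,
  cluster 2, characterize 3, validate 4, survival 5, tree 6, drugs 7), so
  toggling a stage never shifts the seeds of the others; manifests record
  parameters, stage seeds and MD5 checksums of every output, and contain no
  timestamps, making reruns byte-identical.

# Known limitations

* The factorization is unpenalized; with many more features than samples it
  will not match sparse latent-variable models feature-for-feature.
* The GSEA null is gene-set permutation; inter-gene correlation within real
  sets makes this null anti-conservative relative to phenotype permutation.
* The survival tree's normal-approximation p-values are slightly off for
  n near the minimum split size with heavily tied features.
* Fisher's exact p-values are discrete: under the null they are
  super-uniform, not uniform — tests of calibration must account for this.
* At `alpha = 0.25` the tree's false-split rate is ~0.25 per eligible node
  by construction; trees grown at that setting should be read as
  hypothesis-generating.
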