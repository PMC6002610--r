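---
title: "Methods: enrichment transcriptomics with enrichseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment transcriptomics with enrichseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichseq)
```

# The analysis problem

Environmental enrichment (EE) studies contrast animals housed with added
stimulation against barren-housed (B) controls and ask how the brain
transcriptome responds. The design `enrichseq` targets is litter-matched
and two-phased: each litter contributes one EE and one B animal sampled at
1 h after a daily enrichment stimulus and another pair at 4 h, so litter is
a strong random effect crossed with treatment and timepoint. Two biological
signatures organise the expected response: immediate early genes (IEGs,
e.g. *FOS*, *ARC*, the *EGR* family) rise transiently with neuronal
activity and should be elevated in EE brains only at 1 h, while microglial
markers (e.g. *CSF1R*, *P2RY12*, *C1QA*) index brain-resident macrophage
activity and may be persistently lower under enrichment.

The pipeline runs: expression filtering → TMM normalisation → per-comparison
fold changes and gene-wise tests → threshold DE calling → a signature
randomisation test → correlation networks with Markov Clustering. Every
stage is exercised end-to-end against a synthetic-data generator that
reproduces the design.

# Expression filtering

Genes whose expression cannot be distinguished from noise in either
treatment group are removed once, before any comparison, and the same
filtered universe feeds all downstream stages. A gene is retained iff its
group-summary TPM is at least the threshold (default 2) in the EE group
**and** in the B group — failing "in one or both" groups removes it. Two
choices here were genuinely open:

* **Group summary.** The median across the group's samples (configurable).
  The median is robust to a single animal with a spike of expression, which
  matters with six animals per group.
* **Pooling.** Both timepoints are pooled within a treatment, so filtering
  yields a single gene universe rather than one per comparison.
* **Boundary.** The threshold is inclusive (`>= 2` TPM survives).

Filtering is idempotent; the retained-gene list preserves matrix order.

# Normalisation and differential expression

## TMM

Library-size scaling alone is biased when a minority of genes dominates
composition, so between-sample factors follow the trimmed mean of M-values
(TMM) procedure: pick as reference the sample whose upper-quartile of
scaled counts is closest to the mean upper-quartile; for every sample
compute gene-wise log2 expression ratios against the reference (M-values)
and average log abundances (A-values) over genes finite in both; discard
the most extreme 30% of M and 5% of A on each side; the factor is `2^m`
with `m` the precision-weighted mean of the surviving M-values (inverse
asymptotic binomial variances as weights); finally centre the factors so
their log-mean is zero. The implementation is validated against an
independent brute-force oracle at `1e-10` and against an established
reference implementation.

CPM uses effective library sizes: `CPM = count / (libsize × factor) × 1e6`.

## Fold changes and gene-wise tests

Log2 fold changes are prior-damped log ratios of group mean CPM,
`log2((mean_EE + c) / (mean_B + c))` with `c = 0.5`, finite even at zero
counts. The gene-wise test is deliberately plain and fully documented
rather than a re-derivation of any empirical-Bayes machinery:

* `welch_logcpm` (default): Welch's unequal-variance t on
  `log2(CPM + 0.5)`, two-sided; needs two samples per group. Genes with
  zero variance in both groups return p = 1 when the group means agree
  (p = 0 otherwise) — never NaN. Calibration under the simulator's null
  (fraction of p < 0.05 within [0.03, 0.07]) is asserted in the test
  suite.
* `nb_exact_mom`: a negative binomial exact-style alternative usable down
  to one sample per group. Counts are scaled to a common effective
  library; a **common** dispersion is estimated by pooled moments
  (within-group sums of squares have expectation `df · (μ + φμ²)`;
  aggregating over genes before solving for φ avoids the downward bias a
  per-gene median would inherit from small-sample variance skew); each
  gene's group sums are then tested conditionally on their total, summing
  the probabilities of splits no more likely than the observed one. With
  one sample per group the dispersion is inestimable and the split test
  degenerates to its conditional Poisson form — flagged in the
  documentation, and only strong shifts should be trusted there. Totals
  beyond 10,000 use a moment-matched normal approximation.

## DE calling

A gene is called when it passes both thresholds: `|log2FC| ≥ log2(1.2)`
(inclusive) and `p < 0.02` (strict). No multiple-testing correction is
applied: the procedure is a deliberately conservative raw-threshold rule,
and the package preserves it as such rather than silently "improving" it;
the per-direction counts (n_up, n_down) summarise each comparison. Three
comparisons are run by default: EE vs B at 1 h, at 4 h, and pooled.

# The signature randomisation test

The core statistic asks whether a signature's median log2 fold change is
extreme relative to random gene sets of the same size. With `x` the
effective signature size (after intersection with the quantified
universe), subsets of `x` genes are drawn uniformly without replacement,
`s = 10,000` times, from the **full** universe — signature genes included.
`q` counts the subsets the signature strictly beats in its direction
(higher median for an "up" signature, lower for "down"); with `r = s − q`
the p-value is

$$p = \frac{r + 1}{s + 1},$$

whose attainable floor is `1/(s+1)` = 9.999e-05 at the default `s`. Design
choices:

* **Log scale.** Medians are compared on log2 fold changes; log2 is
  strictly monotone, so subset-median comparisons are identical to
  comparisons of raw fold-change medians and the choice is
  consequence-free.
* **Ties.** A subset median exactly equal to the signature median never
  counts towards `q`. This keeps the p-value valid (super-uniform under an
  exchangeable null); with all fold changes identical, p = 1.
* **Direction.** Fold changes are always EE − B; the signature carries its
  expected direction, and the subset draws do not depend on it, so
  negating every fold change and flipping the direction reproduces the
  identical result for a fixed seed.
* **Seeding.** The seed is recorded in the result for exact replay. One
  caution discovered while validating calibration: seeding successive
  replicates from *consecutive* integers while drawing the signatures from
  a second stream produced a measurable excess of small p-values
  (P(p ≤ 0.01) ≈ 0.022 over 1,000 replicates) — an artifact of correlated
  Mersenne–Twister initialisations, not of the test. Calibration holds
  exactly on a single stream, and the pipeline derives stage seeds by
  hashing the master seed with the stage name rather than incrementing it.

The implementation is checked against exhaustive enumeration (all 15
subsets of a 6-gene universe), against the analytic floor, and for
super-uniformity under random null signatures.

# Correlation networks and Markov Clustering

Sample-to-sample and gene-to-gene graphs connect pairs whose Pearson
correlation reaches a threshold; the threshold applies to the *signed*
correlation (anti-correlated pairs are never linked), matching the
convention of the interactive network tools this export targets. The
conventional thresholds are high: 0.99 for the all-gene sample graph, 0.93
for the DE-gene sample graph, 0.90 gene-to-gene. Correlations are computed
on `log2(TPM + 1)` by default (configurable to the raw scale); the
transform tempers the leverage of highly expressed genes. Constant
profiles have undefined correlations and stay in the graph edgeless, with
a warning.

Clustering is a from-scratch Markov Clustering (MCL) implementation on the
thresholded weighted adjacency: self-loops with weight equal to each
node's maximum incident weight, column-normalisation to a stochastic
matrix, then alternating expansion (matrix squaring) and inflation
(elementwise power 2.2, renormalise) until the largest entry change drops
below `1e-6` or 100 iterations (non-convergence returns the current state
with a warning). Entries below `1e-8` are pruned each iteration for
sparsity. Clusters are the connected components of the limit matrix's
nonzero pattern, numbered by decreasing size with ties broken by the
smallest member label — so results are invariant to node input order — and
clusters below `min_size = 3` are reported but flagged. The inflation
value 2.2 is the granularity conventional for co-expression work; the
numerical constants are standard MCL practice and all configurable. MCL
can only refine, never merge, connected components of the input graph,
which the suite asserts alongside exact recovery of planted block
structure.

Graphs export to GraphML with cluster and metadata attributes and
round-trip losslessly through igraph's parser.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions the rest of the suite assumes; they were fixed from the
design considerations below, not adjusted afterwards.

Counts for gene *g* in sample *j* are negative binomial with mean

$$\mu_{gj} = d_j \, \pi_g \, e^{u_{\ell(j),g}} \, 2^{\delta_{gj}},$$

where `d_j` is the sample's depth (uniform in 0.8–1.2 million), `π_g` the
gene's baseline relative abundance (log-uniform mean expression between 20
and 2,000), `u` a per-(litter, gene) Gaussian log-scale random effect
(SD 0.1) shared by every sample of a litter, and `δ` the signature effect:
+1 log2 unit for IEG genes in EE samples at 1 h only, −1 for microglial
genes in EE samples at both timepoints. Dispersion is `φ = 0.05`
(variance `μ + φμ²`). The design grid is 6 litters × {EE, B} × {1 h, 4 h},
one male per cell — 24 samples. Gene lengths are log-uniform in
500–10,000 nt and exist solely so that TPM ≠ CPM and length handling is
exercised.

Parameter rationale:

* **Signature sizes 11 and 52 of 2,000.** Cortex-wide signature catalogues
  put IEG and microglial sets at roughly 0.6% and 2.6% of the expressed
  universe. Keeping those *proportions* at the simulator's 2,000-gene
  default matters: the randomisation test draws its null from the
  quantified universe itself, so a universe where a third of all genes
  carries an injected effect would shift every subset median and distort
  the null in a way real data does not.
* **Baseline range 20–2,000 mean counts.** The pipeline filters genes
  below 2 TPM as noise; the generator emulates the *post-filterable*
  expressed universe rather than padding with unexpressed genes, while
  still spanning two orders of magnitude of expression.
* **Dispersion 0.05, litter SD 0.1.** Within-group biological variance of
  the motivating design is not published; these values give a
  biological-CV regime (~22%) typical of inbred-adjacent livestock
  cohorts, and they are stated here as the package's chosen test-bed, not
  as an empirical claim.

The truth table records each gene's signature membership and true log2
fold change per timepoint. Determinism is bit-exact given the seed.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: isoform-level effects and length-offset
corrections in transcript aggregation, correlated gene–gene co-expression
modules beyond the injected signatures, outlier animals, GC/batch
technical effects, and sex differences (all simulated brains are male, as
in the motivating design; the metadata field exists for generality).

# Pipeline reproducibility

`run_pipeline()` writes every table as TSV, the DE summaries and a
manifest as JSON. A master seed is hashed with each stage name to give
per-stage seeds (recorded in the manifest), so any stage can be replayed
in isolation and two runs with the same config produce byte-identical
tables. The manifest also stores the full configuration and its hash.

Problem sizes used throughout the validation suite — 300–2,000 genes,
24 samples, `s` between 400 and 10,000, ten-seed sweeps for the
stochastic recovery properties — were chosen so the whole suite documents
the method's behaviour at desk scale; the statistics themselves are
size-agnostic.

# Known limitations

* The gene-wise test is not an empirical-Bayes NB fit; with n = 6 per
  group its power profile differs from shrinkage-based tools, and exact
  DE counts from any specific study are not a reproduction target.
* Transcript aggregation is a plain sum; no average-transcript-length
  offsets are applied.
* The randomisation test's resolution is bounded by `1/(s+1)`; report the
  floor, not zero.
* MCL post-processing in interactive network tools (e.g. smallest-cluster
  merging) varies by tool; only the structural properties documented above
  are guaranteed.
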