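# enrichseq

Transcriptomic analysis of environmental enrichment experiments in a
litter-matched, two-timepoint design.

## What problem this solves

Enrichment studies house animals with added stimulation (EE) against
barren-housed controls (B), matched by litter, and sample brain tissue at
two times after a daily enrichment stimulus (1 h and 4 h). Two gene
signatures structure the expected response: **immediate early genes**
(IEGs — *FOS*, *ARC*, *EGR* family), induced transiently by neuronal
activity, and **microglial markers** (*CSF1R*, *P2RY12*, *C1QA*), whose
relative down-regulation suggests reduced neuroinflammatory tone.
`enrichseq` packages the full analysis for this design, for researchers
who have gene- or transcript-level expression matrices (counts + TPM) and
want a reproducible, tested pipeline rather than an ad-hoc script chain:

* expression I/O, transcript→gene aggregation, group-wise 2-TPM noise
  filtering;
* TMM normalisation, prior-damped fold changes, gene-wise testing, and
  threshold DE calling (|FC| ≥ 1.2 and p < 0.02);
* the **signature randomisation test**: for a signature of `x` genes,
  draw `s = 10,000` random `x`-gene subsets from the quantified universe
  and count the draws `q` whose median log2 fold change the signature
  beats in its direction; with `r = s − q`,

  `p = (r + 1) / (s + 1)`,

  so the attainable floor is 1/(s+1) = 9.999e-05;
* Pearson correlation networks at fixed thresholds (0.99 all-gene
  samples, 0.93 DE-gene samples, 0.90 gene–gene) clustered by a
  from-scratch Markov Clustering (MCL) implementation at inflation 2.2,
  exported as GraphML;
* a negative-binomial simulator of the whole design (litter random
  effects, transient IEG-up and persistent microglia-down effects) with
  ground-truth labels, used to validate every stage.

## Worked example

```r
library(enrichseq)

sim <- simulate_experiment(sim_config(seed = 10))
sim
#> sim_experiment: 2000 genes x 24 samples (11 IEG, 52 microglial)

s <- sim$samples
a <- s$sample_id[s$treatment == "EE" & s$timepoint == "1h"]
b <- s$sample_id[s$treatment == "B"  & s$timepoint == "1h"]

keep <- filter_low_expression(sim$tpm, s)        # 2-TPM group filter
f    <- tmm_factors(sim$counts[keep, ])          # TMM scaling factors
cpm  <- cpm_matrix(sim$counts[keep, ], f)
fc   <- fold_changes(cpm, a, b)                  # EE minus B, log2
pv   <- gene_test(sim$counts[keep, ], a, b, factors = f)
de   <- call_de(fc, pv)
de_summary(de)
#>  n_up n_down
#>    26     58

ieg <- gene_signature("IEG",
                      sim$truth$gene_id[sim$truth$signature == "IEG"], "up")
randomization_test(fc, intersect_signature(ieg, keep), s = 10000, seed = 11)
#> randomisation test 'IEG' (up): x = 11, s = 10000, q = 10000, median log2FC = 0.9665
#>   p = (r+1)/(s+1) = 9.999e-05
```

26 genes pass both DE thresholds upward at 1 h (the 11 injected IEG genes
among them) and the IEG signature's median fold change (0.97, true value
1) beats all 10,000 random subsets, so the test returns its floor,
p = 9.999e-05 — the strongest claim a 10,000-draw randomisation test can
make. Clustering the DE-gene sample network then separates treatments:

```r
g  <- correlation_graph(sim$tpm[de$gene_id[de$call != "none"], ],
                        "samples", 0.93)
mcl_cluster(g)
#> mcl_clustering: 24 nodes in 1 clusters (0 below min size 3)
```

(with the default moderate effect sizes all 24 samples stay connected at
r ≥ 0.93; strong-effect configurations split the graph by treatment — see
the network tests).

The one-call version of all of the above, writing every table, GraphML
network and a reproducibility manifest:

```r
res <- run_pipeline(pipeline_config(seed = 1), "results_dir")
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`
(`--config config.yaml --out dir --seed 1`).

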