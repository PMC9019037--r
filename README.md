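# basalshift

Quantifying gain of basal-like transcriptional state ("basal-ness") and
immune activation in estrogen-receptor-positive (ER+) breast cancer
cohorts — the computational pipeline behind analyses of ESR1-mutant
tumors that acquire basal cytokeratin (BCK: *KRT5/6A/6B/14/16/17*)
expression.

## Who this is for

Computational biologists comparing matched primary/metastatic ER+
tumor pairs (or engineered cell-line panels) who need, in one place:

- **Signature derivation** from labeled luminal/basal reference data:
  a two-group FDR filter (Mann–Whitney + Benjamini–Hochberg, FDR < 0.01),
  top-N intersection of two independent comparisons, and
  knockdown-response (top-100 down-regulated) signatures.
- **Single-sample enrichment scoring**: a kernel-ECDF GSVA statistic and
  a rank-weighted ssGSEA statistic (ESTIMATE-style, `alpha = 0.25`),
  with paired **delta scores** (metastasis − primary) and quartile
  stratification into score-high/low groups.
- **Subtype calling** by Spearman nearest-centroid against a labeled
  reference panel, with normalized positive-correlation probabilities.
- **Immune readouts**: pathway differential enrichment with
  direction-aware multi-comparison intersection, mean-z immune-cell-type
  scores, percent-of-cells-expressing, and weighted **tumor mutation
  burden** (TMB = 2·truncating + non-truncating) from MAF tables.
- **Survival**: Kaplan–Meier, log-rank, and Cox proportional-hazards
  comparisons of score-high vs score-low patients.
- **Chromatin-boundary logic**: insulated-neighborhood boundary calls
  from CTCF/cohesin co-occupancy, convergent-motif loop assembly with a
  "> 3 linkages" strength rule, ±3 kb promoter / 50 kb flank peak-gene
  annotation, and gain-of-function binding-site classification.
- **Seeded synthetic-data generators** with planted effects and ground
  truth, so every analysis step can be validated end-to-end.

## The statistics at the core

For a log2 expression matrix with genes *i* and samples *j*, the
kernel-ECDF statistic is

```
ẑ_ij = (1/n) Σ_k Φ((x_ij − x_ik) / h_i),   h_i = s_i / 4
```

with Φ the standard normal CDF and s_i the gene's sample SD. Per
sample, genes are ranked by ẑ (descending) and a weighted
Kolmogorov–Smirnov-like walk is run for each gene set γ (|γ| = m,
universe size p):

```
ν(ℓ) = Σ_{i≤ℓ, i∈γ} w_i^τ / Σ_{i∈γ} w_i^τ  −  Σ_{i≤ℓ, i∉γ} 1/(p−m),
w_i = |p/2 − rank_i|
```

The default score is `max(0, max ν) + min(0, min ν)`; the
maximum-deviation variant is also available. ssGSEA ranks by raw
expression with weights `r^α` and sums the running difference without
normalization. TMB is `2·(truncating) + (non-truncating)` over the
canonical MAF classes (nonsense, frame-shift ins/del, splice-site vs
missense, in-frame ins/del, nonstop).

## Worked example

```r
library(basalshift)

cfg <- simulation_config(n_wt_patients = 20, n_mut_patients = 20,
                         basal_shift_log2 = 2)
cohort <- simulate_paired_cohort(cfg)

scores <- gsva_scores(cohort$matrix,
                      list(BCK = cohort$truth$basal_genes))
delta  <- delta_paired_scores(scores, cohort$annotations)
ann    <- cohort$annotations
geno   <- ann$genotype[match(rownames(delta), ann$patient_id)]

mean(delta[geno == "mutant", "BCK"])   # 0.845
mean(delta[geno == "WT", "BCK"])       # -0.021
wilcox.test(delta[geno == "mutant", "BCK"],
            delta[geno == "WT", "BCK"])$p.value   # 1.45e-11

fit <- cox_fit(cohort$survival, "bck_high")
fit$hazard_ratios                      # ~2 when the planted HR is 2
```

The mutant metastases carry a planted +2 log2 shift on the basal
program, so their metastasis-minus-primary delta GSVA score is strongly
positive (≈ 0.85) while wild-type pairs center at zero; the
Mann–Whitney p-value quantifies the separation, and the Cox fit
recovers the hazard ratio planted for basal-score-high samples.

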