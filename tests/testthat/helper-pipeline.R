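# End-to-end pipeline runs reused by the acceptance tests.

# Mutant-vs-WT Mann-Whitney p-value on paired delta GSVA scores of the
# planted basal set, for one simulated cohort.
delta_recovery_pvalue <- function(seed, shift, n_wt = 20, n_mut = 20) {
  cfg <- simulation_config(seed = seed, basal_shift_log2 = shift,
                           n_wt_patients = n_wt, n_mut_patients = n_mut)
  coh <- simulate_paired_cohort(cfg)
  sc <- gsva_scores(coh$matrix, list(BCK = coh$truth$basal_genes))
  delta <- delta_paired_scores(sc, coh$annotations)
  ann <- coh$annotations
  geno <- ann$genotype[match(rownames(delta), ann$patient_id)]
  wilcox.test(delta[geno == "mutant", "BCK"],
              delta[geno == "WT", "BCK"], exact = FALSE)$p.value
}

# Three-comparison pathway analysis on synthetic cohorts: two unpaired
# tumor-cohort analogues split into basal-score quartiles, plus one
# paired mutant-vs-WT delta comparison; direction-aware intersection of
# the enriched pathway sets. Returns TRUE when the planted immune
# program survives the intersection.
three_way_immune_hit <- function(seed, coupling, n_genes = 200,
                                 n_decoys = 8, fdr = 0.05) {
  mk_cfg <- function(s) {
    simulation_config(seed = s, n_genes = n_genes, n_basal_genes = 25,
                      n_luminal_genes = 25, n_immune_genes = 25,
                      n_wt_patients = 20, n_mut_patients = 20,
                      immune_coupling = coupling)
  }
  pathway_sets <- function(coh, s) {
    background <- setdiff(rownames(coh$matrix),
                          c(coh$truth$basal_genes, coh$truth$immune_genes,
                            coh$truth$luminal_genes))
    set.seed(s + 13L)
    decoys <- lapply(seq_len(n_decoys), function(k) {
      sample(background, 20)
    })
    names(decoys) <- sprintf("decoy%02d", seq_len(n_decoys))
    c(list(immune = coh$truth$immune_genes), decoys)
  }
  quartile_comparison <- function(s) {
    coh <- simulate_paired_cohort(mk_cfg(s))
    sets <- c(list(BCK = coh$truth$basal_genes), pathway_sets(coh, s))
    sc <- gsva_scores(coh$matrix, sets)
    strat <- stratify_quartiles(sc[, "BCK"])
    high <- names(strat$labels)[strat$labels == "high"]
    low <- names(strat$labels)[strat$labels == "low"]
    pathway_differential_enrichment(sc[, colnames(sc) != "BCK"],
                                    high, low, fdr = fdr)
  }
  paired_comparison <- function(s) {
    coh <- simulate_paired_cohort(mk_cfg(s))
    sc <- gsva_scores(coh$matrix, pathway_sets(coh, s))
    delta <- delta_paired_scores(sc, coh$annotations)
    ann <- coh$annotations
    geno <- ann$genotype[match(rownames(delta), ann$patient_id)]
    pathway_differential_enrichment(delta,
                                    rownames(delta)[geno == "mutant"],
                                    rownames(delta)[geno == "WT"],
                                    fdr = fdr)
  }
  res <- list(cohort_a = quartile_comparison(seed),
              cohort_b = quartile_comparison(seed + 500000L),
              paired = paired_comparison(seed + 1000000L))
  "immune" %in% intersect_pathways(res)$intersection
}
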