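#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generators.
#' Defaults mirror the study design the package targets: a reference
#' panel of 33 luminal and 39 basal breast cancer cell lines, an intra-
#' patient paired primary/metastasis ER+ cohort with wild-type and
#' ESR1-mutant patients, a planted basal-cytokeratin up-shift of 2 (log2)
#' in mutant metastases, an immune program coupled to the realized basal
#' elevation, Poisson mutation counts, a doubled hazard for
#' basal-score-high tumors, and peak/motif/linkage tracks containing
#' planted convergent insulated-neighborhood boundaries.
#'
#' Bulk expression is simulated as Gaussian log2 values (not negative-
#' binomial counts): every downstream statistic is rank-based or operates
#' on the log2 scale, so the Gaussian family carries the required
#' structure. Counts are used only for the single-cell QC path.
#'
#' @param seed Integer RNG seed; every generator is a pure function of
#'   the config (same config, same output).
#' @param n_genes Total number of genes.
#' @param n_basal_genes,n_luminal_genes,n_immune_genes Sizes of the
#'   planted disjoint programs; their sum must not exceed `n_genes`.
#' @param n_luminal_lines,n_basal_lines Cell-line panel sizes per class.
#' @param n_wt_patients,n_mut_patients Paired-cohort sizes per genotype.
#' @param basal_shift_log2 Planted log2 up-shift of basal genes (in basal
#'   cell lines, and in mutant metastases only, for the cohort).
#' @param immune_coupling In `[0, 1]`; immune genes gain
#'   `immune_coupling` times the sample's realized mean basal-gene
#'   elevation.
#' @param noise_sd Residual Gaussian SD (log2 units).
#' @param pairing_sd SD of the per-patient, per-gene random effect shared
#'   by the two lesions of a patient.
#' @param hazard_ratio_bck_high Hazard multiplier for samples in the top
#'   quartile of realized basal elevation.
#' @param base_hazard Baseline exponential event rate (per time unit).
#' @param censor_rate Rate of the independent exponential censoring time;
#'   `0` disables censoring.
#' @param mutation_rates Named numeric: expected truncating and
#'   non-truncating mutation counts per sample (`truncating`,
#'   `non_truncating`).
#' @param silent_rate Expected number of Silent (excluded-class) rows per
#'   sample in simulated MAFs.
#' @param n_boundary_pairs Number of planted convergent boundary pairs in
#'   the chromatin tracks.
#' @param linkage_counts Integer vector (recycled over planted pairs) of
#'   linkage counts for the planted loops.
#' @param n_decoy_ctcf Number of CTCF-only decoy peaks (no cohesin).
#' @param n_nonconvergent_pairs Number of planted cohesin-supported but
#'   non-convergent boundary pairs.
#' @return A validated list of class `"sim_config"`.
#' @export
simulation_config <- function(seed = 20220419,
                              n_genes = 500,
                              n_basal_genes = 40,
                              n_luminal_genes = 40,
                              n_immune_genes = 40,
                              n_luminal_lines = 33,
                              n_basal_lines = 39,
                              n_wt_patients = 44,
                              n_mut_patients = 7,
                              basal_shift_log2 = 2,
                              immune_coupling = 0.8,
                              noise_sd = 1,
                              pairing_sd = 1,
                              hazard_ratio_bck_high = 2,
                              base_hazard = 0.1,
                              censor_rate = 0.02,
                              mutation_rates = c(truncating = 3, non_truncating = 4),
                              silent_rate = 1,
                              n_boundary_pairs = 4,
                              linkage_counts = c(5L, 6L, 4L, 3L),
                              n_decoy_ctcf = 6,
                              n_nonconvergent_pairs = 2) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_basal_genes = as.integer(n_basal_genes),
              n_luminal_genes = as.integer(n_luminal_genes),
              n_immune_genes = as.integer(n_immune_genes),
              n_luminal_lines = as.integer(n_luminal_lines),
              n_basal_lines = as.integer(n_basal_lines),
              n_wt_patients = as.integer(n_wt_patients),
              n_mut_patients = as.integer(n_mut_patients),
              basal_shift_log2 = basal_shift_log2,
              immune_coupling = immune_coupling,
              noise_sd = noise_sd, pairing_sd = pairing_sd,
              hazard_ratio_bck_high = hazard_ratio_bck_high,
              base_hazard = base_hazard, censor_rate = censor_rate,
              mutation_rates = mutation_rates, silent_rate = silent_rate,
              n_boundary_pairs = as.integer(n_boundary_pairs),
              linkage_counts = as.integer(linkage_counts),
              n_decoy_ctcf = as.integer(n_decoy_ctcf),
              n_nonconvergent_pairs = as.integer(n_nonconvergent_pairs))
  counts <- c(cfg$n_genes, cfg$n_basal_genes, cfg$n_luminal_genes,
              cfg$n_immune_genes, cfg$n_luminal_lines, cfg$n_basal_lines,
              cfg$n_wt_patients, cfg$n_mut_patients)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (cfg$n_basal_genes + cfg$n_luminal_genes + cfg$n_immune_genes > cfg$n_genes) {
    stop("planted gene programs exceed n_genes", call. = FALSE)
  }
  if (cfg$basal_shift_log2 < 0) stop("basal_shift_log2 must be >= 0", call. = FALSE)
  if (cfg$immune_coupling < 0 || cfg$immune_coupling > 1) {
    stop("immune_coupling must be in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$pairing_sd < 0) stop("pairing_sd must be >= 0", call. = FALSE)
  if (cfg$hazard_ratio_bck_high <= 0) stop("hazard_ratio_bck_high must be > 0", call. = FALSE)
  if (!all(c("truncating", "non_truncating") %in% names(cfg$mutation_rates)) ||
      any(cfg$mutation_rates < 0)) {
    stop("mutation_rates needs non-negative 'truncating' and 'non_truncating'",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# planted gene identities: disjoint programs at the head of the gene list
planted_genes <- function(config) {
  ids <- sprintf("G%04d", seq_len(config$n_genes))
  nb <- config$n_basal_genes; nl <- config$n_luminal_genes
  ni <- config$n_immune_genes
  list(gene_ids = ids,
       basal = ids[seq_len(nb)],
       luminal = ids[nb + seq_len(nl)],
       immune = ids[nb + nl + seq_len(ni)])
}

#' Simulate a labeled luminal/basal cell-line panel
#'
#' Gaussian log2 expression with per-gene baselines; planted basal genes
#' are shifted up by `basal_shift_log2` in basal lines and planted
#' luminal genes in luminal lines.
#'
#' @param config A [simulation_config()].
#' @return List with `matrix` (log2 [expression_matrix()]), `labels`
#'   (named character, `"luminal"`/`"basal"` per sample) and `truth`
#'   (planted gene programs and effect size).
#' @export
simulate_cell_line_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pg <- planted_genes(config)
  n <- config$n_luminal_lines + config$n_basal_lines
  samples <- c(sprintf("LUM%02d", seq_len(config$n_luminal_lines)),
               sprintf("BAS%02d", seq_len(config$n_basal_lines)))
  labels <- setNames(rep(c("luminal", "basal"),
                         c(config$n_luminal_lines, config$n_basal_lines)),
                     samples)
  baseline <- rnorm(config$n_genes, mean = 6, sd = 1.5)
  m <- baseline + matrix(rnorm(config$n_genes * n, sd = config$noise_sd),
                         config$n_genes, n)
  dimnames(m) <- list(pg$gene_ids, samples)
  m[pg$basal, labels == "basal"] <-
    m[pg$basal, labels == "basal"] + config$basal_shift_log2
  m[pg$luminal, labels == "luminal"] <-
    m[pg$luminal, labels == "luminal"] + config$basal_shift_log2
  list(matrix = expression_matrix(m, "log2"), labels = labels,
       truth = list(basal_genes = pg$basal, luminal_genes = pg$luminal,
                    immune_genes = pg$immune,
                    effect_log2 = config$basal_shift_log2))
}

#' Simulate a paired primary/metastasis ER+ cohort
#'
#' Each patient contributes a primary and a metastatic sample sharing a
#' per-gene Gaussian patient effect (SD `pairing_sd`). Mutant patients
#' receive a `basal_shift_log2` up-shift on planted basal genes in the
#' metastatic sample only. Planted immune genes gain `immune_coupling`
#' times the sample's realized mean basal-gene elevation. Survival times
#' are exponential with the hazard multiplied by
#' `hazard_ratio_bck_high` for samples in the top quartile of realized
#' basal elevation, with independent exponential censoring.
#'
#' @param config A [simulation_config()]; needs at least 4 patients in
#'   total (quartile stratification is undefined below that).
#' @return List with `matrix` (log2 [expression_matrix()]),
#'   `annotations` (data frame: `sample_id`, `patient_id`, `lesion`,
#'   `genotype`), `survival` (data frame: `sample_id`, `time`, `event`,
#'   `bck_high`) and `truth` (planted programs, per-sample realized basal
#'   elevation, effect sizes).
#' @export
simulate_paired_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_pat <- config$n_wt_patients + config$n_mut_patients
  if (n_pat < 4L) stop("need at least 4 patients", call. = FALSE)
  set.seed(config$seed)
  pg <- planted_genes(config)
  p <- config$n_genes
  patients <- sprintf("PT%03d", seq_len(n_pat))
  genotype <- rep(c("WT", "mutant"),
                  c(config$n_wt_patients, config$n_mut_patients))
  ann <- data.frame(
    sample_id = as.vector(rbind(paste0(patients, "_P"), paste0(patients, "_M"))),
    patient_id = rep(patients, each = 2L),
    lesion = rep(c("primary", "metastasis"), n_pat),
    genotype = rep(genotype, each = 2L),
    stringsAsFactors = FALSE)
  n <- nrow(ann)

  baseline <- rnorm(p, mean = 6, sd = 1.5)
  patient_eff <- matrix(rnorm(p * n_pat, sd = config$pairing_sd), p, n_pat,
                        dimnames = list(pg$gene_ids, patients))
  m <- baseline + patient_eff[, ann$patient_id] +
    matrix(rnorm(p * n, sd = config$noise_sd), p, n)
  dimnames(m) <- list(pg$gene_ids, ann$sample_id)

  mut_met <- ann$genotype == "mutant" & ann$lesion == "metastasis"
  m[pg$basal, mut_met] <- m[pg$basal, mut_met] + config$basal_shift_log2

  # realized basal elevation relative to the gene baselines
  elevation <- colMeans(m[pg$basal, , drop = FALSE] - baseline[match(pg$basal, pg$gene_ids)])
  m[pg$immune, ] <- m[pg$immune, ] +
    rep(config$immune_coupling * elevation, each = length(pg$immune))

  bck_high <- elevation >= quantile(elevation, 0.75)
  rate <- config$base_hazard *
    ifelse(bck_high, config$hazard_ratio_bck_high, 1)
  t_event <- rexp(n, rate = rate)
  if (config$censor_rate > 0) {
    t_cens <- rexp(n, rate = config$censor_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  surv <- data.frame(sample_id = ann$sample_id, time = time, event = event,
                     bck_high = bck_high, stringsAsFactors = FALSE)

  list(matrix = expression_matrix(m, "log2"), annotations = ann,
       survival = surv,
       truth = list(basal_genes = pg$basal, luminal_genes = pg$luminal,
                    immune_genes = pg$immune,
                    basal_elevation = setNames(elevation, ann$sample_id),
                    bck_high = setNames(bck_high, ann$sample_id),
                    effect_log2 = config$basal_shift_log2,
                    immune_coupling = config$immune_coupling,
                    hazard_ratio = config$hazard_ratio_bck_high))
}

truncating_tokens <- c("Nonsense_Mutation", "Frame_Shift_Del",
                       "Frame_Shift_Ins", "Splice_Site")
non_truncating_tokens <- c("Missense_Mutation", "In_Frame_Del",
                           "In_Frame_Ins", "Nonstop_Mutation")

#' Simulate a MAF-style mutation table
#'
#' Per-sample truncating and non-truncating mutation counts are Poisson
#' with the configured means; classification tokens are drawn uniformly
#' from the canonical truncating and non-truncating MAF class lists, plus
#' Poisson(`silent_rate`) `Silent` rows per sample.
#'
#' @param config A [simulation_config()].
#' @param n_samples Number of samples; defaults to the cohort patient
#'   count.
#' @return Data frame with columns `sample_id`, `gene_symbol`,
#'   `variant_classification`.
#' @export
simulate_maf <- function(config, n_samples = config$n_wt_patients + config$n_mut_patients) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  samples <- sprintf("S%05d", seq_len(n_samples))
  n_tr <- rpois(n_samples, config$mutation_rates[["truncating"]])
  n_nt <- rpois(n_samples, config$mutation_rates[["non_truncating"]])
  n_si <- rpois(n_samples, config$silent_rate)
  total <- sum(n_tr) + sum(n_nt) + sum(n_si)
  if (total == 0L) {
    return(data.frame(sample_id = character(), gene_symbol = character(),
                      variant_classification = character(),
                      stringsAsFactors = FALSE))
  }
  sample_id <- c(rep(samples, n_tr), rep(samples, n_nt), rep(samples, n_si))
  cls <- c(sample(truncating_tokens, sum(n_tr), replace = TRUE),
           sample(non_truncating_tokens, sum(n_nt), replace = TRUE),
           rep("Silent", sum(n_si)))
  df <- data.frame(sample_id = sample_id,
                   gene_symbol = sprintf("GENE%04d",
                                         sample.int(2000L, total, replace = TRUE)),
                   variant_classification = cls, stringsAsFactors = FALSE)
  df[order(match(df$sample_id, samples)), , drop = FALSE]
}

#' Simulate chromatin peak, motif and linkage tracks
#'
#' Plants `n_boundary_pairs` convergent insulated-neighborhood boundary
#' pairs on one chromosome: each boundary is a CTCF peak co-occupied by
#' all three cohesin subunit peaks (RAD21, STAG1, SMC1A) and containing a
#' single CTCF motif ("+" on the left boundary, "-" on the right), with a
#' linkage of the configured count spanning the pair. Decoy CTCF-only
#' peaks (no cohesin) and non-convergent cohesin-supported pairs (both
#' motifs "+") are added, and TSS positions are placed inside each
#' planted loop and in inter-loop gaps.
#'
#' @param config A [simulation_config()].
#' @return List with `ctcf`, `motifs` (BED-style data frames; motifs
#'   stranded), `cohesin` (named list of BED-style data frames for
#'   RAD21/STAG1/SMC1A), `linkages` (BEDPE-style data frame with
#'   `count`), `tss` (data frame: `chrom`, `pos`, `gene_id`, `strand`)
#'   and `truth` (planted boundary intervals with strands, planted loop
#'   table with counts and convergent/strong flags).
#' @export
simulate_chromatin_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom <- "chr17"
  peak_w <- 400L
  n_pairs <- config$n_boundary_pairs + config$n_nonconvergent_pairs
  counts <- rep_len(config$linkage_counts, n_pairs)
  convergent <- rep(c(TRUE, FALSE),
                    c(config$n_boundary_pairs, config$n_nonconvergent_pairs))

  lefts <- 100000L + (seq_len(n_pairs) - 1L) * 200000L +
    as.integer(runif(n_pairs, 0, 5000))
  rights <- lefts + 40000L + as.integer(runif(n_pairs, 0, 5000))

  bnd_start <- c(lefts, rights)
  bnd_strand <- c(rep("+", n_pairs), ifelse(convergent, "-", "+"))
  bnd <- data.frame(chrom = chrom, start = bnd_start,
                    end = bnd_start + peak_w,
                    name = c(sprintf("bndL%02d", seq_len(n_pairs)),
                             sprintf("bndR%02d", seq_len(n_pairs))),
                    score = 1000, strand = ".", stringsAsFactors = FALSE)

  decoy_start <- max(rights) + peak_w + 50000L +
    (seq_len(config$n_decoy_ctcf) - 1L) * 30000L +
    as.integer(runif(config$n_decoy_ctcf, 0, 2000))
  decoys <- data.frame(chrom = chrom, start = decoy_start,
                       end = decoy_start + peak_w,
                       name = sprintf("decoy%02d", seq_len(config$n_decoy_ctcf)),
                       score = 500, strand = ".", stringsAsFactors = FALSE)
  ctcf <- rbind(bnd, decoys)

  jitter_track <- function(base, dl, dr) {
    data.frame(chrom = chrom, start = base$start + dl, end = base$end + dr,
               name = ".", score = NA_real_, strand = ".",
               stringsAsFactors = FALSE)
  }
  cohesin <- list(RAD21 = jitter_track(bnd, -50L, 60L),
                  STAG1 = jitter_track(bnd, 30L, -40L),
                  SMC1A = jitter_track(bnd, -20L, 20L))

  motifs <- data.frame(chrom = chrom, start = bnd$start + 190L,
                       end = bnd$start + 209L, name = "CTCF_motif",
                       score = NA_real_, strand = bnd_strand,
                       stringsAsFactors = FALSE)

  linkages <- data.frame(chrom = chrom,
                         start_a = lefts, end_a = lefts + peak_w,
                         start_b = rights, end_b = rights + peak_w,
                         count = counts, stringsAsFactors = FALSE)

  inside <- as.integer((lefts + rights + peak_w) / 2)
  outside <- lefts - 20000L
  tss <- data.frame(chrom = chrom, pos = c(inside, outside),
                    gene_id = c(sprintf("GIN%02d", seq_len(n_pairs)),
                                sprintf("GOUT%02d", seq_len(n_pairs))),
                    strand = rep(c("+", "-"), length.out = 2L * n_pairs),
                    stringsAsFactors = FALSE)

  truth_loops <- data.frame(
    chrom = chrom, left_start = lefts, left_end = lefts + peak_w,
    right_start = rights, right_end = rights + peak_w,
    count = counts, convergent = convergent, strong = counts > 3,
    stringsAsFactors = FALSE)

  list(ctcf = ctcf, motifs = motifs, cohesin = cohesin,
       linkages = linkages, tss = tss,
       truth = list(boundaries = bnd, boundary_strands = bnd_strand,
                    loops = truth_loops))
}
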