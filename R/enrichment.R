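#' Enrichment scoring parameters
#'
#' @param tau Rank-weight exponent of the GSVA random walk (default 1).
#' @param mode `"magnitude_difference"` (score = max(0, max nu) +
#'   min(0, min nu), the package default) or `"max_deviation"` (the walk
#'   value at its largest absolute excursion).
#' @param kernel_bandwidth_factor Per-gene kernel bandwidth is the
#'   gene's sample SD times this factor (default 1/4).
#' @param alpha ssGSEA rank-weight exponent (default 0.25).
#' @return List of class `"enrichment_params"`.
#' @export
enrichment_params <- function(tau = 1,
                              mode = c("magnitude_difference", "max_deviation"),
                              kernel_bandwidth_factor = 1 / 4,
                              alpha = 0.25) {
  mode <- match.arg(mode)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (kernel_bandwidth_factor <= 0) {
    stop("kernel_bandwidth_factor must be > 0", call. = FALSE)
  }
  structure(list(tau = tau, mode = mode,
                 kernel_bandwidth_factor = kernel_bandwidth_factor,
                 alpha = alpha),
            class = "enrichment_params")
}

#' Kernel-ECDF expression statistic
#'
#' Per-gene Gaussian-kernel cumulative-density estimate evaluated at
#' each sample's own value:
#' `zhat_ij = (1/n) * sum_k Phi((x_ij - x_ik) / h_i)` with bandwidth
#' `h_i = s_i * factor`, `s_i` the gene's sample standard deviation.
#' Zero-variance genes get `zhat = 0.5` everywhere (kept, not dropped,
#' so the gene universe stays stable across gene sets).
#'
#' @param matrix Log2-scale genes x samples matrix (n >= 2 samples).
#' @param bandwidth_factor Bandwidth factor (default 1/4).
#' @return Matrix of `zhat` values, same dimnames as the input.
#' @export
kernel_cdf_stat <- function(matrix, bandwidth_factor = 1 / 4) {
  m <- as_log2_matrix(matrix)
  n <- ncol(m)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  out <- m
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    s <- sd(x)
    if (s == 0) {
      out[i, ] <- 0.5
    } else {
      h <- s * bandwidth_factor
      out[i, ] <- rowMeans(pnorm(outer(x, x, "-") / h))
    }
  }
  out
}

# deterministic descending order with lexicographic gene-id tie-break
rank_descending <- function(values, gene_ids) {
  order(-values, gene_ids)
}

# GSVA-style weighted KS random walk for one sample.
# ord: permutation placing genes in rank order; in_set: logical over
# genes (original order); weights w = |p/2 - rank|^tau.
gsva_walk <- function(ord, in_set, tau, mode) {
  p <- length(ord)
  in_rank <- in_set[ord]
  m <- sum(in_rank)
  w <- abs(p / 2 - seq_len(p))^tau
  denom_in <- sum(w[in_rank])
  # accumulate raw weights and divide once: keeps the walk's arithmetic
  # stable so excursion ties resolve deterministically
  num <- if (denom_in > 0) {
    cumsum(ifelse(in_rank, w, 0)) / denom_in
  } else {
    cumsum(in_rank) / m  # degenerate: all set weights zero
  }
  nu <- num - cumsum(!in_rank) / (p - m)
  if (mode == "magnitude_difference") {
    max(0, max(nu)) + min(0, min(nu))
  } else {
    nu[which.max(abs(nu))]
  }
}

#' GSVA-style single-sample enrichment scores
#'
#' For each sample, genes are ranked by the kernel-ECDF statistic
#' (descending, ties broken by lexicographic gene id) and a weighted
#' Kolmogorov-Smirnov-like random walk is run for each gene set: set
#' genes step up proportionally to `|p/2 - rank|^tau` (normalized over
#' the set), non-set genes step down by `1/(p - m)`. The score is either
#' the sum of the maximal positive and maximal negative excursions
#' (`magnitude_difference`, default) or the walk value at the largest
#' absolute excursion (`max_deviation`). Scores lie in `[-1, 1]`.
#'
#' Gene sets with an empty intersection with the matrix genes, or
#' covering the whole matrix, cannot be scored: they get `NA` scores and
#' a warning, other sets are scored normally.
#'
#' @param matrix Log2-scale genes x samples matrix (n >= 2 samples).
#' @param gene_sets Named list of character vectors.
#' @param params An [enrichment_params()].
#' @return Samples x sets score matrix with attributes `params` and
#'   `set_sizes` (the per-set intersection size with matrix genes).
#' @export
gsva_scores <- function(matrix, gene_sets, params = enrichment_params()) {
  m <- as_log2_matrix(matrix)
  stopifnot(inherits(params, "enrichment_params"),
            is.list(gene_sets), !is.null(names(gene_sets)))
  z <- kernel_cdf_stat(m, params$kernel_bandwidth_factor)
  p <- nrow(m)
  gene_ids <- rownames(m)
  in_set_mat <- vapply(gene_sets, function(g) gene_ids %in% g,
                       logical(p))
  sizes <- colSums(in_set_mat)
  bad <- sizes == 0L | sizes == p
  if (any(bad)) {
    warning("gene set(s) not scorable (empty intersection or full universe): ",
            paste(names(gene_sets)[bad], collapse = ", "), call. = FALSE)
  }
  scores <- matrix(NA_real_, ncol(m), length(gene_sets),
                   dimnames = list(colnames(m), names(gene_sets)))
  for (j in seq_len(ncol(m))) {
    ord <- rank_descending(z[, j], gene_ids)
    for (k in which(!bad)) {
      scores[j, k] <- gsva_walk(ord, in_set_mat[, k], params$tau,
                                params$mode)
    }
  }
  structure(scores, params = params, set_sizes = sizes)
}

#' ssGSEA single-sample enrichment score
#'
#' For each sample, genes are ranked by raw expression (descending, ties
#' by lexicographic gene id); the gene at position `l` carries rank
#' weight `r = p - l + 1` (largest for the highest-expressed gene). The
#' score is the unnormalized sum over all positions of the difference
#' between the weighted in-set ECDF (`r^alpha` weights, normalized over
#' the set) and the uniform out-of-set ECDF.
#'
#' @param matrix Log2-scale genes x samples matrix.
#' @param gene_set Character vector of gene symbols.
#' @param alpha Rank-weight exponent (default 0.25, the value used by
#'   ESTIMATE-style immune scoring).
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea_scores <- function(matrix, gene_set, alpha = 0.25) {
  m <- as_log2_matrix(matrix)
  p <- nrow(m)
  gene_ids <- rownames(m)
  in_set <- gene_ids %in% gene_set
  msize <- sum(in_set)
  if (msize == 0L || msize == p) {
    stop("gene set must intersect the matrix genes without covering them",
         call. = FALSE)
  }
  out <- setNames(numeric(ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    ord <- rank_descending(m[, j], gene_ids)
    in_rank <- in_set[ord]
    r <- p - seq_len(p) + 1L
    win <- ifelse(in_rank, r^alpha, 0)
    p_in <- cumsum(win) / sum(win)
    p_out <- cumsum(!in_rank) / (p - msize)
    out[j] <- sum(p_in - p_out)
  }
  out
}

#' Paired metastasis-minus-primary delta scores
#'
#' Reduces a samples x sets enrichment score table to one row per fully
#' paired patient: the metastatic sample's score minus the primary
#' sample's score. Patients missing either lesion are excluded with a
#' warning; a patient with duplicated lesions is an error.
#'
#' @param score_table Samples x sets matrix (e.g. from [gsva_scores()]).
#' @param annotations Data frame with columns `sample_id`, `patient_id`,
#'   `lesion` (values `"primary"` / `"metastasis"`).
#' @return Patients x sets matrix of delta scores.
#' @export
delta_paired_scores <- function(score_table, annotations) {
  stopifnot(all(c("sample_id", "patient_id", "lesion") %in%
                  colnames(annotations)))
  ann <- annotations[annotations$sample_id %in% rownames(score_table), ,
                     drop = FALSE]
  if (any(!ann$lesion %in% c("primary", "metastasis"))) {
    stop("lesion must be 'primary' or 'metastasis'", call. = FALSE)
  }
  dup <- duplicated(ann[, c("patient_id", "lesion")])
  if (any(dup)) {
    stop("duplicate lesion for patient(s): ",
         paste(unique(ann$patient_id[dup]), collapse = ", "), call. = FALSE)
  }
  tab <- table(ann$patient_id)
  complete <- names(tab)[tab == 2L]
  dropped <- setdiff(unique(ann$patient_id), complete)
  if (length(dropped) > 0L) {
    warning("excluding unpaired patient(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(complete) == 0L) stop("no fully paired patients", call. = FALSE)
  complete <- unique(ann$patient_id[ann$patient_id %in% complete])
  prim <- ann$sample_id[match(paste(complete, "primary"),
                              paste(ann$patient_id, ann$lesion))]
  met <- ann$sample_id[match(paste(complete, "metastasis"),
                             paste(ann$patient_id, ann$lesion))]
  delta <- score_table[met, , drop = FALSE] -
    score_table[prim, , drop = FALSE]
  rownames(delta) <- complete
  delta
}

#' Quartile stratification of a per-sample score
#'
#' Splits samples at the empirical 25th and 75th percentiles (linear
#' interpolation): `high` for scores at or above the upper quartile,
#' `low` for scores at or below the lower quartile, `mid` otherwise. If
#' all scores are equal the quartiles coincide and every sample would be
#' both high and low; in that degenerate case all samples are labeled
#' `mid` with a warning.
#'
#' @param scores Named numeric vector (n >= 4).
#' @return List with `labels` (named character), `q1` and `q3`.
#' @export
stratify_quartiles <- function(scores) {
  if (length(scores) < 4L) stop("need at least 4 samples", call. = FALSE)
  if (is.null(names(scores))) stop("scores must be named", call. = FALSE)
  q1 <- unname(quantile(scores, 0.25, type = 7))
  q3 <- unname(quantile(scores, 0.75, type = 7))
  if (q1 == q3) {
    warning("degenerate score distribution (q1 == q3); all samples 'mid'",
            call. = FALSE)
    labels <- setNames(rep("mid", length(scores)), names(scores))
  } else {
    labels <- ifelse(scores >= q3, "high",
                     ifelse(scores <= q1, "low", "mid"))
    labels <- setNames(labels, names(scores))
  }
  list(labels = labels, q1 = q1, q3 = q3)
}
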