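#' Per-gene two-group differential expression
#'
#' Rank-based differential expression between two sample groups on a
#' log2-scale matrix. The p-value is a two-sided Mann-Whitney U test
#' (exact when the combined group size is at most 20 and there are no
#' ties, otherwise the normal approximation with tie correction); the
#' effect is the difference of group means on the log2 scale
#' (`group_b` minus `group_a`); q-values are Benjamini-Hochberg across
#' genes. Genes with zero variance across both groups get `p = 1`,
#' `log2_fc = 0` and are flagged.
#'
#' @param matrix Log2-scale genes x samples matrix or
#'   [expression_matrix()].
#' @param group_a_ids,group_b_ids Disjoint sample-id vectors, each of
#'   size >= 2, all present in the matrix.
#' @return Data frame with columns `gene_id`, `log2_fc`, `p_value`,
#'   `q_value`, `zero_variance`.
#' @export
differential_expression <- function(matrix, group_a_ids, group_b_ids) {
  m <- as_log2_matrix(matrix)
  if (length(intersect(group_a_ids, group_b_ids)) > 0L) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (length(group_a_ids) < 2L || length(group_b_ids) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  missing <- setdiff(c(group_a_ids, group_b_ids), colnames(m))
  if (length(missing) > 0L) {
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  a <- m[, group_a_ids, drop = FALSE]
  b <- m[, group_b_ids, drop = FALSE]
  n_comb <- length(group_a_ids) + length(group_b_ids)
  p <- numeric(nrow(m)); fc <- numeric(nrow(m)); zv <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    xa <- a[i, ]; xb <- b[i, ]
    if (stats::var(c(xa, xb)) == 0) {
      p[i] <- 1; fc[i] <- 0; zv[i] <- TRUE
    } else {
      exact <- n_comb <= 20L && !anyDuplicated(c(xa, xb))
      p[i] <- suppressWarnings(
        wilcox.test(xb, xa, exact = exact)$p.value)
      fc[i] <- mean(xb) - mean(xa)
    }
  }
  data.frame(gene_id = rownames(m), log2_fc = fc, p_value = p,
             q_value = benjamini_hochberg(p), zero_variance = zv,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j`, capped at 1.
#' Ties keep their input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Derive a luminal/basal signature pair by two-group FDR filter
#'
#' Candidate genes significantly higher (FDR below `fdr_cutoff`) in the
#' basal group (positive `log2_fc`, basal coded as group B upstream)
#' form the basal set; those significantly higher in the luminal group
#' (negative `log2_fc`) form the luminal set.
#'
#' @param de_records Data frame from [differential_expression()] with
#'   basal as group B.
#' @param candidate_genes Genes eligible for membership; must be a
#'   subset of the DE table's genes.
#' @param fdr_cutoff FDR threshold (default 0.01).
#' @return List with character vectors `basal` and `luminal` and the
#'   `provenance` string `"two_group_filter"`.
#' @export
derive_two_group_signature <- function(de_records, candidate_genes,
                                       fdr_cutoff = 0.01) {
  extra <- setdiff(candidate_genes, de_records$gene_id)
  if (length(extra) > 0L) {
    stop("candidate gene(s) absent from DE table: ",
         paste(head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  de <- de_records[de_records$gene_id %in% candidate_genes, , drop = FALSE]
  sig <- de$q_value < fdr_cutoff
  list(basal = de$gene_id[sig & de$log2_fc > 0],
       luminal = de$gene_id[sig & de$log2_fc < 0],
       provenance = "two_group_filter")
}

# deterministic top-N ranking used by signature derivation: largest
# log2_fc first, ties by smaller p then lexicographic gene id
rank_by_fc <- function(de, decreasing = TRUE) {
  key <- if (decreasing) -de$log2_fc else de$log2_fc
  de[order(key, de$p_value, de$gene_id), , drop = FALSE]
}

#' Derive a signature by intersecting top-N up-regulated genes
#'
#' Takes the `n` genes with the largest positive fold change in each of
#' two differential-expression comparisons (within genes passing the
#' significance gate), breaking ties by smaller p-value then gene id,
#' and returns the intersection.
#'
#' @param de_1,de_2 DE tables from [differential_expression()] over the
#'   same gene universe.
#' @param n Number of top genes per comparison (default 200).
#' @param fdr_gate Only genes with `q_value < fdr_gate` are ranked;
#'   `NULL` disables the gate.
#' @return Character vector of intersected gene ids.
#' @export
derive_topN_intersection_signature <- function(de_1, de_2, n = 200,
                                               fdr_gate = 0.05) {
  if (!setequal(de_1$gene_id, de_2$gene_id)) {
    stop("DE tables must share one gene universe", call. = FALSE)
  }
  top_up <- function(de) {
    if (!is.null(fdr_gate)) de <- de[de$q_value < fdr_gate, , drop = FALSE]
    de <- de[de$log2_fc > 0, , drop = FALSE]
    if (nrow(de) < n) {
      warning(sprintf("only %d gene(s) with positive fold change; using all",
                      nrow(de)), call. = FALSE)
    }
    head(rank_by_fc(de)$gene_id, n)
  }
  intersect(top_up(de_1), top_up(de_2))
}

#' Derive a knockdown-response signature
#'
#' The `n` genes most down-regulated (most negative fold change) in a
#' knockdown-versus-control comparison; with `direction = "up"`, the
#' most up-regulated instead. Ties break by smaller p-value then gene
#' id.
#'
#' @param de_records DE table (knockdown as group B).
#' @param n Signature size (default 100).
#' @param direction `"down"` (default) or `"up"`.
#' @return Character vector of gene ids.
#' @export
derive_knockdown_signature <- function(de_records, n = 100,
                                       direction = c("down", "up")) {
  direction <- match.arg(direction)
  de <- if (direction == "down") {
    de_records[de_records$log2_fc < 0, , drop = FALSE]
  } else {
    de_records[de_records$log2_fc > 0, , drop = FALSE]
  }
  if (nrow(de) < n) {
    warning(sprintf("only %d gene(s) in the %s direction; using all",
                    nrow(de), direction), call. = FALSE)
  }
  head(rank_by_fc(de, decreasing = direction == "up")$gene_id, n)
}
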