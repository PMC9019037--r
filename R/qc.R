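#' Single-cell QC filtering
#'
#' One-pass quality filter for a single-cell counts matrix (genes x
#' cells). Genes detected (count > 0) in fewer than `min_cells` cells are
#' removed first; then cells expressing fewer than `min_genes` or more
#' than `max_genes` detected genes, or with a mitochondrial count
#' fraction above `max_mito_frac`, are removed. Detected-gene counts and
#' the mitochondrial fraction are computed on the gene-filtered matrix.
#' The filter runs strictly once; it does not iterate.
#'
#' Mitochondrial genes are identified by symbol prefix (default `"MT-"`).
#' Boundary behaviour: a gene detected in exactly `min_cells` cells is
#' retained; a cell at exactly `max_mito_frac` is retained.
#'
#' @param counts Counts-scale [expression_matrix()] with cells as samples.
#' @param min_cells Minimum number of cells a gene must be detected in.
#' @param min_genes,max_genes Allowed range of detected genes per cell.
#' @param max_mito_frac Maximum mitochondrial count fraction per cell.
#' @param mito_prefix Symbol prefix identifying mitochondrial genes.
#' @return List with `matrix` (the filtered [expression_matrix()]) and
#'   `report`, a list of tallies: `genes_in`, `genes_kept`,
#'   `genes_removed`, `cells_in`, `cells_kept`, `cells_removed`,
#'   `cells_removed_low_genes`, `cells_removed_high_genes`,
#'   `cells_removed_mito`.
#' @export
filter_single_cell_matrix <- function(counts, min_cells = 20,
                                      min_genes = 300, max_genes = 8000,
                                      max_mito_frac = 0.45,
                                      mito_prefix = "MT-") {
  if (inherits(counts, "expr_matrix") && expr_scale(counts) != "counts") {
    stop("single-cell QC requires a counts-scale matrix", call. = FALSE)
  }
  m <- unclass(counts)
  n_genes_in <- nrow(m); n_cells_in <- ncol(m)

  detected_cells <- rowSums(m > 0)
  keep_gene <- detected_cells >= min_cells
  m2 <- m[keep_gene, , drop = FALSE]

  genes_per_cell <- colSums(m2 > 0)
  is_mito <- startsWith(rownames(m2), mito_prefix)
  total <- colSums(m2)
  mito_frac <- ifelse(total > 0, colSums(m2[is_mito, , drop = FALSE]) / total, 0)

  low <- genes_per_cell < min_genes
  high <- genes_per_cell > max_genes
  mito_bad <- mito_frac > max_mito_frac
  keep_cell <- !(low | high | mito_bad)

  out <- m2[, keep_cell, drop = FALSE]
  if (nrow(out) == 0L || ncol(out) == 0L) {
    stop("all cells removed", call. = FALSE)
  }
  list(
    matrix = expression_matrix(out, "counts"),
    report = list(
      genes_in = n_genes_in,
      genes_kept = sum(keep_gene),
      genes_removed = n_genes_in - sum(keep_gene),
      cells_in = n_cells_in,
      cells_kept = sum(keep_cell),
      cells_removed = n_cells_in - sum(keep_cell),
      cells_removed_low_genes = sum(low),
      cells_removed_high_genes = sum(high),
      cells_removed_mito = sum(mito_bad)
    )
  )
}
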