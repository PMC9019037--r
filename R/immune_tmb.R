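#' Classify a MAF variant-classification token
#'
#' Truncating classes: `Nonsense_Mutation`, `Frame_Shift_Del`,
#' `Frame_Shift_Ins`, `Splice_Site`. Non-truncating classes:
#' `Missense_Mutation`, `In_Frame_Del`, `In_Frame_Ins`,
#' `Nonstop_Mutation`. Any other token (e.g. `Silent`) is excluded from
#' tumor-mutation-burden counting.
#'
#' @param variant_classification Character vector of MAF tokens.
#' @return Character vector: `"truncating"`, `"non_truncating"` or
#'   `"excluded"`.
#' @export
classify_variant <- function(variant_classification) {
  ifelse(variant_classification %in% truncating_tokens, "truncating",
         ifelse(variant_classification %in% non_truncating_tokens,
                "non_truncating", "excluded"))
}

#' Weighted tumor mutation burden per sample
#'
#' `TMB = 2 * (truncating count) + (non-truncating count)`, counting
#' classified rows of the mutation table per sample; excluded rows are
#' ignored. Samples absent from the table get no record (the caller
#' decides whether absence means zero).
#'
#' @param mutation_table Data frame with columns `sample_id` and
#'   `variant_classification` (e.g. from [read_maf()] or
#'   [simulate_maf()]).
#' @return Data frame with `sample_id`, `n_truncating`,
#'   `n_non_truncating`, `tmb`, one row per sample present, in first-
#'   appearance order.
#' @export
compute_tmb <- function(mutation_table) {
  stopifnot(all(c("sample_id", "variant_classification") %in%
                  colnames(mutation_table)))
  cls <- classify_variant(mutation_table$variant_classification)
  keep <- cls != "excluded"
  samples <- unique(mutation_table$sample_id)
  tr <- table(factor(mutation_table$sample_id[keep & cls == "truncating"],
                     levels = samples))
  nt <- table(factor(mutation_table$sample_id[keep & cls == "non_truncating"],
                     levels = samples))
  data.frame(sample_id = samples,
             n_truncating = as.integer(tr),
             n_non_truncating = as.integer(nt),
             tmb = 2 * as.integer(tr) + as.integer(nt),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential pathway enrichment between two sample groups
#'
#' Per gene set, a two-sided Mann-Whitney test on the per-sample
#' enrichment scores of the two groups, Benjamini-Hochberg adjusted
#' across sets. A set is called `enriched` (in the group of interest)
#' when `q < fdr` and the group-of-interest median score exceeds the
#' other group's. For paired designs, pass a delta-score table (e.g.
#' from [delta_paired_scores()]) and group the rows by genotype.
#'
#' @param score_table Samples x sets numeric matrix.
#' @param group_of_interest_ids,reference_ids Disjoint row-id vectors.
#' @param fdr FDR threshold for the enriched call (default 0.05).
#' @return Data frame with `set_name`, `statistic` (Mann-Whitney U of
#'   the group of interest), `p_value`, `q_value`,
#'   `direction_up` (group-of-interest median higher) and `enriched`.
#' @export
pathway_differential_enrichment <- function(score_table,
                                            group_of_interest_ids,
                                            reference_ids, fdr = 0.05) {
  if (length(intersect(group_of_interest_ids, reference_ids)) > 0L) {
    stop("groups must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(group_of_interest_ids, reference_ids),
                     rownames(score_table))
  if (length(missing) > 0L) {
    stop("sample(s) not in score table: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  g <- score_table[group_of_interest_ids, , drop = FALSE]
  r <- score_table[reference_ids, , drop = FALSE]
  n_comb <- length(group_of_interest_ids) + length(reference_ids)
  res <- lapply(seq_len(ncol(score_table)), function(k) {
    xg <- g[, k]; xr <- r[, k]
    if (all(c(xg, xr) == c(xg, xr)[1L])) {
      return(c(stat = length(xg) * length(xr) / 2, p = 1, up = 0))
    }
    exact <- n_comb <= 20L && !anyDuplicated(c(xg, xr))
    wt <- suppressWarnings(wilcox.test(xg, xr, exact = exact))
    c(stat = unname(wt$statistic), p = wt$p.value,
      up = as.numeric(median(xg) > median(xr)))
  })
  res <- do.call(rbind, res)
  q <- benjamini_hochberg(res[, "p"])
  data.frame(set_name = colnames(score_table),
             statistic = res[, "stat"], p_value = res[, "p"],
             q_value = q, direction_up = res[, "up"] == 1,
             enriched = q < fdr & res[, "up"] == 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect enriched pathways across comparisons
#'
#' Direction-aware intersection of the `enriched` sets of two or more
#' [pathway_differential_enrichment()] results, plus Venn region counts
#' (for 2 or 3 comparisons).
#'
#' @param result_list Named list of enrichment result data frames.
#' @return List with `intersection` (character vector of set names
#'   enriched in every comparison), `enriched_per_comparison` and
#'   `venn_counts` (named by binary membership pattern, e.g. `"110"`;
#'   `NULL` for > 3 comparisons).
#' @export
intersect_pathways <- function(result_list) {
  if (!is.list(result_list) || length(result_list) < 2L) {
    stop("need at least 2 enrichment results", call. = FALSE)
  }
  enriched <- lapply(result_list, function(r) r$set_name[r$enriched])
  inter <- Reduce(intersect, enriched)
  venn <- NULL
  if (length(result_list) <= 3L) {
    universe <- unique(unlist(enriched))
    if (length(universe) > 0L) {
      membership <- vapply(enriched, function(e) universe %in% e,
                           logical(length(universe)))
      membership <- matrix(membership, nrow = length(universe))
      pattern <- apply(membership, 1L, function(b) {
        paste(as.integer(b), collapse = "")
      })
      venn <- table(pattern)
      venn <- setNames(as.integer(venn), names(venn))
    } else {
      venn <- integer(0)
    }
  }
  list(intersection = inter, enriched_per_comparison = enriched,
       venn_counts = venn)
}

#' Mean z-score immune-cell-type scores
#'
#' Each gene is z-scored across samples (zero-variance genes skipped
#' with a warning); a cell type's score in a sample is the mean z over
#' the signature genes available in the matrix.
#'
#' @param matrix Log2-scale genes x samples matrix.
#' @param celltype_signatures Named list of gene-symbol vectors.
#' @return Samples x cell-types score matrix.
#' @export
immune_cell_scores <- function(matrix, celltype_signatures) {
  m <- as_log2_matrix(matrix)
  stopifnot(is.list(celltype_signatures),
            !is.null(names(celltype_signatures)))
  sds <- apply(m, 1L, sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance gene(s) skipped", sum(sds == 0)),
            call. = FALSE)
  }
  usable <- sds > 0
  z <- (m[usable, , drop = FALSE] -
          rowMeans(m[usable, , drop = FALSE])) / sds[usable]
  out <- vapply(celltype_signatures, function(genes) {
    avail <- intersect(genes, rownames(z))
    if (length(avail) == 0L) {
      stop("signature has no usable genes in the matrix", call. = FALSE)
    }
    colMeans(z[avail, , drop = FALSE])
  }, numeric(ncol(m)))
  matrix(out, nrow = ncol(m),
         dimnames = list(colnames(m), names(celltype_signatures)))
}

#' Fraction of cells expressing a gene, per group
#'
#' @param counts Counts-scale genes x cells matrix.
#' @param gene Gene symbol (must be present).
#' @param groups Character/factor of group labels, one per cell (named
#'   by cell id, or in column order).
#' @return Named numeric vector: per-group fraction of cells with
#'   count > 0.
#' @export
percent_expressing <- function(counts, gene, groups) {
  m <- if (inherits(counts, "expr_matrix")) unclass(counts) else counts
  if (!gene %in% rownames(m)) {
    stop(sprintf("gene '%s' not present in the counts matrix", gene),
         call. = FALSE)
  }
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  if (length(groups) != ncol(m)) {
    stop("one group label per cell required", call. = FALSE)
  }
  detected <- m[gene, ] > 0
  vapply(split(detected, as.character(groups)), mean, numeric(1))
}
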