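#' Build nearest-centroid subtype model from a labeled reference panel
#'
#' Per-gene, per-class median log2 expression over a labeled reference
#' panel (medians rather than means for robustness to outlying lines).
#'
#' @param matrix Log2-scale genes x samples matrix.
#' @param labels Character vector of class labels, one per sample
#'   (named by sample id, or in column order).
#' @param center `"median"` (default) or `"mean"`.
#' @return List of class `"centroid_model"` with `genes`, `subtypes` and
#'   `centroids` (genes x subtypes matrix).
#' @export
build_centroids <- function(matrix, labels, center = c("median", "mean")) {
  center <- match.arg(center)
  m <- as_log2_matrix(matrix)
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(m), names(labels))
    if (length(missing) > 0L) {
      stop("labels missing for sample(s): ",
           paste(head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    labels <- labels[colnames(m)]
  }
  if (length(labels) != ncol(m)) {
    stop("one label per sample required", call. = FALSE)
  }
  subtypes <- sort(unique(as.character(labels)))
  if (length(subtypes) < 2L) stop("need at least 2 subtypes", call. = FALSE)
  fun <- if (center == "median") stats::median else mean
  centroids <- vapply(subtypes, function(s) {
    apply(m[, labels == s, drop = FALSE], 1L, fun)
  }, numeric(nrow(m)))
  rownames(centroids) <- rownames(m)
  structure(list(genes = rownames(m), subtypes = subtypes,
                 centroids = centroids, center = center),
            class = "centroid_model")
}

#' Call the subtype of one expression profile
#'
#' Spearman correlation between the profile and each class centroid over
#' the shared genes; the call is the highest-correlating subtype.
#' Probabilities are the positive correlations normalized to sum to 1
#' (negative correlations contribute zero). If no centroid correlates
#' positively the label is still the argmax but the probabilities are
#' returned as `NA` and flagged. An exact tie for the best correlation is
#' broken by subtype label order, with a warning.
#'
#' Because the statistic is rank-based, the call is invariant to any
#' strictly monotone transform of the profile.
#'
#' @param profile Named numeric vector of log2 expression.
#' @param model A [build_centroids()] model.
#' @return List of class `"subtype_call"` with `label`, `probabilities`
#'   (named, summing to 1 or all `NA`), `correlations` and
#'   `no_positive_correlation` flag.
#' @export
call_subtype <- function(profile, model) {
  stopifnot(inherits(model, "centroid_model"))
  shared <- intersect(names(profile), model$genes)
  if (length(shared) < 3L) {
    stop("fewer than 3 genes shared with the centroid model", call. = FALSE)
  }
  rho <- vapply(model$subtypes, function(s) {
    suppressWarnings(cor(profile[shared], model$centroids[shared, s],
                         method = "spearman"))
  }, numeric(1))
  rho[is.na(rho)] <- 0  # constant centroid or profile over shared genes
  best <- which(rho == max(rho))
  if (length(best) > 1L) {
    warning("tie for best-correlated subtype; broken by label order",
            call. = FALSE)
  }
  label <- model$subtypes[best[1L]]
  pos <- pmax(rho, 0)
  no_pos <- all(rho <= 0)
  probabilities <- if (no_pos) {
    setNames(rep(NA_real_, length(rho)), model$subtypes)
  } else {
    setNames(pos / sum(pos), model$subtypes)
  }
  structure(list(label = label, probabilities = probabilities,
                 correlations = setNames(rho, model$subtypes),
                 no_positive_correlation = no_pos),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat("subtype call:", x$label)
  if (x$no_positive_correlation) {
    cat(" (no positive correlation; probabilities undefined)\n")
  } else {
    cat(sprintf(" (probability %.3f)\n", max(x$probabilities)))
  }
  invisible(x)
}

#' Per-gene log2 fold changes between two groups
#'
#' Difference of group means on the log2 scale, `group_b` minus
#' `group_a`.
#'
#' @param matrix Log2-scale genes x samples matrix.
#' @param group_a_ids,group_b_ids Sample-id vectors present in the
#'   matrix.
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log_fold_changes <- function(matrix, group_a_ids, group_b_ids) {
  m <- as_log2_matrix(matrix)
  missing <- setdiff(c(group_a_ids, group_b_ids), colnames(m))
  if (length(missing) > 0L) {
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rowMeans(m[, group_b_ids, drop = FALSE]) -
    rowMeans(m[, group_a_ids, drop = FALSE])
}

#' Classify cross-comparison fold-change concordance
#'
#' A gene is `consistent_up` when its log2 fold change exceeds
#' `min_abs_fc` in every comparison, `consistent_down` when it is below
#' `-min_abs_fc` in every comparison, and `inconsistent` otherwise.
#' Inequalities are strict, so with the default `min_abs_fc = 0` a zero
#' fold change in any comparison makes the gene inconsistent.
#'
#' @param fc_tables List (>= 2) of named numeric fold-change vectors
#'   over the same genes.
#' @param min_abs_fc Magnitude threshold (default 0: strict sign
#'   agreement).
#' @return Data frame with `gene_id`, one `fc_*` column per comparison,
#'   and `class`.
#' @export
classify_concordance <- function(fc_tables, min_abs_fc = 0) {
  if (!is.list(fc_tables) || length(fc_tables) < 2L) {
    stop("need at least 2 fold-change tables", call. = FALSE)
  }
  genes <- names(fc_tables[[1]])
  if (is.null(genes)) stop("fold-change vectors must be named", call. = FALSE)
  for (k in seq_along(fc_tables)) {
    if (!setequal(names(fc_tables[[k]]), genes)) {
      stop("fold-change tables must cover the same genes", call. = FALSE)
    }
  }
  fc <- vapply(fc_tables, function(v) v[genes], numeric(length(genes)))
  if (is.null(colnames(fc)) || any(!nzchar(colnames(fc)))) {
    colnames(fc) <- paste0("cmp", seq_len(ncol(fc)))
  }
  up <- rowSums(fc > min_abs_fc) == ncol(fc)
  down <- rowSums(fc < -min_abs_fc) == ncol(fc)
  cls <- ifelse(up, "consistent_up",
                ifelse(down, "consistent_down", "inconsistent"))
  out <- data.frame(gene_id = genes, fc, class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(out)[1L + seq_len(ncol(fc))] <- paste0("fc_", colnames(fc))
  out
}
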