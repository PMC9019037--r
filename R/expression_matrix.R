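#' Construct an expression matrix
#'
#' A thin, validated container for a genes-by-samples expression matrix.
#' Rows are genes (unique symbols), columns are samples (unique identifiers).
#' The `scale` attribute records whether values are log2-transformed
#' expression or raw non-negative integer counts; downstream scoring
#' functions require `"log2"`, the single-cell QC filter requires
#' `"counts"`.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene
#'   symbols) and colnames (sample identifiers). All values must be finite;
#'   on the counts scale they must additionally be non-negative integers.
#' @param scale Either `"log2"` or `"counts"`.
#' @return A numeric matrix of class `"expr_matrix"` with a `scale`
#'   attribute.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' em <- expression_matrix(m, "log2")
#' expr_scale(em)
#' @export
expression_matrix <- function(values, scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gn <- rownames(values)
  sn <- colnames(values)
  if (is.null(gn) || is.null(sn) || anyNA(gn) || anyNA(sn) ||
      any(!nzchar(gn)) || any(!nzchar(sn))) {
    stop("`values` needs non-empty gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(gn)) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(sn)) stop("duplicate sample identifiers", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (scale == "counts" &&
      (any(values < 0) || any(values != round(values)))) {
    stop("counts-scale values must be non-negative integers", call. = FALSE)
  }
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' Scale of an expression matrix
#' @param x An `expr_matrix`.
#' @return `"log2"` or `"counts"`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "log2" else s
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), expr_scale(x)))
  k <- min(5L, nrow(x)); j <- min(5L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(j), drop = FALSE])
  if (nrow(x) > k || ncol(x) > j) cat("...\n")
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) {
    structure(out, scale = expr_scale(x),
              class = c("expr_matrix", "matrix", "array"))
  } else {
    out
  }
}

# internal: coerce/validate input for scoring functions (log2 scale)
as_log2_matrix <- function(matrix) {
  if (inherits(matrix, "expr_matrix")) {
    if (expr_scale(matrix) != "log2") {
      stop("expression matrix must be on the log2 scale", call. = FALSE)
    }
    return(unclass(matrix))
  }
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("expected a numeric genes x samples matrix", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  matrix
}
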