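#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT format (one gene set per line:
#' name, description, then gene symbols). The description field is
#' discarded. Duplicate genes within a line are removed with a warning.
#' Gene symbol matching throughout the package is exact and
#' case-sensitive; no alias resolution is attempted.
#'
#' @param path Path to a GMT file (plain text or gzip).
#' @return Named list of character vectors of gene symbols.
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT format error at line %d: fewer than 3 fields", k),
           call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): duplicate genes removed",
                      k, fields[[1]]), call. = FALSE)
      genes <- unique(genes)
    }
    if (length(genes) < 1L) {
      stop(sprintf("GMT format error at line %d: empty gene set", k),
           call. = FALSE)
    }
    nms[[k]] <- fields[[1]]
    sets[[k]] <- genes
  }
  names(sets) <- nms
  sets
}

#' Write a GMT gene-set collection
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set (GMT column 2).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  lines <- vapply(seq_along(gene_sets), function(k) {
    paste(c(names(gene_sets)[[k]], description, gene_sets[[k]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF-style mutation table
#'
#' Reads the minimal tab-delimited mutation-annotation format used for
#' tumor-mutation-burden scoring. Lines starting with `#` are skipped.
#' Only the three required columns are retained; any extra columns are
#' ignored.
#'
#' @param path Path to a tab-delimited file whose header contains
#'   `Hugo_Symbol`, `Variant_Classification` and `Tumor_Sample_Barcode`.
#' @return Data frame with columns `sample_id`, `gene_symbol`,
#'   `variant_classification`, in file order.
#' @export
read_maf <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   quote = "", stringsAsFactors = FALSE,
                   check.names = FALSE)
  required <- c("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L) {
    stop("MAF format error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(sample_id = as.character(df$Tumor_Sample_Barcode),
                    gene_symbol = as.character(df$Hugo_Symbol),
                    variant_classification = as.character(df$Variant_Classification),
                    stringsAsFactors = FALSE)
  bad <- !nzchar(out$sample_id) | !nzchar(out$gene_symbol) |
    !nzchar(out$variant_classification)
  if (any(bad)) {
    stop(sprintf("MAF format error: %d row(s) with empty required field",
                 sum(bad)), call. = FALSE)
  }
  out
}

#' Write a MAF-style mutation table
#' @param mutations Data frame as returned by [read_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(mutations, path) {
  df <- data.frame(Hugo_Symbol = mutations$gene_symbol,
                   Variant_Classification = mutations$variant_classification,
                   Tumor_Sample_Barcode = mutations$sample_id)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomic intervals (BED) or linkages (BEDPE)
#'
#' All interval I/O in this package uses the BED convention: 0-based,
#' half-open coordinates. BED requires at least 3 columns; name, score
#' and strand are taken from columns 4-6 when present. BEDPE requires at
#' least 6 columns; an optional 7th column gives the linkage count
#' (default 1). BEDPE anchors must lie on the same chromosome and are
#' normalized so the left anchor starts first.
#'
#' @param path Path to the file.
#' @param kind `"bed"` or `"bedpe"`.
#' @return For `"bed"` a data frame with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`; for `"bedpe"` a data frame with columns
#'   `chrom`, `start_a`, `end_a`, `start_b`, `end_b`, `count`.
#' @export
read_intervals <- function(path, kind = c("bed", "bedpe")) {
  kind <- match.arg(kind)
  if (kind == "bed") {
    df <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                     quote = "", stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("BED format error: fewer than 3 columns",
                            call. = FALSE)
    out <- data.frame(
      chrom = as.character(df[[1]]),
      start = check_coord(df[[2]]),
      end = check_coord(df[[3]]),
      name = if (ncol(df) >= 4L) as.character(df[[4]]) else ".",
      score = if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5]])) else NA_real_,
      strand = if (ncol(df) >= 6L) as.character(df[[6]]) else ".",
      stringsAsFactors = FALSE)
    if (any(out$start >= out$end)) {
      stop("BED format error: start >= end", call. = FALSE)
    }
    if (!all(out$strand %in% c("+", "-", "."))) {
      stop("BED format error: strand must be +, - or .", call. = FALSE)
    }
    out
  } else {
    # rows may or may not carry the optional count column: parse by line
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 6L)) {
      stop("BEDPE format error: fewer than 6 columns", call. = FALSE)
    }
    col <- function(k) vapply(fields, `[[`, "", k)
    cnt <- vapply(fields, function(f) if (length(f) >= 7L) f[[7]] else "1",
                  "")
    v <- suppressWarnings(as.numeric(cnt))
    if (anyNA(v) || any(v != round(v)) || any(v < 1)) {
      stop("BEDPE format error: count column must be a positive integer",
           call. = FALSE)
    }
    out <- data.frame(
      chrom = col(1),
      start_a = check_coord(col(2)), end_a = check_coord(col(3)),
      start_b = check_coord(col(5)), end_b = check_coord(col(6)),
      count = as.integer(v), stringsAsFactors = FALSE)
    if (!all(col(4) == out$chrom)) {
      stop("BEDPE format error: inter-chromosomal linkage", call. = FALSE)
    }
    if (any(out$start_a >= out$end_a) || any(out$start_b >= out$end_b)) {
      stop("BEDPE format error: start >= end", call. = FALSE)
    }
    swap <- out$start_b < out$start_a
    if (any(swap)) {
      tmp <- out[swap, c("start_a", "end_a")]
      out[swap, c("start_a", "end_a")] <- out[swap, c("start_b", "end_b")]
      out[swap, c("start_b", "end_b")] <- tmp
    }
    out
  }
}

check_coord <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v) || any(v != round(v))) {
    stop("format error: non-integer coordinate", call. = FALSE)
  }
  as.integer(v)
}

#' Write genomic intervals or linkages
#' @param x Data frame from [read_intervals()] (either kind).
#' @param path Output path.
#' @param kind `"bed"` or `"bedpe"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, kind = c("bed", "bedpe")) {
  kind <- match.arg(kind)
  if (kind == "bed") {
    df <- data.frame(x$chrom, x$start, x$end, x$name,
                     ifelse(is.na(x$score), 0, x$score), x$strand)
  } else {
    df <- data.frame(x$chrom, x$start_a, x$end_a,
                     x$chrom, x$start_b, x$end_b, x$count)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' symbols.
#'
#' @param path Path to the TSV.
#' @param scale `"log2"` or `"counts"`.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, scale = c("log2", "counts")) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  expression_matrix(m, match.arg(scale))
}

#' Write an expression matrix to TSV
#' @param x An [expression_matrix()] or genes x samples matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-cell counts matrix in MatrixMarket triple format
#'
#' Reads the conventional triple of files: an `.mtx` sparse matrix
#' (genes x cells), a gene file and a barcode file (one identifier per
#' line; first tab-separated field used).
#'
#' @param mtx_path,genes_path,barcodes_path Paths to the three files.
#' @return A dense counts-scale [expression_matrix()] (cells as samples).
#' @export
read_mtx_counts <- function(mtx_path, genes_path, barcodes_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- vapply(strsplit(readLines(genes_path), "\t"), `[[`, "", 1L)
  cells <- vapply(strsplit(readLines(barcodes_path), "\t"), `[[`, "", 1L)
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("MTX format error: dimensions do not match gene/barcode files",
         call. = FALSE)
  }
  dimnames(m) <- list(genes, cells)
  expression_matrix(m, "counts")
}
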