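# BED-convention data frame (0-based half-open) -> GRanges (1-based)
bed_to_granges <- function(df, window = 0L) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L - window,
                              end = df$end + window))
}

#' Call insulated-neighborhood boundaries
#'
#' A CTCF peak is called a boundary when at least `min_cohesin` of the
#' supplied cohesin subunit tracks (typically RAD21, STAG1, SMC1A) have
#' a peak overlapping it. Intervals are expanded by `window` bp on each
#' side before the overlap test (default 0: literal overlap). The
#' boundary's motif strand is taken from the unique CTCF motif
#' overlapping the peak; zero or multiple overlapping motifs give
#' `"unknown"`.
#'
#' @param ctcf_peaks BED-style data frame (`chrom`, `start`, `end`, ...).
#' @param cohesin_tracks Named list of BED-style data frames.
#' @param motif_intervals BED-style data frame with a `strand` column.
#' @param window Slack in bp added to each interval end before overlap.
#' @param min_cohesin Minimum number of supporting cohesin tracks
#'   (default 2).
#' @return Data frame with `chrom`, `start`, `end`, `motif_strand`,
#'   `n_cohesin`, `factors` (comma-separated supporting track names),
#'   one row per called boundary, in CTCF peak order.
#' @export
call_boundaries <- function(ctcf_peaks, cohesin_tracks, motif_intervals,
                            window = 0, min_cohesin = 2) {
  stopifnot(is.list(cohesin_tracks), !is.null(names(cohesin_tracks)))
  if (min_cohesin > length(cohesin_tracks)) {
    stop("min_cohesin exceeds the number of supplied cohesin tracks",
         call. = FALSE)
  }
  gr_ctcf <- bed_to_granges(ctcf_peaks, window = window)
  support <- vapply(cohesin_tracks, function(track) {
    GenomicRanges::countOverlaps(gr_ctcf, bed_to_granges(track,
                                                         window = window)) > 0L
  }, logical(nrow(ctcf_peaks)))
  support <- matrix(support, nrow = nrow(ctcf_peaks))
  n_cohesin <- rowSums(support)
  keep <- n_cohesin >= min_cohesin

  hits <- GenomicRanges::findOverlaps(gr_ctcf, bed_to_granges(motif_intervals))
  motif_strand <- rep("unknown", nrow(ctcf_peaks))
  n_motifs <- tabulate(S4Vectors::queryHits(hits), nrow(ctcf_peaks))
  unique_hit <- n_motifs == 1L
  first_hit <- S4Vectors::queryHits(hits)[!duplicated(S4Vectors::queryHits(hits))]
  first_sub <- S4Vectors::subjectHits(hits)[!duplicated(S4Vectors::queryHits(hits))]
  sel <- unique_hit[first_hit]
  motif_strand[first_hit[sel]] <-
    as.character(motif_intervals$strand[first_sub[sel]])
  motif_strand[!motif_strand %in% c("+", "-")] <- "unknown"

  factors <- apply(support, 1L, function(row) {
    paste(names(cohesin_tracks)[row], collapse = ",")
  })
  data.frame(chrom = ctcf_peaks$chrom[keep],
             start = ctcf_peaks$start[keep],
             end = ctcf_peaks$end[keep],
             motif_strand = motif_strand[keep],
             n_cohesin = n_cohesin[keep],
             factors = factors[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble chromatin loops from boundaries and linkages
#'
#' A linkage forms a loop when each of its two anchors overlaps a
#' distinct called boundary. If an anchor overlaps several boundaries,
#' the one with the largest overlap (ties: smaller start) is taken.
#' Linkage counts for the same boundary pair are summed. A loop is
#' `convergent` when the left boundary's motif strand is `"+"` and the
#' right one's `"-"`, and `strong` when the summed linkage count is at
#' least `min_linkages_strong` (default 4, i.e. the "> 3 linkages"
#' rule).
#'
#' @param boundaries Data frame from [call_boundaries()].
#' @param linkages BEDPE-style data frame (`chrom`, `start_a`, `end_a`,
#'   `start_b`, `end_b`, `count`).
#' @param min_linkages_strong Minimum summed count for a strong loop.
#' @return Data frame with the left/right boundary coordinates and
#'   strands, `linkage_count`, `convergent`, `strong`; one row per
#'   boundary pair, ordered by position.
#' @export
assemble_loops <- function(boundaries, linkages, min_linkages_strong = 4) {
  if (nrow(boundaries) == 0L || nrow(linkages) == 0L) {
    return(empty_loop_table())
  }
  gr_bnd <- bed_to_granges(boundaries)
  match_anchor <- function(starts, ends) {
    gr_anchor <- GenomicRanges::GRanges(
      seqnames = linkages$chrom,
      ranges = IRanges::IRanges(start = starts + 1L, end = ends))
    hits <- GenomicRanges::findOverlaps(gr_anchor, gr_bnd)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_anchor)[qh], IRanges::ranges(gr_bnd)[sh]))
    best <- rep(NA_integer_, nrow(linkages))
    if (length(qh) > 0L) {
      o <- order(qh, -ov, boundaries$start[sh])
      qh <- qh[o]; sh <- sh[o]
      first <- !duplicated(qh)
      best[qh[first]] <- sh[first]
    }
    best
  }
  ba <- match_anchor(linkages$start_a, linkages$end_a)
  bb <- match_anchor(linkages$start_b, linkages$end_b)
  ok <- !is.na(ba) & !is.na(bb) & ba != bb
  if (!any(ok)) return(empty_loop_table())
  left <- pmin(ba[ok], bb[ok])
  right <- pmax(ba[ok], bb[ok])
  key <- paste(left, right)
  counts <- tapply(linkages$count[ok], key, sum)
  left_i <- as.integer(vapply(strsplit(names(counts), " "), `[[`, "", 1L))
  right_i <- as.integer(vapply(strsplit(names(counts), " "), `[[`, "", 2L))
  out <- data.frame(
    chrom = boundaries$chrom[left_i],
    left_start = boundaries$start[left_i],
    left_end = boundaries$end[left_i],
    left_strand = boundaries$motif_strand[left_i],
    right_start = boundaries$start[right_i],
    right_end = boundaries$end[right_i],
    right_strand = boundaries$motif_strand[right_i],
    linkage_count = as.integer(counts),
    stringsAsFactors = FALSE, row.names = NULL)
  out$convergent <- out$left_strand == "+" & out$right_strand == "-"
  out$strong <- out$linkage_count >= min_linkages_strong
  out[order(out$chrom, out$left_start, out$right_start), , drop = FALSE]
}

empty_loop_table <- function() {
  data.frame(chrom = character(), left_start = integer(),
             left_end = integer(), left_strand = character(),
             right_start = integer(), right_end = integer(),
             right_strand = character(), linkage_count = integer(),
             convergent = logical(), strong = logical(),
             stringsAsFactors = FALSE)
}

#' Annotate peaks to nearest genes
#'
#' Assigns each peak to its nearest TSS on the same chromosome by signed
#' distance from the peak midpoint: positive distances are downstream of
#' transcription (for a "-" strand gene the sign flips). Equidistant
#' TSSs break ties by lexicographic gene id. The relation is `promoter`
#' when `|distance| <= promoter_bp`, `flank` when
#' `promoter_bp < |distance| <= flank_bp`, and `none` beyond that (or
#' when the chromosome has no TSS).
#'
#' @param peaks BED-style data frame; if a `summit` column is present it
#'   overrides the midpoint as the peak position.
#' @param tss_table Data frame with columns `chrom`, `pos` (TSS
#'   coordinate, bp), `gene_id`, `strand`.
#' @param promoter_bp Promoter half-window (default 3000).
#' @param flank_bp Flank limit (default 50000).
#' @return Data frame with one row per peak: peak coordinates,
#'   `gene_id`, `distance`, `relation`.
#' @export
annotate_peaks_to_genes <- function(peaks, tss_table, promoter_bp = 3000,
                                    flank_bp = 50000) {
  stopifnot(all(c("chrom", "pos", "gene_id", "strand") %in%
                  colnames(tss_table)))
  pos <- if ("summit" %in% colnames(peaks)) {
    peaks$summit
  } else {
    (peaks$start + peaks$end) / 2
  }
  n <- nrow(peaks)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  relation <- rep("none", n)
  for (i in seq_len(n)) {
    cand <- tss_table[tss_table$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- ifelse(cand$strand == "-", cand$pos - pos[i], pos[i] - cand$pos)
    o <- order(abs(d), cand$gene_id)
    best <- o[1L]
    gene_id[i] <- cand$gene_id[best]
    distance[i] <- d[best]
    ad <- abs(d[best])
    relation[i] <- if (ad <= promoter_bp) "promoter"
      else if (ad <= flank_bp) "flank" else "none"
  }
  data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
             gene_id = gene_id, distance = distance, relation = relation,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gain-of-function binding sites
#'
#' The subset of mutant-condition peaks with zero base-pair overlap with
#' any reference-condition peak, and the fraction of mutant peaks that
#' subset represents.
#'
#' @param mutant_peaks,reference_peaks BED-style data frames.
#' @return List with `sites` (the non-overlapping subset, same columns
#'   as `mutant_peaks`) and `fraction`.
#' @export
gain_of_function_sites <- function(mutant_peaks, reference_peaks) {
  if (nrow(mutant_peaks) == 0L) {
    stop("mutant peak set is empty", call. = FALSE)
  }
  if (nrow(reference_peaks) == 0L) {
    return(list(sites = mutant_peaks, fraction = 1))
  }
  ov <- GenomicRanges::countOverlaps(bed_to_granges(mutant_peaks),
                                     bed_to_granges(reference_peaks))
  sites <- mutant_peaks[ov == 0L, , drop = FALSE]
  list(sites = sites, fraction = nrow(sites) / nrow(mutant_peaks))
}
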