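bed_row <- function(chrom, start, end, strand = ".") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), name = ".", score = NA_real_,
             strand = strand, stringsAsFactors = FALSE)
}

test_that("boundary calling requires the cohesin co-occupancy quorum", {
  ctcf <- rbind(bed_row("chr17", 100, 200),   # 2 of 3 cohesin: boundary
                bed_row("chr17", 1000, 1100)) # no cohesin: not a boundary
  cohesin <- list(RAD21 = bed_row("chr17", 150, 250),
                  STAG1 = bed_row("chr17", 120, 180),
                  SMC1A = bed_row("chr17", 5000, 5100))
  motifs <- bed_row("chr17", 140, 160, "+")
  b <- call_boundaries(ctcf, cohesin, motifs)
  expect_identical(nrow(b), 1L)
  expect_identical(b$start, 100L)
  expect_identical(b$motif_strand, "+")
  expect_identical(b$n_cohesin, 2)
  expect_identical(b$factors, "RAD21,STAG1")

  # quorum of 3 excludes it
  b3 <- call_boundaries(ctcf, cohesin, motifs, min_cohesin = 3)
  expect_identical(nrow(b3), 0L)
  expect_error(call_boundaries(ctcf, cohesin, motifs, min_cohesin = 4),
               "min_cohesin")
})

test_that("motif strand is taken only from a unique overlapping motif", {
  ctcf <- bed_row("chr1", 100, 200)
  cohesin <- list(RAD21 = bed_row("chr1", 100, 200),
                  STAG1 = bed_row("chr1", 100, 200))
  none <- call_boundaries(ctcf, cohesin, bed_row("chr1", 900, 950, "+"))
  expect_identical(none$motif_strand, "unknown")
  two <- call_boundaries(ctcf, cohesin,
                         rbind(bed_row("chr1", 110, 130, "+"),
                               bed_row("chr1", 150, 170, "-")))
  expect_identical(two$motif_strand, "unknown")
})

test_that("window expansion and overlap agree with the quadratic oracle", {
  set.seed(71)
  for (rep in 1:3) {
    n <- 300
    ctcf <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                       start = sample.int(100000, n),
                       stringsAsFactors = FALSE)
    ctcf$end <- ctcf$start + sample.int(500, n)
    ctcf$name <- "."; ctcf$score <- NA_real_; ctcf$strand <- "."
    track <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                        start = sample.int(100000, n),
                        stringsAsFactors = FALSE)
    track$end <- track$start + sample.int(500, n)
    track$name <- "."; track$score <- NA_real_; track$strand <- "."
    for (window in c(0, 100)) {
      called <- call_boundaries(ctcf, list(T1 = track),
                                bed_row("chr1", 99999000, 99999100, "+"),
                                window = window, min_cohesin = 1)
      oracle_hit <- oracle_any_overlap(ctcf, track, window = window)
      expect_identical(paste(called$chrom, called$start),
                       paste(ctcf$chrom[oracle_hit], ctcf$start[oracle_hit]))
    }
  }
})

test_that("loops require two distinct boundary anchors and sum linkage counts", {
  boundaries <- data.frame(chrom = "chr1",
                           start = c(100L, 5000L, 9000L),
                           end = c(300L, 5200L, 9200L),
                           motif_strand = c("+", "-", "+"),
                           n_cohesin = 3, factors = "RAD21,STAG1,SMC1A",
                           stringsAsFactors = FALSE)
  linkages <- data.frame(chrom = "chr1",
                         start_a = c(120L, 150L, 130L, 700L),
                         end_a = c(250L, 280L, 260L, 800L),
                         start_b = c(5050L, 5100L, 9050L, 950L),
                         end_b = c(5150L, 5180L, 9150L, 1000L),
                         count = c(2L, 2L, 3L, 9L),
                         stringsAsFactors = FALSE)
  loops <- assemble_loops(boundaries, linkages)
  # linkage 4 has both anchors off any boundary except anchor_b near none:
  # rows 1-2 join boundaries 1-2 (counts summed 2+2), row 3 joins 1-3
  expect_identical(nrow(loops), 2L)
  l12 <- loops[loops$right_start == 5000L, ]
  expect_identical(l12$linkage_count, 4L)
  expect_true(l12$convergent)     # "+" then "-"
  expect_true(l12$strong)         # 4 linkages: > 3
  l13 <- loops[loops$right_start == 9000L, ]
  expect_identical(l13$linkage_count, 3L)
  expect_false(l13$strong)        # exactly 3 is not "> 3"
  expect_false(l13$convergent)    # "+" then "+"
})

test_that("left-minus/right-plus boundary pairs are never convergent", {
  boundaries <- data.frame(chrom = "chr1", start = c(100L, 5000L),
                           end = c(300L, 5200L),
                           motif_strand = c("-", "+"),
                           n_cohesin = 2, factors = "RAD21,STAG1",
                           stringsAsFactors = FALSE)
  linkages <- data.frame(chrom = "chr1", start_a = 150L, end_a = 250L,
                         start_b = 5050L, end_b = 5150L, count = 10L,
                         stringsAsFactors = FALSE)
  loops <- assemble_loops(boundaries, linkages)
  expect_false(loops$convergent)
  expect_true(loops$strong)
})

test_that("planted chromatin configurations are recovered exactly", {
  cfg <- simulation_config(seed = 12)
  tracks <- simulate_chromatin_tracks(cfg)
  b <- call_boundaries(tracks$ctcf, tracks$cohesin, tracks$motifs)
  truth_b <- tracks$truth$boundaries
  # precision and recall 1.0 on boundaries
  expect_identical(paste(b$chrom, b$start, b$end),
                   paste(truth_b$chrom, truth_b$start, truth_b$end))
  expect_identical(b$motif_strand, tracks$truth$boundary_strands)
  loops <- assemble_loops(b, tracks$linkages)
  truth_l <- tracks$truth$loops
  key <- function(d, l, r) paste(d[[l]], d[[r]])
  o <- match(key(truth_l, "left_start", "right_start"),
             key(loops, "left_start", "right_start"))
  expect_false(anyNA(o))
  expect_identical(nrow(loops), nrow(truth_l))
  expect_identical(loops$linkage_count[o], truth_l$count)
  expect_identical(loops$convergent[o], truth_l$convergent)
  expect_identical(loops$strong[o], truth_l$strong)
})

test_that("peak annotation applies the promoter and flank windows", {
  tss <- data.frame(chrom = "chr1", pos = 10000L, gene_id = "KRT14",
                    strand = "+", stringsAsFactors = FALSE)
  peak_at <- function(mid) bed_row("chr1", mid - 50, mid + 50)
  ann <- annotate_peaks_to_genes(peak_at(12000), tss)
  expect_identical(ann$relation, "promoter")
  expect_equal(ann$distance, 2000)
  expect_identical(annotate_peaks_to_genes(peak_at(55000), tss)$relation,
                   "flank")
  expect_identical(annotate_peaks_to_genes(peak_at(70001), tss)$relation,
                   "none")
  # boundary cases: exactly 3000 is promoter, exactly 50000 is flank
  expect_identical(annotate_peaks_to_genes(peak_at(13000), tss)$relation,
                   "promoter")
  expect_identical(annotate_peaks_to_genes(peak_at(60000), tss)$relation,
                   "flank")
  # strand-aware sign: midpoint downstream of a "-" TSS has negative offset
  tss_minus <- transform(tss, strand = "-")
  ann_m <- annotate_peaks_to_genes(peak_at(12000), tss_minus)
  expect_equal(ann_m$distance, -2000)
  # nearest TSS wins; equidistant ties break lexicographically
  tss2 <- rbind(tss,
                data.frame(chrom = "chr1", pos = 14000L, gene_id = "AAA",
                           strand = "+"))
  expect_identical(annotate_peaks_to_genes(peak_at(12000), tss2)$gene_id,
                   "AAA")
  # summit column overrides the midpoint
  pk <- peak_at(70001); pk$summit <- 10100
  expect_identical(annotate_peaks_to_genes(pk, tss)$relation, "promoter")
})

test_that("gain-of-function sites are mutant peaks with zero reference overlap", {
  mutant <- rbind(bed_row("chr1", 100, 200), bed_row("chr1", 1000, 1100),
                  bed_row("chr2", 50, 150))
  reference <- bed_row("chr1", 150, 250)
  res <- gain_of_function_sites(mutant, reference)
  expect_identical(nrow(res$sites), 2L)
  expect_equal(res$fraction, 2 / 3)
  full <- gain_of_function_sites(mutant, mutant)
  expect_equal(full$fraction, 0)
  expect_error(gain_of_function_sites(mutant[0, ], reference), "empty")

  set.seed(81)
  a <- data.frame(chrom = "chr3", start = sample.int(5000, 100),
                  stringsAsFactors = FALSE)
  a$end <- a$start + sample.int(100, 100)
  a$name <- "."; a$score <- NA_real_; a$strand <- "."
  b <- data.frame(chrom = "chr3", start = sample.int(5000, 100),
                  stringsAsFactors = FALSE)
  b$end <- b$start + sample.int(100, 100)
  b$name <- "."; b$score <- NA_real_; b$strand <- "."
  res2 <- gain_of_function_sites(a, b)
  expect_equal(res2$fraction, mean(!oracle_any_overlap(a, b)))
})
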