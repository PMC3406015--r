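# Transcript assembly, filtering, genic context, locus clustering,
# promoters, antisense rules and bidirectional detection.

test_that("transfrag assembly merges by gap and separates strands", {
  reads <- tibble::tibble(chrom = "chr1", start = c(100L, 150L),
                          end = c(200L, 260L), strand = "+")
  tf <- assemble_transfrags(reads, min_gap = 50, min_length = 100)
  expect_identical(nrow(tf), 1L)
  expect_identical(c(tf$start, tf$end), c(100L, 260L))
  reads2 <- dplyr::mutate(reads, strand = c("+", "-"))
  tf2 <- assemble_transfrags(reads2, min_gap = 50, min_length = 50)
  expect_identical(nrow(tf2), 2L)
  expect_error(assemble_transfrags(reads, min_gap = -1), "non-negative")
})

test_that("assembly equals the brute-force union oracle on random reads", {
  set.seed(9)
  reads <- random_intervals(1000, chrom_len = 50000, max_len = 120)
  tf <- assemble_transfrags(reads, min_gap = 30, min_length = 1)
  oracle <- oracle_merge(as.data.frame(reads), min_gap = 30)
  expect_identical(nrow(tf), nrow(oracle))
  expect_identical(tf$start, as.integer(oracle$start))
  expect_identical(tf$end, as.integer(oracle$end))
  expect_identical(tf$strand, oracle$strand)
})

test_that("TSS support filter enforces length and peak-at-TSS rules", {
  tx <- tibble::tibble(
    transcript_id = c("short", "no_peak", "boundary"),
    chrom = "chr1",
    start = c(1000L, 3000L, 5000L),
    end = c(1150L, 3500L, 5200L),
    strand = "+")
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(990L, 4990L), end = c(1010L, 5010L))
  kept <- tss_supported_transcripts(tx, peaks, min_length = 200)
  # 150 nt transcript removed despite peak; 500 nt without peak removed;
  # exactly 200 nt with peak containing the TSS retained
  expect_identical(kept$transcript_id, "boundary")
  expect_identical(nrow(tss_supported_transcripts(tx[0, ], peaks)), 0L)
})

test_that("genic context uses >= 1 bp span overlap, strand-agnostic", {
  tx <- tibble::tibble(transcript_id = c("t1", "t2"), chrom = "chr1",
                       start = c(100L, 100L), end = c(300L, 300L),
                       strand = c("+", "+"))
  genes1 <- tibble::tibble(gene_id = "g", chrom = "chr1",
                           start = 299L, end = 500L)
  genes2 <- tibble::tibble(gene_id = "g", chrom = "chr1",
                           start = 300L, end = 500L)
  expect_identical(classify_genic_context(tx[1, ], genes1)$context,
                   "intragenic")
  expect_identical(classify_genic_context(tx[1, ], genes2)$context,
                   "intergenic")
})

test_that("genic context matches a brute-force overlap scan", {
  set.seed(4)
  tx <- random_intervals(500, chrom_len = 100000, max_len = 2000)
  tx$transcript_id <- sprintf("t%03d", 1:500)
  genes <- random_intervals(40, chrom_len = 100000, max_len = 5000,
                            stranded = FALSE)
  genes$gene_id <- sprintf("g%02d", 1:40)
  ctx <- classify_genic_context(tx, genes)
  spans <- transcript_spans(tx)
  expected <- ifelse(oracle_overlaps_any(as.data.frame(spans),
                                         as.data.frame(genes)),
                     "intragenic", "intergenic")
  expect_identical(ctx$context[match(spans$transcript_id,
                                     ctx$transcript_id)], expected)
})

test_that("locus clustering merges on span overlap and classifies members", {
  # two transcripts sharing only intronic bases: spans overlap
  tx <- tibble::tibble(
    transcript_id = c("a", "a", "b", "c"),
    chrom = "chr1",
    start = c(100L, 900L, 450L, 5000L),
    end = c(200L, 1000L, 550L, 5300L),
    strand = c("+", "+", "-", "+"))
  classes <- tibble::tibble(transcript_id = c("a", "b", "c"),
                            context = "intergenic", label = "noncoding")
  loci <- cluster_loci(tx, classes)
  expect_identical(nrow(loci), 2L)
  expect_setequal(loci$members[[which(loci$start == 100L)]], c("a", "b"))
  expect_true(all(loci$locus_class == "intergenic_lncRNA"))
  # mixed locus is not an intergenic lncRNA locus
  classes2 <- dplyr::mutate(classes,
                            label = c("noncoding", "coding", "noncoding"))
  loci2 <- cluster_loci(tx, classes2)
  expect_identical(loci2$locus_class[loci2$start == 100L], "protein_coding")
})

test_that("locus clustering is a partition (random instances)", {
  set.seed(12)
  for (rep in 1:10) {
    tx <- random_intervals(60, chrom_len = 30000, max_len = 1500)
    tx$transcript_id <- sprintf("t%02d", 1:60)
    classes <- tibble::tibble(transcript_id = tx$transcript_id,
                              context = "intergenic", label = "noncoding")
    loci <- cluster_loci(tx, classes)
    # every transcript in exactly one locus
    members <- unlist(loci$members)
    expect_setequal(members, tx$transcript_id)
    expect_identical(anyDuplicated(members), 0L)
    # envelopes pairwise non-overlapping
    loci <- dplyr::arrange(loci, .data$start)
    if (nrow(loci) > 1) {
      expect_true(all(loci$start[-1] >= loci$end[-nrow(loci)]))
    }
  }
})

test_that("promoters are 400 bp upstream, strand-aware, edge-truncated", {
  tx <- tibble::tibble(transcript_id = c("p", "m", "edge"),
                       chrom = "chr1",
                       start = c(1000L, 500L, 100L),
                       end = c(2000L, 1001L, 400L),
                       strand = c("+", "-", "+"))
  pr <- define_promoter(tx, promoter_bp = 400)
  expect_identical(pr$start[pr$transcript_id == "p"], 600L)
  expect_identical(pr$end[pr$transcript_id == "p"], 1000L)
  expect_identical(pr$start[pr$transcript_id == "m"], 1001L)
  expect_identical(pr$end[pr$transcript_id == "m"], 1401L)
  e <- pr[pr$transcript_id == "edge", ]
  expect_identical(c(e$start, e$end), c(0L, 100L))
  expect_true(e$truncated)
  # TSS at 0 on + strand: empty, flagged
  tx0 <- tibble::tibble(transcript_id = "zero", chrom = "chr1",
                        start = 0L, end = 300L, strand = "+")
  p0 <- define_promoter(tx0)
  expect_true(p0$empty && p0$truncated)
})

test_that("antisense rules remove transcripts in order with reasons", {
  genes <- tibble::tibble(gene_id = "host", chrom = "chr1",
                          start = 1000L, end = 5000L, strand = "+")
  # host TSS at 1000; shared peak covers both host TSS and antisense TSS
  tx <- tibble::tibble(
    transcript_id = c("own_peak", "shared_peak", "no_peak", "coding_like"),
    chrom = "chr1",
    start = c(2000L, 1000L, 3000L, 1500L),
    end = c(3000L, 1200L, 4000L, 2500L),
    strand = c("-", "-", "-", "+"))
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(2950L, 950L), end = c(3050L, 1250L))
  calls <- identify_antisense(tx, genes, peaks)
  reason <- function(id) calls$removal_reason[calls$transcript_id == id]
  expect_identical(reason("own_peak"), "none")
  expect_identical(reason("shared_peak"), "no_independent_peak")
  expect_identical(reason("no_peak"), "no_5prime_peak")
  # same-strand overlap with the annotated gene: not an antisense call
  expect_false("coding_like" %in% calls$transcript_id)
  # manual artifact list
  calls2 <- identify_antisense(tx, genes, peaks,
                               artifact_ids = "own_peak")
  expect_identical(calls2$removal_reason[calls2$transcript_id == "own_peak"],
                   "flagged_artifact")
})

test_that("bidirectional detection finds opposite-strand upstream reads", {
  genes <- tibble::tibble(gene_id = c("gp", "gm"), chrom = "chr1",
                          start = c(10000L, 30000L),
                          end = c(12000L, 32000L),
                          strand = c("+", "-"))
  reads <- tibble::tibble(
    chrom = "chr1",
    start = c(9400L, 4900L, 32200L),
    end = c(9450L, 4950L, 32250L),
    strand = c("-", "-", "+"))
  hits <- detect_bidirectional(genes, reads, window = 1000)
  # 500 bp upstream divergent read reported; 5 kb upstream is not;
  # minus-strand gene mirrored
  expect_setequal(hits$gene_id, c("gp", "gm"))
  hits2 <- detect_bidirectional(genes, reads[2, ], window = 1000)
  expect_identical(nrow(hits2), 0L)
})

test_that("bidirectional detection matches a brute-force window scan", {
  set.seed(21)
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                          start = as.integer(seq(5000, 100000, by = 5000)),
                          end = as.integer(seq(5000, 100000, by = 5000)) + 2000L,
                          strand = sample(c("+", "-"), 20, TRUE))
  reads <- random_intervals(400, chrom_len = 110000, max_len = 60)
  hits <- detect_bidirectional(genes, reads, window = 1000)
  expected <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tss <- if (g$strand == "+") g$start else g$end - 1L
    found <- FALSE
    for (j in seq_len(nrow(reads))) {
      r <- reads[j, ]
      if (r$strand == g$strand) next
      five <- if (r$strand == "+") r$start else r$end - 1L
      if (g$strand == "+" && r$strand == "-" &&
          five < tss && five >= tss - 1000) found <- TRUE
      if (g$strand == "-" && r$strand == "+" &&
          five > tss && five <= tss + 1000) found <- TRUE
    }
    if (found) expected <- c(expected, g$gene_id)
  }
  expect_setequal(hits$gene_id, expected)
})

test_that("filtering is monotone in the peak set", {
  set.seed(30)
  tx <- random_intervals(50, chrom_len = 50000, max_len = 1000)
  tx$end <- tx$start + pmax(250L, tx$end - tx$start)  # all long enough
  tx$transcript_id <- sprintf("t%02d", 1:50)
  peaks1 <- random_intervals(10, chrom_len = 50000, max_len = 400,
                             stranded = FALSE)
  peaks2 <- dplyr::bind_rows(peaks1,
                             random_intervals(10, chrom_len = 50000,
                                              max_len = 400,
                                              stranded = FALSE))
  kept1 <- tss_supported_transcripts(tx, peaks1)
  kept2 <- tss_supported_transcripts(tx, peaks2)
  expect_true(all(kept1$transcript_id %in% kept2$transcript_id))
})
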