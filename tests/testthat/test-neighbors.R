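# Neighbour pairing, orientation, territories, permutation enrichment
# and shift tests.

test_that("gene A is the nearest gene and paralogous B is replaced", {
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                          start = c(1000L, 20000L, 40000L),
                          end = c(3000L, 22000L, 42000L),
                          strand = "+")
  lnc <- tibble::tibble(locus_id = "L", chrom = "chr1", start = 5000L,
                        end = 6000L, strand = "+")
  p <- neighbor_pairs(lnc, genes)
  expect_identical(p$gene_a, "g1")
  expect_identical(p$gene_b, "g2")
  expect_identical(p$reason, "ok")
  # g2 is a paralog of g1: next qualifying gene becomes B
  p2 <- neighbor_pairs(lnc, genes,
                       paralogs = tibble::tibble(gene1 = "g1",
                                                 gene2 = "g2"))
  expect_identical(p2$gene_b, "g3")
  # missing one-to-one ortholog drops the pair with a reason
  p3 <- neighbor_pairs(lnc, genes, orthologs = c("g2", "g3"))
  expect_identical(p3$reason, "no_ortholog_a")
  # single-gene chromosome: incomplete
  p4 <- neighbor_pairs(lnc, genes[1, ])
  expect_identical(p4$reason, "incomplete")
})

test_that("nearest/next-gene selection matches a brute-force scan", {
  set.seed(61)
  for (rep in 1:20) {
    n_g <- 15
    gs <- sort(sample.int(200000, n_g))
    genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:n_g),
                            chrom = "chr1", start = gs, end = gs + 500L,
                            strand = sample(c("+", "-"), n_g, TRUE))
    lnc_s <- sample.int(200000, 1)
    lnc <- tibble::tibble(locus_id = "L", chrom = "chr1", start = lnc_s,
                          end = lnc_s + 300L, strand = "+")
    p <- neighbor_pairs(lnc, genes)
    d <- pmax(0, pmax(genes$start - lnc$end, lnc$start - genes$end))
    ord <- order(d)
    expect_identical(p$gene_a, genes$gene_id[ord[1]])
    expect_identical(p$gene_b, genes$gene_id[ord[2]])
  }
})

test_that("orientation classes follow strand geometry", {
  expect_identical(orientation_class(100, "+", 500, "+"), "tandem")
  # minus element left of plus element: transcribing apart
  expect_identical(orientation_class(100, "-", 500, "+"), "divergent")
  # plus element left of minus element: transcribing toward each other
  expect_identical(orientation_class(100, "+", 500, "-"), "convergent")
  expect_identical(orientation_class(500, "-", 100, "+"), "convergent")
  expect_error(orientation_class(1, ".", 2, "+"), "stranded")
})

test_that("territories tile the chromosome at envelope midpoints", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          start = c(0L, 900L), end = c(100L, 1000L))
  t <- gene_territories(genes, c(chr1 = 1000L))
  expect_identical(t$end[t$gene_id == "a"], 500L)
  expect_identical(t$start[t$gene_id == "b"], 500L)
  t1 <- gene_territories(genes[1, ], c(chr1 = 1000L))
  expect_identical(c(t1$start, t1$end), c(0L, 1000L))
})

test_that("territory assignment matches the per-base nearest gene", {
  set.seed(71)
  for (rep in 1:10) {
    n_g <- 6
    gs <- sort(sample(seq(0L, 4500L, by = 500L), n_g))
    genes <- tibble::tibble(gene_id = sprintf("g%d", 1:n_g), chrom = "chr1",
                            start = gs, end = gs + 200L)
    terr <- gene_territories(genes, c(chr1 = 5000L))
    # partition: disjoint cover of [0, 5000)
    terr <- dplyr::arrange(terr, .data$start)
    expect_identical(terr$start, c(0L, terr$end[-nrow(terr)]))
    expect_identical(terr$end[nrow(terr)], 5000L)
    # each base belongs to its nearest gene (ties go either side)
    for (b in sample(0:4999, 200)) {
      d <- pmax(0, pmax(genes$start - b - 1L, b - genes$end))
      nearest <- genes$gene_id[which.min(d)]
      assigned <- terr$gene_id[terr$start <= b & terr$end > b]
      dmin <- min(d)
      d_assigned <- d[match(assigned, genes$gene_id)]
      expect_lte(d_assigned, dmin + 1L)
    }
  }
})

test_that("enrichment over the whole workspace is null by construction", {
  en <- simulate_enrichment_scenario(n_windows = 40, n_segments = 20,
                                     seed = 2)
  er <- permutation_enrichment(en$segments, en$workspace, en$workspace,
                               n_perms = 99, seed = 3)
  expect_equal(er$fold, 1)
  expect_equal(er$p_value, 1)
})

test_that("tiny-instance empirical p matches exhaustive enumeration", {
  workspace <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  annotation <- tibble::tibble(chrom = "chr1", start = 40L, end = 60L)
  segment <- tibble::tibble(chrom = "chr1", start = 45L, end = 55L)
  obs <- 10  # fully inside the annotation
  # exact null: uniform over start positions 0..90
  overlaps <- vapply(0:90, function(s) {
    max(0, min(s + 10, 60) - max(s, 40))
  }, numeric(1))
  p_exact <- mean(overlaps >= obs)
  er <- permutation_enrichment(segment, annotation, workspace,
                               n_perms = 4999, seed = 11)
  se <- sqrt(p_exact * (1 - p_exact) / 4999)
  expect_lt(abs(er$p_value - p_exact), 4 * se + 1 / 5000)
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(81)
  # segments drawn by the same uniform law the permutation uses
  starts <- (0:29) * 3000L
  workspace <- tibble::tibble(chrom = "chr1", start = starts,
                              end = starts + 2000L)
  pvals <- vapply(1:200, function(i) {
    ann <- workspace[sample.int(30, 12), ]
    win <- sample.int(30, 8, replace = TRUE)
    seg_start <- workspace$start[win] +
      floor(runif(8) * (2000 - 200))
    segments <- tibble::tibble(chrom = "chr1",
                               start = as.integer(seg_start),
                               end = as.integer(seg_start + 200L))
    permutation_enrichment(segments, ann, workspace,
                           n_perms = 99)$p_enrichment
  }, numeric(1))
  # one-sided KS against uniform: reject only clear anti-conservatism
  ks <- suppressWarnings(ks.test(pvals, "punif",
                                 alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("GC-matched placement stays within the origin decile", {
  set.seed(91)
  ws <- tibble::tibble(chrom = "chr1",
                       start = seq(0L, 19000L, by = 1000L),
                       end = seq(0L, 19000L, by = 1000L) + 800L,
                       gc = rep(c(0.3, 0.6), each = 10))
  seg <- tibble::tibble(chrom = "chr1", start = 100L, end = 300L)
  # annotation = the high-GC half; the segment originates in low GC
  ann <- ws[11:20, 1:3]
  er <- permutation_enrichment(seg, ann, ws, n_perms = 99, seed = 5,
                               match_gc = TRUE)
  expect_identical(er$expected_mean, 0)
})

test_that("shift tests report medians, p-values and power notes", {
  set.seed(55)
  baseline <- rnorm(200, 0, 0.3)
  fv <- tibble::tibble(
    group = rep(c("up", "null", "tiny"), c(100, 100, 3)),
    value = c(rnorm(100, 0.25, 0.3), rnorm(100, 0, 0.3), rnorm(3)))
  res <- expression_shift_test(fv, baseline)
  expect_lt(res$p_value[res$group == "up"], 0.05)
  expect_gt(res$p_value[res$group == "null"], 0.05)
  expect_true(is.na(res$p_value[res$group == "tiny"]))
  # all-zero fold differences: medians zero, no significance
  fv0 <- tibble::tibble(group = "g", value = rep(0, 50))
  res0 <- expression_shift_test(fv0, rep(0, 50))
  expect_identical(res0$median, 0)
})

test_that("distance correlation handles perfect, null and degenerate input", {
  d <- 10^seq(3, 5, length.out = 20)
  perfect <- distance_correlation(d, log10(d))
  expect_equal(perfect$r, 1)
  flat <- distance_correlation(d, rep(0.2, 20))
  expect_true(flat$flagged)
  set.seed(3)
  nulls <- vapply(1:50, function(i) {
    dd <- 10^runif(137, 3, 6)
    abs(distance_correlation(dd, rnorm(137, 0.22, 0.3))$r)
  }, numeric(1))
  expect_gt(mean(nulls < 0.15), 0.9)
})
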