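# Projection, evidence, category classification, exon coverage and
# contingency statistics.

simple_map <- function() {
  tibble::tibble(src_chrom = "chr1", src_start = c(0L, 5000L),
                 src_end = c(4000L, 9000L), tgt_chrom = "chrA",
                 tgt_start = c(1000L, 20000L),
                 orientation = c("same", "flipped"))
}

test_that("projection shifts, drops and flips intervals correctly", {
  map <- simple_map()
  # fully inside a same-orientation block: shifted by the offset
  p <- project_interval(tibble::tibble(chrom = "chr1", start = 100L,
                                       end = 200L, strand = "+"), map)
  expect_identical(p$start, 1100L)
  expect_identical(p$end, 1200L)
  expect_identical(p$strand, "+")
  # entirely between blocks: none
  p2 <- project_interval(tibble::tibble(chrom = "chr1", start = 4200L,
                                        end = 4800L), map)
  expect_identical(nrow(p2), 0L)
  # malformed map rejected
  bad <- dplyr::mutate(map, src_start = c(0L, 3000L))
  expect_error(project_interval(p, bad), "overlapping source blocks")
})

test_that("straddling a flipped block matches the per-base oracle", {
  set.seed(17)
  map <- simple_map()
  for (i in 1:50) {
    start <- sample.int(9500, 1) - 1L
    end <- start + sample.int(1500, 1)
    p <- project_interval(tibble::tibble(chrom = "chr1",
                                         start = start, end = end), map)
    oracle <- oracle_project_bases("chr1", start, end, map)
    got <- if (nrow(p) == 0) integer(0) else
      sort(unlist(purrr::map2(p$start, p$end - 1L, `:`)))
    expect_setequal(got, oracle$tgt[!is.na(oracle$tgt)])
  }
})

test_that("projection inverts through the reversed map", {
  map <- simple_map()
  iv <- tibble::tibble(chrom = "chr1", start = 3500L, end = 6000L,
                       strand = "-")
  fwd <- project_interval(iv, map)
  back <- project_interval(fwd, invert_orthology_map(map))
  # covered source bases recovered exactly
  src_bases <- sort(unlist(purrr::map2(back$start, back$end - 1L, `:`)))
  cov <- oracle_project_bases("chr1", 3500L, 6000L, map)
  expect_setequal(src_bases, cov$src[!is.na(cov$tgt)])
  expect_true(all(back$strand == "-"))
})

test_that("expression evidence applies the strict conjunction", {
  region <- tibble::tibble(chrom = "chr1", start = 1000L, end = 2000L,
                           strand = "+")
  peaks <- tibble::tibble(chrom = "chr1", start = 995L, end = 1005L)
  reads_plus <- tibble::tibble(chrom = "chr1", start = 1500L, end = 1550L,
                               strand = "+")
  reads_minus <- dplyr::mutate(reads_plus, strand = "-")
  # peak but no reads: not expressed under strict
  ev <- expression_evidence_at(region, peaks, reads_plus[0, ], "strict")
  expect_false(ev$expressed)
  # reads_only ignores missing peaks
  ev2 <- expression_evidence_at(region, peaks[0, ], reads_plus,
                                "reads_only")
  expect_true(ev2$expressed)
  # 1 bp peak overlap + 1 matching read: expressed under strict
  peaks1 <- tibble::tibble(chrom = "chr1", start = 900L, end = 1001L)
  ev3 <- expression_evidence_at(region, peaks1, reads_plus, "strict")
  expect_true(ev3$expressed)
  # read evidence is strand-aware
  ev4 <- expression_evidence_at(region, peaks, reads_minus, "strict")
  expect_false(ev4$expressed)
})

test_that("conservation categories follow the three-species truth table", {
  ev <- function(f, s, o, orth = TRUE) {
    tibble::tibble(locus_id = "L", species = c("focal", "sister", "outgroup"),
                   has_ortholog = c(TRUE, TRUE, orth),
                   expressed = c(f, s, o))
  }
  cat_of <- function(e) classify_conservation(e)$category
  expect_identical(cat_of(ev(TRUE, TRUE, TRUE)), "I")
  expect_identical(cat_of(ev(TRUE, TRUE, FALSE)), "II")
  expect_identical(cat_of(ev(TRUE, FALSE, FALSE)), "III")
  expect_identical(cat_of(ev(FALSE, TRUE, FALSE)), "IV")
  expect_identical(cat_of(ev(FALSE, FALSE, TRUE)), "V")
  expect_identical(cat_of(ev(TRUE, FALSE, FALSE, orth = FALSE)),
                   "excluded_no_ortholog")
  expect_error(classify_conservation(ev(FALSE, FALSE, FALSE)),
               "no expression evidence")
})

test_that("exon coverage fraction counts projected covered bases", {
  map <- tibble::tibble(src_chrom = "chr1", src_start = 0L,
                        src_end = 10000L, tgt_chrom = "chrA",
                        tgt_start = 0L, orientation = "same")
  exons <- tibble::tibble(chrom = "chr1", start = c(100L, 500L),
                          end = c(200L, 600L), strand = "+")
  full <- tibble::tibble(chrom = "chrA", start = c(100L, 500L),
                         end = c(200L, 600L), strand = "+")
  expect_equal(exon_coverage_fraction(exons, full, map)$fraction, 1)
  expect_equal(exon_coverage_fraction(exons, full[0, ], map)$fraction, 0)
  # random reads vs a per-base counting oracle
  set.seed(23)
  reads <- random_intervals(60, chrom_len = 1000, max_len = 40)
  reads <- dplyr::mutate(reads, chrom = "chrA", strand = "+")
  got <- exon_coverage_fraction(exons, reads, map)$fraction
  bases <- c(100:199, 500:599)
  covered <- vapply(bases, function(b) {
    any(reads$start <= b & reads$end > b)
  }, logical(1))
  expect_equal(got, mean(covered))
  # unprojectable exons: NA and flagged
  no_map <- dplyr::mutate(map, src_end = 50L)
  res <- exon_coverage_fraction(exons, reads, no_map)
  expect_true(is.na(res$fraction) && res$flagged)
})

test_that("Fisher contingency matches hypergeometric enumeration", {
  t1 <- turnover_contingency(rep(c("I", "other"), c(1326, 1089)),
                             rep(c("I", "other"), c(31, 79)), "I")
  expect_equal(t1$p_value, oracle_fisher_two_tailed(t1$table),
               tolerance = 1e-10)
  # identical proportions: p = 1
  t2 <- turnover_contingency(rep(c("I", "x"), c(50, 50)),
                             rep(c("I", "x"), c(50, 50)), "I")
  expect_equal(t2$p_value, 1)
  expect_error(turnover_contingency(character(0), "I", "I"), "empty")
  g <- glance(t1)
  expect_equal(g$prop_group1, 1326 / 2415)
})
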