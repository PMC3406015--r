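# Constitutive exons, length adjustment, TMM, FPKM and oriented fold
# differences.

test_that("constitutive exons are the per-gene transcript intersection", {
  # single transcript: all exons; two transcripts sharing one exon
  gm <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2", "g2"),
    transcript_id = c("g1t1", "g1t1", "g2t1", "g2t1", "g2t2"),
    chrom = "chr1",
    start = c(100L, 500L, 1000L, 2000L, 2000L),
    end = c(200L, 600L, 1200L, 2300L, 2300L),
    strand = "+")
  ce <- constitutive_exons(gm)
  expect_identical(nrow(ce[ce$gene_id == "g1", ]), 2L)
  g2 <- ce[ce$gene_id == "g2", ]
  expect_identical(c(g2$start, g2$end), c(2000L, 2300L))
})

test_that("constitutive exons match a per-base intersection oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n_tx <- sample(2:4, 1)
    exon_rows <- purrr::map_dfr(seq_len(n_tx), function(t) {
      n_ex <- sample(1:3, 1)
      iv <- random_intervals(n_ex, chrom_len = 2000, max_len = 400,
                             stranded = FALSE)
      iv <- oracle_merge(dplyr::mutate(as.data.frame(iv), strand = "+"), -1)
      tibble::tibble(gene_id = "g", transcript_id = paste0("t", t),
                     chrom = "chr1", start = as.integer(iv$start),
                     end = as.integer(iv$end), strand = "+")
    })
    per_base <- vapply(0:1999, function(b) {
      all(vapply(split(exon_rows, exon_rows$transcript_id), function(tx) {
        any(tx$start <= b & tx$end > b)
      }, logical(1)))
    }, logical(1))
    if (!any(per_base)) {
      expect_warning(ce <- constitutive_exons(exon_rows), "dropped")
      expect_identical(nrow(ce), 0L)
    } else {
      ce <- constitutive_exons(exon_rows)
      got <- unlist(purrr::map2(ce$start, ce$end - 1L, `:`))
      expect_setequal(got, which(per_base) - 1L)
    }
  }
})

test_that("length adjustment scales counts to the focal feature length", {
  expect_equal(length_adjust_counts(100, 1000, 1000), 100)
  expect_equal(length_adjust_counts(100, 2000, 1000), 200)
  cx <- c(10, 50, 80)
  expect_equal(length_adjust_counts(cx, c(1000, 1500, 300),
                                    c(500, 1500, 600)),
               cx * c(2, 1, 0.5))
  expect_error(length_adjust_counts(1, 0, 10), "positive")
})

test_that("a pure library-depth difference is fully normalized away", {
  set.seed(41)
  counts_x <- rpois(500, exp(rnorm(500, 4, 1)))
  counts_x <- pmax(counts_x, 1)
  counts_y <- counts_x * 3L
  f <- tmm_factors(counts_x, counts_y)
  expect_equal(f$norm_lib_y / f$norm_lib_x, 3, tolerance = 1e-9)
  rec <- tibble::tibble(gene_id = as.character(1:500),
                        count_x = counts_x, count_y = counts_y,
                        length_x = 1000, length_y = 1000)
  fp <- fpkm_table(rec, f)
  expect_equal(fp$fpkm_x, fp$fpkm_y, tolerance = 1e-12)
})

test_that("TMM recovers a planted scaling despite perturbed genes", {
  st <- simulate_expression_study(seed = 77, scale_y = 3,
                                  perturbed_fraction = 0.4)
  f <- tmm_factors(st$records$count_x, st$records$count_y)
  expect_lt(abs(f$norm_lib_y / f$norm_lib_x - 3) / 3, 0.05)
  # alternative similar-fraction assumptions give similar factors
  f50 <- tmm_factors(st$records$count_x, st$records$count_y,
                     assumed_fraction = 0.5)
  f70 <- tmm_factors(st$records$count_x, st$records$count_y,
                     assumed_fraction = 0.7)
  expect_lt(abs(f50$norm_lib_y / f70$norm_lib_y - 1), 0.10)
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  st <- simulate_expression_study(seed = 19, scale_y = 2,
                                  perturbed_fraction = 0.3)
  m <- cbind(x = st$records$count_x, y = st$records$count_y)
  nf <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1,
                               logratioTrim = 0.2, sumTrim = 0.05,
                               doWeighting = FALSE)
  eff_edger <- (colSums(m)[2] * nf[2]) / (colSums(m)[1] * nf[1])
  f <- tmm_factors(st$records$count_x, st$records$count_y)
  expect_equal(unname(f$norm_lib_y / f$norm_lib_x), unname(eff_edger),
               tolerance = 0.02)
})

test_that("TMM refuses unstable inputs", {
  expect_error(tmm_factors(c(rep(0, 30), 1:10), c(1:30, rep(0, 10))),
               "fewer than 20")
  expect_error(tmm_factors(1:30, 1:30, assumed_fraction = 1.2), "0, 1")
})

test_that("FPKM follows the formula and is zero iff the count is zero", {
  f <- structure(list(norm_lib_x = 1e6, norm_lib_y = 1e6),
                 class = "tmm_factors")
  rec <- tibble::tibble(gene_id = c("a", "b"), count_x = c(1000, 0),
                        count_y = c(0, 10), length_x = 1000,
                        length_y = 1000)
  fp <- fpkm_table(rec, f)
  expect_equal(fp$fpkm_x, c(1e9 * 1000 / (1000 * 1e6), 0))
  expect_identical(fp$fpkm_y == 0, rec$count_y == 0)
})

test_that("fold differences are antisymmetric and respect orientation", {
  fpkm <- tibble::tibble(gene_id = c("a", "b", "c"),
                         fpkm_x = c(2, 5, 1.25), fpkm_y = c(2, 10, 1),
                         bearing = "x")
  fd <- fold_differences(fpkm, orientation = "bearing")
  expect_equal(fd$value, log(c(1, 0.5, 1.25)))
  swapped <- dplyr::rename(fpkm, fpkm_x = "fpkm_y", fpkm_y = "fpkm_x")
  fd_sw <- fold_differences(swapped, orientation = "bearing")
  expect_equal(fd_sw$value, -fd$value)
  # zero-FPKM genes excluded and reported
  fpkm0 <- dplyr::mutate(fpkm, fpkm_y = c(0, 10, 1))
  fd0 <- fold_differences(fpkm0, orientation = "bearing")
  expect_identical(attr(fd0, "excluded"), "a")
  expect_identical(nrow(fd0), 2L)
})

test_that("post-TMM fold differences are invariant to count rescaling", {
  st <- simulate_expression_study(n_genes = 800, seed = 55)
  rec <- st$records
  run <- function(mult) {
    r <- dplyr::mutate(rec, count_y = .data$count_y * mult)
    f <- tmm_factors(r$count_x, r$count_y)
    fp <- fpkm_table(r, f)
    fold_differences(dplyr::mutate(fp, bearing = "x"), "bearing")$value
  }
  expect_equal(run(1), run(7), tolerance = 1e-9)
})

test_that("random-orientation baseline is centred on zero", {
  meds <- vapply(1:50, function(s) {
    st <- simulate_expression_study(n_genes = 600, n_lineage_a = 0,
                                    n_conserved_a = 0, n_b = 0,
                                    n_housekeeping = 230, seed = 1000 + s)
    an <- analyze_expression_study(st, seed = 2000 + s)
    an$housekeeping_median
  }, numeric(1))
  expect_lt(median(abs(meds)), 0.05)
})
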