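# Cross-species expression quantification: constitutive exons, length
# adjustment, trimmed-mean-of-M-values (TMM) normalization with a
# stated similar-expression fraction, FPKM, and oriented log
# fold-differences.

#' Constitutive exons of each gene
#'
#' The constitutive exon set of a gene is the set of genomic bases
#' present in every annotated transcript of the gene, reported as
#' maximal intervals. Genes whose transcripts share no bases are
#' dropped with a warning (they cannot anchor a between-species
#' comparison).
#'
#' @param gene_models Exon tibble with `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`.
#' @return Exon tibble: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
constitutive_exons <- function(gene_models) {
  gene_models <- validate_intervals(as_tibble(gene_models),
                                    require_strand = TRUE)
  stopifnot(all(c("gene_id", "transcript_id") %in% names(gene_models)))
  by_gene <- split(gene_models, gene_models$gene_id)
  dropped <- character(0)
  rows <- map(by_gene, function(g) {
    txs <- split(g, g$transcript_id)
    common <- GenomicRanges::reduce(as_granges(txs[[1]]))
    if (length(txs) > 1) {
      for (t in txs[-1]) {
        common <- GenomicRanges::intersect(
          common, GenomicRanges::reduce(as_granges(t)))
        if (length(common) == 0) break
      }
    }
    if (length(common) == 0) {
      dropped <<- c(dropped, g$gene_id[1])
      return(NULL)
    }
    out <- granges_to_tbl(common)
    mutate(out, gene_id = g$gene_id[1], strand = g$strand[1], .before = 1)
  })
  if (length(dropped) > 0) {
    warn(sprintf("%d gene(s) with empty constitutive-exon intersection dropped: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  bind_rows(rows)
}

#' Length-adjust read counts between species
#'
#' Adjusts a count observed over a feature of length `len_other` to the
#' count expected if the feature had length `len_focal` (reads per
#' nucleotide held constant): `count * len_focal / len_other`.
#'
#' @param count_other Numeric counts in the other species.
#' @param len_focal,len_other Constitutive lengths (bp, > 0) in the
#'   focal and other species.
#' @return Adjusted (real-valued) counts.
#' @export
length_adjust_counts <- function(count_other, len_focal, len_other) {
  if (any(len_focal <= 0) || any(len_other <= 0)) {
    abort("lengths must be positive")
  }
  count_other * len_focal / len_other
}

#' TMM normalization factors between two species
#'
#' Trimmed mean of per-gene log2 expression ratios (M-values) computed
#' on library-size-scaled counts of one-to-one orthologs. Symmetric
#' trimming retains the central `assumed_fraction` of genes by M-value
#' rank -- encoding the assumption that this fraction of expressed
#' genes is transcribed at similar levels in the two species -- and
#' additionally drops `a_trim` of each extreme-intensity (A-value)
#' tail. The resulting factor rescales species Y's library size.
#'
#' @param counts_x,counts_y Non-negative counts over the same ordered
#'   set of one-to-one orthologous genes.
#' @param lib_x,lib_y Library sizes (default: sum of the counts).
#' @param assumed_fraction Fraction of genes assumed similarly
#'   expressed (default 0.6).
#' @param a_trim Fraction trimmed from each A-value tail (default
#'   0.05).
#' @return Object of class `tmm_factors`: list with `log2_factor`,
#'   `norm_lib_x`, `norm_lib_y`, `assumed_fraction`, `n_used`.
#' @export
tmm_factors <- function(counts_x, counts_y, lib_x = sum(counts_x),
                        lib_y = sum(counts_y), assumed_fraction = 0.6,
                        a_trim = 0.05) {
  if (assumed_fraction <= 0 || assumed_fraction >= 1) {
    abort("assumed_fraction must be in (0, 1)")
  }
  if (length(counts_x) != length(counts_y)) {
    abort("counts_x and counts_y must be paired over the same genes")
  }
  both <- counts_x > 0 & counts_y > 0
  if (sum(both) < 20) {
    abort("fewer than 20 doubly-expressed genes: normalization unstable")
  }
  x <- counts_x[both] / lib_x
  y <- counts_y[both] / lib_y
  M <- log2(y / x)
  A <- 0.5 * log2(y * x)
  n <- length(M)
  lo <- (1 - assumed_fraction) / 2
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep <- rM > n * lo & rM <= n * (1 - lo) &
    rA > n * a_trim & rA <= n * (1 - a_trim)
  log2_factor <- mean(M[keep])
  structure(
    list(log2_factor = log2_factor,
         norm_lib_x = lib_x,
         norm_lib_y = lib_y * 2^log2_factor,
         lib_x = lib_x, lib_y = lib_y,
         assumed_fraction = assumed_fraction, a_trim = a_trim,
         n_used = sum(keep), n_expressed = n),
    class = "tmm_factors"
  )
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat(sprintf(
    "TMM factors (assumed similar fraction %.2f): log2 factor %.4f\n",
    x$assumed_fraction, x$log2_factor))
  cat(sprintf("normalized library sizes: X %.0f, Y %.0f\n",
              x$norm_lib_x, x$norm_lib_y))
  invisible(x)
}

#' @export
glance.tmm_factors <- function(x, ...) {
  tibble(log2_factor = x$log2_factor,
         effective_ratio = x$norm_lib_y / x$norm_lib_x,
         norm_lib_x = x$norm_lib_x, norm_lib_y = x$norm_lib_y,
         assumed_fraction = x$assumed_fraction,
         n_used = x$n_used, n_expressed = x$n_expressed)
}

#' Per-gene FPKM in both species
#'
#' FPKM = 1e9 * count / (constitutive length * normalized library
#' size), using the TMM-normalized library sizes.
#'
#' @param records Tibble with `gene_id`, `count_x`, `count_y`,
#'   `length_x`, `length_y` (constitutive lengths, bp). When species
#'   Y's counts should be length-adjusted to species X's feature
#'   length, apply \code{\link{length_adjust_counts}} first and supply
#'   `length_y = length_x`.
#' @param factors A \code{\link{tmm_factors}} object.
#' @return `records` with added `fpkm_x`, `fpkm_y`.
#' @export
fpkm_table <- function(records, factors) {
  records <- as_tibble(records)
  stopifnot(inherits(factors, "tmm_factors"))
  mutate(records,
         fpkm_x = 1e9 * .data$count_x /
           (.data$length_x * factors$norm_lib_x),
         fpkm_y = 1e9 * .data$count_y /
           (.data$length_y * factors$norm_lib_y))
}

#' Oriented log fold-differences in expression
#'
#' The fold-difference of a gene is the natural log of the FPKM ratio
#' between species X and Y. For genes near a lineage-specific lncRNA
#' the numerator species is the lncRNA-bearing species (supply a
#' per-gene `bearing` column with values `"x"`/`"y"`); for baselines
#' such as housekeeping genes the numerator is assigned at random per
#' gene (seeded). Genes with zero FPKM in either species are excluded
#' and reported via the `excluded` attribute.
#'
#' @param fpkm Tibble with `gene_id`, `fpkm_x`, `fpkm_y` and optional
#'   `bearing`.
#' @param orientation `"bearing"` (use the `bearing` column) or
#'   `"random_xy"`.
#' @param seed Seed for the random assignment.
#' @return Tibble `gene_id`, `value` (ln fold-difference),
#'   `orientation`; excluded gene ids in `attr(, "excluded")`.
#' @export
fold_differences <- function(fpkm, orientation = c("bearing", "random_xy"),
                             seed = NULL) {
  orientation <- match.arg(orientation)
  fpkm <- as_tibble(fpkm)
  ok <- fpkm$fpkm_x > 0 & fpkm$fpkm_y > 0
  excluded <- fpkm$gene_id[!ok]
  use <- fpkm[ok, ]
  if (nrow(use) == 0) abort("all genes have zero FPKM in one species")
  if (orientation == "bearing") {
    if (!"bearing" %in% names(use)) {
      abort("orientation 'bearing' needs a bearing column ('x'/'y')")
    }
    num_is_x <- use$bearing == "x"
  } else {
    if (!is.null(seed)) set.seed(seed)
    num_is_x <- runif(nrow(use)) < 0.5
  }
  value <- ifelse(num_is_x, log(use$fpkm_x / use$fpkm_y),
                  log(use$fpkm_y / use$fpkm_x))
  out <- tibble(gene_id = use$gene_id, value = value,
                orientation = orientation)
  attr(out, "excluded") <- excluded
  out
}
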