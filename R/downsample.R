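# Library-size equalization across species and locus-count sensitivity
# to sequencing depth.

#' Subsample a read library without replacement
#'
#' @param reads Read tibble.
#' @param n Number of reads to keep (0 <= n <= nrow(reads)).
#' @param seed Optional seed.
#' @return Tibble of exactly `n` distinct rows of `reads`.
#' @export
subsample_library <- function(reads, n, seed = NULL) {
  reads <- as_tibble(reads)
  if (n < 0 || n > nrow(reads)) {
    abort(sprintf("n must be between 0 and the library size (%d)",
                  nrow(reads)))
  }
  if (!is.null(seed)) set.seed(seed)
  reads[sample.int(nrow(reads), n), ]
}

#' Locus counts after downsampling to a common library size
#'
#' Emulates equalizing library sizes across species: per replicate,
#' each species' library is subsampled (without replacement) to the
#' target size, transcript fragments are re-assembled and re-filtered
#' against the (fixed) peak set, and the number of full-depth lncRNA
#' loci overlapped by at least 1 bp by a recreated transcript is
#' counted. The summary reports the per-replicate counts with their
#' mean and sample standard deviation (n - 1 denominator).
#'
#' @param reads_per_species Named list of read tibbles.
#' @param peaks_per_species Named list of peak tibbles (held fixed; the
#'   chromatin libraries are not downsampled).
#' @param loci_per_species Named list of full-depth lncRNA locus
#'   tibbles (`chrom`, `start`, `end`).
#' @param target_species Name of the species whose (smallest) library
#'   size is the target.
#' @param replicates Number of subsampling replicates (default 10).
#' @param seed Integer seed; replicate r of species s uses an
#'   independent derived stream.
#' @param min_gap,min_length Assembly parameters
#'   (\code{\link{assemble_transfrags}}).
#' @return Tibble with one row per species: `species`, `target_size`,
#'   `replicate_counts` (list), `mean`, `sd`, `full_depth_count`.
#' @export
downsampled_locus_counts <- function(reads_per_species, peaks_per_species,
                                     loci_per_species, target_species,
                                     replicates = 10, seed = NULL,
                                     min_gap = 50, min_length = 200) {
  if (replicates < 1) abort("replicates must be at least 1")
  sizes <- vapply(reads_per_species, nrow, integer(1))
  if (!target_species %in% names(reads_per_species)) {
    abort("target_species not found among the read libraries")
  }
  target_size <- sizes[[target_species]]
  if (any(sizes < target_size)) {
    abort("the target species must have the smallest library")
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- map(setdiff(names(reads_per_species), target_species),
              function(sp) {
    loci <- as_tibble(loci_per_species[[sp]])
    counts <- vapply(seq_len(replicates), function(r) {
      sub <- subsample_library(reads_per_species[[sp]], target_size)
      tf <- assemble_transfrags(sub, min_gap = min_gap,
                                min_length = min_length)
      tf <- tss_supported_transcripts(tf, peaks_per_species[[sp]],
                                      min_length = min_length)
      length(overlapping_rows(loci, tf))
    }, numeric(1))
    tibble(species = sp, target_size = target_size,
           replicate_counts = list(as.integer(counts)),
           mean = mean(counts),
           sd = if (replicates > 1) sd(counts) else 0,
           full_depth_count = nrow(loci))
  })
  bind_rows(rows)
}
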