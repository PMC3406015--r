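# Simulation of diverged sequence pairs under the REV model. Used by
# the scenario generator to plant known substitution rates, and as the
# ground truth for parameter-recovery tests of the rate estimator.

#' Simulate a gap-free diverged sequence pair
#'
#' Draws an ancestral-side sequence from the stationary composition and
#' evolves the partner sequence site-by-site with the REV transition
#' matrix at distance `d`. Because the model is time-reversible this
#' pairwise distribution is identical to evolving both sequences from a
#' common ancestor with total path length `d`.
#'
#' @param length Number of aligned sites (> 0).
#' @param d Expected substitutions per site (>= 0).
#' @param params A \code{\link{rev_params}} object.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `seq1`, `seq2` (character scalars, equal length).
#' @export
evolve_pair <- function(length, d, params = rev_params(), seed = NULL) {
  if (length <= 0) abort("length must be positive")
  if (d < 0) abort("d must be non-negative")
  if (!inherits(params, "rev_params")) abort("params must be a rev_params object")
  if (!is.null(seed)) set.seed(seed)
  pi <- params$frequencies
  anc <- sample.int(4, length, replace = TRUE, prob = pi)
  if (d == 0) {
    s <- paste0(BASES[anc], collapse = "")
    return(list(seq1 = s, seq2 = s))
  }
  P <- rev_transition_matrix(params, d)
  der <- integer(length)
  for (b in 1:4) {
    idx <- which(anc == b)
    if (length(idx) > 0) {
      der[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  list(seq1 = paste0(BASES[anc], collapse = ""),
       seq2 = paste0(BASES[der], collapse = ""))
}

#' Simulate a stranded read library over transcript models
#'
#' Places fixed-length single-end reads inside transcript exons, on the
#' transcript strand, with per-transcript read counts proportional to
#' the supplied expression weights (largest-remainder apportionment so
#' that the total equals `depth` exactly). Within a transcript, read
#' start positions are uniform over the positions at which a full read
#' fits inside one exon.
#'
#' @param transcripts Tibble with `transcript_id`, `chrom`, `start`,
#'   `end`, `strand` exon rows (one row per exon) and optionally a
#'   per-transcript `weight` column (recycled across exon rows).
#' @param depth Total number of reads to draw (>= 0).
#' @param read_length Read length in bp (reads are truncated to the
#'   exon when an exon is shorter).
#' @param seed Optional integer seed.
#' @return Tibble of reads: `chrom`, `start`, `end`, `strand`,
#'   `transcript_id`.
#' @export
simulate_read_library <- function(transcripts, depth, read_length = 50,
                                  seed = NULL) {
  if (depth < 0) abort("depth must be non-negative")
  transcripts <- validate_intervals(as_tibble(transcripts),
                                    require_strand = TRUE)
  if (depth == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), transcript_id = character()))
  }
  if (nrow(transcripts) == 0) {
    abort("cannot draw reads from an empty transcript set")
  }
  if (!is.null(seed)) set.seed(seed)
  if (!"weight" %in% names(transcripts)) transcripts$weight <- 1
  per_tx <- summarise(group_by(transcripts, .data$transcript_id),
                      weight = first(.data$weight), .groups = "drop")
  counts <- apportion_counts(per_tx$weight, depth)
  reads <- map(seq_len(nrow(per_tx)), function(i) {
    n_i <- counts[i]
    if (n_i == 0) return(NULL)
    ex <- filter(transcripts, .data$transcript_id == per_tx$transcript_id[i])
    sample_reads_in_exons(ex, n_i, read_length)
  })
  bind_rows(reads)
}

# Integer apportionment of `total` by weights (largest remainder).
apportion_counts <- function(weights, total) {
  if (all(weights == 0)) weights <- rep(1, length(weights))
  exact <- total * weights / sum(weights)
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    order_idx <- order(exact - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# n reads uniform over valid start positions within single exons.
sample_reads_in_exons <- function(exons, n, read_length) {
  len_ok <- pmax(exons$end - exons$start - read_length + 1, 1)
  pick <- sample.int(nrow(exons), n, replace = TRUE, prob = len_ok)
  starts <- exons$start[pick] +
    floor(runif(n) * len_ok[pick])
  ends <- pmin(starts + read_length, exons$end[pick])
  tibble(chrom = exons$chrom[pick], start = as.integer(starts),
         end = as.integer(ends), strand = exons$strand[pick],
         transcript_id = exons$transcript_id[pick])
}
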