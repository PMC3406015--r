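# Transcript and promoter annotation: from stranded reads / transcript
# fragments plus H3K4me3 peaks and a protein-coding annotation to
# filtered transcripts, loci, promoters, antisense calls and
# bidirectional-promoter calls.

#' Per-transcript spans, lengths and TSS positions
#'
#' Collapses an exon-level tibble (one row per exon, sharing
#' `transcript_id`, `chrom`, `strand`) to one row per transcript with
#' the envelope span, the summed exonic length and the predicted TSS
#' (most 5' transcribed base: span start on `+`, span end - 1 on `-`).
#'
#' @param transcripts Exon-level tibble: `transcript_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @return Tibble: `transcript_id`, `chrom`, `start`, `end`, `strand`,
#'   `length`, `tss`.
#' @export
transcript_spans <- function(transcripts) {
  transcripts <- validate_intervals(as_tibble(transcripts),
                                    require_strand = TRUE)
  out <- summarise(group_by(transcripts, .data$transcript_id),
                   chrom = first(.data$chrom),
                   start = min(.data$start),
                   end = max(.data$end),
                   strand = first(.data$strand),
                   length = sum(.data$end - .data$start),
                   .groups = "drop")
  mutate(out, tss = tss_position(.data$start, .data$end, .data$strand))
}

#' Assemble transcript fragments from stranded reads
#'
#' Desk-scale stand-in for de novo assembly: per chromosome and strand,
#' maximal runs of reads whose inter-read gap is at most `min_gap` are
#' merged into single-exon transcript fragments; fragments shorter than
#' `min_length` are discarded.
#'
#' @param reads Tibble of stranded reads (`chrom`, `start`, `end`,
#'   `strand`).
#' @param min_gap Maximum gap (bp) bridged when merging (default 50).
#' @param min_length Minimum fragment length retained (default 200).
#' @return Exon-level transcript tibble (`transcript_id`, `chrom`,
#'   `start`, `end`, `strand`), one exon per fragment.
#' @export
assemble_transfrags <- function(reads, min_gap = 50, min_length = 200) {
  if (min_gap < 0) abort("min_gap must be non-negative")
  reads <- validate_intervals(as_tibble(reads), require_strand = TRUE)
  merged <- merge_intervals(reads, max_gap = min_gap, by_strand = TRUE)
  merged <- filter(merged, .data$end - .data$start >= min_length)
  merged <- arrange(merged, .data$chrom, .data$start, .data$strand)
  mutate(merged,
         transcript_id = sprintf("transfrag_%05d", row_number()),
         .before = 1)
}

#' Filter transcripts by length and TSS peak support
#'
#' Retains transcripts whose summed exonic length is at least
#' `min_length` (default 200 nt) and whose predicted TSS coordinate is
#' contained in at least one (strandless) peak interval. The peak must
#' contain the TSS base itself, not merely overlap the transcript.
#'
#' @param transcripts Exon-level transcript tibble.
#' @param peaks Tibble of peak intervals (`chrom`, `start`, `end`).
#' @param min_length Minimum transcript length (default 200).
#' @return The retained rows of `transcripts`.
#' @export
tss_supported_transcripts <- function(transcripts, peaks, min_length = 200) {
  transcripts <- as_tibble(transcripts)
  if (nrow(transcripts) == 0) return(transcripts)
  spans <- transcript_spans(transcripts)
  peaks <- validate_intervals(as_tibble(peaks))
  tss_iv <- tibble(chrom = spans$chrom, start = spans$tss,
                   end = spans$tss + 1L)
  has_peak <- rep(FALSE, nrow(spans))
  idx <- overlapping_rows(tss_iv, peaks)
  has_peak[idx] <- TRUE
  keep_ids <- spans$transcript_id[spans$length >= min_length & has_peak]
  filter(transcripts, .data$transcript_id %in% keep_ids)
}

#' Classify transcripts as intergenic or intragenic
#'
#' A transcript is intragenic when its span (first-exon start to
#' last-exon end, introns included) overlaps any protein-coding gene
#' span by one or more base pairs, strand-agnostically; otherwise it is
#' intergenic. Antisense relationships are handled separately by
#' \code{\link{identify_antisense}}.
#'
#' @param transcripts Exon-level transcript tibble.
#' @param genes Tibble of protein-coding gene spans (`gene_id`,
#'   `chrom`, `start`, `end`).
#' @return Tibble: `transcript_id`, `context`
#'   (`intergenic`/`intragenic`).
#' @export
classify_genic_context <- function(transcripts, genes) {
  spans <- transcript_spans(transcripts)
  genes <- validate_intervals(as_tibble(genes))
  idx <- overlapping_rows(spans, genes)
  tibble(transcript_id = spans$transcript_id,
         context = ifelse(seq_len(nrow(spans)) %in% idx,
                          "intragenic", "intergenic"))
}

#' Cluster transcripts into non-overlapping loci
#'
#' Transcripts whose spans overlap (by exonic or intronic bases) are
#' merged transitively into loci. A locus is an `intergenic_lncRNA`
#' locus only when every member transcript is intergenic and noncoding;
#' loci with any coding member are `protein_coding`; remaining mixed
#' loci are `intragenic_other`.
#'
#' @param transcripts Exon-level transcript tibble.
#' @param classes Tibble with `transcript_id`, `context`
#'   (`intergenic`/`intragenic`) and `label`
#'   (`coding`/`noncoding`/`NA`).
#' @return Tibble of loci: `locus_id`, `chrom`, `start`, `end`,
#'   `locus_class`, `n_members`, `members` (list of transcript ids).
#' @export
cluster_loci <- function(transcripts, classes) {
  spans <- transcript_spans(transcripts)
  classes <- as_tibble(classes)
  spans <- left_join(spans, classes, by = "transcript_id")
  if (nrow(spans) == 0) {
    return(tibble(locus_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  locus_class = character(), n_members = integer(),
                  members = list()))
  }
  # strict overlap only: abutting spans stay separate loci
  envelopes <- merge_intervals(spans, max_gap = -1L, by_strand = FALSE)
  gr_env <- as_granges(envelopes)
  gr_tx <- as_granges(spans)
  hits <- GenomicRanges::findOverlaps(gr_tx, gr_env)
  locus_of <- integer(nrow(spans))
  locus_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  rows <- map(seq_len(nrow(envelopes)), function(i) {
    mem <- spans[locus_of == i, ]
    cls <- if (all(mem$context == "intergenic") &&
               all(!is.na(mem$label) & mem$label == "noncoding")) {
      "intergenic_lncRNA"
    } else if (any(!is.na(mem$label) & mem$label == "coding")) {
      "protein_coding"
    } else {
      "intragenic_other"
    }
    tibble(chrom = envelopes$chrom[i],
           start = min(mem$start), end = max(mem$end),
           locus_class = cls, n_members = nrow(mem),
           members = list(mem$transcript_id))
  })
  out <- bind_rows(rows)
  out <- arrange(out, .data$chrom, .data$start)
  mutate(out, locus_id = sprintf("locus_%05d", row_number()), .before = 1)
}

#' Promoter intervals upstream of transcript TSSs
#'
#' The promoter is the `promoter_bp` (default 400) bases immediately
#' upstream of the TSS, strand-aware: `[tss - 400, tss)` on `+`,
#' `[tss + 1, tss + 401)` on `-`. Promoters are truncated at chromosome
#' bounds and flagged; a TSS at position 0 on `+` yields an empty,
#' flagged promoter.
#'
#' @param transcripts Exon-level transcript tibble.
#' @param promoter_bp Promoter width in bp (default 400).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   right-edge truncation.
#' @return Tibble: `transcript_id`, `chrom`, `start`, `end`, `strand`,
#'   `truncated`, `empty`.
#' @export
define_promoter <- function(transcripts, promoter_bp = 400,
                            chrom_lengths = NULL) {
  spans <- transcript_spans(transcripts)
  plus <- spans$strand != "-"
  start <- ifelse(plus, spans$tss - promoter_bp, spans$tss + 1L)
  end <- ifelse(plus, spans$tss, spans$tss + 1L + promoter_bp)
  truncated <- rep(FALSE, nrow(spans))
  truncated[start < 0] <- TRUE
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[spans$chrom])
    over <- !is.na(lim) & end > lim
    truncated[over] <- TRUE
    end <- ifelse(!is.na(lim), pmin(end, lim), end)
  }
  tibble(transcript_id = spans$transcript_id, chrom = spans$chrom,
         start = as.integer(start), end = as.integer(end),
         strand = spans$strand,
         truncated = truncated | start >= end,
         empty = start >= end)
}

#' Identify and filter antisense transcripts
#'
#' Considers transcripts overlapping a protein-coding gene on the
#' opposite strand and applies the removal rules in order: (i) the
#' transcript also overlaps an annotated coding gene on its own strand
#' (it is itself an annotated coding transcript); (ii) the transcript
#' has H3K4me3 peak(s) at its TSS but every such peak also contains the
#' host gene's TSS (no independent transcriptional initiation);
#' (iii) the transcript has no peak at its 5' end at all; (iv) the
#' transcript id is on a caller-supplied manual artifact list (never
#' applied automatically).
#'
#' @param transcripts Exon-level transcript tibble.
#' @param genes Protein-coding gene tibble with `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param artifact_ids Optional character vector of transcript ids to
#'   flag as visual-inspection artifacts.
#' @return Tibble of antisense calls: `transcript_id`, `host_gene`,
#'   `removal_reason` (`none` = retained).
#' @export
identify_antisense <- function(transcripts, genes, peaks,
                               artifact_ids = character()) {
  spans <- transcript_spans(transcripts)
  genes <- validate_intervals(as_tibble(genes), require_strand = TRUE)
  peaks <- validate_intervals(as_tibble(peaks))
  if (nrow(spans) == 0 || nrow(genes) == 0) {
    return(tibble(transcript_id = character(), host_gene = character(),
                  removal_reason = character()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(spans), as_granges(genes))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  anti <- spans$strand[qh] != genes$strand[sh]
  qh_a <- qh[anti]; sh_a <- sh[anti]
  if (length(qh_a) == 0) {
    return(tibble(transcript_id = character(), host_gene = character(),
                  removal_reason = character()))
  }
  # one host per transcript: the opposite-strand gene with most overlap
  ov <- pmin(spans$end[qh_a], genes$end[sh_a]) -
    pmax(spans$start[qh_a], genes$start[sh_a])
  best <- tibble(q = qh_a, s = sh_a, ov = ov)
  best <- slice(group_by(best, .data$q), which.max(.data$ov))
  best <- ungroup(best)
  same_strand_idx <- {
    ss <- spans$strand[qh] == genes$strand[sh]
    unique(qh[ss])
  }
  gene_tss <- tss_position(genes$start, genes$end, genes$strand)
  calls <- map(seq_len(nrow(best)), function(k) {
    i <- best$q[k]; j <- best$s[k]
    tx <- spans[i, ]
    reason <- "none"
    if (i %in% same_strand_idx) {
      reason <- "annotated_coding"
    } else {
      own_pk <- filter(peaks, .data$chrom == tx$chrom,
                       .data$start <= tx$tss, .data$end > tx$tss)
      if (nrow(own_pk) == 0) {
        reason <- "no_5prime_peak"
      } else {
        host_tss <- gene_tss[j]
        shared <- own_pk$start <= host_tss & own_pk$end > host_tss
        if (all(shared)) reason <- "no_independent_peak"
      }
    }
    if (reason == "none" && tx$transcript_id %in% artifact_ids) {
      reason <- "flagged_artifact"
    }
    tibble(transcript_id = tx$transcript_id,
           host_gene = as.character(genes$gene_id[j]),
           removal_reason = reason)
  })
  bind_rows(calls)
}

#' Detect bidirectional (divergent) transcription at gene TSSs
#'
#' Reports genes with at least one read on the opposite strand,
#' oriented away from the gene body, whose 5' end lies within `window`
#' bp upstream of the gene's annotated TSS.
#'
#' @param genes Gene tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param reads Stranded read tibble.
#' @param window Window size in bp (default 1000).
#' @return Tibble: `gene_id`, `n_divergent_reads` (reported genes only).
#' @export
detect_bidirectional <- function(genes, reads, window = 1000) {
  genes <- validate_intervals(as_tibble(genes), require_strand = TRUE)
  reads <- validate_intervals(as_tibble(reads), require_strand = TRUE)
  rows <- map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tssg <- tss_position(g$start, g$end, g$strand)
    r <- filter(reads, .data$chrom == g$chrom, .data$strand != g$strand,
                .data$strand != ".")
    n_div <- if (g$strand == "+") {
      # away = leftward; read 5' end (end - 1) upstream of the TSS
      sum(r$strand == "-" & r$end - 1 < tssg & r$end - 1 >= tssg - window)
    } else {
      sum(r$strand == "+" & r$start > tssg & r$start <= tssg + window)
    }
    if (n_div > 0) {
      tibble(gene_id = as.character(g$gene_id), n_divergent_reads = n_div)
    } else {
      NULL
    }
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(gene_id = character(), n_divergent_reads = integer())
  }
  out
}

#' Annotate intergenic lncRNA loci from transcripts, peaks and genes
#'
#' Convenience wrapper running the annotation chain:
#' TSS/length filter, genic-context classification, coding-potential
#' scoring of intergenic transcripts (needs the genome sequence) and
#' locus clustering.
#'
#' @param transcripts Exon-level transcript tibble (e.g. from
#'   \code{\link{assemble_transfrags}}).
#' @param peaks Peak tibble.
#' @param genes Protein-coding gene tibble.
#' @param genome Named character vector (or list) of chromosome
#'   sequences; required to score coding potential. When `NULL`, all
#'   intergenic transcripts are treated as noncoding (useful when
#'   coding potential was pre-computed or is planted by a simulation).
#' @param min_length Minimum transcript length (default 200).
#' @param cpc_shuffles Shuffle count for the coding-potential null.
#' @param seed Seed for the shuffle null.
#' @return List with `transcripts` (retained exon tibble), `classes`
#'   (per-transcript context/label) and `loci`
#'   (\code{\link{cluster_loci}} output).
#' @export
annotate_loci <- function(transcripts, peaks, genes, genome = NULL,
                          min_length = 200, cpc_shuffles = 50, seed = NULL) {
  kept <- tss_supported_transcripts(transcripts, peaks, min_length)
  ctx <- classify_genic_context(kept, genes)
  label <- rep(NA_character_, nrow(ctx))
  inter <- which(ctx$context == "intergenic")
  if (length(inter) > 0) {
    if (is.null(genome)) {
      label[inter] <- "noncoding"
    } else {
      if (!is.null(seed)) set.seed(seed)
      for (i in inter) {
        seq_i <- spliced_sequence(genome, kept, ctx$transcript_id[i])
        label[i] <- coding_potential_score(seq_i, k = cpc_shuffles)$label
      }
    }
  }
  classes <- mutate(ctx, label = label)
  list(transcripts = kept, classes = classes,
       loci = cluster_loci(kept, classes))
}

# Substring of a chromosome sequence, reverse-complemented on "-".
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome[[chrom]], start + 1, end)
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

# Spliced (exon-concatenated) transcript sequence in 5'->3' orientation.
spliced_sequence <- function(genome, transcripts, id) {
  ex <- arrange(filter(as_tibble(transcripts), .data$transcript_id == id),
                .data$start)
  plus <- paste0(vapply(seq_len(nrow(ex)), function(k) {
    substr(genome[[ex$chrom[k]]], ex$start[k] + 1, ex$end[k])
  }, character(1)), collapse = "")
  if (ex$strand[1] == "-") {
    plus <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(plus)))
  }
  plus
}
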