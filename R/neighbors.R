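# Neighbour-gene analysis: lncRNA-gene pairing, orientation classes,
# gene territories, GAT-style permutation enrichment, and expression
# shift tests against a housekeeping baseline.

#' Pair lncRNA loci with their closest protein-coding genes
#'
#' For each lncRNA locus, gene A is the genomically closest
#' protein-coding gene (envelope distance) and gene B the next most
#' proximal gene beyond A, skipping genes annotated as paralogs of A.
#' Pairs whose gene A or B lacks a one-to-one ortholog are reported
#' with a drop reason; chromosomes with fewer than two genes yield
#' incomplete pairs.
#'
#' @param lncrna_loci Tibble with `locus_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `category` (carried through).
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param paralogs Tibble of paralogous pairs (`gene1`, `gene2`),
#'   direction-agnostic.
#' @param orthologs Character vector (or tibble with `gene_id`) of
#'   genes having one-to-one orthologs.
#' @return Tibble: `locus_id`, `category`, `gene_a`, `gene_b`,
#'   `tss_distance`, `orientation`, `reason` (`ok`, `no_ortholog_a`,
#'   `no_ortholog_b`, `incomplete`).
#' @export
neighbor_pairs <- function(lncrna_loci, genes, paralogs = NULL,
                           orthologs = NULL) {
  lncrna_loci <- validate_intervals(as_tibble(lncrna_loci),
                                    require_strand = TRUE)
  genes <- validate_intervals(as_tibble(genes), require_strand = TRUE)
  if (!"category" %in% names(lncrna_loci)) {
    lncrna_loci$category <- NA_character_
  }
  ortho_ids <- if (is.null(orthologs)) {
    as.character(genes$gene_id)
  } else if (is.data.frame(orthologs)) {
    as.character(orthologs$gene_id)
  } else {
    as.character(orthologs)
  }
  para <- if (is.null(paralogs) || nrow(as_tibble(paralogs)) == 0) {
    tibble(gene1 = character(), gene2 = character())
  } else {
    as_tibble(paralogs)
  }
  is_paralog_pair <- function(a, b) {
    any((para$gene1 == a & para$gene2 == b) |
          (para$gene1 == b & para$gene2 == a))
  }
  gene_tss <- tss_position(genes$start, genes$end, genes$strand)
  rows <- map(seq_len(nrow(lncrna_loci)), function(i) {
    l <- lncrna_loci[i, ]
    cand <- which(genes$chrom == l$chrom)
    out <- tibble(locus_id = l$locus_id, category = l$category,
                  gene_a = NA_character_, gene_b = NA_character_,
                  tss_distance = NA_real_, orientation = NA_character_,
                  reason = "incomplete")
    if (length(cand) == 0) return(out)
    d <- pmax(0, pmax(genes$start[cand] - l$end, l$start - genes$end[cand]))
    ord <- cand[order(d)]
    a_idx <- ord[1]
    a_id <- as.character(genes$gene_id[a_idx])
    l_tss <- tss_position(l$start, l$end, l$strand)
    out$gene_a <- a_id
    out$tss_distance <- abs(gene_tss[a_idx] - l_tss)
    out$orientation <- orientation_class(
      l_tss, l$strand, gene_tss[a_idx], genes$strand[a_idx])
    if (!a_id %in% ortho_ids) {
      out$reason <- "no_ortholog_a"
      return(out)
    }
    b_idx <- NA_integer_
    for (j in ord[-1]) {
      jid <- as.character(genes$gene_id[j])
      if (is_paralog_pair(a_id, jid)) next
      b_idx <- j
      break
    }
    if (is.na(b_idx)) {
      out$reason <- "incomplete"
      return(out)
    }
    b_id <- as.character(genes$gene_id[b_idx])
    out$gene_b <- b_id
    if (!b_id %in% ortho_ids) {
      out$reason <- "no_ortholog_b"
      return(out)
    }
    out$reason <- "ok"
    out
  })
  bind_rows(rows)
}

#' Relative orientation of a lncRNA-gene pair
#'
#' Same strand is `tandem`. On opposite strands the pair is `divergent`
#' when the two TSSs point away from each other (the minus-strand
#' element lies to the left of the plus-strand element) and
#' `convergent` when they transcribe toward each other.
#'
#' @param lnc_tss,gene_tss TSS coordinates.
#' @param lnc_strand,gene_strand Strands (`+`/`-`; strandless input is
#'   an error).
#' @return Character vector: `tandem`, `divergent` or `convergent`.
#' @export
orientation_class <- function(lnc_tss, lnc_strand, gene_tss, gene_strand) {
  if (any(lnc_strand == ".") || any(gene_strand == ".")) {
    abort("orientation requires stranded input")
  }
  same <- lnc_strand == gene_strand
  minus_tss <- ifelse(lnc_strand == "-", lnc_tss, gene_tss)
  plus_tss <- ifelse(lnc_strand == "-", gene_tss, lnc_tss)
  ifelse(same, "tandem",
         ifelse(minus_tss < plus_tss, "divergent", "convergent"))
}

#' Gene territories
#'
#' The territory of a gene contains all bases closer to that gene than
#' to its flanking protein-coding genes: boundaries lie at midpoints
#' between adjacent gene envelopes, and chromosome ends close the
#' terminal territories. Territories tile each chromosome.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`
#'   (non-overlapping genes).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_territories <- function(genes, chrom_lengths) {
  genes <- validate_intervals(as_tibble(genes))
  rows <- map(split(genes, genes$chrom), function(g) {
    g <- arrange(g, .data$start)
    len <- unname(chrom_lengths[g$chrom[1]])
    if (is.na(len)) abort(paste("no chromosome length for", g$chrom[1]))
    n <- nrow(g)
    if (n == 1) {
      return(tibble(gene_id = as.character(g$gene_id), chrom = g$chrom,
                    start = 0L, end = as.integer(len)))
    }
    mids <- as.integer(floor((g$end[-n] + g$start[-1]) / 2))
    tibble(gene_id = as.character(g$gene_id), chrom = g$chrom,
           start = c(0L, mids), end = c(mids, as.integer(len)))
  })
  bind_rows(rows)
}

#' GAT-style permutation enrichment of segment overlap
#'
#' Compares the observed number of nucleotides shared between a segment
#' set and an annotation to the distribution obtained by repeatedly
#' re-placing the segments uniformly at random within the workspace
#' (per chromosome, length-preserving, each segment inside a single
#' workspace interval, optionally restricted to workspace intervals in
#' the same G+C decile bin as the segment's origin). The overlap
#' statistic is the per-segment overlap summed over segments.
#'
#' @param segments Tibble of segments (must lie within the workspace).
#' @param annotation Tibble of annotation intervals.
#' @param workspace Tibble of workspace intervals; a `gc` column is
#'   required when `match_gc = TRUE`.
#' @param n_perms Number of permutations (>= 99; default 1000).
#' @param seed Optional seed.
#' @param match_gc Restrict random placement to workspace intervals in
#'   the segment's G+C decile bin.
#' @return Object of class `enrichment_result`: `observed`,
#'   `expected_mean`, `expected_sd`, `fold`, `p_value`, `direction`,
#'   `n_permutations`. `glance()` gives a one-row tibble.
#' @export
permutation_enrichment <- function(segments, annotation, workspace,
                                   n_perms = 1000, seed = NULL,
                                   match_gc = FALSE) {
  if (n_perms < 99) abort("n_perms must be at least 99")
  segments <- validate_intervals(as_tibble(segments))
  annotation <- validate_intervals(as_tibble(annotation))
  workspace <- validate_intervals(as_tibble(workspace))
  if (!is.null(seed)) set.seed(seed)
  seg_len <- segments$end - segments$start
  n_seg <- nrow(segments)
  # workspace interval containing each segment (for GC binning and the
  # containment precondition)
  ws_of_seg <- integer(n_seg)
  for (i in seq_len(n_seg)) {
    j <- which(workspace$chrom == segments$chrom[i] &
                 workspace$start <= segments$start[i] &
                 workspace$end >= segments$end[i])
    if (length(j) == 0) {
      abort("every segment must lie within a single workspace interval")
    }
    ws_of_seg[i] <- j[1]
  }
  if (match_gc) {
    if (!"gc" %in% names(workspace)) {
      abort("match_gc = TRUE requires a gc column on the workspace")
    }
    breaks <- unique(quantile(workspace$gc, probs = seq(0, 1, 0.1)))
    ws_bin <- cut(workspace$gc, breaks = breaks, include.lowest = TRUE,
                  labels = FALSE)
  } else {
    ws_bin <- rep(1L, nrow(workspace))
  }
  ws_width <- workspace$end - workspace$start
  # merged annotation with cumulative covered length, per chromosome,
  # so the bases of [s, e) under the annotation are a pair of lookups
  ann_by_chrom <- map(split(annotation, annotation$chrom), function(a) {
    m <- merge_intervals(a)
    list(start = m$start, end = m$end,
         cum = cumsum(m$end - m$start))
  })
  covered_upto <- function(chrom_tab, x) {
    # bases of [0, x) covered by the merged annotation intervals
    k <- findInterval(x, chrom_tab$start)
    prev <- ifelse(k > 1, chrom_tab$cum[pmax(k - 1, 1)], 0)
    prev[k == 0] <- 0
    inside <- ifelse(k >= 1,
                     pmax(0, pmin(x, chrom_tab$end[pmax(k, 1)]) -
                            chrom_tab$start[pmax(k, 1)]),
                     0)
    prev + inside
  }
  seg_overlap <- function(chroms, starts, ends) {
    out <- numeric(length(starts))
    for (ch in unique(chroms)) {
      tab <- ann_by_chrom[[ch]]
      idx <- which(chroms == ch)
      if (is.null(tab)) next
      out[idx] <- covered_upto(tab, ends[idx]) -
        covered_upto(tab, starts[idx])
    }
    out
  }
  # eligible workspace intervals per segment (same chromosome and GC
  # bin, wide enough), with per-interval start-slot counts
  allowed <- map(seq_len(n_seg), function(i) {
    a <- which(ws_bin == ws_bin[ws_of_seg[i]] &
                 workspace$chrom == segments$chrom[i] &
                 ws_width >= seg_len[i])
    if (length(a) == 0) {
      abort("segment longer than any eligible workspace interval")
    }
    a
  })
  # observed statistic: summed per-segment overlap with the annotation
  observed <- sum(seg_overlap(segments$chrom, segments$start,
                              segments$end))
  perm_mat <- matrix(0, nrow = n_perms, ncol = n_seg)
  for (i in seq_len(n_seg)) {
    a <- allowed[[i]]
    slots <- ws_width[a] - seg_len[i] + 1
    k <- a[sample.int(length(a), n_perms, replace = TRUE, prob = slots)]
    starts <- workspace$start[k] +
      floor(runif(n_perms) * (ws_width[k] - seg_len[i] + 1))
    perm_mat[, i] <- seg_overlap(workspace$chrom[k], starts,
                                 starts + seg_len[i])
  }
  perms <- rowSums(perm_mat)
  expected <- mean(perms)
  fold <- if (expected > 0) observed / expected else NA_real_
  p_enrich <- (1 + sum(perms >= observed)) / (n_perms + 1)
  p_deplete <- (1 + sum(perms <= observed)) / (n_perms + 1)
  direction <- if (!is.na(fold) && fold < 1) "depletion" else "enrichment"
  structure(
    list(observed = observed, expected_mean = expected,
         expected_sd = sd(perms), fold = fold,
         p_value = if (direction == "enrichment") p_enrich else p_deplete,
         p_enrichment = p_enrich, p_depletion = p_deplete,
         direction = direction, n_permutations = n_perms,
         permuted = perms),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Permutation %s: observed %s bp, expected %.1f +- %.1f, fold %.2f, p = %.3g (%d perms)\n",
    x$direction, format(x$observed, big.mark = ","), x$expected_mean,
    x$expected_sd, x$fold, x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(observed = x$observed, expected_mean = x$expected_mean,
         expected_sd = x$expected_sd, fold = x$fold,
         p_value = x$p_value, p_enrichment = x$p_enrichment,
         p_depletion = x$p_depletion, direction = x$direction,
         n_permutations = x$n_permutations)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(permutation = seq_along(x$permuted), overlap_bp = x$permuted)
}

#' Expression-shift tests against a housekeeping baseline
#'
#' For each group of genes, reports the median ln fold-difference and a
#' two-tailed Mann-Whitney test against the housekeeping baseline
#' distribution. Groups with fewer than 5 genes are reported as
#' underpowered without a p-value.
#'
#' @param fold_values Tibble with `group` and `value` (per-gene ln
#'   fold-differences).
#' @param baseline Numeric vector of housekeeping fold-differences.
#' @return Tibble: `group`, `n`, `median`, `p_value`, `note`.
#' @export
expression_shift_test <- function(fold_values, baseline) {
  fold_values <- as_tibble(fold_values)
  stopifnot(all(c("group", "value") %in% names(fold_values)))
  groups <- split(fold_values$value, fold_values$group)
  bind_rows(imap(groups, function(v, g) {
    if (length(v) < 5) {
      return(tibble(group = g, n = length(v), median = median(v),
                    p_value = NA_real_, note = "underpowered (n < 5)"))
    }
    p <- wilcox.test(v, baseline, exact = FALSE)$p.value
    tibble(group = g, n = length(v), median = median(v),
           p_value = p, note = NA_character_)
  }))
}

#' Correlation between TSS distance and fold-difference
#'
#' Pearson correlation of log10(TSS distance) against the ln
#' fold-difference, with two-sided p-value. Zero variance in either
#' variable makes the correlation undefined (flagged).
#'
#' @param distances TSS-to-TSS distances in bp (> 0).
#' @param values Matching ln fold-differences.
#' @return Tibble: `r`, `p_value`, `n`, `flagged`.
#' @export
distance_correlation <- function(distances, values) {
  ok <- !is.na(distances) & !is.na(values) & distances > 0
  x <- log10(distances[ok])
  y <- values[ok]
  if (length(x) < 3) abort("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = length(x),
                  flagged = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
         flagged = FALSE)
}
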