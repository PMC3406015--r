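# Cross-species projection of loci through syntenic-block orthology
# maps, peak/read evidence collection, conservation-category
# classification and turnover contingency statistics.

#' Validate a syntenic-block orthology map
#'
#' A map is a tibble of co-linear blocks: `src_chrom`, `src_start`,
#' `src_end` (0-based half-open), `tgt_chrom`, `tgt_start`,
#' `orientation` (`same`/`flipped`). Blocks must not overlap on the
#' source genome and the mapping is length-preserving.
#'
#' @param map The orthology map tibble.
#' @return The map, sorted by source position, invisibly-validated.
#' @export
validate_orthology_map <- function(map) {
  map <- as_tibble(map)
  need <- c("src_chrom", "src_start", "src_end", "tgt_chrom", "tgt_start",
            "orientation")
  if (!all(need %in% names(map))) {
    abort(paste("orthology map needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(map) > 0) {
    if (any(map$src_start < 0 | map$src_start >= map$src_end)) {
      abort("malformed orthology map: bad source intervals")
    }
    if (!all(map$orientation %in% c("same", "flipped"))) {
      abort("orientation must be 'same' or 'flipped'")
    }
    map <- arrange(map, .data$src_chrom, .data$src_start)
    by_chrom <- split(map, map$src_chrom)
    for (b in by_chrom) {
      if (nrow(b) > 1 && any(b$src_start[-1] < b$src_end[-nrow(b)])) {
        abort("malformed orthology map: overlapping source blocks")
      }
    }
  }
  map
}

#' Project intervals through an orthology map
#'
#' Each source interval is intersected with the covering syntenic
#' blocks and the covered portions are mapped by block offset
#' (coordinates reversed within `flipped` blocks, which also flip the
#' strand). Intervals entirely between blocks yield no output rows;
#' partial overlaps map the covered portion only.
#'
#' @param intervals Tibble of intervals (`chrom`, `start`, `end`,
#'   optional `strand`).
#' @param map Orthology map (see \code{\link{validate_orthology_map}}).
#' @return Tibble with one row per projected piece: `src_index` (row of
#'   `intervals`), `chrom`, `start`, `end`, `strand` (projected
#'   coordinates).
#' @export
project_interval <- function(intervals, map) {
  intervals <- validate_intervals(as_tibble(intervals))
  map <- validate_orthology_map(map)
  if (!"strand" %in% names(intervals)) intervals$strand <- "."
  out <- list()
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    blocks <- filter(map, .data$src_chrom == iv$chrom,
                     .data$src_start < iv$end, .data$src_end > iv$start)
    if (nrow(blocks) == 0) next
    for (k in seq_len(nrow(blocks))) {
      b <- blocks[k, ]
      a <- max(iv$start, b$src_start)
      z <- min(iv$end, b$src_end)
      if (b$orientation == "same") {
        t_start <- b$tgt_start + (a - b$src_start)
        t_end <- b$tgt_start + (z - b$src_start)
        t_strand <- iv$strand
      } else {
        t_start <- b$tgt_start + (b$src_end - z)
        t_end <- b$tgt_start + (b$src_end - a)
        t_strand <- flip_strand(iv$strand)
      }
      out[[length(out) + 1]] <- tibble(
        src_index = i, chrom = b$tgt_chrom,
        start = as.integer(t_start), end = as.integer(t_end),
        strand = t_strand)
    }
  }
  if (length(out) == 0) {
    return(tibble(src_index = integer(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  bind_rows(out)
}

flip_strand <- function(s) {
  ifelse(s == "+", "-", ifelse(s == "-", "+", s))
}

#' Invert an orthology map
#'
#' Produces the target-to-source map; projecting through the map and
#' then its inverse is the identity on covered bases.
#'
#' @param map Orthology map tibble.
#' @return The inverted map tibble.
#' @export
invert_orthology_map <- function(map) {
  map <- validate_orthology_map(map)
  len <- map$src_end - map$src_start
  tibble(src_chrom = map$tgt_chrom,
         src_start = map$tgt_start,
         src_end = map$tgt_start + len,
         tgt_chrom = map$src_chrom,
         tgt_start = map$src_start,
         orientation = map$orientation)
}

#' Transcriptional evidence at a (projected) region
#'
#' Under the `strict` rule a region counts as expressed when it has at
#' least `min_overlap_bp` of (strandless) H3K4me3 peak overlap AND at
#' least one overlapping read on the matching strand. Under
#' `reads_only` (used when no chromatin data exist for a species) the
#' read criterion alone suffices.
#'
#' @param region Tibble of one or more interval pieces with `strand`
#'   (the projected strand; use `"."` for strand-agnostic read
#'   matching).
#' @param peaks Peak tibble for the species.
#' @param reads Stranded read tibble for the species.
#' @param mode `"strict"` or `"reads_only"`.
#' @param min_overlap_bp Minimum peak overlap in bp (default 1).
#' @return Tibble: `has_peak`, `has_reads`, `expressed`.
#' @export
expression_evidence_at <- function(region, peaks, reads,
                                   mode = c("strict", "reads_only"),
                                   min_overlap_bp = 1) {
  mode <- match.arg(mode)
  region <- validate_intervals(as_tibble(region))
  if (nrow(region) == 0) abort("region must be non-empty")
  if (!"strand" %in% names(region)) region$strand <- "."
  peaks <- as_tibble(peaks)
  reads <- as_tibble(reads)
  has_peak <- length(overlapping_rows(region, peaks,
                                      min_bp = min_overlap_bp)) > 0
  reads_use <- reads
  strands <- unique(region$strand)
  if (!any(strands == ".") && "strand" %in% names(reads)) {
    reads_use <- filter(reads, .data$strand %in% strands)
  }
  has_reads <- FALSE
  if (nrow(reads_use) > 0) {
    for (s in strands) {
      piece <- filter(region, .data$strand == s)
      r <- if (s == "." || !"strand" %in% names(reads_use)) reads_use else
        filter(reads_use, .data$strand == s)
      if (length(overlapping_rows(r, piece, min_bp = min_overlap_bp)) > 0) {
        has_reads <- TRUE
        break
      }
    }
  }
  expressed <- if (mode == "strict") has_peak && has_reads else has_reads
  tibble(has_peak = has_peak, has_reads = has_reads, expressed = expressed)
}

#' Classify transcriptional conservation of loci
#'
#' Applies the three-species truth table: a locus is excluded when its
#' outgroup ortholog is absent; otherwise categories are assigned from
#' the focal/sister/outgroup expression evidence -- `I` (all three),
#' `II` (focal and sister only), `III` (focal only), `IV` (sister
#' only), `V` (outgroup only). Evidence combinations outside this
#' palette are reported as `unclassified`. A locus with no expression
#' evidence in any species contradicts its annotation and is an error.
#'
#' @param evidence Tibble with columns `locus_id`, `species`,
#'   `has_ortholog` (logical) and `expressed` (logical); one row per
#'   locus x species.
#' @param focal,sister,outgroup Species names as used in `evidence`.
#' @return Tibble: `locus_id`, `category` (`I`..`V`,
#'   `excluded_no_ortholog`, `unclassified`).
#' @export
classify_conservation <- function(evidence, focal = "focal",
                                  sister = "sister", outgroup = "outgroup") {
  evidence <- as_tibble(evidence)
  need <- c("locus_id", "species", "has_ortholog", "expressed")
  stopifnot(all(need %in% names(evidence)))
  wide <- pivot_wider(evidence, id_cols = "locus_id",
                      names_from = "species",
                      values_from = c("has_ortholog", "expressed"))
  f <- wide[[paste0("expressed_", focal)]]
  s <- wide[[paste0("expressed_", sister)]]
  o <- wide[[paste0("expressed_", outgroup)]]
  orth_o <- wide[[paste0("has_ortholog_", outgroup)]]
  if (any(!f & !s & !o & orth_o)) {
    bad <- wide$locus_id[!f & !s & !o & orth_o][1]
    abort(paste0("locus ", bad, " has no expression evidence in any ",
                 "species but was annotated as expressed"))
  }
  category <- dplyr::case_when(
    !orth_o ~ "excluded_no_ortholog",
    f & s & o ~ "I",
    f & s & !o ~ "II",
    f & !s & !o ~ "III",
    !f & s & !o ~ "IV",
    !f & !s & o ~ "V",
    TRUE ~ "unclassified"
  )
  tibble(locus_id = wide$locus_id, category = category)
}

#' Fraction of exonic bases covered by reads in the other species
#'
#' Projects exons through the orthology map and reports the fraction of
#' projected exonic bases overlapped by at least one read in the target
#' species. When only part of the exons projects, the fraction is over
#' the projectable bases and the result is flagged; with zero
#' projectable bases the fraction is undefined (NA, flagged).
#'
#' @param exons Exon tibble (`chrom`, `start`, `end`, `strand`).
#' @param reads Target-species read tibble.
#' @param map Orthology map source -> target.
#' @param stranded Match read strand to the projected exon strand
#'   (default TRUE; the libraries are stranded).
#' @return Tibble: `fraction`, `projected_bases`, `total_bases`,
#'   `flagged`.
#' @export
exon_coverage_fraction <- function(exons, reads, map, stranded = TRUE) {
  exons <- validate_intervals(as_tibble(exons))
  total <- sum(exons$end - exons$start)
  proj <- project_interval(exons, map)
  if (nrow(proj) == 0) {
    return(tibble(fraction = NA_real_, projected_bases = 0L,
                  total_bases = as.integer(total), flagged = TRUE))
  }
  projected <- sum(proj$end - proj$start)
  reads <- as_tibble(reads)
  covered <- 0L
  for (s in unique(proj$strand)) {
    piece <- filter(proj, .data$strand == s)
    r <- if (stranded && s != "." && "strand" %in% names(reads)) {
      filter(reads, .data$strand == s)
    } else {
      reads
    }
    covered <- covered + overlap_bp(piece, r)
  }
  tibble(fraction = covered / projected,
         projected_bases = as.integer(projected),
         total_bases = as.integer(total),
         flagged = projected < total)
}

#' Two-group transcriptional-turnover contingency test
#'
#' Builds the 2x2 table (rows = groups, columns = in category vs not)
#' and computes the exact two-tailed Fisher p-value (sum of table
#' probabilities no larger than the observed one).
#'
#' @param calls_group1,calls_group2 Character vectors of per-locus
#'   categories (no-ortholog loci excluded beforehand), or tibbles with
#'   a `category` column.
#' @param category The category tested, e.g. `"I"`.
#' @return Object of class `turnover_test`: list with `table`,
#'   `p_value`, `proportions`. `glance()` gives a one-row summary.
#' @export
turnover_contingency <- function(calls_group1, calls_group2, category) {
  get_cat <- function(x) {
    if (is.data.frame(x)) x <- x$category
    as.character(x)
  }
  g1 <- get_cat(calls_group1)
  g2 <- get_cat(calls_group2)
  if (length(g1) == 0 || length(g2) == 0) abort("empty group")
  tab <- matrix(c(sum(g1 == category), sum(g1 != category),
                  sum(g2 == category), sum(g2 != category)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("group1", "group2"),
                                c("in_category", "not_in_category")))
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  structure(
    list(table = tab, p_value = p,
         proportions = tab[, 1] / rowSums(tab), category = category),
    class = "turnover_test"
  )
}

#' @export
print.turnover_test <- function(x, ...) {
  cat(sprintf("Turnover contingency (category %s): p = %.3g\n",
              x$category, x$p_value))
  print(x$table)
  invisible(x)
}

#' @export
glance.turnover_test <- function(x, ...) {
  tibble(category = x$category,
         prop_group1 = unname(x$proportions[1]),
         prop_group2 = unname(x$proportions[2]),
         p_value = x$p_value)
}

#' @export
tidy.turnover_test <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$table))) |>
    setNames(c("group", "status", "count"))
}
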