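# Interval tibbles and their bridge to IRanges/GenomicRanges.
#
# Convention throughout the package: 0-based half-open [start, end),
# strand one of "+", "-", "." . IRanges is 1-based closed, so the bridge
# is start + 1 on the way in and start - 1 on the way out.

#' Validate an interval tibble
#'
#' Checks the coordinate convention used everywhere in the package:
#' `chrom` non-empty, `0 <= start < end` (0-based half-open) and, when a
#' strand column is present, strand in `+`, `-`, `.`.
#'
#' @param x A data frame with at least `chrom`, `start`, `end` columns.
#' @param require_strand Require a valid `strand` column.
#' @return `x` invisibly, as a tibble; aborts on violation.
#' @export
validate_intervals <- function(x, require_strand = FALSE) {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing interval columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(is.na(x$chrom) | !nzchar(as.character(x$chrom)))) {
      abort("chrom must be non-empty")
    }
    if (any(x$start < 0) || any(x$start >= x$end)) {
      abort("intervals must satisfy 0 <= start < end (0-based half-open)")
    }
  }
  if (require_strand) {
    if (!"strand" %in% names(x)) abort("strand column required")
    if (nrow(x) > 0 && !all(x$strand %in% c("+", "-", "."))) {
      abort("strand must be one of '+', '-', '.'")
    }
  }
  invisible(x)
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x, use_strand = FALSE) {
  if (nrow(x) == 0) {
    return(GenomicRanges::GRanges())
  }
  strand <- if (use_strand && "strand" %in% names(x)) {
    ifelse(x$strand == ".", "*", x$strand)
  } else {
    "*"
  }
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

granges_to_tbl <- function(gr) {
  if (length(gr) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  s <- as.character(GenomicRanges::strand(gr))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(s == "*", ".", s)
  )
}

# Row indices of `x` having >= min_bp overlap with any interval in `y`,
# strand-agnostic.
overlapping_rows <- function(x, y, min_bp = 1L) {
  if (nrow(x) == 0 || nrow(y) == 0) return(integer(0))
  hits <- GenomicRanges::findOverlaps(as_granges(x), as_granges(y),
                                      minoverlap = min_bp)
  sort(unique(S4Vectors::queryHits(hits)))
}

# Total number of bases of `x` covered by >= 1 interval of `y`.
overlap_bp <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(0L)
  gx <- GenomicRanges::reduce(as_granges(x))
  gy <- GenomicRanges::reduce(as_granges(y))
  sum(GenomicRanges::width(GenomicRanges::intersect(gx, gy)))
}

# Merge intervals on the same chrom (and strand when by_strand = TRUE)
# whose gap is <= max_gap; returns a tibble.
merge_intervals <- function(x, max_gap = 0L, by_strand = FALSE) {
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  gr <- as_granges(x, use_strand = by_strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                               ignore.strand = !by_strand)
  granges_to_tbl(red)
}

# The 5' coordinate (0-based position of the most 5' transcribed base)
# of a stranded interval: start on "+", end - 1 on "-".
tss_position <- function(start, end, strand) {
  ifelse(strand == "-", end - 1L, start)
}
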