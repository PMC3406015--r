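# Self-contained coding-potential statistic: the z-score of the longest
# open reading frame length against a dinucleotide-preserving shuffle
# null. Negative scores (shorter ORFs than shuffled sequence of the
# same composition) mark a transcript as noncoding, preserving the
# "coding potential < 0" convention for lncRNA calling.

#' Longest open reading frame length
#'
#' Scans the three forward frames for the longest ATG-to-stop open
#' reading frame and returns its length in nucleotides (including the
#' stop codon). An ORF with a start but no in-frame stop runs to the
#' last complete codon. Codons containing N are treated as neither
#' start nor stop.
#'
#' @param sequence Character scalar, alphabet ACGTN.
#' @return Integer ORF length in nt (0 if no ATG).
#' @export
longest_orf_length <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts_at <- seq.int(1 + frame, n - 2, by = 3)
    if (length(starts_at) == 0) next
    codons <- substring(s, starts_at, starts_at + 2)
    is_start <- codons == "ATG"
    is_stop <- codons %in% stops
    open_from <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_from) && is_start[i]) open_from <- i
      if (!is.na(open_from) && is_stop[i]) {
        best <- max(best, (i - open_from + 1L) * 3L)
        open_from <- NA_integer_
      }
    }
    if (!is.na(open_from)) {
      best <- max(best, (length(codons) - open_from + 1L) * 3L)
    }
  }
  best
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Uniform random Eulerian-path shuffle (Altschul-Erickson): the
#' shuffled sequence has exactly the original dinucleotide (and hence
#' mononucleotide) counts, with the same first and last character.
#'
#' @param sequence Character scalar.
#' @return A shuffled character scalar.
#' @export
dinucleotide_shuffle <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 3) return(sequence)
  verts <- unique(chars)
  from <- chars[-n]
  to <- chars[-1]
  edges <- split(to, factor(from, levels = verts))
  last_vert <- chars[n]
  # choose random "last out-edges" forming a tree into last_vert
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last_vert) return(NA_character_)
      e <- edges[[v]]
      e[sample.int(length(e), 1)]
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last_vert) next
      seen <- character(0)
      cur <- v
      while (cur != last_vert) {
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
        if (is.na(cur)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute remaining edges, appending the chosen last edge
  ordered <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v != last_vert) {
      drop_idx <- match(last_edge[[v]], e)
      e <- e[-drop_idx]
      c(sample(e), last_edge[[v]])
    } else {
      sample(e)
    }
  })
  names(ordered) <- verts
  pos <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][pos[[cur]]]
    pos[[cur]] <- pos[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste0(out, collapse = "")
}

#' Coding-potential score of a transcript sequence
#'
#' Scores coding potential as the z-score of the observed longest-ORF
#' length against the mean and standard deviation of longest-ORF
#' lengths over `k` dinucleotide-preserving shuffles of the same
#' sequence. Sequences are labelled `noncoding` when the score is below
#' zero; a sequence with no ORF at all is always noncoding.
#'
#' @param sequence Character scalar, length >= 200, alphabet ACGTN with
#'   at most 10 percent N.
#' @param k Number of shuffles in the null (default 50).
#' @param seed Optional integer seed for the shuffle null.
#' @return Tibble with `score`, `label` (`coding`/`noncoding`),
#'   `orf_length`, `null_mean`, `null_sd`.
#' @export
coding_potential_score <- function(sequence, k = 50, seed = NULL) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 200) abort("sequence must be at least 200 nt")
  chars <- strsplit(s, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    abort("sequence alphabet must be ACGTN")
  }
  if (mean(chars == "N") > 0.10) {
    abort("sequence has more than 10% N")
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- longest_orf_length(s)
  null_lengths <- vapply(seq_len(k), function(i) {
    longest_orf_length(dinucleotide_shuffle(s))
  }, numeric(1))
  m <- mean(null_lengths)
  sdev <- sd(null_lengths)
  score <- if (obs == 0) {
    -Inf  # no start codon anywhere: cannot encode protein
  } else if (sdev == 0) {
    if (obs == m) 0 else sign(obs - m) * Inf
  } else {
    (obs - m) / sdev
  }
  tibble(score = score,
         label = if (score < 0) "noncoding" else "coding",
         orf_length = obs, null_mean = m, null_sd = sdev)
}
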