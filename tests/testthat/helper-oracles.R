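# Brute-force oracles, independent of the package's interval machinery
# (plain sorting / per-base loops), plus a cached default scenario
# shared across test files.

.fixture_cache <- new.env(parent = emptyenv())

shared_scenario <- function() {
  if (is.null(.fixture_cache$scenario)) {
    .fixture_cache$scenario <- generate_scenario(scenario_config(seed = 101))
  }
  .fixture_cache$scenario
}

# merge stranded reads with gap <= min_gap: simple sort-and-sweep
oracle_merge <- function(reads, min_gap) {
  out <- list()
  for (key in unique(paste(reads$chrom, reads$strand))) {
    sub <- reads[paste(reads$chrom, reads$strand) == key, ]
    sub <- sub[order(sub$start), ]
    cur_s <- sub$start[1]; cur_e <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] - cur_e <= min_gap) {
        cur_e <- max(cur_e, sub$end[i])
      } else {
        out[[length(out) + 1]] <- data.frame(
          chrom = sub$chrom[1], start = cur_s, end = cur_e,
          strand = sub$strand[1])
        cur_s <- sub$start[i]; cur_e <- sub$end[i]
      }
    }
    out[[length(out) + 1]] <- data.frame(
      chrom = sub$chrom[1], start = cur_s, end = cur_e,
      strand = sub$strand[1])
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), ]
}

# does interval i of x overlap any interval of y by >= 1 bp?
oracle_overlaps_any <- function(x, y) {
  vapply(seq_len(nrow(x)), function(i) {
    any(y$chrom == x$chrom[i] & y$start < x$end[i] & y$end > x$start[i])
  }, logical(1))
}

# per-base projection of one interval through a block map
oracle_project_bases <- function(chrom, start, end, map) {
  pos <- start:(end - 1)
  res <- data.frame(src = pos, tgt = NA_real_, tgt_chrom = NA_character_,
                    flip = NA)
  for (b in seq_len(nrow(map))) {
    inb <- pos >= map$src_start[b] & pos < map$src_end[b] &
      chrom == map$src_chrom[b]
    if (!any(inb)) next
    if (map$orientation[b] == "same") {
      res$tgt[inb] <- map$tgt_start[b] + (pos[inb] - map$src_start[b])
      res$flip[inb] <- FALSE
    } else {
      res$tgt[inb] <- map$tgt_start[b] + (map$src_end[b] - 1 - pos[inb])
      res$flip[inb] <- TRUE
    }
    res$tgt_chrom[inb] <- map$tgt_chrom[b]
  }
  res
}

# exact two-tailed Fisher p by hypergeometric enumeration
oracle_fisher_two_tailed <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# longest ORF by explicitly scanning every ATG
oracle_longest_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- 0
  for (i in seq_len(max(0, n - 2))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i
    found_stop <- FALSE
    while (j + 2 <= n) {
      codon <- substr(s, j, j + 2)
      if (j > i && codon %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 2 - i + 1)
        found_stop <- TRUE
        break
      }
      j <- j + 3
    }
    if (!found_stop) {
      n_codons <- (n - i + 1) %/% 3
      best <- max(best, n_codons * 3)
    }
  }
  best
}

dinucleotide_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}

# random stranded intervals on one chromosome
random_intervals <- function(n, chrom_len = 10000, max_len = 500,
                             stranded = TRUE) {
  start <- sample.int(chrom_len - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = "chr1", start = start, end = start + len,
                 strand = if (stranded) sample(c("+", "-"), n, TRUE)
                 else ".")
}
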