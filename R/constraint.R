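# Pairwise substitution-rate estimation under the REV model and
# normalization against nearby G+C-matched ancestral repeats (ARs).

#' Maximum-likelihood REV distance for one aligned sequence pair
#'
#' Fits the general time-reversible model to a gap-free pairwise
#' alignment. Base frequencies are the empirical frequencies of the
#' pooled pair. The distance `d` (expected substitutions per site) and
#' the six exchangeabilities are obtained by eigendecomposition of the
#' symmetrized divergence matrix -- the matrix logarithm of the fitted
#' reversible transition matrix is `d * Q`, which is the exact maximum
#' of the multinomial likelihood within the reversible family -- and
#' `d` is then polished by bounded scalar likelihood optimization at
#' the fitted exchangeabilities (tolerance 1e-9). Degenerate tables
#' (non-positive eigenvalues near saturation) fall back to direct
#' numerical optimization of the likelihood.
#'
#' @param seq1,seq2 Aligned sequences of equal length (character
#'   scalars, ACGT; non-ACGT columns are dropped with a warning).
#' @return An object of class `rev_fit`: list with `d`, `frequencies`,
#'   `exchangeabilities`, `loglik`, `aligned_length`, `p_distance`.
#' @export
rev_distance <- function(seq1, seq2) {
  N <- alignment_count_matrix(seq1, seq2)
  n <- sum(N)
  if (n == 0) abort("no usable (ACGT/ACGT) alignment columns")
  p <- 1 - sum(diag(N)) / n
  freq <- (rowSums(N) + colSums(N)) / (2 * n)
  exch_names <- c("AC", "AG", "AT", "CG", "CT", "GT")
  if (p == 0) {
    return(structure(
      list(d = 0, frequencies = setNames(freq, BASES),
           exchangeabilities = setNames(rep(1, 6), exch_names),
           loglik = sum(N[cbind(1:4, 1:4)] * log(pmax(freq, 1e-300))),
           aligned_length = n, p_distance = 0),
      class = "rev_fit"
    ))
  }
  keep <- freq > 0
  Fs <- (N + t(N)) / (2 * n)            # symmetrized joint proportions
  Fk <- Fs[keep, keep, drop = FALSE]
  pik <- rowSums(Fk)
  sq <- sqrt(pik)
  B <- Fk / (sq %o% sq)                 # symmetric similar form of P
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  fit <- NULL
  if (all(eig$values > 1e-12)) {
    # logm(P) = d * Q on the observed composition
    L <- diag(1 / sq) %*% (eig$vectors %*% diag(log(eig$values)) %*%
                             t(eig$vectors)) %*% diag(sq)
    d0 <- -sum(pik * diag(L))
    if (is.finite(d0) && d0 > 0) {
      Q <- L / d0
      # exchangeabilities s_ij = Q_ij / pi_j, scaled to s_GT = 1
      s_full <- matrix(1, 4, 4, dimnames = list(BASES, BASES))
      Qfull <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
      Qfull[keep, keep] <- Q
      pi_full <- freq
      for (i in 1:4) for (j in 1:4) {
        if (i != j && pi_full[j] > 0) {
          s_full[i, j] <- Qfull[i, j] / pi_full[j]
        }
      }
      s_hat <- pmax(c(s_full["A", "C"], s_full["A", "G"], s_full["A", "T"],
                      s_full["C", "G"], s_full["C", "T"],
                      s_full["G", "T"]), 1e-8)
      if (s_hat[6] > 0) s_hat <- s_hat / s_hat[6]
      fit <- list(d = d0, s = s_hat)
    }
  }
  if (is.null(fit)) {
    fit <- rev_fit_numeric(N, freq, p)
  }
  # bounded scalar polish of d at the fitted exchangeabilities
  pars <- rev_params(freq / sum(freq), fit$s)
  negll_d <- function(d) {
    P <- rev_transition_matrix(pars, d)
    -sum(N * log(pmax(freq * P, 1e-300)))
  }
  pol <- optimize(negll_d, interval = c(fit$d / 2, fit$d * 2), tol = 1e-9)
  structure(
    list(d = pol$minimum,
         frequencies = setNames(freq, BASES),
         exchangeabilities = setNames(fit$s, exch_names),
         loglik = -pol$objective,
         aligned_length = n, p_distance = p),
    class = "rev_fit"
  )
}

# Fallback: joint Nelder-Mead optimization of d and the
# exchangeabilities on the multinomial likelihood.
rev_fit_numeric <- function(N, freq, p) {
  d0 <- jc_distance(min(p, 0.74))
  negll <- function(theta) {
    d <- exp(theta[1])
    s <- c(exp(theta[2:6]), 1)
    pars <- rev_params(freq / sum(freq), s)
    P <- rev_transition_matrix(pars, d)
    -sum(N * log(pmax(freq * P, 1e-300)))
  }
  opt <- optim(c(log(d0), rep(0, 5)), negll, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 4000))
  list(d = exp(opt$par[1]), s = c(exp(opt$par[2:6]), 1))
}

# Jukes-Cantor closed form, the symmetric limit of the REV distance.
jc_distance <- function(p) {
  if (p >= 0.75) return(Inf)
  -(3 / 4) * log(1 - 4 * p / 3)
}

#' @export
print.rev_fit <- function(x, ...) {
  cat(sprintf("REV pairwise fit: d = %.5f over %d sites (p-distance %.4f)\n",
              x$d, x$aligned_length, x$p_distance))
  invisible(x)
}

#' @export
tidy.rev_fit <- function(x, ...) {
  tibble(term = c("d", paste0("freq_", BASES),
                  paste0("exch_", names(x$exchangeabilities))),
         estimate = c(x$d, unname(x$frequencies),
                      unname(x$exchangeabilities)))
}

#' @export
glance.rev_fit <- function(x, ...) {
  tibble(d = x$d, p_distance = x$p_distance, loglik = x$loglik,
         aligned_length = x$aligned_length)
}

#' Estimate substitution rates for a table of pairwise alignments
#'
#' Applies \code{\link{rev_distance}} to each aligned pair. Alignments
#' shorter than `min_length` usable columns are retained in the output
#' but flagged (`flagged = TRUE`) and should be excluded from summaries.
#'
#' @param alignments Tibble with columns `region_id`, `seq1`, `seq2`
#'   and optionally `feature_class` (carried through).
#' @param min_length Minimum usable aligned length (default 50).
#' @return Tibble: `region_id`, (`feature_class`,) `d`,
#'   `aligned_length`, `p_distance`, `flagged`.
#' @export
estimate_substitution_rate <- function(alignments, min_length = 50) {
  alignments <- as_tibble(alignments)
  stopifnot(all(c("region_id", "seq1", "seq2") %in% names(alignments)))
  fits <- map2(alignments$seq1, alignments$seq2, rev_distance)
  out <- tibble(
    region_id = alignments$region_id,
    d = map_dbl(fits, "d"),
    aligned_length = map_int(fits, function(f) as.integer(f$aligned_length)),
    p_distance = map_dbl(fits, "p_distance")
  )
  if ("feature_class" %in% names(alignments)) {
    out$feature_class <- alignments$feature_class
    out <- select(out, "region_id", "feature_class", everything())
  }
  mutate(out, flagged = .data$aligned_length < min_length)
}

#' Match ancestral repeats to focal regions
#'
#' For each focal region, selects ancestral repeats (ARs) lying within
#' `max_dist` bp of the region envelope, not overlapping any annotated
#' locus, and with G+C content within `gc_tol` of the focal region's.
#' The matched ARs of a region are intended to be pooled into a single
#' neutral-rate estimate (see \code{\link{pooled_ar_rates}}).
#'
#' @param focal_regions Tibble with `region_id`, `chrom`, `start`,
#'   `end`, `gc`.
#' @param ars Tibble with `ar_id`, `chrom`, `start`, `end`, `gc`.
#' @param annotated_loci Tibble of intervals ARs must not overlap.
#' @param max_dist Maximum distance AR-to-region (default 500000).
#' @param gc_tol Maximum |GC difference| (default 0.05).
#' @return Tibble with one row per (region, matched AR):
#'   `region_id`, `ar_id`, `gc_focal`, `gc_ar`, `distance`. Regions with
#'   no qualifying AR appear once with `ar_id = NA` (unnormalizable).
#' @export
match_ancestral_repeats <- function(focal_regions, ars, annotated_loci,
                                    max_dist = 500000, gc_tol = 0.05) {
  focal_regions <- validate_intervals(focal_regions)
  ars <- validate_intervals(ars)
  stopifnot("gc" %in% names(focal_regions), "gc" %in% names(ars))
  clean_idx <- setdiff(seq_len(nrow(ars)),
                       overlapping_rows(ars, as_tibble(annotated_loci)))
  ars_clean <- ars[clean_idx, ]
  rows <- map(seq_len(nrow(focal_regions)), function(i) {
    fr <- focal_regions[i, ]
    cand <- filter(ars_clean, .data$chrom == fr$chrom)
    if (nrow(cand) > 0) {
      dist <- pmax(0, pmax(fr$start - cand$end, cand$start - fr$end))
      keep <- dist < max_dist & abs(cand$gc - fr$gc) <= gc_tol
      cand <- cand[keep, ]
      dist <- dist[keep]
    } else {
      dist <- numeric(0)
    }
    if (nrow(cand) == 0) {
      tibble(region_id = fr$region_id, ar_id = NA_character_,
             gc_focal = fr$gc, gc_ar = NA_real_, distance = NA_real_)
    } else {
      tibble(region_id = fr$region_id, ar_id = as.character(cand$ar_id),
             gc_focal = fr$gc, gc_ar = cand$gc, distance = dist)
    }
  })
  bind_rows(rows)
}

#' Pooled ancestral-repeat rate per focal region
#'
#' Concatenates the alignments of each region's matched ARs and fits a
#' single REV distance to the pooled site-pattern counts, yielding one
#' neutral rate `d_ar` per region. Pooling (rather than averaging
#' per-AR estimates) keeps short repeats from destabilizing the ML fit.
#'
#' @param matches Output of \code{\link{match_ancestral_repeats}}.
#' @param ar_alignments Tibble with `ar_id`, `seq1`, `seq2`.
#' @return Tibble `region_id`, `d_ar`, `ar_aligned_length`, `n_ars`;
#'   unnormalizable regions are omitted.
#' @export
pooled_ar_rates <- function(matches, ar_alignments) {
  matches <- filter(as_tibble(matches), !is.na(.data$ar_id))
  if (nrow(matches) == 0) {
    return(tibble(region_id = character(), d_ar = numeric(),
                  ar_aligned_length = integer(), n_ars = integer()))
  }
  aln <- as_tibble(ar_alignments)
  joined <- inner_join(matches, aln, by = "ar_id")
  grouped <- split(joined, joined$region_id)
  bind_rows(map(grouped, function(g) {
    fit <- rev_distance(paste0(g$seq1, collapse = ""),
                        paste0(g$seq2, collapse = ""))
    tibble(region_id = g$region_id[1], d_ar = fit$d,
           ar_aligned_length = as.integer(fit$aligned_length),
           n_ars = nrow(g))
  }))
}

#' Normalized substitution-rate summary
#'
#' Joins per-region REV rates with their pooled matched-AR rates,
#' forms the normalized rate `d / d_ar`, and reports group medians plus
#' two-tailed Mann-Whitney tests: (a) each group's rates against its
#' matched AR rates, and (b) all group pairs on the normalized rates.
#' Groups with fewer than 2 regions are skipped with a notice column.
#'
#' @param estimates Tibble with `region_id`, `group`, `d` (flagged or
#'   unnormalizable regions should be removed beforehand; rows whose
#'   `region_id` lacks an AR rate are dropped here).
#' @param ar_rates Tibble `region_id`, `d_ar`
#'   (\code{\link{pooled_ar_rates}}).
#' @return Object of class `constraint_summary`: list with `ratios`
#'   (per-region tibble), `medians` (per-group tibble) and `tests`
#'   (tibble of Mann-Whitney results). `tidy()` returns the ratios,
#'   `glance()` the tests.
#' @export
normalized_rate_summary <- function(estimates, ar_rates) {
  estimates <- as_tibble(estimates)
  stopifnot(all(c("region_id", "group", "d") %in% names(estimates)))
  ratios <- inner_join(estimates, as_tibble(ar_rates), by = "region_id")
  ratios <- mutate(ratios, ratio = .data$d / .data$d_ar)
  medians <- summarise(group_by(ratios, .data$group),
                       n = n(),
                       median_d = median(.data$d),
                       median_d_ar = median(.data$d_ar),
                       median_ratio = median(.data$ratio),
                       .groups = "drop")
  groups <- unique(ratios$group)
  tests <- list()
  for (g in groups) {
    sub <- filter(ratios, .data$group == g)
    if (nrow(sub) < 2) {
      tests[[length(tests) + 1]] <- tibble(
        test = "rates_vs_AR", group1 = g, group2 = "AR",
        p_value = NA_real_, note = "group size < 2, skipped")
      next
    }
    p <- wilcox.test(sub$d, sub$d_ar, exact = FALSE)$p.value
    tests[[length(tests) + 1]] <- tibble(
      test = "rates_vs_AR", group1 = g, group2 = "AR",
      p_value = p, note = NA_character_)
  }
  if (length(groups) > 1) {
    combs <- utils::combn(sort(groups), 2)
    for (k in seq_len(ncol(combs))) {
      g1 <- combs[1, k]; g2 <- combs[2, k]
      s1 <- filter(ratios, .data$group == g1)
      s2 <- filter(ratios, .data$group == g2)
      if (nrow(s1) < 2 || nrow(s2) < 2) {
        tests[[length(tests) + 1]] <- tibble(
          test = "ratio_between_groups", group1 = g1, group2 = g2,
          p_value = NA_real_, note = "group size < 2, skipped")
        next
      }
      p <- wilcox.test(s1$ratio, s2$ratio, exact = FALSE)$p.value
      tests[[length(tests) + 1]] <- tibble(
        test = "ratio_between_groups", group1 = g1, group2 = g2,
        p_value = p, note = NA_character_)
    }
  }
  structure(list(ratios = ratios, medians = medians,
                 tests = bind_rows(tests)),
            class = "constraint_summary")
}

#' @export
print.constraint_summary <- function(x, ...) {
  cat("Normalized substitution-rate summary\n")
  print(x$medians)
  invisible(x)
}

#' @export
tidy.constraint_summary <- function(x, ...) x$ratios

#' @export
glance.constraint_summary <- function(x, ...) x$tests
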