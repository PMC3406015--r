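# General time-reversible (REV/GTR) nucleotide model machinery shared by
# the pairwise-rate estimator and the alignment simulator.
#
# Parameterization: stationary frequencies pi (A,C,G,T) and six
# exchangeabilities s (AC, AG, AT, CG, CT, GT). Off-diagonal rates are
# Q[i,j] = s[ij] * pi[j]; the matrix is scaled so that the expected
# number of substitutions per site per unit time is 1, making the
# branch length d directly interpretable as substitutions/site.

BASES <- c("A", "C", "G", "T")

#' REV model parameter set
#'
#' Bundles stationary base frequencies and the six exchangeabilities of
#' the general time-reversible model. The default (all frequencies 1/4,
#' all exchangeabilities 1) is the Jukes-Cantor symmetric limit.
#'
#' @param frequencies Numeric length-4 vector (A, C, G, T), summing to 1.
#' @param exchangeabilities Numeric length-6 positive vector in the order
#'   AC, AG, AT, CG, CT, GT.
#' @return A list with class `rev_params`.
#' @export
rev_params <- function(frequencies = rep(0.25, 4),
                       exchangeabilities = rep(1, 6)) {
  frequencies <- as.numeric(frequencies)
  exchangeabilities <- as.numeric(exchangeabilities)
  if (length(frequencies) != 4 || any(frequencies < 0)) {
    abort("frequencies must be 4 non-negative values (A, C, G, T)")
  }
  if (abs(sum(frequencies) - 1) > 1e-8) {
    abort("frequencies must sum to 1")
  }
  if (length(exchangeabilities) != 6 || any(exchangeabilities < 0) ||
      all(exchangeabilities == 0)) {
    abort("exchangeabilities must be 6 non-negative values, not all zero")
  }
  structure(
    list(frequencies = setNames(frequencies, BASES),
         exchangeabilities = setNames(exchangeabilities,
                                      c("AC", "AG", "AT", "CG", "CT", "GT"))),
    class = "rev_params"
  )
}

# Build the scaled 4x4 rate matrix Q from a rev_params object.
rev_rate_matrix <- function(params) {
  pi <- params$frequencies
  s <- params$exchangeabilities
  S <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  S["A", "C"] <- S["C", "A"] <- s["AC"]
  S["A", "G"] <- S["G", "A"] <- s["AG"]
  S["A", "T"] <- S["T", "A"] <- s["AT"]
  S["C", "G"] <- S["G", "C"] <- s["CG"]
  S["C", "T"] <- S["T", "C"] <- s["CT"]
  S["G", "T"] <- S["T", "G"] <- s["GT"]
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (rate <= 0) abort("degenerate REV parameters: zero total rate")
  Q / rate
}

# Transition probability matrix P(d) = expm(Q d) via symmetric
# eigendecomposition (Q is reversible). Frequencies of exactly zero are
# handled by restricting to the support.
rev_transition_matrix <- function(params, d) {
  pi <- params$frequencies
  keep <- pi > 0
  P <- diag(4)
  dimnames(P) <- list(BASES, BASES)
  if (d == 0) return(P)
  if (sum(keep) == 1) {
    # absorbing composition: the single allowed base never changes
    return(P)
  }
  pik <- pi[keep] / sum(pi[keep])
  Qfull <- rev_rate_matrix_sub(params, keep)
  sq <- sqrt(pik)
  B <- diag(sq) %*% Qfull %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  Pk <- diag(1 / sq) %*% eig$vectors %*% diag(exp(eig$values * d)) %*%
    t(eig$vectors) %*% diag(sq)
  Pk[Pk < 0] <- 0
  Pk <- Pk / rowSums(Pk)
  P[keep, keep] <- Pk
  P[!keep, ] <- 0
  P[cbind(which(!keep), which(!keep))] <- 1
  P
}

# Rate matrix restricted to bases with non-zero frequency, rescaled so
# that one unit of d is one expected substitution per site on the
# restricted composition.
rev_rate_matrix_sub <- function(params, keep) {
  pi <- params$frequencies
  s <- params$exchangeabilities
  S <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  S["A", "C"] <- S["C", "A"] <- s["AC"]
  S["A", "G"] <- S["G", "A"] <- s["AG"]
  S["A", "T"] <- S["T", "A"] <- s["AT"]
  S["C", "G"] <- S["G", "C"] <- s["CG"]
  S["C", "T"] <- S["T", "C"] <- s["CT"]
  S["G", "T"] <- S["T", "G"] <- s["GT"]
  pik <- pi[keep] / sum(pi[keep])
  Q <- S[keep, keep, drop = FALSE] %*% diag(pik, nrow = sum(keep))
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pik * diag(Q))
  if (rate <= 0) abort("degenerate REV parameters on restricted composition")
  Q / rate
}

# 4x4 site-pattern count matrix from two aligned character sequences.
# Columns containing non-ACGT symbols are dropped (with a warning when
# requested).
alignment_count_matrix <- function(seq1, seq2, warn_non_acgt = TRUE) {
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  if (length(a) != length(b)) abort("aligned sequences must have equal length")
  ok <- a %in% BASES & b %in% BASES
  if (!all(ok)) {
    if (warn_non_acgt) {
      warn(sprintf("dropping %d alignment columns with non-ACGT symbols",
                   sum(!ok)))
    }
    a <- a[ok]
    b <- b[ok]
  }
  tab <- table(factor(a, levels = BASES), factor(b, levels = BASES))
  matrix(as.numeric(tab), 4, 4, dimnames = list(BASES, BASES))
}
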