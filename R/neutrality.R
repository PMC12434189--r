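# Neutrality tests: Tajima's D and Fu's Fs.

#' Number of segregating sites
#' @param aln a gap-filtered `alignment`
#' @return count of columns with two or more states
#' @export
segregating_sites <- function(aln) {
  mat <- aln$mat
  sum(vapply(seq_len(ncol(mat)), function(j) length(unique(mat[, j])) > 1L, logical(1)))
}

#' Normalizing constants for Tajima's D
#'
#' The standard constants a1, a2, b1, b2, c1, c2, e1, e2 as functions of the
#' sample size n.
#'
#' @param n sample size (>= 2)
#' @return named list of constants
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-difference estimator of theta
#' (`k`, mean pairwise differences) and the Watterson estimator (`S/a1`):
#' `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))`. Negative values indicate an
#' excess of rare variants, as after a recent expansion.
#'
#' @param n sample size (>= 4)
#' @param S number of segregating sites
#' @param k mean number of pairwise differences
#' @return D, or `NA` (with a warning) when `S = 0`
#' @export
tajimas_d <- function(n, S, k) {
  if (n < 4) stop_erodiv("erodiv_precondition_error", "Tajima's D requires n >= 4")
  if (S == 0) {
    warning("Tajima's D undefined for S = 0; returning NA")
    return(NA_real_)
  }
  cc <- tajima_constants(n)
  (k - S / cc$a1) / sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
}

#' Log probabilities of the number of alleles under the Ewens sampling formula
#'
#' `log P(K = k) = log|s(n,k)| + k log(theta) - sum_{i=0}^{n-1} log(theta+i)`
#' for k = 1..n, with unsigned Stirling numbers of the first kind computed by
#' the recurrence `|s(n,k)| = |s(n-1,k-1)| + (n-1)|s(n-1,k)|` entirely in log
#' space, so the result is stable up to n in the hundreds.
#'
#' @param n sample size (>= 1)
#' @param theta scaled mutation parameter (> 0)
#' @return numeric vector of length n of log probabilities
#' @export
ewens_log_pmf <- function(n, theta) {
  stopifnot(n >= 1)
  if (theta <= 0) stop_erodiv("erodiv_domain_error", "theta must be > 0")
  ls <- 0  # log |s(1,1)|
  if (n > 1) {
    for (m in 2:n) {
      left <- c(-Inf, ls)                  # |s(m-1, k-1)|
      right <- c(ls + log(m - 1), -Inf)    # (m-1) |s(m-1, k)|
      ls <- logspace_add(left, right)
    }
  }
  k <- seq_len(n)
  ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
}

#' Fu's Fs
#'
#' With `S' = P(K >= k_alleles | theta = theta_pi)` under the Ewens sampling
#' formula, `Fs = ln(S'/(1 - S'))`. `theta_pi` is the pairwise-difference
#' estimator of theta (mean pairwise differences). Strongly negative values
#' indicate an excess of rare haplotypes, as after a recent expansion.
#'
#' @param n sample size (>= 2)
#' @param k_alleles observed number of distinct haplotypes (1..n)
#' @param theta_pi mean pairwise differences (> 0); `0` (monomorphic data)
#'   returns `NA` with a warning
#' @return Fs; `+Inf` sentinel when the tail probability is numerically 1
#' @export
fus_fs <- function(n, k_alleles, theta_pi) {
  stopifnot(n >= 2, k_alleles >= 1, k_alleles <= n)
  if (theta_pi == 0) {
    warning("Fu's Fs undefined for monomorphic data (theta_pi = 0); returning NA")
    return(NA_real_)
  }
  logp <- ewens_log_pmf(n, theta_pi)
  logSp <- logsumexp(logp[k_alleles:n])
  if (logSp >= 0 || 1 - exp(logSp) < 1e-15) return(Inf)
  logSp - log1p(-exp(logSp))
}

#' One-stop neutrality summary for an alignment
#'
#' Computes S, k, pi, haplotype count, Tajima's D and Fu's Fs in one call.
#'
#' @param aln gap-filtered `alignment` with n >= 4
#' @return named list
#' @export
neutrality_tests <- function(aln) {
  nd <- nucleotide_diversity(aln)
  S <- segregating_sites(aln)
  seqs <- apply(aln$mat, 1L, paste0, collapse = "")
  k_alleles <- length(unique(seqs))
  D <- if (S > 0) tajimas_d(nd$n, S, nd$k) else NA_real_
  Fs <- if (nd$k > 0) fus_fs(nd$n, k_alleles, nd$k) else NA_real_
  list(n = nd$n, S = S, k = nd$k, pi = nd$pi, k_alleles = k_alleles,
       tajimas_d = D, fus_fs = Fs, theta_pi = nd$k)
}
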