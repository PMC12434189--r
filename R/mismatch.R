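# Mismatch distributions and the sudden-expansion demographic model.
#
# Time is measured in mutational units: 1 unit = 1/(2u) generations, so the
# number of differences between a pair of sequences that coalesced t units
# ago is Poisson(t). Under the sudden-expansion model the population had
# scaled size theta0 before the expansion (tau units ago) and theta1 after,
# so the pair coalescence density is
#   f(t) = (1/theta1) exp(-t/theta1)                          t <  tau
#   f(t) = exp(-tau/theta1) (1/theta0) exp(-(t-tau)/theta0)   t >= tau

new_mismatch <- function(freq, n_pairs = NULL) {
  names(freq) <- 0:(length(freq) - 1)
  structure(list(freq = freq, j_max = length(freq) - 1L, n_pairs = n_pairs),
            class = "mismatch_distribution")
}

#' @export
print.mismatch_distribution <- function(x, ...) {
  cat(sprintf("<mismatch_distribution> classes 0..%d%s\n", x$j_max,
              if (is.null(x$n_pairs)) "" else sprintf(" (%d pairs)", x$n_pairs)))
  invisible(x)
}

#' Observed mismatch distribution
#'
#' Relative frequency of pairwise difference counts over all C(n,2) pairs.
#'
#' @param aln a gap-filtered `alignment` with n >= 2
#' @return a `mismatch_distribution` (frequencies sum to 1)
#' @export
observed_mismatch <- function(aln) {
  n <- n_samples(aln)
  if (n < 2) stop_erodiv("erodiv_precondition_error", "need at least 2 sequences")
  d <- pairwise_difference_matrix(aln)
  dl <- d[lower.tri(d)]
  mismatch_from_pairs(dl)
}

mismatch_from_pairs <- function(dl) {
  j_max <- max(dl)
  cnt <- tabulate(dl + 1L, nbins = j_max + 1L)
  new_mismatch(cnt / length(dl), n_pairs = length(dl))
}

#' Expected mismatch distribution under sudden expansion
#'
#' `F_j = integral Pois(j; t) f(t) dt` with the piecewise-exponential pair
#' coalescence density above. `method = "quadrature"` integrates the
#' generative density numerically (the reference route);
#' `method = "analytic"` evaluates the same integral in closed form via
#' regularized incomplete gamma functions and a Poisson-geometric
#' convolution (fast, used inside fitting loops). When `theta0 = theta1` or
#' `tau = 0` the distribution is geometric:
#' `F_j = theta^j / (1+theta)^(j+1)`.
#'
#' @param tau expansion age in mutational units (>= 0)
#' @param theta0,theta1 scaled sizes before/after expansion, `theta1 >= theta0 > 0`
#' @param j_max largest difference class to evaluate
#' @param method "quadrature" or "analytic"
#' @return a `mismatch_distribution` of raw probabilities (tail mass beyond
#'   `j_max` is not folded back in)
#' @export
expected_mismatch <- function(tau, theta0, theta1, j_max,
                              method = c("quadrature", "analytic")) {
  method <- match.arg(method)
  if (tau < 0 || theta0 <= 0 || theta1 < theta0)
    stop_erodiv("erodiv_domain_error", "need tau >= 0 and theta1 >= theta0 > 0")
  f <- switch(method,
    quadrature = expected_mismatch_quad(tau, theta0, theta1, j_max),
    analytic = expected_mismatch_analytic(tau, theta0, theta1, j_max))
  new_mismatch(f)
}

expected_mismatch_quad <- function(tau, theta0, theta1, j_max) {
  vapply(0:j_max, function(j) {
    p1 <- if (tau > 0) {
      stats::integrate(function(t) stats::dpois(j, t) * exp(-t / theta1) / theta1,
                       0, tau, abs.tol = 1e-10, rel.tol = 1e-10)$value
    } else 0
    p2 <- exp(-tau / theta1) *
      stats::integrate(function(s) stats::dpois(j, tau + s) * exp(-s / theta0) / theta0,
                       0, Inf, abs.tol = 1e-10, rel.tol = 1e-10)$value
    p1 + p2
  }, numeric(1))
}

expected_mismatch_analytic <- function(tau, theta0, theta1, j_max) {
  j <- 0:j_max
  # geometric kernels theta^j / (1+theta)^(j+1)
  g0 <- exp(j * log(theta0) - (j + 1) * log1p(theta0))
  g1 <- exp(j * log(theta1) - (j + 1) * log1p(theta1))
  piece1 <- g1 * stats::pgamma(tau * (1 + 1 / theta1), shape = j + 1)
  dp <- stats::dpois(j, tau)   # tau^i/i! e^-tau
  piece2 <- exp(-tau / theta1) *
    vapply(j, function(jj) sum(dp[1:(jj + 1)] * g0[(jj:0) + 1]), numeric(1))
  piece1 + piece2
}

#' Harpending's raggedness index
#'
#' Sum of squared successive differences of the mismatch spectrum over the
#' observed classes 1..j_max. Smooth unimodal (expansion-like) spectra give
#' small values.
#'
#' @param obs a `mismatch_distribution` with `j_max >= 1`
#' @return r >= 0
#' @export
raggedness <- function(obs) {
  if (obs$j_max < 1) stop_erodiv("erodiv_precondition_error", "raggedness needs j_max >= 1")
  sum(diff(obs$freq)^2)
}

ssd_between <- function(obs_freq, exp_freq) sum((obs_freq - exp_freq)^2)

#' Fit the sudden-expansion model to an observed mismatch distribution
#'
#' Minimizes `SSD = sum_j (obs_j - F_j)^2` over `(tau, theta0, theta1)` by a
#' deterministic coarse grid (tau linear on `[0, 2*j_max]`; theta0, theta1
#' log-spaced around the mean pairwise difference) followed by Nelder-Mead
#' refinement from the best grid points.
#'
#' @param obs observed `mismatch_distribution` (from >= 3 sequences with at
#'   least one variable site, i.e. `j_max >= 1`)
#' @param n number of sequences behind `obs` (stored for the bootstrap)
#' @param control list of optional knobs: `n_tau`, `n_theta` (grid sizes),
#'   `n_refine` (grid points refined), `maxit`
#' @return a `mismatch_fit`: list with `tau`, `theta0`, `theta1`, `ssd`,
#'   `raggedness`, `j_max`, `n`, `convergence`, and `p_ssd`/`p_raggedness`
#'   slots filled by [mismatch_bootstrap_p()]
#' @export
fit_sudden_expansion <- function(obs, n, control = list()) {
  if (obs$j_max < 1) stop_erodiv("erodiv_precondition_error",
    "cannot fit the expansion model to a monomorphic sample")
  n_tau <- control$n_tau %||% 15L
  n_theta <- control$n_theta %||% 8L
  n_refine <- control$n_refine %||% 3L
  maxit <- control$maxit %||% 2000L
  jm <- obs$j_max
  of <- obs$freq
  k_hat <- sum((0:jm) * of)
  obj_raw <- function(tau, th0, th1)
    ssd_between(of, expected_mismatch_analytic(tau, th0, th1, jm))
  taus <- seq(0, 2 * jm, length.out = n_tau)
  th0s <- exp(seq(log(1e-3), log(max(k_hat, 1e-2)), length.out = n_theta))
  th1s <- exp(seq(log(max(k_hat, 1)), log(1e4), length.out = n_theta))
  grid <- expand.grid(tau = taus, th0 = th0s, th1 = th1s)
  grid <- grid[grid$th1 >= grid$th0, , drop = FALSE]
  vals <- mapply(obj_raw, grid$tau, grid$th0, grid$th1)
  top <- grid[order(vals)[seq_len(min(n_refine, nrow(grid)))], , drop = FALSE]
  # unconstrained parametrization: tau = st^2, theta0 = exp(l0),
  # theta1 = theta0 + exp(ld)
  obj_par <- function(p) obj_raw(p[1]^2, exp(p[2]), exp(p[2]) + exp(p[3]))
  best <- NULL
  for (i in seq_len(nrow(top))) {
    p0 <- c(sqrt(top$tau[i]), log(top$th0[i]),
            log(max(top$th1[i] - top$th0[i], 1e-6)))
    fit <- stats::optim(p0, obj_par, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- best$par
  structure(list(tau = p[1]^2, theta0 = exp(p[2]), theta1 = exp(p[2]) + exp(p[3]),
                 ssd = best$value, raggedness = raggedness(obs),
                 j_max = jm, n = n, obs = obs,
                 convergence = best$convergence,
                 p_ssd = NA_real_, p_raggedness = NA_real_),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("<mismatch_fit> tau=%.4g theta0=%.4g theta1=%.4g SSD=%.3g r=%.4g\n",
              x$tau, x$theta0, x$theta1, x$ssd, x$raggedness))
  if (!is.na(x$p_ssd))
    cat(sprintf("  p(SSD)=%.3f p(raggedness)=%.3f\n", x$p_ssd, x$p_raggedness))
  invisible(x)
}

#' Parametric bootstrap p-values for the mismatch goodness-of-fit
#'
#' Simulates `B` coalescent samples of `n` sequences under the fitted
#' `(tau, theta0, theta1)` (n-lineage piecewise-constant coalescent, Poisson
#' mutations under infinite sites), refits the expansion model to each
#' replicate, and reports the proportion of replicates whose SSD (and
#' raggedness) is at least the observed value.
#'
#' @param fit a `mismatch_fit`
#' @param n sample size to simulate (defaults to `fit$n`)
#' @param B number of bootstrap replicates (>= 100)
#' @param seed RNG seed (required for reproducibility)
#' @param control fitting control passed to [fit_sudden_expansion()]
#'   (defaults to a lighter grid than the primary fit)
#' @return the `mismatch_fit` with `p_ssd` and `p_raggedness` filled in
#' @export
mismatch_bootstrap_p <- function(fit, n = fit$n, B = 1000L, seed,
                                 control = list(n_tau = 8L, n_theta = 5L,
                                                n_refine = 1L, maxit = 300L)) {
  if (B < 100) stop_erodiv("erodiv_precondition_error", "bootstrap needs B >= 100")
  if (missing(seed)) stop_erodiv("erodiv_precondition_error", "seed is required")
  set.seed(seed)
  ssd_b <- rag_b <- numeric(B)
  for (b in seq_len(B)) {
    spec <- sim_mismatch_spectrum(n, fit$tau, fit$theta0, fit$theta1)
    if (spec$j_max < 1) {            # degenerate monomorphic replicate
      ssd_b[b] <- 0; rag_b[b] <- 0
      next
    }
    rfit <- fit_sudden_expansion(spec, n, control = control)
    ssd_b[b] <- rfit$ssd
    rag_b[b] <- raggedness(spec)
  }
  fit$p_ssd <- mean(ssd_b >= fit$ssd)
  fit$p_raggedness <- mean(rag_b >= fit$raggedness)
  fit$B <- B
  fit$seed <- seed
  fit
}
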