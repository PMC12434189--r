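# Population structure: pairwise difference matrices, AMOVA-based Phi-ST,
# geographic distances and the Mantel isolation-by-distance test.

#' Pairwise difference matrix
#'
#' Entry (i, j) is the number of sites at which sequences i and j differ.
#' Computed with one-hot matrix products, so it is fast even for hundreds of
#' sequences.
#'
#' @param aln an `alignment` with n >= 2
#' @return symmetric integer matrix with zero diagonal, labeled by sample id
#' @export
pairwise_difference_matrix <- function(aln) {
  mat <- aln$mat
  n <- nrow(mat); L <- ncol(mat)
  states <- unique(as.vector(mat))
  matches <- matrix(0, n, n)
  for (s in states) {
    M <- (mat == s) * 1
    matches <- matches + tcrossprod(M)
  }
  d <- L - matches
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

# two-level AMOVA sums of squares from a squared-distance matrix and a
# locality factor; returns variance components (Excoffier et al. framework)
amova_components2 <- function(d, pop) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ss_total <- sum(d[lower.tri(d)]) / N
  ss_within <- 0
  sizes <- numeric(P)
  for (i in seq_len(P)) {
    idx <- which(pop == pops[i])
    sizes[i] <- length(idx)
    if (length(idx) > 1) {
      dd <- d[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(dd[lower.tri(dd)]) / length(idx)
    }
  }
  ss_among <- ss_total - ss_within
  df_among <- P - 1
  df_within <- N - P
  ms_within <- if (df_within > 0) ss_within / df_within else 0
  ms_among <- if (df_among > 0) ss_among / df_among else 0
  n_c <- (N - sum(sizes^2) / N) / df_among
  sigma_b <- ms_within
  sigma_a <- (ms_among - ms_within) / n_c
  list(sigma_a = sigma_a, sigma_b = sigma_b,
       ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
       df_among = df_among, df_within = df_within,
       phi_st = sigma_a / (sigma_a + sigma_b))
}

#' Phi-ST between two localities
#'
#' AMOVA-based fixation index computed from pairwise sequence differences:
#' the proportion of molecular variance among the two localities. The raw
#' value is returned and may be slightly negative.
#'
#' @param dm pairwise difference matrix (see [pairwise_difference_matrix()])
#' @param membershipA,membershipB sample ids (labels of `dm`) in each locality
#' @return Phi-ST, or `NA` with a warning when all distances are zero
#' @export
phi_st_pair <- function(dm, membershipA, membershipB) {
  ids <- c(membershipA, membershipB)
  if (length(ids) < 2) stop_erodiv("erodiv_precondition_error", "need >= 2 samples")
  d <- dm[ids, ids, drop = FALSE]
  if (all(d == 0)) {
    warning("Phi-ST undefined: both localities monomorphic and identical")
    return(NA_real_)
  }
  pop <- rep(c("A", "B"), c(length(membershipA), length(membershipB)))
  amova_components2(d, pop)$phi_st
}

#' Pairwise Phi-ST matrix with permutation p-values
#'
#' Computes Phi-ST between every pair of localities and tests each value by
#' permuting individuals between the two localities;
#' `p = (#{permuted >= observed} + 1) / (n_permutations + 1)`.
#'
#' @param dm pairwise difference matrix
#' @param loc locality table covering the labels of `dm`
#' @param n_permutations permutations per pair (default 100000)
#' @param seed RNG seed
#' @return list with `phi_st` and `p` (locality x locality matrices)
#' @export
phi_st_matrix <- function(dm, loc, n_permutations = 100000L, seed) {
  if (!missing(seed)) set.seed(seed)
  ids <- rownames(dm)
  pop <- loc$locality_code[match(ids, loc$sample_id)]
  locs <- sort(unique(pop))
  P <- length(locs)
  phi <- p <- matrix(NA_real_, P, P, dimnames = list(locs, locs))
  diag(phi) <- 0
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    a <- ids[pop == locs[i]]; b <- ids[pop == locs[j]]
    if (length(a) + length(b) < 2) next  # flagged cell stays NA
    sub <- dm[c(a, b), c(a, b), drop = FALSE]
    grp <- rep(c(0L, 1L), c(length(a), length(b)))
    if (all(sub == 0)) { phi[i, j] <- phi[j, i] <- NA_real_; next }
    obs <- amova_components2(sub, grp)$phi_st
    cnt <- 0L
    for (r in seq_len(n_permutations)) {
      pg <- sample(grp)
      if (amova_components2(sub, pg)$phi_st >= obs) cnt <- cnt + 1L
    }
    phi[i, j] <- phi[j, i] <- obs
    p[i, j] <- p[j, i] <- (cnt + 1) / (n_permutations + 1)
  }
  list(phi_st = phi, p = p)
}

#' Analysis of molecular variance
#'
#' Two-level decomposition (among / within localities) by default; a
#' three-level decomposition (among groups / among localities within groups /
#' within localities) when `groups` maps every locality to a group.
#' Permutation p-values shuffle individuals among localities (and, for the
#' group component, localities among groups). Negative variance components
#' are reported raw with percentages computed on raw components.
#'
#' @param dm pairwise difference matrix
#' @param loc locality table
#' @param groups optional named vector: locality_code -> group label
#' @param n_permutations permutations (default 100000)
#' @param seed RNG seed
#' @return an `amova_result`: data frame of components plus `phi_st` (and
#'   `phi_sc`, `phi_ct` for three-level) and permutation p-values
#' @export
amova <- function(dm, loc, groups = NULL, n_permutations = 100000L, seed) {
  if (!missing(seed)) set.seed(seed)
  ids <- rownames(dm)
  pop <- loc$locality_code[match(ids, loc$sample_id)]
  if (any(is.na(pop))) stop_erodiv("erodiv_join_error", "samples missing from locality table")
  tab <- table(pop)
  if (any(tab == 0)) stop_erodiv("erodiv_schema_error", "locality with zero samples")
  if (length(tab) < 2) stop_erodiv("erodiv_precondition_error", "need >= 2 localities")
  if (is.null(groups)) {
    comp <- amova_components2(dm, pop)
    obs_phi <- comp$phi_st
    cnt <- 0L
    for (r in seq_len(n_permutations)) {
      if (amova_components2(dm, sample(pop))$phi_st >= obs_phi) cnt <- cnt + 1L
    }
    p_phi <- (cnt + 1) / (n_permutations + 1)
    sig <- c(among_localities = comp$sigma_a, within_localities = comp$sigma_b)
    res <- list(components = data.frame(
                  source = names(sig), sigma2 = as.numeric(sig),
                  percent = 100 * as.numeric(sig) / sum(sig)),
                phi_st = obs_phi, p_phi_st = p_phi,
                n_permutations = n_permutations, levels = 2L)
  } else {
    grp_of_pop <- groups[pop]
    if (any(is.na(grp_of_pop))) stop_erodiv("erodiv_schema_error", "groups must cover every locality")
    comp <- amova_components3(dm, pop, grp_of_pop)
    cnt_st <- cnt_sc <- cnt_ct <- 0L
    pops <- unique(pop)
    for (r in seq_len(n_permutations)) {
      c1 <- amova_components3(dm, sample(pop), grp_of_pop)
      # note: permuting individuals tests Phi_ST / Phi_SC
      if (c1$phi_st >= comp$phi_st) cnt_st <- cnt_st + 1L
      if (c1$phi_sc >= comp$phi_sc) cnt_sc <- cnt_sc + 1L
      perm_groups <- stats::setNames(sample(groups[pops]), pops)
      c2 <- amova_components3(dm, pop, perm_groups[pop])
      if (c2$phi_ct >= comp$phi_ct) cnt_ct <- cnt_ct + 1L
    }
    sig <- c(among_groups = comp$sigma_a, among_localities_within_groups = comp$sigma_b,
             within_localities = comp$sigma_c)
    res <- list(components = data.frame(
                  source = names(sig), sigma2 = as.numeric(sig),
                  percent = 100 * as.numeric(sig) / sum(sig)),
                phi_st = comp$phi_st, phi_sc = comp$phi_sc, phi_ct = comp$phi_ct,
                p_phi_st = (cnt_st + 1) / (n_permutations + 1),
                p_phi_sc = (cnt_sc + 1) / (n_permutations + 1),
                p_phi_ct = (cnt_ct + 1) / (n_permutations + 1),
                n_permutations = n_permutations, levels = 3L)
  }
  structure(res, class = "amova_result")
}

amova_components3 <- function(d, pop, grp) {
  N <- length(pop)
  pops <- unique(pop); P <- length(pops)
  grps <- unique(grp); G <- length(grps)
  grp_of <- grp[match(pops, pop)]
  ss_total <- sum(d[lower.tri(d)]) / N
  ss_wp <- 0
  n_p <- numeric(P)
  for (i in seq_len(P)) {
    idx <- which(pop == pops[i])
    n_p[i] <- length(idx)
    if (n_p[i] > 1) {
      dd <- d[idx, idx, drop = FALSE]
      ss_wp <- ss_wp + sum(dd[lower.tri(dd)]) / n_p[i]
    }
  }
  ss_wg <- 0  # within groups (pooled)
  n_g <- numeric(G)
  for (g in seq_len(G)) {
    idx <- which(grp == grps[g])
    n_g[g] <- length(idx)
    dd <- d[idx, idx, drop = FALSE]
    ss_wg <- ss_wg + sum(dd[lower.tri(dd)]) / n_g[g]
  }
  ss_ag <- ss_total - ss_wg          # among groups
  ss_ap <- ss_wg - ss_wp             # among pops within groups
  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  ms_wp <- ss_wp / df_wp
  ms_ap <- if (df_ap > 0) ss_ap / df_ap else 0
  ms_ag <- ss_ag / df_ag
  sum_npsq_over_ng <- sum(vapply(seq_len(G), function(g) {
    sel <- grp_of == grps[g]
    sum(n_p[sel]^2) / n_g[g]
  }, numeric(1)))
  n1 <- (N - sum_npsq_over_ng) / df_ap
  n2 <- (sum_npsq_over_ng - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(n_g^2) / N) / df_ag
  sigma_c <- ms_wp
  sigma_b <- if (df_ap > 0) (ms_ap - sigma_c) / n1 else 0
  sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c
  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       phi_st = (sigma_a + sigma_b) / tot,
       phi_sc = sigma_b / (sigma_b + sigma_c),
       phi_ct = sigma_a / tot)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  print(x$components, row.names = FALSE)
  cat(sprintf("Phi_ST = %.4f (p = %.4g, %d permutations)\n",
              x$phi_st, x$p_phi_st, x$n_permutations))
  invisible(x)
}

#' Geographic distance matrix between localities
#'
#' `mode = "euclidean-degrees"` (default) is the plain Euclidean distance on
#' decimal-degree coordinates, the convention of simple distance-matrix
#' tools; `mode = "great-circle"` is the haversine distance in km and is the
#' geodetically correct choice.
#'
#' @param loc locality table
#' @param mode "euclidean-degrees" or "great-circle"
#' @return symmetric matrix labeled by locality code
#' @export
geographic_distance_matrix <- function(loc, mode = c("euclidean-degrees", "great-circle")) {
  mode <- match.arg(mode)
  u <- locality_coords(loc)
  if (nrow(u) < 2) stop_erodiv("erodiv_precondition_error", "need >= 2 localities")
  P <- nrow(u)
  d <- matrix(0, P, P, dimnames = list(u$locality_code, u$locality_code))
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    d[i, j] <- d[j, i] <- switch(mode,
      "euclidean-degrees" = sqrt((u$latitude[i] - u$latitude[j])^2 +
                                 (u$longitude[i] - u$longitude[j])^2),
      "great-circle" = geosphere::distHaversine(
        c(u$longitude[i], u$latitude[i]), c(u$longitude[j], u$latitude[j])) / 1000)
  }
  d
}

#' Linearize a fixation-index matrix as Fst/(1 - Fst)
#'
#' Entries within `1e-9` of 1 (or above) are capped at a large finite
#' sentinel (`1e9`) with a warning rather than returned as infinity.
#'
#' @param m matrix of Fst-like values
#' @return transformed matrix
#' @export
linearize_fst <- function(m) {
  out <- m / (1 - m)
  hit <- !is.na(m) & m >= 1 - 1e-9
  if (any(hit)) {
    warning(sprintf("%d Fst value(s) >= 1 - 1e-9 capped at sentinel 1e9", sum(hit)))
    out[hit] <- 1e9
  }
  diag(out) <- 0
  out
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation of the lower triangles of a genetic and a geographic
#' distance matrix, with a one-tailed (upper) permutation test — isolation
#' by distance predicts a positive correlation. Backed by `vegan::mantel`;
#' the genetic matrix is typically linearized Phi-ST ([linearize_fst()]).
#'
#' @param genetic,geographic distance matrices sharing labels and order
#' @param n_permutations permutations (default 10000)
#' @param seed RNG seed
#' @return list with `R`, `p`, `n_permutations`
#' @export
mantel_ibd <- function(genetic, geographic, n_permutations = 10000L, seed) {
  if (!identical(rownames(genetic), rownames(geographic)))
    stop_erodiv("erodiv_join_error", "matrix labels do not match")
  if (nrow(genetic) < 3) stop_erodiv("erodiv_precondition_error", "need >= 3 localities")
  if (!missing(seed)) set.seed(seed)
  res <- vegan::mantel(stats::as.dist(genetic), stats::as.dist(geographic),
                       method = "pearson", permutations = n_permutations)
  list(R = unname(res$statistic), p = res$signif, n_permutations = n_permutations)
}
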