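# Shared fixtures and independent brute-force oracles. The oracles here are
# deliberately naive (double loops, set operations) so they stay independent
# of the implementation paths they check.

aln_of <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  alignment_from_strings(seqs)
}

rand_aln <- function(n, L, states = c("A", "C", "G", "T")) {
  m <- matrix(sample(states, n * L, replace = TRUE), n, L)
  rownames(m) <- paste0("s", seq_len(n))
  alignment_from_strings(apply(m, 1, paste0, collapse = ""))
}

# O(n^2 L) pairwise difference count
brute_diffs <- function(aln) {
  m <- as.matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(m[i, ] != m[j, ])
  }
  d
}

brute_pi <- function(aln) {
  d <- brute_diffs(aln)
  n <- nrow(d)
  mean_k <- sum(d[upper.tri(d)]) / choose(n, 2)
  list(k = mean_k, pi = mean_k / ncol(as.matrix(aln)))
}

brute_S <- function(aln) {
  m <- as.matrix(aln)
  sum(apply(m, 2, function(col) length(unique(col)) > 1))
}

brute_hd <- function(aln) {
  m <- as.matrix(aln)
  seqs <- apply(m, 1, paste0, collapse = "")
  n <- length(seqs)
  p <- table(seqs) / n
  n / (n - 1) * (1 - sum(p^2))
}

brute_mismatch <- function(aln) {
  d <- brute_diffs(aln)
  dl <- d[lower.tri(d)]
  tab <- tabulate(dl + 1, nbins = max(dl) + 1)
  tab / length(dl)
}

# simple locality table over an alignment's samples
loc_of <- function(aln, codes, lat = NULL, lon = NULL) {
  u <- sort(unique(codes))
  if (is.null(lat)) lat <- seq(25, 26, length.out = length(u))[match(codes, u)]
  if (is.null(lon)) lon <- seq(105, 106, length.out = length(u))[match(codes, u)]
  data.frame(sample_id = sample_ids(aln), locality_code = codes,
             latitude = lat, longitude = lon)
}

toy_raster <- function(values, xll = 0, yll = 0, cellsize = 1) {
  suitability_raster(values, xll, yll, cellsize)
}

quiet_cfg <- function(seed, ...) sim_config(seed = seed, ...)
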