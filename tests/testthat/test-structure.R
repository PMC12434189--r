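test_that("pairwise difference matrix equals the brute-force loop", {
  expect_equal(unname(pairwise_difference_matrix(aln_of(s1 = "ACGTA", s2 = "TGCAT"))[1, 2]), 5)
  expect_equal(unname(pairwise_difference_matrix(aln_of(s1 = "ACGTA", s2 = "ACGTA"))[1, 2]), 0)
  set.seed(61)
  for (rep in 1:15) {
    aln <- rand_aln(sample(3:12, 1), sample(4:30, 1))
    d <- pairwise_difference_matrix(aln)
    expect_equal(d, brute_diffs(aln), tolerance = 1e-12)
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0))
  }
})

test_that("Phi-ST: sorted, identical and hand-computed toy cases", {
  sorted <- aln_of(a1 = "AAAA", a2 = "AAAA", a3 = "AAAA",
                   b1 = "TTTT", b2 = "TTTT", b3 = "TTTT")
  dm <- pairwise_difference_matrix(sorted)
  expect_equal(phi_st_pair(dm, c("a1", "a2", "a3"), c("b1", "b2", "b3")), 1)

  same <- aln_of(a1 = "AAAA", a2 = "TTTT", b1 = "AAAA", b2 = "TTTT")
  dm2 <- pairwise_difference_matrix(same)
  expect_lte(phi_st_pair(dm2, c("a1", "a2"), c("b1", "b2")), 0)

  mono <- aln_of(a1 = "AAAA", a2 = "AAAA", b1 = "AAAA")
  dm3 <- pairwise_difference_matrix(mono)
  expect_warning(ph <- phi_st_pair(dm3, c("a1", "a2"), "b1"), "monomorphic")
  expect_true(is.na(ph))

  # 3+3 toy with hand-computed variance components:
  # within-pair sums 2 and 2, between-pair sum 22 =>
  # SS_total = 26/6, SS_within = 4/3, SS_among = 3
  # MS_within = 1/3 = sigma_b; n_c = 3; sigma_a = (3 - 1/3)/3 = 8/9
  # Phi_ST = (8/9) / (8/9 + 1/3) = 8/11
  toy <- aln_of(a1 = "AAAA", a2 = "AAAT", a3 = "AAAA",
                b1 = "TTAA", b2 = "TTAT", b3 = "TTAA")
  dmt <- pairwise_difference_matrix(toy)
  expect_equal(phi_st_pair(dmt, c("a1", "a2", "a3"), c("b1", "b2", "b3")),
               8 / 11, tolerance = 1e-12)
})

test_that("Phi-ST matrix is seeded, symmetric and p-values use +1 correction", {
  set.seed(62)
  aln <- rand_aln(18, 40, states = c("A", "G"))
  loc <- loc_of(aln, rep(c("L1", "L2", "L3"), each = 6))
  dm <- pairwise_difference_matrix(aln)
  r1 <- phi_st_matrix(dm, loc, n_permutations = 99, seed = 5)
  r2 <- phi_st_matrix(dm, loc, n_permutations = 99, seed = 5)
  expect_identical(r1, r2)
  expect_identical(r1$phi_st, t(r1$phi_st))
  expect_true(all(diag(r1$phi_st) == 0))
  expect_true(all(r1$p[upper.tri(r1$p)] > 0))   # never exactly 0
  expect_true(all(r1$p[upper.tri(r1$p)] >= 1 / 100))
  # invariant to sample order
  ord <- sample(rownames(dm))
  r3 <- phi_st_matrix(dm[ord, ord], loc, n_permutations = 99, seed = 5)
  expect_equal(r3$phi_st, r1$phi_st, tolerance = 1e-12)

  # fully sorted haplotypes reach the minimal attainable p
  sorted <- aln_of(a1 = "AAAA", a2 = "AAAA", a3 = "AAAA",
                   b1 = "TTTT", b2 = "TTTT", b3 = "TTTT")
  locs <- loc_of(sorted, rep(c("A", "B"), each = 3))
  rs <- phi_st_matrix(pairwise_difference_matrix(sorted), locs,
                      n_permutations = 99, seed = 1)
  expect_equal(rs$phi_st["A", "B"], 1)
  expect_lte(rs$p["A", "B"], 0.2)  # only 2 of 20 label splits reach phi = 1
})

test_that("AMOVA: degenerate compositions, percentage identity, determinism", {
  sorted <- aln_of(a1 = "AAAA", a2 = "AAAA", a3 = "AAAA",
                   b1 = "TTTT", b2 = "TTTT", b3 = "TTTT")
  loc <- loc_of(sorted, rep(c("A", "B"), each = 3))
  am <- amova(pairwise_difference_matrix(sorted), loc, n_permutations = 199, seed = 3)
  expect_equal(am$components$percent[am$components$source == "among_localities"], 100)
  expect_equal(am$phi_st, 1)
  expect_equal(sum(am$components$percent), 100, tolerance = 1e-6)

  ident <- aln_of(a1 = "AAAA", a2 = "TTTT", b1 = "AAAA", b2 = "TTTT")
  loci <- loc_of(ident, rep(c("A", "B"), each = 2))
  ami <- amova(pairwise_difference_matrix(ident), loci, n_permutations = 199, seed = 3)
  expect_lte(ami$components$percent[1], 0)  # raw negative component reported

  set.seed(63)
  aln <- rand_aln(20, 30)
  locr <- loc_of(aln, rep(c("L1", "L2", "L3", "L4"), each = 5))
  dm <- pairwise_difference_matrix(aln)
  a1 <- amova(dm, locr, n_permutations = 199, seed = 11)
  a2 <- amova(dm, locr, n_permutations = 199, seed = 11)
  expect_identical(a1$p_phi_st, a2$p_phi_st)
  expect_equal(sum(a1$components$percent), 100, tolerance = 1e-6)
})

test_that("three-level AMOVA decomposes group-sorted variation onto groups", {
  aln <- aln_of(a1 = "AAAA", a2 = "AAAT", b1 = "AAAA", b2 = "AAAT",
                c1 = "TTTT", c2 = "TTTA", d1 = "TTTT", d2 = "TTTA")
  loc <- loc_of(aln, rep(c("LA", "LB", "LC", "LD"), each = 2))
  groups <- c(LA = "G1", LB = "G1", LC = "G2", LD = "G2")
  am <- amova(pairwise_difference_matrix(aln), loc, groups = groups,
              n_permutations = 199, seed = 2)
  expect_equal(nrow(am$components), 3)
  expect_equal(sum(am$components$percent), 100, tolerance = 1e-6)
  # all divergence lies between the two groups
  expect_gt(am$components$percent[am$components$source == "among_groups"], 50)
  expect_lte(am$phi_ct, 1)
})

test_that("geographic distances: euclidean-on-degrees and haversine", {
  loc <- data.frame(sample_id = c("x", "y"), locality_code = c("P", "Q"),
                    latitude = c(0, 3), longitude = c(0, 4))
  d <- geographic_distance_matrix(loc)
  expect_equal(d["P", "Q"], 5)
  loc2 <- data.frame(sample_id = c("x", "y"), locality_code = c("P", "Q"),
                     latitude = c(0, 0), longitude = c(0, 1))
  gc <- geographic_distance_matrix(loc2, mode = "great-circle")
  # inline haversine oracle for one degree of longitude at the equator
  R <- 6378137 / 1000
  oracle <- 2 * R * asin(sqrt(cos(0) * cos(0) * sin((pi / 180) / 2)^2))
  expect_equal(gc["P", "Q"], oracle, tolerance = 5e-3)
  expect_lt(abs(gc["P", "Q"] - 111.19) / 111.19, 0.005)
  expect_error(geographic_distance_matrix(loc, mode = "nope"))
})

test_that("linearized Fst transform caps near-unity entries", {
  m <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(linearize_fst(m)["A", "B"], 1)
  m[1, 2] <- m[2, 1] <- 1
  expect_warning(lz <- linearize_fst(m), "capped")
  expect_equal(lz["A", "B"], 1e9)
})

test_that("Mantel test: perfect correlation, determinism, null calibration", {
  set.seed(64)
  P <- 8
  g <- matrix(0, P, P, dimnames = list(paste0("L", 1:P), paste0("L", 1:P)))
  g[upper.tri(g)] <- runif(choose(P, 2))
  g <- g + t(g)
  r <- mantel_ibd(g, g, n_permutations = 99, seed = 1)
  expect_equal(r$R, 1)
  r2 <- mantel_ibd(g, g, n_permutations = 99, seed = 1)
  expect_identical(r, r2)
  colnames(g)[1] <- rownames(g)[1] <- "other"
  expect_error(mantel_ibd(g, diag(P)), class = "erodiv_join_error")

  # independent random matrices: rejection at 5% stays within binomial bounds
  set.seed(65)
  n_rep <- 50
  pv <- vapply(seq_len(n_rep), function(i) {
    a <- b <- matrix(0, 6, 6, dimnames = list(paste0("L", 1:6), paste0("L", 1:6)))
    a[upper.tri(a)] <- runif(15); b[upper.tri(b)] <- runif(15)
    mantel_ibd(a + t(a), b + t(b), n_permutations = 199, seed = i)$p
  }, numeric(1))
  expect_lte(sum(pv < 0.05), qbinom(0.995, n_rep, 0.05))
  expect_gt(mean(pv), 0.25)
  expect_lt(mean(pv), 0.75)
})
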