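make_erosion_fixture <- function() {
  aln <- aln_of(s1 = "AAAA", s2 = "AAAA", s3 = "AAAT", s4 = "AATT",
                s5 = "AAAA", s6 = "AAAT", s7 = "GGGG", s8 = "GGGG")
  loc <- loc_of(aln, c("L1", "L1", "L1", "L2", "L2", "L2", "L3", "L3"))
  list(aln = aln, loc = loc, asn = collapse_haplotypes(aln, loc))
}

test_that("erosion identities: all-survive and none-survive", {
  fx <- make_erosion_fixture()
  scen <- scenario_spec("2050", "RCP2.6")
  all_surv <- setNames(rep(TRUE, 3), c("L1", "L2", "L3"))
  rep_all <- erode_diversity(fx$aln, fx$asn, all_surv, scen, fx$loc)
  expect_equal(rep_all$haplotypes_survived, rep_all$haplotypes_total)
  expect_equal(rep_all$hd_survived, brute_hd(fx$aln))
  expect_equal(rep_all$pi_survived, brute_pi(fx$aln)$pi)
  expect_equal(rep_all$proportion_haplotypes_lost, 0)
  expect_equal(rep_all$proportion_pi_lost, 0)

  none <- setNames(rep(FALSE, 3), c("L1", "L2", "L3"))
  rep_none <- erode_diversity(fx$aln, fx$asn, none, scenario_spec("2070", "RCP8.5"), fx$loc)
  expect_equal(rep_none$haplotypes_survived, 0)
  expect_equal(rep_none$hd_survived, 0)
  expect_equal(rep_none$pi_survived, 0)
  expect_equal(rep_none$proportion_localities_lost, 1)

  missing <- setNames(TRUE, "L1")
  expect_error(erode_diversity(fx$aln, fx$asn, missing, scen, fx$loc),
               class = "erodiv_coverage_error")
})

test_that("erosion bookkeeping matches a constructed ground truth", {
  fx <- make_erosion_fixture()
  # lose L3 (sole carrier of GGGG); survivors: s1..s6
  surv <- setNames(c(TRUE, TRUE, FALSE), c("L1", "L2", "L3"))
  rep1 <- erode_diversity(fx$aln, fx$asn, surv, scenario_spec("2050", "RCP4.5"), fx$loc)
  expect_equal(rep1$localities_survived, 2)
  expect_equal(rep1$haplotypes_survived, 3)       # AAAA, AAAT, AATT persist
  expect_equal(rep1$n_survived, 6)
  keep <- paste0("s", 1:6)
  expect_equal(rep1$hd_survived, brute_hd(subset_alignment(fx$aln, keep)))
  expect_equal(rep1$pi_survived, brute_pi(subset_alignment(fx$aln, keep))$pi)
  expect_equal(rep1$proportion_haplotypes_lost, 1 / 4)
  # permuting sample ids within a locality leaves the report unchanged
  loc2 <- fx$loc
  loc2$sample_id[1:3] <- c("s2", "s3", "s1")
  asn2 <- collapse_haplotypes(fx$aln, loc2)
  rep2 <- erode_diversity(fx$aln, asn2, surv, scenario_spec("2050", "RCP4.5"), loc2)
  expect_equal(rep2$haplotypes_survived, rep1$haplotypes_survived)
  expect_equal(rep2$pi_survived, rep1$pi_survived)
})

test_that("single-survivor subsets report zero diversity with a degeneracy flag", {
  aln <- aln_of(s1 = "AAAA", s2 = "TTTT", s3 = "GGGG")
  loc <- loc_of(aln, c("L1", "L2", "L3"))
  asn <- collapse_haplotypes(aln, loc)
  surv <- setNames(c(TRUE, FALSE, FALSE), c("L1", "L2", "L3"))
  rep1 <- erode_diversity(aln, asn, surv, scenario_spec("2070", "RCP6.0"), loc)
  expect_equal(rep1$n_survived, 1)
  expect_equal(rep1$haplotypes_survived, 1)
  expect_equal(rep1$hd_survived, 0)
  expect_equal(rep1$pi_survived, 0)
  expect_true(rep1$degenerate)
})

test_that("survival monotonicity over random nested locality chains", {
  set.seed(81)
  cfg <- quiet_cfg(seed = 303, n = 60, L = 600, n_localities = 8)
  aln <- simulate_expansion_alignment(cfg)
  loc <- simulate_structured_sampling(aln, cfg)
  asn <- collapse_haplotypes(aln, loc)
  locs <- sort(unique(loc$locality_code))
  scen <- scenario_spec("2050", "RCP2.6")
  for (chain in 1:50) {
    ord <- sample(locs)
    sizes <- sort(sample(0:length(locs), 3))
    prev_h <- -1; prev_pi <- -1
    for (s in sizes) {
      surv <- setNames(locs %in% ord[seq_len(s)], locs)
      r <- erode_diversity(aln, asn, surv, scen, loc)
      expect_gte(r$haplotypes_survived, prev_h)
      prev_h <- r$haplotypes_survived
    }
  }
})

test_that("scenario table ordering, duplicates and serialization round-trip", {
  fx <- make_erosion_fixture()
  locs <- c("L1", "L2", "L3")
  reports <- list()
  for (h in c("2050", "2070")) for (p in c("RCP2.6", "RCP4.5", "RCP6.0", "RCP8.5")) {
    surv <- setNames(c(TRUE, h == "2050", p == "RCP2.6"), locs)
    reports[[paste(h, p)]] <- erode_diversity(fx$aln, fx$asn, surv,
                                              scenario_spec(h, p), fx$loc)
  }
  current <- list(pi = brute_pi(fx$aln)$pi, n_haplotypes = 4, hd = brute_hd(fx$aln))
  tab <- scenario_table(reports, current)
  expect_equal(nrow(tab), 9)
  expect_equal(tab$time, c("Current", rep("2050", 4), rep("2070", 4)))
  expect_equal(tab$scenario[2:5], c("RCP2.6", "RCP4.5", "RCP6.0", "RCP8.5"))

  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read.csv(f, colClasses = c(time = "character"))
  expect_equal(back$nucleotide_diversity, tab$nucleotide_diversity, tolerance = 1e-12)
  expect_equal(back$n_haplotypes, tab$n_haplotypes)

  dup <- c(reports, reports[1])
  expect_error(scenario_table(dup, current), class = "erodiv_schema_error")

  single <- scenario_table(list(), current)
  expect_equal(nrow(single), 1)
  expect_equal(single$scenario, "Current")

  fmt <- format_scenario_table(tab)
  expect_match(fmt$nucleotide_diversity[1], "^0\\.[0-9]{5}$")
  expect_match(fmt$haplotype_diversity[1], "^0\\.[0-9]{3}$")
})

test_that("loss percentages are exact divisions on the 0-100 scale", {
  fx <- make_erosion_fixture()
  surv <- setNames(c(TRUE, FALSE, FALSE), c("L1", "L2", "L3"))
  r <- erode_diversity(fx$aln, fx$asn, surv, scenario_spec("2070", "RCP4.5"), fx$loc)
  lp <- loss_percentages(r)
  expect_equal(unname(lp["localities_lost_pct"]), 100 * 2 / 3)
  all_surv <- setNames(rep(TRUE, 3), c("L1", "L2", "L3"))
  r0 <- erode_diversity(fx$aln, fx$asn, all_surv, scenario_spec("2050", "RCP2.6"), fx$loc)
  expect_equal(unname(loss_percentages(r0)), c(0, 0))
})
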