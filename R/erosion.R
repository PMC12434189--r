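# Genetic-erosion accounting: subset sequences to surviving localities and
# quantify losses of haplotypes, haplotype diversity and nucleotide
# diversity per climate scenario.

SCENARIO_HORIZONS <- c("2050", "2070")
SCENARIO_PATHWAYS <- c("RCP2.6", "RCP4.5", "RCP6.0", "RCP8.5")

#' Scenario label
#' @param horizon "2050" or "2070"
#' @param pathway one of "RCP2.6", "RCP4.5", "RCP6.0", "RCP8.5"
#' @return a `scenario_spec` list
#' @export
scenario_spec <- function(horizon, pathway) {
  horizon <- as.character(horizon)
  if (!horizon %in% SCENARIO_HORIZONS || !pathway %in% SCENARIO_PATHWAYS)
    stop_erodiv("erodiv_domain_error", "unknown scenario horizon or pathway")
  structure(list(horizon = horizon, pathway = pathway), class = "scenario_spec")
}

#' Quantify genetic erosion under a survival pattern
#'
#' Samples whose locality loses suitable habitat are removed; haplotype
#' count, Hd and pi are recomputed on the surviving subset (pi from the
#' actual sequences, not haplotype frequencies, so unequal within-haplotype
#' sampling is handled exactly). A haplotype persists iff at least one
#' carrier is in a surviving locality. With zero survivors the zero report
#' is returned; a single-survivor subset reports Hd and pi as 0 with a
#' degeneracy flag.
#'
#' @param aln gap-filtered `alignment`
#' @param assignment [collapse_haplotypes()] result consistent with `aln`
#' @param survival data frame from [locality_survival()] (or named logical
#'   vector per locality) covering every locality in `assignment`
#' @param scenario a `scenario_spec`
#' @param loc locality table
#' @return an `erosion_report` list
#' @export
erode_diversity <- function(aln, assignment, survival, scenario, loc) {
  if (is.data.frame(survival))
    survival <- stats::setNames(survival$survived, survival$locality)
  locs <- colnames(assignment$counts)
  miss <- setdiff(locs, names(survival))
  if (length(miss)) stop_erodiv("erodiv_coverage_error",
    paste0("survival flags missing for localities: ", paste(miss, collapse = ", ")))
  ids <- sample_ids(aln)
  loc_of <- loc$locality_code[match(ids, loc$sample_id)]
  keep <- ids[survival[loc_of]]
  nd_total <- nucleotide_diversity(aln)
  totals <- list(localities = length(locs),
                 haplotypes = length(assignment$haplotype_ids),
                 hd = haplotype_diversity(rowSums(assignment$counts)),
                 pi = nd_total$pi)
  n_surv_loc <- sum(survival[locs])
  degenerate <- FALSE
  if (length(keep) == 0) {
    hap_surv <- 0L; hd_s <- 0; pi_s <- 0
  } else if (length(keep) == 1) {
    hap_surv <- 1L; hd_s <- 0; pi_s <- 0; degenerate <- TRUE
  } else {
    sub_assign <- assignment$assignment[keep]
    hap_surv <- length(unique(sub_assign))
    hd_s <- haplotype_diversity(as.numeric(table(sub_assign)))
    pi_s <- nucleotide_diversity(subset_alignment(aln, keep))$pi
  }
  structure(list(
    scenario = scenario,
    localities_total = totals$localities,
    localities_survived = n_surv_loc,
    haplotypes_total = totals$haplotypes,
    haplotypes_survived = hap_surv,
    n_survived = length(keep),
    hd_survived = hd_s,
    pi_survived = pi_s,
    proportion_localities_lost = 1 - n_surv_loc / totals$localities,
    proportion_haplotypes_lost = 1 - hap_surv / totals$haplotypes,
    proportion_pi_lost = max(0, 1 - pi_s / totals$pi),
    degenerate = degenerate
  ), class = "erosion_report")
}

#' @export
print.erosion_report <- function(x, ...) {
  cat(sprintf("<erosion_report> %s %s: %d/%d localities, %d/%d haplotypes, Hd=%.3f pi=%.5f\n",
              x$scenario$horizon, x$scenario$pathway,
              x$localities_survived, x$localities_total,
              x$haplotypes_survived, x$haplotypes_total, x$hd_survived, x$pi_survived))
  invisible(x)
}

#' Scenario comparison table
#'
#' Rows ordered Current, then 2050 RCP2.6..RCP8.5, then 2070 RCP2.6..RCP8.5;
#' columns: nucleotide diversity, number of haplotypes, haplotype diversity.
#' Values are unrounded; [format_scenario_table()] applies the presentation
#' rounding (pi to 5 decimals, Hd to 3).
#'
#' @param reports list of `erosion_report`, one per (horizon, pathway)
#' @param current overall `DiversitySummary`-style list with `pi`,
#'   `n_haplotypes`, `hd`
#' @return data frame
#' @export
scenario_table <- function(reports, current) {
  keys <- vapply(reports, function(r) paste(r$scenario$horizon, r$scenario$pathway), "")
  if (anyDuplicated(keys)) stop_erodiv("erodiv_schema_error",
    paste0("duplicate scenario: ", keys[duplicated(keys)][1]))
  rows <- list(data.frame(time = "Current", scenario = "Current",
                          nucleotide_diversity = current$pi,
                          n_haplotypes = current$n_haplotypes,
                          haplotype_diversity = current$hd))
  for (h in SCENARIO_HORIZONS) for (p in SCENARIO_PATHWAYS) {
    key <- paste(h, p)
    if (!key %in% keys) next
    r <- reports[[which(keys == key)]]
    rows[[length(rows) + 1]] <- data.frame(time = h, scenario = p,
      nucleotide_diversity = r$pi_survived,
      n_haplotypes = r$haplotypes_survived,
      haplotype_diversity = r$hd_survived)
  }
  do.call(rbind, rows)
}

#' @rdname scenario_table
#' @param tab a scenario table
#' @export
format_scenario_table <- function(tab) {
  tab$nucleotide_diversity <- sprintf("%.5f", tab$nucleotide_diversity)
  tab$haplotype_diversity <- sprintf("%.3f", tab$haplotype_diversity)
  tab
}

#' Percent losses for a scenario
#'
#' Percentages on the 0-100 scale, unrounded (round only at presentation).
#'
#' @param report an `erosion_report`
#' @return named vector: `localities_lost_pct`, `haplotypes_lost_pct`
#' @export
loss_percentages <- function(report) {
  c(localities_lost_pct = 100 * report$proportion_localities_lost,
    haplotypes_lost_pct = 100 * report$proportion_haplotypes_lost)
}
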