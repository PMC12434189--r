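# End-to-end orchestration with a single config and reproducible seeds.

#' Default pipeline configuration
#'
#' Every threshold printed in the study design is a named default: 1 km
#' occurrence thinning, collinearity cutoff r = 0.8, MTSS = 0.3893, 10,000
#' Mantel randomizations, 100,000 Phi-ST/AMOVA permutations, bootstrap
#' B = 1000. Desk-scale runs override the permutation counts explicitly.
#'
#' @param input_dir directory holding a fixture bundle
#'   ([make_fixture_bundle()] layout)
#' @param out_dir output directory
#' @param seed master seed for all stochastic stages
#' @param ... overrides for any default
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(input_dir, out_dir, seed, ...) {
  cfg <- list(
    alignment = file.path(input_dir, "alignment.fasta"),
    localities = file.path(input_dir, "localities.csv"),
    occurrences = file.path(input_dir, "occurrences.csv"),
    raster_current = file.path(input_dir, "suitability_current.asc"),
    rasters_future = NULL,   # named list scenario_key -> path; autodetected if NULL
    input_dir = input_dir,
    out_dir = out_dir,
    mtss = 0.3893,
    thinning_km = 1,
    collinearity_r = 0.8,
    phist_permutations = 100000L,
    amova_permutations = 100000L,
    mantel_permutations = 10000L,
    bootstrap_B = 1000L,
    cell_area_km2 = 1,
    seed = seed)
  over <- list(...)
  cfg[names(over)] <- over
  if (is.null(cfg$rasters_future)) {
    fs <- list.files(input_dir, pattern = "^suitability_2[0-9]{3}_RCP.*\\.asc$")
    keys <- sub("^suitability_(.*)\\.asc$", "\\1", fs)
    cfg$rasters_future <- stats::setNames(as.list(file.path(input_dir, fs)), keys)
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with the [pipeline_config()] fields
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

validate_pipeline_config <- function(cfg) {
  paths <- c(cfg$alignment, cfg$localities, cfg$occurrences, cfg$raster_current,
             unlist(cfg$rasters_future))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop_erodiv("erodiv_config_error",
    paste0("missing input file(s): ", paste(missing, collapse = ", ")))
  if (length(cfg$rasters_future) == 0) stop_erodiv("erodiv_config_error",
    "no future scenario rasters declared or found")
  for (p in c("phist_permutations", "amova_permutations", "mantel_permutations"))
    if (cfg[[p]] < 100) stop_erodiv("erodiv_config_error",
      paste0(p, " must be >= 100"))
  if (is.null(cfg$seed)) stop_erodiv("erodiv_config_error", "seed is required")
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes read -> gap filter -> haplotype collapse -> diversity /
#' neutrality / mismatch -> structure (Phi-ST, AMOVA, Mantel) -> occurrence
#' thinning -> per-scenario thresholding, change maps, area accounting and
#' locality survival -> genetic erosion -> scenario table. All reports are
#' written under `cfg$out_dir` and returned invisibly. Rerunning with the
#' same config and seed reproduces the outputs exactly.
#'
#' @param cfg a `pipeline_config` (or path to a YAML file)
#' @param verbose print stage-level progress counts?
#' @return list of stage results, invisibly
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  aln_raw <- read_alignment(cfg$alignment)
  loc <- read_locality_table(cfg$localities)
  occ <- read_occurrences(cfg$occurrences)
  say("read %d sequences x %d sites, %d samples in %d localities, %d occurrences",
      n_samples(aln_raw), n_sites(aln_raw), nrow(loc),
      length(unique(loc$locality_code)), nrow(occ))

  aln <- complete_deletion(aln_raw)
  say("complete deletion removed %d of %d columns", attr(aln, "removed_sites"),
      attr(aln, "L_original"))

  assignment <- collapse_haplotypes(aln, loc)
  say("collapsed to %d haplotypes", length(assignment$haplotype_ids))
  write_haplotype_table(assignment, file.path(cfg$out_dir, "haplotypes.csv"))

  summary_tab <- per_locality_summary(aln, assignment, loc)
  utils::write.csv(summary_tab, file.path(cfg$out_dir, "diversity_by_locality.csv"),
                   row.names = FALSE)

  neut <- neutrality_tests(aln)
  obs_mm <- observed_mismatch(aln)
  fit <- fit_sudden_expansion(obs_mm, n = neut$n)
  fit <- mismatch_bootstrap_p(fit, B = cfg$bootstrap_B, seed = cfg$seed + 11L)
  neut_report <- c(neut[c("n", "S", "k", "pi", "k_alleles", "tajimas_d", "fus_fs")],
                   list(hd = haplotype_diversity(rowSums(assignment$counts)),
                        tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
                        ssd = fit$ssd, p_ssd = fit$p_ssd,
                        raggedness = fit$raggedness, p_raggedness = fit$p_raggedness,
                        bootstrap_B = cfg$bootstrap_B, seed = cfg$seed))
  jsonlite::write_json(neut_report, file.path(cfg$out_dir, "neutrality_mismatch.json"),
                       auto_unbox = TRUE, digits = NA)
  say("neutrality: S=%d k=%.3f D=%.3f Fs=%.3f; mismatch SSD=%.3g (p=%.3f)",
      neut$S, neut$k, neut$tajimas_d, neut$fus_fs, fit$ssd, fit$p_ssd)

  dm <- pairwise_difference_matrix(aln)
  phist <- phi_st_matrix(dm, loc, n_permutations = cfg$phist_permutations,
                         seed = cfg$seed + 21L)
  utils::write.csv(phist$phi_st, file.path(cfg$out_dir, "phist.csv"))
  utils::write.csv(phist$p, file.path(cfg$out_dir, "phist_p.csv"))
  am <- amova(dm, loc, n_permutations = cfg$amova_permutations, seed = cfg$seed + 22L)
  geo <- geographic_distance_matrix(loc)
  lin <- suppressWarnings(linearize_fst(phist$phi_st))
  lin[is.na(lin)] <- 0
  mt <- mantel_ibd(lin, geo, n_permutations = cfg$mantel_permutations,
                   seed = cfg$seed + 23L)
  jsonlite::write_json(list(
      amova = list(components = am$components, phi_st = am$phi_st, p = am$p_phi_st),
      mantel = mt),
    file.path(cfg$out_dir, "structure.json"), auto_unbox = TRUE, digits = NA)
  say("structure: Phi_ST=%.3f (among %.1f%%), Mantel R=%.3f (p=%.3f)",
      am$phi_st, am$components$percent[1], mt$R, mt$p)

  occ_thin <- thin_occurrences(occ, cfg$thinning_km, seed = cfg$seed + 31L)
  say("thinning retained %d of %d occurrence records", nrow(occ_thin), nrow(occ))
  utils::write.csv(occ_thin, file.path(cfg$out_dir, "occurrences_thinned.csv"),
                   row.names = FALSE)

  cur <- read_ascii_grid(cfg$raster_current)
  cur_bin <- binarize_suitability(cur, cfg$mtss)
  reports <- list()
  areas <- list()
  surv_tab <- list()
  for (key in names(cfg$rasters_future)) {
    fut <- read_ascii_grid(cfg$rasters_future[[key]])
    fut_bin <- binarize_suitability(fut, cfg$mtss)
    cm <- change_map(cur_bin, fut_bin)
    a <- area_summary(cm, cfg$cell_area_km2)
    a$scenario <- key
    areas[[key]] <- a
    surv <- locality_survival(fut_bin, loc)
    surv$scenario <- key
    surv_tab[[key]] <- surv
    parts <- strsplit(key, "_")[[1]]
    rep <- erode_diversity(aln, assignment, surv,
                           scenario_spec(parts[1], parts[2]), loc)
    reports[[key]] <- rep
    say("%s: %d/%d localities survive, %d/%d haplotypes persist", key,
        rep$localities_survived, rep$localities_total,
        rep$haplotypes_survived, rep$haplotypes_total)
  }
  utils::write.csv(do.call(rbind, areas), file.path(cfg$out_dir, "change_areas.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, surv_tab), file.path(cfg$out_dir, "locality_survival.csv"),
                   row.names = FALSE)

  current <- list(pi = neut$pi, n_haplotypes = neut$k_alleles,
                  hd = neut_report$hd)
  scen_tab <- scenario_table(reports, current)
  utils::write.csv(scen_tab, file.path(cfg$out_dir, "scenario_table.csv"),
                   row.names = FALSE)
  losses <- do.call(rbind, lapply(names(reports), function(k) {
    lp <- loss_percentages(reports[[k]])
    data.frame(scenario = k, localities_lost_pct = lp[1], haplotypes_lost_pct = lp[2],
               pi_lost_pct = 100 * reports[[k]]$proportion_pi_lost)
  }))
  utils::write.csv(losses, file.path(cfg$out_dir, "loss_percentages.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
      config = cfg[setdiff(names(cfg), c("rasters_future"))],
      rasters_future = cfg$rasters_future,
      package_version = as.character(utils::packageVersion("erodiv"))),
    file.path(cfg$out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(alignment = aln, assignment = assignment,
                 locality_summary = summary_tab, neutrality = neut_report,
                 mismatch_fit = fit, phist = phist, amova = am, mantel = mt,
                 occurrences_thinned = occ_thin, areas = areas,
                 survival = surv_tab, erosion = reports,
                 scenario_table = scen_tab, losses = losses))
}
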