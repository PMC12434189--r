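# Synthetic-data generators: expansion-shaped coalescent sequence data,
# locality-structured sampling, and paired current/future suitability
# surfaces with a controlled fraction of localities losing habitat.

#' Simulation configuration
#'
#' Defaults define the "paper-mini" study conditions: 120 sequences from 20
#' localities with a strong sudden-expansion history (tau = 3, theta0 = 0.5,
#' theta1 = 50), moderate locality differentiation (alpha = 1), a 40 x 40
#' degree-cell grid, the published-style MTSS threshold 0.3893, and
#' per-scenario survival fractions declining from 2050 RCP2.6 to 2070
#' RCP8.5 (which loses every locality).
#'
#' @param n samples (>= 2)
#' @param L sites; must leave headroom for infinite-sites placement
#'   (L >= 10 * theta1 recommended)
#' @param tau expansion age in mutational units
#' @param theta0,theta1 scaled sizes before/after the expansion
#' @param n_localities number of sampling localities (>= 2)
#' @param alpha Dirichlet concentration for per-locality haplotype weights;
#'   small alpha -> sorted localities (high Phi-ST), large -> panmixia
#' @param grid_nrow,grid_ncol,cellsize raster dimensions (degrees)
#' @param lon0,lat0 lower-left corner of the study bounding box
#' @param mtss suitability threshold
#' @param survival_fractions named vector `"<horizon>_<pathway>"` -> fraction
#'   of localities retaining suitable habitat
#' @param seed RNG seed (mandatory)
#' @return a `sim_config` list
#' @export
sim_config <- function(n = 120L, L = 1200L, tau = 3, theta0 = 0.5, theta1 = 50,
                       n_localities = 20L, alpha = 1,
                       grid_nrow = 40L, grid_ncol = 40L, cellsize = 0.1,
                       lon0 = 104, lat0 = 24, mtss = 0.3893,
                       survival_fractions = c(
                         "2050_RCP2.6" = 0.90, "2050_RCP4.5" = 0.80,
                         "2050_RCP6.0" = 0.75, "2050_RCP8.5" = 0.60,
                         "2070_RCP2.6" = 0.60, "2070_RCP4.5" = 0.25,
                         "2070_RCP6.0" = 0.10, "2070_RCP8.5" = 0.00),
                       seed) {
  if (missing(seed)) stop_erodiv("erodiv_precondition_error", "seed is mandatory")
  stopifnot(n >= 2, L >= 1, alpha > 0, theta0 > 0, theta1 >= theta0, tau >= 0,
            all(survival_fractions >= 0 & survival_fractions <= 1))
  structure(as.list(environment()), class = "sim_config")
}

# n-lineage coalescent with piecewise-constant theta(t): theta1 for t < tau,
# theta0 beyond. Waiting rate C(m,2)/theta(t) in mutational time; the epoch
# boundary is handled by the memoryless property (redraw the remainder at
# the epoch-2 rate). Mutations on a lineage over an interval dt are
# Poisson(dt/2) so that a pair coalescing at t differs at Poisson(t) sites.
# Returns mutation events as (tipset, count) plus summary times.
sim_genealogy_mutations <- function(n, tau, theta0, theta1) {
  lineages <- as.list(seq_len(n))
  t <- 0
  ev_tips <- list(); ev_k <- integer(0)
  while (length(lineages) > 1) {
    m <- length(lineages)
    rate <- m * (m - 1) / 2
    if (t < tau) {
      w <- stats::rexp(1, rate / theta1)
      tnew <- if (t + w <= tau) t + w else tau + stats::rexp(1, rate / theta0)
    } else {
      tnew <- t + stats::rexp(1, rate / theta0)
    }
    dt <- tnew - t
    muts <- stats::rpois(m, dt / 2)
    hit <- which(muts > 0)
    for (i in hit) {
      ev_tips[[length(ev_tips) + 1]] <- lineages[[i]]
      ev_k <- c(ev_k, muts[i])
    }
    pair <- sample.int(m, 2)
    lineages[[pair[1]]] <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages[[pair[2]]] <- NULL
    t <- tnew
  }
  list(tips = ev_tips, k = ev_k, tmrca = t, total_mutations = sum(ev_k))
}

# mismatch spectrum implied by a genealogy's mutation events, without
# building sequences: a mutation on a branch with tipset A separates every
# (inside, outside) pair.
sim_mismatch_spectrum <- function(n, tau, theta0, theta1) {
  g <- sim_genealogy_mutations(n, tau, theta0, theta1)
  D <- matrix(0L, n, n)
  for (e in seq_along(g$k)) {
    A <- g$tips[[e]]
    D[A, -A] <- D[A, -A] + g$k[e]
  }
  D <- D + t(D)
  mismatch_from_pairs(D[lower.tri(D)])
}

#' Simulate an alignment under the sudden-expansion coalescent
#'
#' Coalescent genealogy with piecewise-constant theta(t), Poisson mutations
#' on branches, and infinite-sites placement of each mutation onto a
#' distinct uniformly chosen column of a random ancestral sequence, so
#' haplotype identity is exact. The realized genealogy summary (tmrca,
#' mutation count) is attached as attribute `genealogy`.
#'
#' @param cfg a `sim_config`
#' @return an `alignment` of `cfg$n` sequences named s001, s002, ...
#' @export
simulate_expansion_alignment <- function(cfg) {
  set.seed(cfg$seed)
  g <- sim_genealogy_mutations(cfg$n, cfg$tau, cfg$theta0, cfg$theta1)
  if (g$total_mutations > cfg$L)
    stop_erodiv("erodiv_capacity_error", sprintf(
      "%d mutations exceed L = %d sites; increase L", g$total_mutations, cfg$L))
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, cfg$L, replace = TRUE)
  mat <- matrix(rep(anc, each = cfg$n), nrow = cfg$n)
  cols <- sample.int(cfg$L, g$total_mutations)
  ci <- 1L
  for (e in seq_along(g$k)) {
    A <- g$tips[[e]]
    for (rep_i in seq_len(g$k[e])) {
      col <- cols[ci]; ci <- ci + 1L
      mat[A, col] <- sample(setdiff(bases, anc[col]), 1)
    }
  }
  rownames(mat) <- sprintf("s%03d", seq_len(cfg$n))
  out <- validate_alignment(new_alignment(mat))
  attr(out, "genealogy") <- g[c("tmrca", "total_mutations")]
  out
}

#' Assign simulated samples to structured localities
#'
#' Each locality gets haplotype weights `w_l ~ Dirichlet(alpha * p)` around
#' the global haplotype frequencies `p`; each sample is then placed in a
#' locality with probability proportional to that locality's weight on its
#' haplotype. Small `alpha` sorts haplotypes into localities (high Phi-ST);
#' large `alpha` approaches panmixia. Localities left empty by the draw are
#' re-seeded with one sample moved from the largest locality. Coordinates
#' lie on a jittered grid inside the configured bounding box.
#'
#' @param aln alignment from [simulate_expansion_alignment()]
#' @param cfg a `sim_config` (`n_localities <= n`)
#' @return a locality table (data frame)
#' @export
simulate_structured_sampling <- function(aln, cfg) {
  if (cfg$n_localities > n_samples(aln))
    stop_erodiv("erodiv_precondition_error", "more localities than samples")
  set.seed(cfg$seed + 1L)
  seqs <- apply(aln$mat, 1L, paste0, collapse = "")
  hap <- match(seqs, unique(seqs))
  H <- max(hap)
  p <- tabulate(hap, H) / length(hap)
  P <- cfg$n_localities
  # per-locality Dirichlet(alpha * p) weights over haplotypes, drawn in log
  # space (Gamma(a) = Gamma(a+1) * U^(1/a)) so tiny shapes never underflow
  shp <- rep(cfg$alpha * p, each = P)
  logW <- matrix(log(stats::rgamma(P * H, shape = shp + 1)) +
                 log(stats::runif(P * H)) / shp, nrow = P)
  assign_loc <- integer(length(hap))
  for (i in seq_along(hap)) {
    lw <- logW[, hap[i]]
    assign_loc[i] <- sample.int(P, 1, prob = exp(lw - max(lw)))
  }
  # re-seed empty localities from the largest one
  for (l in which(tabulate(assign_loc, P) == 0L)) {
    big <- which.max(tabulate(assign_loc, P))
    assign_loc[sample(which(assign_loc == big), 1)] <- l
  }
  # jittered lattice of locality coordinates inside the bounding box
  side <- ceiling(sqrt(P))
  extent_lon <- cfg$grid_ncol * cfg$cellsize
  extent_lat <- cfg$grid_nrow * cfg$cellsize
  gx <- ((seq_len(P) - 1) %% side + 0.5) / side
  gy <- ((seq_len(P) - 1) %/% side + 0.5) / side
  jit <- 0.25 / side
  lon <- cfg$lon0 + (gx + stats::runif(P, -jit, jit)) * extent_lon
  lat <- cfg$lat0 + (gy + stats::runif(P, -jit, jit)) * extent_lat
  codes <- sprintf("L%02d", seq_len(P))
  validate_locality_table(data.frame(
    sample_id = sample_ids(aln),
    locality_code = codes[assign_loc],
    latitude = lat[assign_loc],
    longitude = lon[assign_loc]))
}

#' Simulate a current/future suitability raster pair
#'
#' The current surface is a normalized sum of Gaussian bumps centered on the
#' localities, with every locality's containing cell guaranteed suitable at
#' `mtss`. The future surface keeps (attenuated) bumps only for surviving
#' localities, chosen at random so that exactly
#' `ceiling((1 - survival_fraction) * n_localities)` localities fall below
#' `mtss`; the containing cells of lost/surviving localities are clamped to
#' guarantee the realized flags, which are returned as ground truth.
#'
#' @param cfg a `sim_config`
#' @param loc locality table inside the configured bounding box
#' @param survival_fraction fraction of localities that keep suitable habitat
#' @param salt small integer distinguishing scenarios that share a survival
#'   fraction (folded into the seed)
#' @return list `current`, `future` (suitability rasters), `flags`
#'   (named logical per locality)
#' @export
simulate_suitability_pair <- function(cfg, loc, survival_fraction, salt = 0L) {
  stopifnot(survival_fraction >= 0, survival_fraction <= 1)
  u <- locality_coords(loc)
  P <- nrow(u)
  n_lost <- ceiling((1 - survival_fraction) * P)
  set.seed(cfg$seed + 2L + 1009L * salt + round(1e4 * survival_fraction))
  lost <- if (n_lost > 0) sample(u$locality_code, n_lost) else character(0)
  flags <- stats::setNames(!(u$locality_code %in% lost), u$locality_code)

  bump_surface <- function(keep_codes, scale) {
    nr <- cfg$grid_nrow; nc <- cfg$grid_ncol; cs <- cfg$cellsize
    xc <- cfg$lon0 + (seq_len(nc) - 0.5) * cs
    yc <- cfg$lat0 + (nr - seq_len(nr) + 0.5) * cs  # row 1 at top
    v <- matrix(0, nr, nc)
    sigma <- 2 * cs
    for (i in which(u$locality_code %in% keep_codes)) {
      dx2 <- outer(rep(1, nr), (xc - u$longitude[i])^2)
      dy2 <- outer((yc - u$latitude[i])^2, rep(1, nc))
      v <- v + exp(-(dx2 + dy2) / (2 * sigma^2))
    }
    if (max(v) > 0) v <- v / max(v) * scale
    v
  }
  cur_v <- bump_surface(u$locality_code, 1.0)
  fut_v <- bump_surface(u$locality_code[flags], 0.9)

  cells <- t(vapply(seq_len(P), function(i) {
    rc <- containing_cell(list(values = cur_v, xll = cfg$lon0, yll = cfg$lat0,
                               cellsize = cfg$cellsize), u$longitude[i], u$latitude[i])
    if (is.na(rc[1])) stop_erodiv("erodiv_constructive_failure_error",
      "locality outside the configured grid")
    rc
  }, integer(2)))
  cell_key <- paste(cells[, 1], cells[, 2])
  clash <- cell_key[flags[u$locality_code]] %in% cell_key[!flags[u$locality_code]]
  if (any(clash)) stop_erodiv("erodiv_constructive_failure_error",
    "a surviving and a lost locality share a raster cell; enlarge the grid")

  margin <- cfg$mtss + 0.1 * (1 - cfg$mtss)
  for (i in seq_len(P)) {
    r <- cells[i, 1]; c <- cells[i, 2]
    cur_v[r, c] <- max(cur_v[r, c], margin)
    if (flags[u$locality_code[i]]) {
      fut_v[r, c] <- max(fut_v[r, c], margin)
    } else {
      fut_v[r, c] <- min(fut_v[r, c], 0.8 * cfg$mtss)
    }
  }
  list(current = suitability_raster(pmin(cur_v, 1), cfg$lon0, cfg$lat0, cfg$cellsize),
       future = suitability_raster(pmin(fut_v, 1), cfg$lon0, cfg$lat0, cfg$cellsize),
       flags = flags)
}

#' Write a complete synthetic input bundle
#'
#' Writes the FASTA alignment, locality table, occurrence table, the current
#' suitability raster, one future raster per (horizon, pathway), and a JSON
#' manifest holding the seed, configuration and all ground truths. The
#' default configuration is the "paper-mini" preset.
#'
#' @param cfg a `sim_config`
#' @param dir output directory
#' @param overwrite overwrite an existing non-empty directory?
#' @return the manifest (invisibly); files under `dir`
#' @export
make_fixture_bundle <- function(cfg, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop_erodiv("erodiv_precondition_error",
      paste0("output directory not empty (use overwrite = TRUE): ", dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aln <- simulate_expansion_alignment(cfg)
  loc <- simulate_structured_sampling(aln, cfg)
  write_alignment(aln, file.path(dir, "alignment.fasta"))
  utils::write.csv(loc, file.path(dir, "localities.csv"), row.names = FALSE)

  # occurrences: locality coordinates plus jittered duplicates (some < 1 km
  # apart, so thinning has work to do)
  set.seed(cfg$seed + 7L)
  u <- locality_coords(loc)
  occ <- data.frame(
    record_id = sprintf("occ%03d", seq_len(3 * nrow(u))),
    latitude = rep(u$latitude, 3) + c(rep(0, nrow(u)), stats::runif(2 * nrow(u), -0.02, 0.02)),
    longitude = rep(u$longitude, 3) + c(rep(0, nrow(u)), stats::runif(2 * nrow(u), -0.02, 0.02)))
  utils::write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)

  flags_by_scen <- list()
  first <- TRUE
  for (key in names(cfg$survival_fractions)) {
    pair <- simulate_suitability_pair(cfg, loc, cfg$survival_fractions[[key]],
                                      salt = match(key, names(cfg$survival_fractions)))
    if (first) {
      write_ascii_grid(pair$current, file.path(dir, "suitability_current.asc"))
      first <- FALSE
    }
    write_ascii_grid(pair$future, file.path(dir, sprintf("suitability_%s.asc", key)))
    flags_by_scen[[key]] <- as.list(pair$flags)
  }
  manifest <- list(
    seed = cfg$seed,
    config = cfg[c("n", "L", "tau", "theta0", "theta1", "n_localities", "alpha",
                   "grid_nrow", "grid_ncol", "cellsize", "lon0", "lat0", "mtss")],
    survival_fractions = as.list(cfg$survival_fractions),
    survival_flags = flags_by_scen,
    genealogy = attr(aln, "genealogy"),
    n_haplotypes = length(unique(apply(aln$mat, 1L, paste0, collapse = ""))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
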