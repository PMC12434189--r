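# Post-model SDM computations: occurrence thinning, collinearity filtering,
# suitability thresholding, change maps, area accounting, locality survival.
#
# A `suitability_raster` is a list: `values` (numeric matrix, row 1 = top /
# northernmost row), `xll`, `yll` (lower-left corner), `cellsize` (degrees),
# `nodata` cells stored as NA. Serialized as single-band ESRI ASCII grid.

#' Construct a suitability raster
#' @param values numeric matrix in \[0,1\] or NA; row 1 is the top row
#' @param xll,yll coordinates of the lower-left corner (decimal degrees)
#' @param cellsize cell edge in degrees (> 0)
#' @return a `suitability_raster`
#' @export
suitability_raster <- function(values, xll, yll, cellsize) {
  stopifnot(is.matrix(values), cellsize > 0)
  rng <- range(values, na.rm = TRUE)
  if (!all(is.na(values)) && (rng[1] < 0 || rng[2] > 1))
    stop_erodiv("erodiv_domain_error", "suitability values must lie in [0, 1]")
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "suitability_raster")
}

#' @export
print.suitability_raster <- function(x, ...) {
  cat(sprintf("<suitability_raster> %d x %d cells, cellsize %g, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  invisible(x)
}

same_georef <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize)))
}

#' Read / write single-band ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows from north
#' to south.
#'
#' @param path file path
#' @return a `suitability_raster` (read) or `path` invisibly (write)
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop_erodiv("erodiv_format_error", "missing ESRI ASCII grid header field(s)")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr[["nodata_value"]] %||% -9999
  m[m == nodata] <- NA
  suitability_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @param r a `suitability_raster` (or integer-coded grid of the same shape)
#' @export
write_ascii_grid <- function(r, path) {
  v <- r$values
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.10g", r$xll), sprintf("yllcorner %.10g", r$yll),
               sprintf("cellsize %.10g", r$cellsize), "NODATA_value -9999"), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Spatially thin occurrence records
#'
#' Randomized greedy thinning: records are visited in a seeded random order
#' and kept if no already-kept record lies within `min_distance_km`
#' (great-circle); several restarts keep the largest retained set. The
#' result is invariant to input row order for a given seed (records are
#' canonically sorted before the seeded shuffle).
#'
#' @param occ occurrence data frame (`record_id, latitude, longitude`)
#' @param min_distance_km minimum allowed pairwise distance (> 0)
#' @param seed RNG seed
#' @param restarts number of random restarts (default 10)
#' @return thinned occurrence data frame; retained count as attribute `retained`
#' @export
thin_occurrences <- function(occ, min_distance_km, seed, restarts = 10L) {
  if (min_distance_km <= 0) stop_erodiv("erodiv_precondition_error",
    "min_distance_km must be > 0")
  if (nrow(occ) == 0) {
    warning("empty occurrence set; nothing to thin")
    attr(occ, "retained") <- 0L
    return(occ)
  }
  occ <- occ[order(occ$latitude, occ$longitude, occ$record_id), , drop = FALSE]
  pts <- as.matrix(occ[, c("longitude", "latitude")])
  n <- nrow(pts)
  dkm <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    ord <- sample.int(n)
    keep <- logical(n)
    for (i in ord) {
      if (!any(keep & dkm[i, ] < min_distance_km)) keep[i] <- TRUE
    }
    if (is.null(best) || sum(keep) > sum(best)) best <- keep
  }
  out <- occ[best, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained") <- nrow(out)
  out
}

#' Collinearity-based variable selection
#'
#' Iteratively drops the variable with the greatest number of partners whose
#' `|r|` exceeds the threshold (ties: larger mean `|r|`, then label order)
#' until no pair exceeds the threshold. Deterministic.
#'
#' @param correlations labeled symmetric correlation matrix with unit diagonal
#' @param threshold exclusion threshold on `|r|` (default 0.8)
#' @return character vector of retained variable names
#' @export
collinearity_filter <- function(correlations, threshold = 0.8) {
  if (!isTRUE(all.equal(correlations, t(correlations), tolerance = 1e-8)))
    stop_erodiv("erodiv_schema_error", "correlation matrix must be symmetric")
  keep <- colnames(correlations)
  m <- abs(correlations)
  diag(m) <- 0
  repeat {
    sub <- m[keep, keep, drop = FALSE]
    viol <- sub > threshold
    if (!any(viol)) return(keep)
    cnt <- rowSums(viol)
    cand <- which(cnt == max(cnt))
    if (length(cand) > 1) {
      mr <- rowMeans(sub)[cand]
      cand <- cand[mr == max(mr)]
    }
    drop_var <- names(cand)[1]   # label order (matrix order) breaks final ties
    keep <- setdiff(keep, drop_var)
  }
}

#' Binarize a suitability raster at the MTSS threshold
#'
#' A cell is suitable iff its value is `>= mtss`; nodata propagates.
#'
#' @param r a `suitability_raster`
#' @param mtss suitability threshold (the paper-style scheme assumes
#'   `0 < mtss < 0.5`)
#' @return raster-shaped object whose values are 1 (suitable) / 0 / NA
#' @export
binarize_suitability <- function(r, mtss) {
  v <- ifelse(r$values >= mtss, 1, 0)
  out <- r
  out$values <- v
  class(out) <- c("binary_raster", "suitability_raster")
  out
}

#' Categorize suitability
#'
#' Intervals `[0, mtss)` unsuitable, `[mtss, 0.5)` low, `[0.5, 0.7)`
#' moderate, `[0.7, 1]` high; all intervals closed on the left, open on the
#' right except the top which is closed at 1. Nodata propagates.
#'
#' @param r a `suitability_raster`
#' @param mtss threshold, must satisfy `0 < mtss < 0.5`
#' @return raster-shaped object of integer codes 0..3 with a `legend` attribute
#' @export
categorize_suitability <- function(r, mtss) {
  if (mtss <= 0 || mtss >= 0.5)
    stop_erodiv("erodiv_domain_error", "mtss must lie in (0, 0.5) for ordered categories")
  v <- r$values
  cat <- ifelse(v < mtss, 0L, ifelse(v < 0.5, 1L, ifelse(v < 0.7, 2L, 3L)))
  out <- r
  out$values <- cat
  class(out) <- c("category_raster", "suitability_raster")
  attr(out, "legend") <- c(`0` = "unsuitable", `1` = "low", `2` = "moderate", `3` = "high")
  out
}

CHANGE_LEGEND <- c(`0` = "absent", `1` = "contraction", `2` = "expansion", `3` = "stable")

#' Current-vs-future range change map
#'
#' Cellwise truth table on two binary suitability maps: suitable in both ->
#' stable; current only -> contraction; future only -> expansion; neither ->
#' absent. Nodata in either input propagates.
#'
#' @param current_bin,future_bin binary rasters on an identical georeference
#' @return a `change_map` raster of codes 0..3 with a `legend` attribute
#' @export
change_map <- function(current_bin, future_bin) {
  if (!same_georef(current_bin, future_bin))
    stop_erodiv("erodiv_georeference_error", "rasters differ in grid or georeference")
  cur <- current_bin$values; fut <- future_bin$values
  v <- ifelse(cur == 1 & fut == 1, 3L,
       ifelse(cur == 1 & fut == 0, 1L,
       ifelse(cur == 0 & fut == 1, 2L, 0L)))
  out <- current_bin
  out$values <- v
  class(out) <- c("change_map", "suitability_raster")
  attr(out, "legend") <- CHANGE_LEGEND
  out
}

#' Areas per change category
#'
#' Category cell counts times cell area, reported in thousands of km^2.
#' `cell_area_km2` is a scalar, or a vector of per-row areas (one value per
#' raster row) for latitude correction.
#'
#' @param cm a `change_map`
#' @param cell_area_km2 positive scalar or per-row vector
#' @return data frame with columns category, cells, area_1e3_km2
#' @export
area_summary <- function(cm, cell_area_km2) {
  v <- cm$values
  if (length(cell_area_km2) == 1L) {
    areas <- matrix(cell_area_km2, nrow(v), ncol(v))
  } else {
    if (length(cell_area_km2) != nrow(v))
      stop_erodiv("erodiv_domain_error", "per-row cell areas must have one value per raster row")
    areas <- matrix(cell_area_km2, nrow(v), ncol(v))
  }
  if (any(areas <= 0)) stop_erodiv("erodiv_domain_error", "cell area must be positive")
  out <- data.frame(category = unname(CHANGE_LEGEND),
                    cells = NA_integer_, area_1e3_km2 = NA_real_)
  for (i in seq_along(CHANGE_LEGEND)) {
    sel <- !is.na(v) & v == as.integer(names(CHANGE_LEGEND)[i])
    out$cells[i] <- sum(sel)
    out$area_1e3_km2[i] <- sum(areas[sel]) / 1000
  }
  out
}

# 1-based (row from top, col) of the cell containing a coordinate; NA if outside
containing_cell <- function(r, lon, lat) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  ytop <- r$yll + nr * r$cellsize
  col <- as.integer(floor((lon - r$xll) / r$cellsize)) + 1L
  row <- as.integer(floor((ytop - lat) / r$cellsize)) + 1L
  if (lat == r$yll) row <- nr  # bottom edge belongs to bottom row
  if (lon == r$xll + nc * r$cellsize) col <- nc
  if (row < 1 || row > nr || col < 1 || col > nc) return(c(NA_integer_, NA_integer_))
  c(row, col)
}

#' Locality survival under a future binary suitability map
#'
#' A locality survives iff the raster cell containing its coordinate is
#' suitable (containing-cell rule, origin-anchored, row 1 at top). A
#' locality on a nodata cell is counted as lost, with a warning.
#'
#' @param future_bin binary raster
#' @param loc locality table (all coordinates must fall inside the extent)
#' @return data frame with columns locality, survived (logical)
#' @export
locality_survival <- function(future_bin, loc) {
  u <- locality_coords(loc)
  surv <- logical(nrow(u))
  outside <- character(0)
  for (i in seq_len(nrow(u))) {
    rc <- containing_cell(future_bin, u$longitude[i], u$latitude[i])
    if (is.na(rc[1])) { outside <- c(outside, u$locality_code[i]); next }
    val <- future_bin$values[rc[1], rc[2]]
    if (is.na(val)) {
      warning(sprintf("locality %s falls on a nodata cell; counted as lost", u$locality_code[i]))
      surv[i] <- FALSE
    } else surv[i] <- val == 1
  }
  if (length(outside)) stop_erodiv("erodiv_locality_coverage_error",
    paste0("localities outside raster extent: ", paste(outside, collapse = ", ")))
  data.frame(locality = u$locality_code, survived = surv)
}
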