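# Alignment and table input/output.
#
# An `alignment` is a character matrix (samples x sites) of upper-case
# symbols from {A,C,G,T,N,-}, with unique rownames holding the sample ids.
# All downstream statistics assume this data model and (for diversity
# statistics) a gap/ambiguity-free matrix produced by complete_deletion().

ALLOWED_CHARS <- c("A", "C", "G", "T", "N", "-")

new_alignment <- function(mat) {
  stopifnot(is.matrix(mat), is.character(mat))
  structure(list(mat = mat), class = "alignment")
}

#' Number of samples / sites in an alignment
#' @param aln an `alignment` object
#' @return integer count
#' @export
n_samples <- function(aln) nrow(aln$mat)

#' @rdname n_samples
#' @export
n_sites <- function(aln) ncol(aln$mat)

#' @rdname n_samples
#' @export
sample_ids <- function(aln) rownames(aln$mat)

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d sequences x %d sites\n", n_samples(x), n_sites(x)))
  removed <- attr(x, "removed_sites")
  if (!is.null(removed)) cat(sprintf("  (%d sites removed by complete deletion)\n", removed))
  invisible(x)
}

#' @export
as.matrix.alignment <- function(x, ...) x$mat

#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment in FASTA format. Sequence ids are the
#' header text up to the first whitespace; lowercase bases are normalized to
#' uppercase. Characters outside `A,C,G,T,N,-` are rejected.
#'
#' @param path path to a FASTA file with at least one record
#' @return an `alignment` object
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop_erodiv("erodiv_format_error", paste0("file not found: ", path))
  dna <- tryCatch(ape::read.FASTA(path),
    error = function(e) stop_erodiv("erodiv_format_error", paste0("not readable as FASTA: ", conditionMessage(e))))
  if (length(dna) == 0L) stop_erodiv("erodiv_format_error", "FASTA file contains no records")
  ids <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(ids)) {
    stop_erodiv("erodiv_identifier_error",
      paste0("duplicate sample ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  chars <- lapply(as.character(dna), function(s) toupper(s))
  lens <- lengths(chars)
  if (length(unique(lens)) > 1L) {
    ref <- lens[1]
    bad <- ids[lens != ref][1]
    stop_erodiv("erodiv_alignment_shape_error",
      sprintf("ragged alignment: record '%s' has length %d, expected %d", bad, lens[ids == bad][1], ref))
  }
  mat <- do.call(rbind, chars)
  rownames(mat) <- ids
  bad <- !(mat %in% ALLOWED_CHARS)
  if (any(bad)) {
    i <- which(matrix(bad, nrow = nrow(mat)), arr.ind = TRUE)[1, ]
    stop_erodiv("erodiv_format_error",
      sprintf("illegal character '%s' in record '%s'", mat[i[1], i[2]], ids[i[1]]))
  }
  validate_alignment(new_alignment(mat))
}

validate_alignment <- function(aln) {
  mat <- aln$mat
  if (ncol(mat) < 1L) stop_erodiv("erodiv_alignment_shape_error", "alignment has zero sites")
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop_erodiv("erodiv_identifier_error", "sample ids missing or duplicated")
  aln
}

#' Construct an alignment from named sequence strings
#'
#' Convenience constructor used heavily by the simulator and tests.
#'
#' @param seqs named character vector of equal-length sequence strings
#' @return an `alignment`
#' @export
alignment_from_strings <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_erodiv("erodiv_identifier_error", "sequences must have unique names")
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop_erodiv("erodiv_alignment_shape_error", "sequences differ in length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  validate_alignment(new_alignment(mat))
}

#' Write an alignment to FASTA
#' @param aln an `alignment`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_alignment <- function(aln, path) {
  dna <- ape::as.DNAbin(tolower(aln$mat))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Concatenate two alignments over the same samples
#'
#' Joins per-sample sequences in `(a, b)` order (e.g. COI then ND2); the
#' output sample order follows `a`. Sample id sets must match exactly.
#'
#' @param a,b `alignment` objects over identical sample id sets
#' @return an `alignment` with `n_sites` equal to the sum of inputs
#' @export
concatenate_alignments <- function(a, b) {
  ia <- sample_ids(a); ib <- sample_ids(b)
  if (!setequal(ia, ib)) {
    diff <- c(setdiff(ia, ib), setdiff(ib, ia))
    stop_erodiv("erodiv_join_error",
      paste0("sample id sets differ; symmetric difference: ", paste(diff, collapse = ", ")))
  }
  mat <- cbind(a$mat, b$mat[ia, , drop = FALSE])
  validate_alignment(new_alignment(mat))
}

#' Remove every column containing a gap or ambiguity
#'
#' Complete-deletion gap policy: any column holding `-` or `N` in any
#' sequence is dropped before statistics are computed. The count of removed
#' columns is attached as attribute `removed_sites`; the original length as
#' `L_original`. Idempotent.
#'
#' @param aln an `alignment`
#' @return the filtered `alignment`
#' @export
complete_deletion <- function(aln) {
  mat <- aln$mat
  keep <- colSums(mat == "N" | mat == "-") == 0L
  if (!any(keep)) stop_erodiv("erodiv_degenerate_alignment_error",
    "complete deletion removed every column")
  out <- validate_alignment(new_alignment(mat[, keep, drop = FALSE]))
  attr(out, "removed_sites") <- sum(!keep)
  attr(out, "L_original") <- attr(aln, "L_original") %||% ncol(mat)
  out
}

#' Read a sample-to-locality table
#'
#' CSV with header columns `sample_id, locality_code, latitude, longitude`
#' (decimal degrees, WGS84). Every sample id must be unique and every
#' locality code must map to exactly one coordinate pair.
#'
#' @param path path to CSV
#' @return validated data frame
#' @export
read_locality_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_locality_table(tab)
}

#' @rdname read_locality_table
#' @param tab a data frame to validate in place
#' @export
validate_locality_table <- function(tab) {
  need <- c("sample_id", "locality_code", "latitude", "longitude")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_erodiv("erodiv_schema_error",
    paste0("locality table missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(tab$sample_id)) stop_erodiv("erodiv_identifier_error",
    paste0("duplicate sample_id: ", paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", ")))
  if (any(tab$latitude < -90 | tab$latitude > 90)) stop_erodiv("erodiv_domain_error",
    "latitude outside [-90, 90]")
  if (any(tab$longitude < -180 | tab$longitude > 180)) stop_erodiv("erodiv_domain_error",
    "longitude outside [-180, 180]")
  coords <- unique(tab[, c("locality_code", "latitude", "longitude")])
  if (anyDuplicated(coords$locality_code)) stop_erodiv("erodiv_domain_error",
    "a locality_code maps to more than one coordinate pair")
  tab
}

#' Read an occurrence-record table
#'
#' CSV with header `record_id, latitude, longitude` (decimal degrees).
#'
#' @param path path to CSV
#' @return validated data frame
#' @export
read_occurrences <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "latitude", "longitude")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_erodiv("erodiv_schema_error",
    paste0("occurrence table missing column(s): ", paste(miss, collapse = ", ")))
  if (any(tab$latitude < -90 | tab$latitude > 90) ||
      any(tab$longitude < -180 | tab$longitude > 180))
    stop_erodiv("erodiv_domain_error", "occurrence coordinate out of range")
  tab
}

# coordinates of each distinct locality, in sorted code order
locality_coords <- function(loc) {
  u <- unique(loc[, c("locality_code", "latitude", "longitude")])
  u[order(u$locality_code), , drop = FALSE]
}
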