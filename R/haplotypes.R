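# Haplotype collapsing and diversity statistics.

#' Collapse an alignment into haplotypes
#'
#' Haplotypes are equivalence classes of identical sequence strings. Labels
#' H1, H2, ... are assigned by descending total count, ties broken by first
#' occurrence in the alignment; labels are presentation only and never affect
#' statistics. Requires a gap/ambiguity-free alignment (run
#' [complete_deletion()] first) and a locality table covering every sample.
#'
#' @param aln an `alignment` containing only A,C,G,T
#' @param loc locality table (see [read_locality_table()])
#' @return a `haplotype_assignment`: list with `haplotype_ids`,
#'   `representative` (named character), `assignment` (sample -> haplotype),
#'   and `counts` (haplotype x locality matrix)
#' @export
collapse_haplotypes <- function(aln, loc) {
  mat <- aln$mat
  if (any(mat == "N" | mat == "-"))
    stop_erodiv("erodiv_precondition_error",
      "alignment contains N or - ; apply complete_deletion() before collapsing")
  ids <- sample_ids(aln)
  missing <- setdiff(ids, loc$sample_id)
  if (length(missing)) stop_erodiv("erodiv_join_error",
    paste0("samples absent from locality table: ", paste(utils::head(missing, 5), collapse = ", ")))
  seqs <- apply(mat, 1L, paste0, collapse = "")
  first <- !duplicated(seqs)
  reps <- seqs[first]                       # in first-occurrence order
  idx <- match(seqs, reps)                  # sample -> class (first-occurrence order)
  tot <- tabulate(idx, nbins = length(reps))
  ord <- order(-tot, seq_along(reps))       # descending count, then first occurrence
  rank <- match(seq_along(reps), ord)       # class -> rank
  hap_ids <- paste0("H", seq_along(reps))
  assignment <- stats::setNames(hap_ids[rank[idx]], ids)
  representative <- stats::setNames(reps[ord], hap_ids)
  loc_of <- loc$locality_code[match(ids, loc$sample_id)]
  counts <- table(factor(assignment, levels = hap_ids),
                  factor(loc_of, levels = sort(unique(loc$locality_code))))
  counts <- unclass(as.matrix(counts))
  structure(list(haplotype_ids = hap_ids,
                 representative = representative,
                 assignment = assignment,
                 counts = counts,
                 n = length(ids)),
            class = "haplotype_assignment")
}

#' @export
print.haplotype_assignment <- function(x, ...) {
  cat(sprintf("<haplotype_assignment> %d haplotypes over %d samples, %d localities\n",
              length(x$haplotype_ids), x$n, ncol(x$counts)))
  invisible(x)
}

#' Haplotype (gene) diversity
#'
#' `Hd = n/(n-1) * (1 - sum p_i^2)` over haplotype frequencies `p_i`, the
#' probability that two randomly drawn sequences carry different haplotypes,
#' with small-sample correction.
#'
#' @param counts vector of haplotype counts, total n >= 2
#' @return Hd in \[0, 1\]
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop_erodiv("erodiv_undefined_statistic_error",
    "haplotype diversity undefined for fewer than 2 sequences")
  p <- counts / n
  max(0, n / (n - 1) * (1 - sum(p^2)))
}

# total pairwise differences summed over all C(n,2) pairs, via per-column
# state counts: sum_cols [ C(n,2) - sum_s C(n_s,2) ]
total_pairwise_differences <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (j in seq_len(ncol(mat))) {
    tab <- table(mat[, j])
    tot <- tot + choose(n, 2) - sum(choose(tab, 2))
  }
  tot
}

#' Nucleotide diversity
#'
#' Mean per-site pairwise difference: `pi = k / L` with
#' `k = sum_{i<j} d_ij / C(n,2)` the mean number of pairwise differences.
#'
#' @param aln an `alignment` (gap-filtered)
#' @return list with `pi`, `k`, `n`, `L_used`
#' @export
nucleotide_diversity <- function(aln) {
  n <- n_samples(aln)
  if (n < 2) stop_erodiv("erodiv_undefined_statistic_error",
    "nucleotide diversity undefined for fewer than 2 sequences")
  L <- n_sites(aln)
  k <- total_pairwise_differences(aln$mat) / choose(n, 2)
  list(pi = k / L, k = k, n = n, L_used = L)
}

#' Per-locality diversity summary
#'
#' One row per locality with sample count, haplotype count, Hd and pi, plus
#' an overall `ALL` row. Localities with a single sample report Hd and pi as
#' `NA` with `defined = FALSE` (undefined, not zero). The mean and standard
#' error of Hd and pi across localities with defined values are attached as
#' attributes `hd_mean_se` and `pi_mean_se`. Per-locality statistics reuse
#' the globally gap-filtered alignment, so values are comparable across
#' localities.
#'
#' @param aln gap-filtered `alignment`
#' @param assignment result of [collapse_haplotypes()]
#' @param loc locality table
#' @return data frame with columns locality, n, n_haplotypes, hd, pi, defined
#' @export
per_locality_summary <- function(aln, assignment, loc) {
  ids <- sample_ids(aln)
  loc_of <- loc$locality_code[match(ids, loc$sample_id)]
  locs <- sort(unique(loc_of))
  rows <- lapply(locs, function(l) {
    sub <- ids[loc_of == l]
    nh <- length(unique(assignment$assignment[sub]))
    if (length(sub) < 2) {
      data.frame(locality = l, n = length(sub), n_haplotypes = nh,
                 hd = NA_real_, pi = NA_real_, defined = FALSE)
    } else {
      cnt <- table(assignment$assignment[sub])
      nd <- nucleotide_diversity(subset_alignment(aln, sub))
      data.frame(locality = l, n = length(sub), n_haplotypes = nh,
                 hd = haplotype_diversity(as.numeric(cnt)), pi = nd$pi, defined = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  ndall <- nucleotide_diversity(aln)
  all_row <- data.frame(locality = "ALL", n = n_samples(aln),
                        n_haplotypes = length(assignment$haplotype_ids),
                        hd = haplotype_diversity(rowSums(assignment$counts)),
                        pi = ndall$pi, defined = TRUE)
  out <- rbind(out, all_row)
  mean_se <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  attr(out, "hd_mean_se") <- mean_se(out$hd[out$locality != "ALL"])
  attr(out, "pi_mean_se") <- mean_se(out$pi[out$locality != "ALL"])
  out
}

#' Subset an alignment by sample ids
#' @param aln an `alignment`
#' @param ids sample ids to keep (order preserved)
#' @return an `alignment`
#' @export
subset_alignment <- function(aln, ids) {
  missing <- setdiff(ids, sample_ids(aln))
  if (length(missing)) stop_erodiv("erodiv_join_error",
    paste0("unknown sample ids: ", paste(utils::head(missing, 5), collapse = ", ")))
  validate_alignment(new_alignment(aln$mat[ids, , drop = FALSE]))
}

#' Write the haplotype table
#' @param assignment a `haplotype_assignment`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_haplotype_table <- function(assignment, path) {
  df <- data.frame(haplotype_id = assignment$haplotype_ids,
                   total_count = rowSums(assignment$counts),
                   assignment$counts, check.names = FALSE,
                   representative_sequence = assignment$representative)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
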