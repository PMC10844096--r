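#' Filter mutation loci by aggregate coverage and mutant-cell count
#'
#' A locus is retained iff its total read coverage summed over cells is at
#' least `min_total_coverage` (default 100) and the number of cells carrying
#' at least one alternate read exceeds `min_mut_cells` (default 20; the
#' comparison is strict, i.e. "over 20 cells" keeps 21 but drops 20; set
#' `strict = FALSE` for a >= reading).
#'
#' @param pileups pileup table (see [read_pileup()]).
#' @param min_total_coverage aggregate coverage floor.
#' @param min_mut_cells mutant-cell count threshold.
#' @param strict strict (>) or inclusive (>=) mutant-cell comparison.
#' @return data.frame locus, total_coverage, n_mut_cells, retained.
#' @export
filter_loci <- function(pileups, min_total_coverage = 100,
                        min_mut_cells = 20, strict = TRUE) {
  cov <- tapply(pileups$total, pileups$locus, sum)
  nmut <- tapply(pileups$alt_reads >= 1, pileups$locus, sum)
  out <- data.frame(locus = names(cov),
                    total_coverage = as.numeric(cov),
                    n_mut_cells = as.integer(nmut),
                    stringsAsFactors = FALSE)
  out$retained <- out$total_coverage >= min_total_coverage &
    (if (strict) out$n_mut_cells > min_mut_cells
     else out$n_mut_cells >= min_mut_cells)
  rownames(out) <- NULL
  out
}

#' Call per-cell genotype at a locus
#'
#' For cells of a patient whose bulk WES lacks the mutation
#' (`absent_by_WES`), the call is WT. For mutant-by-WES patients, a cell with
#' at least `min_alt_reads` alternate reads is MUT; otherwise — no mutant
#' reads or no coverage at all — it is `unknown`, reflecting the frequent
#' allelic dropout of scRNA-seq.
#'
#' @param pileups pileup table rows for one locus.
#' @param patient_status "mutant_by_WES" or "absent_by_WES" (scalar or
#'   per-row vector).
#' @param min_alt_reads alternate reads required for MUT (default 1).
#' @return data.frame barcode, locus, status, alt_reads, total.
#' @export
call_cell_genotype <- function(pileups,
                               patient_status = c("mutant_by_WES", "absent_by_WES"),
                               min_alt_reads = 1) {
  if (any(pileups$ref_reads < 0) || any(pileups$alt_reads < 0))
    stop_named("pileup_error", "negative read counts")
  if (length(patient_status) == 1)
    patient_status <- rep(match.arg(patient_status), nrow(pileups))
  stopifnot(all(patient_status %in% c("mutant_by_WES", "absent_by_WES")))
  status <- ifelse(patient_status == "absent_by_WES", "WT",
                   ifelse(pileups$alt_reads >= min_alt_reads, "MUT", "unknown"))
  data.frame(barcode = pileups$barcode, locus = pileups$locus,
             status = status, alt_reads = pileups$alt_reads,
             total = pileups$ref_reads + pileups$alt_reads,
             stringsAsFactors = FALSE)
}

#' Per-locus genotype fraction summary
#'
#' Over cells of mutant-by-WES patients: the fractions of MUT cells, of
#' covered cells without mutant reads, and of cells without coverage. The
#' three fractions sum to 1.
#'
#' @param calls output of [call_cell_genotype()] restricted to mutant-by-WES
#'   patients.
#' @return data.frame locus, n_cells, frac_mut, frac_no_mut_read,
#'   frac_no_coverage.
#' @export
genotype_fraction_summary <- function(calls) {
  if (!nrow(calls)) stop_named("empty_input_error", "no genotype calls")
  if (any(calls$status == "WT"))
    stop_named("genotype_error",
               "summary is defined over mutant-by-WES patients only")
  per <- split(calls, calls$locus)
  out <- do.call(rbind, lapply(per, function(d) {
    data.frame(locus = d$locus[1], n_cells = nrow(d),
               frac_mut = mean(d$status == "MUT"),
               frac_no_mut_read = mean(d$status == "unknown" & d$total > 0),
               frac_no_coverage = mean(d$total == 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Associate genotype with a per-cell score
#'
#' Two-sided Wilcoxon rank-sum comparison of a per-cell scalar (e.g., a
#' signature score) between MUT and WT cells; `unknown` cells are excluded.
#'
#' @param calls genotype calls for one locus.
#' @param scores named per-cell numeric vector (names = barcodes).
#' @param n_tests number of parallel comparisons for Bonferroni adjustment
#'   (default 1).
#' @return list statistic, p.value, p.adjusted, n_mut, n_wt.
#' @export
genotype_score_association <- function(calls, scores, n_tests = 1) {
  mut <- scores[calls$barcode[calls$status == "MUT"]]
  wt <- scores[calls$barcode[calls$status == "WT"]]
  mut <- mut[!is.na(mut)]; wt <- wt[!is.na(wt)]
  if (!length(mut)) stop_named("empty_group_error", "no scored MUT cells")
  if (!length(wt)) stop_named("empty_group_error", "no scored WT cells")
  wt_res <- wilcoxon_rank_sum(mut, wt)
  list(statistic = wt_res$statistic, p.value = wt_res$p.value,
       p.adjusted = min(1, wt_res$p.value * n_tests),
       n_mut = length(mut), n_wt = length(wt))
}
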