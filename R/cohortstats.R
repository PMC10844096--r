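#' Percent with one-decimal round-half-up
#'
#' `100 * count / total` rounded half-up to one decimal, matching the
#' one-decimal percentage style of clinical cohort tables (base `round()`
#' rounds half to even, which would not).
#'
#' @param count,total non-negative counts, total >= 1.
#' @return numeric percent.
#' @export
percent1 <- function(count, total) {
  if (any(total < 1)) stop_named("cohort_error", "total must be >= 1")
  floor(100 * count / total * 10 + 0.5) / 10
}

#' Cohort recurrence summary for one feature
#'
#' @param cohort data.frame with a `patient` column and logical feature
#'   flag columns (gene mutations, chromosome CNVs).
#' @param feature flag column name.
#' @return list count, total, percent (one decimal, half-up).
#' @export
recurrence_summary <- function(cohort, feature) {
  if (!feature %in% names(cohort))
    stop_named("cohort_error", "unknown feature: %s", feature)
  flags <- as.logical(cohort[[feature]])
  list(count = sum(flags), total = length(flags),
       percent = percent1(sum(flags), length(flags)))
}

#' Compare per-sample cluster proportions between two clinical groups
#'
#' Per sample, the fraction of each cluster among that sample's
#' non-malignant cells (fractions sum to 1 within a sample); per cluster, a
#' two-sided Wilcoxon rank-sum test between the samples of the two groups,
#' BH-adjusted across clusters. Groups with fewer than 2 samples are skipped
#' with a flag.
#'
#' @param meta cell metadata (see [read_cellmeta()]).
#' @param tumor_barcodes barcodes excluded as malignant.
#' @param group_a,group_b clinical status values to compare (from
#'   ND/RR/control).
#' @return list `fractions` (sample, status, cluster, fraction) and `tests`
#'   (cluster, p, p_adj, skipped).
#' @export
proportion_compare <- function(meta, tumor_barcodes = character(),
                               group_a = "ND", group_b = "control") {
  nm <- meta[!meta$barcode %in% tumor_barcodes, , drop = FALSE]
  nm <- nm[nm$status %in% c(group_a, group_b), , drop = FALSE]
  if (!nrow(nm)) stop_named("cohort_error", "no non-malignant cells in groups")
  fr <- do.call(rbind, lapply(split(nm, nm$sample), function(d) {
    tab <- table(factor(d$cluster, unique(nm$cluster)))
    data.frame(sample = d$sample[1], status = d$status[1],
               cluster = names(tab), fraction = as.numeric(tab) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(fr) <- NULL
  na <- length(unique(fr$sample[fr$status == group_a]))
  nb <- length(unique(fr$sample[fr$status == group_b]))
  skipped <- na < 2 || nb < 2
  clusters <- unique(fr$cluster)
  if (skipped) {
    warning(sprintf("group with < 2 samples (%s: %d, %s: %d); tests skipped",
                    group_a, na, group_b, nb))
    tests <- data.frame(cluster = clusters, p = NA_real_, p_adj = NA_real_,
                        skipped = TRUE, stringsAsFactors = FALSE)
  } else {
    p <- vapply(clusters, function(cl) {
      d <- fr[fr$cluster == cl, ]
      wilcoxon_rank_sum(d$fraction[d$status == group_a],
                        d$fraction[d$status == group_b])$p.value
    }, numeric(1))
    tests <- data.frame(cluster = clusters, p = unname(p),
                        p_adj = p.adjust(unname(p), "BH"), skipped = FALSE,
                        stringsAsFactors = FALSE)
  }
  list(fractions = fr, tests = tests)
}

#' Read a cohort flag table
#'
#' TSV with a `patient` column, a `source` column (WES or scRNA) and
#' logical/0-1 feature flag columns.
#'
#' @param path TSV path.
#' @return validated data.frame with logical flags.
#' @export
read_cohort_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("patient", "source") %in% names(df)))
    stop_named("missing_column_error", "cohort table needs patient and source")
  if (!all(df$source %in% c("WES", "scRNA")))
    stop_named("cohort_error", "source must be WES or scRNA")
  if (anyDuplicated(paste(df$patient, df$source)))
    stop_named("cohort_error", "duplicate patient per source")
  flag_cols <- setdiff(names(df), c("patient", "source"))
  df[flag_cols] <- lapply(df[flag_cols], function(x) as.logical(as.integer(x)))
  df
}
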