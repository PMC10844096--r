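#' Per-sample tumor DEG lists against two backgrounds
#'
#' Within one sample, genes significantly up-regulated in tumor cells versus
#' all non-malignant mononuclear cells, and (when a normal-TFH cell set is
#' supplied) versus normal T follicular helper cells. Significance is
#' Bonferroni-adjusted p below `p_adj_max` with log2 fold-change above
#' `min_log2fc`, via [wilcoxon_deg()].
#'
#' @param counts genes x cells count matrix for one sample.
#' @param tumor_cells,background_cells barcode vectors (background = all
#'   non-malignant MNCs).
#' @param tfh_cells optional barcodes of normal TFH cells; when absent the
#'   vs-TFH list is empty with a warning.
#' @param p_adj_max adjusted-p cutoff (default 0.05).
#' @param min_log2fc fold-change gate (default 0.25).
#' @param min_cells minimum tumor and background cells (default 20).
#' @return list with character vectors `vs_mnc` and `vs_tfh`.
#' @export
per_sample_tumor_deg <- function(counts, tumor_cells, background_cells,
                                 tfh_cells = NULL, p_adj_max = 0.05,
                                 min_log2fc = 0.25, min_cells = 20) {
  if (length(tumor_cells) < min_cells || length(background_cells) < min_cells)
    stop_named("group_size_error",
               "need at least %d tumor and background cells", min_cells)
  up <- function(bg) {
    deg <- wilcoxon_deg(counts, tumor_cells, bg, correction = "bonferroni")
    deg$gene[deg$p_adj < p_adj_max & deg$log2fc > min_log2fc]
  }
  vs_mnc <- up(background_cells)
  vs_tfh <- if (is.null(tfh_cells) || !length(tfh_cells)) {
    warning("no normal TFH cells in this sample; vs-TFH list empty")
    character()
  } else up(tfh_cells)
  list(vs_mnc = vs_mnc, vs_tfh = vs_tfh)
}

#' Cross-sample recurrence filter for a compartment
#'
#' A gene is kept when it is significant versus the all-MNC background in at
#' least `min_samples` samples and — when `require_tfh` (the LN rule) — also
#' versus normal TFH cells in at least `min_samples` samples.
#'
#' @param deg_lists list of [per_sample_tumor_deg()] outputs (one per
#'   sample).
#' @param min_samples recurrence threshold (default 2).
#' @param require_tfh also require vs-TFH recurrence (LN compartment).
#' @return data.frame gene, n_vs_mnc, n_vs_tfh, kept.
#' @export
recurrence_filter <- function(deg_lists, min_samples = 2, require_tfh = FALSE) {
  if (length(deg_lists) < min_samples)
    stop_named("recurrence_error", "fewer samples than min_samples")
  genes <- unique(unlist(lapply(deg_lists, function(l) c(l$vs_mnc, l$vs_tfh))))
  if (!length(genes))
    return(data.frame(gene = character(), n_vs_mnc = integer(),
                      n_vs_tfh = integer(), kept = logical()))
  n_mnc <- vapply(genes, function(g)
    sum(vapply(deg_lists, function(l) g %in% l$vs_mnc, logical(1))), integer(1))
  n_tfh <- vapply(genes, function(g)
    sum(vapply(deg_lists, function(l) g %in% l$vs_tfh, logical(1))), integer(1))
  kept <- n_mnc >= min_samples & (!require_tfh | n_tfh >= min_samples)
  data.frame(gene = genes, n_vs_mnc = n_mnc, n_vs_tfh = n_tfh, kept = kept,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect LN and PB candidate sets into final marker candidates
#'
#' Final candidates are genes recurrent in both compartments, sorted by
#' combined recurrence (descending) then gene symbol.
#'
#' @param ln_filter,pb_filter [recurrence_filter()] outputs for the LN and
#'   PB compartments.
#' @return data.frame gene, n_ln, n_pb, in_ln, in_pb, final_candidate.
#' @export
intersect_compartments <- function(ln_filter, pb_filter) {
  genes <- union(ln_filter$gene, pb_filter$gene)
  if (!length(genes))
    return(data.frame(gene = character(), n_ln = integer(), n_pb = integer(),
                      in_ln = logical(), in_pb = logical(),
                      final_candidate = logical()))
  in_ln <- genes %in% ln_filter$gene[ln_filter$kept]
  in_pb <- genes %in% pb_filter$gene[pb_filter$kept]
  n_ln <- ifelse(genes %in% ln_filter$gene,
                 ln_filter$n_vs_mnc[match(genes, ln_filter$gene)], 0L)
  n_pb <- ifelse(genes %in% pb_filter$gene,
                 pb_filter$n_vs_mnc[match(genes, pb_filter$gene)], 0L)
  out <- data.frame(gene = genes, n_ln = n_ln, n_pb = n_pb,
                    in_ln = in_ln, in_pb = in_pb,
                    final_candidate = in_ln & in_pb,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-(out$n_ln + out$n_pb), out$gene), , drop = FALSE]
}

#' Specificity filter on marker candidates
#'
#' Reproducible replacement for a manual embedding-inspection step: a
#' candidate must be expressed (count > 0) in fewer than `max_fraction` of
#' non-malignant cells pooled across samples.
#'
#' @param counts pooled genes x cells matrix.
#' @param nonmalignant_cells barcodes of the pooled non-malignant cells.
#' @param genes candidate genes.
#' @param max_fraction expressing-fraction ceiling (default 0.1).
#' @return the genes passing the filter.
#' @export
marker_specificity_filter <- function(counts, nonmalignant_cells, genes,
                                      max_fraction = 0.1) {
  genes <- intersect(genes, rownames(counts))
  if (!length(genes)) return(character())
  frac <- Matrix::rowMeans(counts[genes, nonmalignant_cells, drop = FALSE] > 0)
  genes[frac < max_fraction]
}
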