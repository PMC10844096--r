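#' Per-cell rank-based signature score
#'
#' A bounded mean-rank enrichment score used as a single-cell stand-in for
#' GSVA-style scoring. Per cell, genes are ranked by expression (ties get
#' average ranks) and the score is
#' `(mean rank of set genes - (N + 1)/2) / ((N - 1)/2)` with N the number of
#' genes in the matrix, so it lies in (-1, 1], is 0 for a fully tied cell and
#' is invariant under any strictly monotone transform of the cell's
#' expression vector.
#'
#' @param counts genes x cells count matrix with gene rownames.
#' @param gene_set character vector of member gene symbols, or a named list
#'   entry from [read_gmt()].
#' @param set_name label used in error messages.
#' @return named numeric vector of per-cell scores.
#' @export
signature_score <- function(counts, gene_set, set_name = "gene set") {
  genes <- rownames(counts)
  members <- intersect(unique(gene_set), genes)
  if (!length(members))
    stop_named("gene_set_error", "no genes of %s present in the matrix", set_name)
  n <- length(genes)
  if (n < 2) stop_named("gene_set_error", "need at least 2 genes to rank")
  m <- as.matrix(counts)
  ranks <- apply(m, 2, rank)
  score <- (colMeans(ranks[members, , drop = FALSE]) - (n + 1) / 2) / ((n - 1) / 2)
  setNames(score, colnames(counts))
}

#' Score several gene sets at once
#'
#' @param counts genes x cells count matrix.
#' @param gene_sets named list of character vectors.
#' @return cells x sets numeric matrix of scores.
#' @export
score_matrix <- function(counts, gene_sets) {
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  out <- vapply(names(gene_sets),
                function(nm) signature_score(counts, gene_sets[[nm]], nm),
                numeric(ncol(counts)))
  rownames(out) <- colnames(counts)
  out
}

#' Assign cell-cycle phase from S and G2M signatures
#'
#' Phase is G1 when both scores are <= 0, otherwise the phase with the larger
#' positive score; exact ties go to S.
#'
#' @param counts genes x cells count matrix.
#' @param s_set,g2m_set gene symbol vectors for the S-phase and G2M programs.
#' @return data.frame with barcode, s_score, g2m_score, phase.
#' @export
cell_cycle_phase <- function(counts, s_set, g2m_set) {
  if (length(intersect(s_set, g2m_set)))
    warning("S and G2M sets overlap; shared genes kept in both")
  s <- signature_score(counts, s_set, "S-phase set")
  g2m <- signature_score(counts, g2m_set, "G2M set")
  phase <- ifelse(s <= 0 & g2m <= 0, "G1", ifelse(g2m > s, "G2M", "S"))
  data.frame(barcode = colnames(counts), s_score = unname(s),
             g2m_score = unname(g2m), phase = phase,
             stringsAsFactors = FALSE)
}

#' Wilcoxon differential expression between two cell groups
#'
#' Per gene, a two-sided rank-sum test on log2(CP10K + 1) values;
#' log2 fold-change is the difference of group means on the same scale.
#' Genes expressed (count > 0) in fewer than `min_cells` cells across both
#' groups are not tested. Correction is over all tested genes.
#'
#' @param counts genes x cells count matrix.
#' @param group_a,group_b barcode vectors; must not overlap.
#' @param correction "bonferroni" or "BH".
#' @param min_cells minimum expressing cells across the union (default 3).
#' @return data.frame gene, log2fc, p, p_adj, direction ("up" = higher in
#'   group_a), sorted by p.
#' @export
wilcoxon_deg <- function(counts, group_a, group_b,
                         correction = c("bonferroni", "BH"), min_cells = 3) {
  correction <- match.arg(correction)
  if (length(intersect(group_a, group_b)))
    stop_named("group_overlap_error", "cell groups overlap")
  if (length(group_a) < 3 || length(group_b) < 3)
    stop_named("group_size_error", "both groups need at least 3 cells")
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  keep <- Matrix::rowSums(sub > 0) >= min_cells
  if (!any(keep))
    return(data.frame(gene = character(), log2fc = numeric(), p = numeric(),
                      p_adj = numeric(), direction = character()))
  lg <- log_cp10k(sub)[keep, , drop = FALSE]
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)
  res <- t(apply(lg, 1, function(v) {
    wt <- wilcoxon_rank_sum(v[ia], v[ib])
    c(mean(v[ia]) - mean(v[ib]), wt$p.value)
  }))
  out <- data.frame(gene = rownames(lg), log2fc = res[, 1], p = res[, 2],
                    stringsAsFactors = FALSE)
  out$p_adj <- p.adjust(out$p, method = if (correction == "BH") "BH" else "bonferroni")
  out$direction <- ifelse(out$log2fc >= 0, "up", "down")
  rownames(out) <- NULL
  out[order(out$p, out$gene), ]
}

#' Compare per-cluster signature scores against the pooled mean
#'
#' For each cluster, a one-sample Wilcoxon signed-rank test of that cluster's
#' scores against the mean score over all cells, BH-adjusted across clusters.
#' Clusters with fewer than 3 cells are excluded with a warning.
#'
#' @param scores per-cell numeric scores.
#' @param clusters per-cell cluster labels, same length.
#' @return data.frame cluster, n, mean_score, p, p_adj.
#' @export
compare_cluster_scores <- function(scores, clusters) {
  stopifnot(length(scores) == length(clusters))
  if (length(unique(clusters)) < 2)
    stop_named("cluster_error", "need at least 2 clusters to compare")
  pooled_mean <- mean(scores)
  tabs <- split(scores, clusters)
  small <- names(tabs)[lengths(tabs) < 3]
  if (length(small)) {
    warning(sprintf("cluster(s) with < 3 cells excluded: %s",
                    paste(small, collapse = ", ")))
    tabs <- tabs[lengths(tabs) >= 3]
  }
  if (!length(tabs))
    return(data.frame(cluster = character(), n = integer(),
                      mean_score = numeric(), p = numeric(), p_adj = numeric()))
  p <- vapply(tabs, function(v) {
    if (all(v == pooled_mean)) return(1)
    suppressWarnings(wilcox.test(v, mu = pooled_mean)$p.value)
  }, numeric(1))
  data.frame(cluster = names(tabs), n = lengths(tabs),
             mean_score = vapply(tabs, mean, numeric(1)),
             p = unname(p), p_adj = p.adjust(unname(p), "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  if (any(!lengths(sets))) stop_named("gene_set_error", "empty gene set in GMT")
  sets
}
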