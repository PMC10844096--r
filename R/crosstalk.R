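#' Built-in ligand-receptor pair list
#'
#' A small starter list of immune ligand-receptor pairs (complexes as
#' comma-separated members); real analyses should supply a curated table via
#' [read_lr_pairs()].
#'
#' @return data.frame pair_id, ligand_genes, receptor_genes.
#' @export
builtin_lr_pairs <- function() {
  data.frame(
    pair_id = c("IL21_IL21R", "TNF_TNFRSF1A", "TGFB1_TGFBR1R2",
                "CD40LG_CD40", "CD80_CD28", "CD86_CD28"),
    ligand_genes = c("IL21", "TNF", "TGFB1", "CD40LG", "CD80", "CD86"),
    receptor_genes = c("IL21R", "TNFRSF1A", "TGFBR1,TGFBR2", "CD40",
                       "CD28", "CD28"),
    stringsAsFactors = FALSE)
}

#' Read a ligand-receptor pair table
#'
#' TSV with columns pair_id, ligand_genes, receptor_genes; complex members
#' comma-separated.
#'
#' @param path TSV path.
#' @return list of pair lists (pair_id, ligand, receptor gene vectors).
#' @export
read_lr_pairs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "ligand_genes", "receptor_genes")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop_named("missing_column_error", "LR table lacks column(s): %s",
               paste(absent, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    list(pair_id = df$pair_id[i],
         ligand = strsplit(df$ligand_genes[i], ",")[[1]],
         receptor = strsplit(df$receptor_genes[i], ",")[[1]]))
}

# log2(CP10K + 1) for a gene subset, with library sizes from the full matrix
log_cp10k_rows <- function(counts, genes) {
  libs <- Matrix::colSums(counts)
  libs[libs == 0] <- 1
  m <- as.matrix(counts[genes, , drop = FALSE])
  log2(sweep(m, 2, libs, "/") * 1e4 + 1)
}

cluster_gene_stats <- function(lg, counts, labels, cluster, genes) {
  cols <- which(labels == cluster)
  list(means = rowMeans(lg[genes, cols, drop = FALSE]),
       frac = Matrix::rowMeans(counts[genes, cols, drop = FALSE] > 0))
}

#' Ligand-receptor mean expression score between two clusters
#'
#' Complex expression per cluster is the minimum over member genes of the
#' mean log2(CP10K + 1) expression; the pair score is the mean of the ligand
#' value in the sender cluster and the receptor value in the receiver
#' cluster. The pair is filtered (score NA) when any member gene on either
#' side is expressed in fewer than `min_expr_fraction` of its cluster's
#' cells.
#'
#' @param counts genes x cells count matrix.
#' @param labels per-cell cluster labels aligned with columns.
#' @param pair list with `pair_id`, `ligand`, `receptor` gene vectors.
#' @param sender,receiver cluster names.
#' @param min_expr_fraction expressing-cell floor (default 0.1).
#' @return list score (NA when filtered), filtered, ligand_value,
#'   receptor_value.
#' @export
lr_mean_score <- function(counts, labels, pair, sender, receiver,
                          min_expr_fraction = 0.1) {
  stopifnot(length(labels) == ncol(counts))
  for (cl in c(sender, receiver))
    if (!cl %in% labels)
      stop_named("cluster_error", "unknown cluster: %s", cl)
  genes <- c(pair$ligand, pair$receptor)
  missing <- setdiff(genes, rownames(counts))
  if (length(missing))
    stop_named("gene_set_error", "LR gene(s) absent from matrix: %s",
               paste(missing, collapse = ", "))
  lg <- log_cp10k_rows(counts, genes)
  s <- cluster_gene_stats(lg, counts, labels, sender, pair$ligand)
  r <- cluster_gene_stats(lg, counts, labels, receiver, pair$receptor)
  lig <- min(s$means); rec <- min(r$means)
  filtered <- any(s$frac < min_expr_fraction) || any(r$frac < min_expr_fraction)
  list(score = if (filtered) NA_real_ else (lig + rec) / 2,
       filtered = filtered, ligand_value = lig, receptor_value = rec)
}

#' Permutation p-value for a ligand-receptor score
#'
#' Cluster labels are shuffled across cells `n_perm` times and the score
#' recomputed (without the expression-fraction filter, the standard null);
#' `p = (1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @inheritParams lr_mean_score
#' @param n_perm permutations (default 1000; below 100 triggers a warning).
#' @param seed optional RNG seed.
#' @return list p.value, observed, null_mean.
#' @export
lr_permutation_p <- function(counts, labels, pair, sender, receiver,
                             n_perm = 1000, seed = NULL,
                             min_expr_fraction = 0.1) {
  if (n_perm < 100) warning("fewer than 100 permutations; p resolution is coarse")
  if (!is.null(seed)) set.seed(seed)
  obs <- lr_mean_score(counts, labels, pair, sender, receiver,
                       min_expr_fraction)
  observed <- (obs$ligand_value + obs$receptor_value) / 2
  genes <- c(pair$ligand, pair$receptor)
  lg <- log_cp10k_rows(counts, genes)
  n <- ncol(counts)
  is_s <- labels == sender
  is_r <- labels == receiver
  ind_s <- matrix(0, n, n_perm)
  ind_r <- matrix(0, n, n_perm)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n)
    ind_s[, p] <- is_s[ord]
    ind_r[, p] <- is_r[ord]
  }
  means_s <- (lg[pair$ligand, , drop = FALSE] %*% ind_s) / sum(is_s)
  means_r <- (lg[pair$receptor, , drop = FALSE] %*% ind_r) / sum(is_r)
  null_stats <- (apply(means_s, 2, min) + apply(means_r, 2, min)) / 2
  list(p.value = (1 + sum(null_stats >= observed - 1e-12)) / (n_perm + 1),
       observed = observed, null_mean = mean(null_stats))
}
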