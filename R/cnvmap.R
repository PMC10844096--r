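#' Relative expression against a reference cell set
#'
#' Standard expression-CNV preprocessing: counts are library-size normalized
#' to CP10K, log2(x + 1) transformed, centred per gene by the mean over the
#' reference cells, and clipped to `[-clip, +clip]`. Genes without a genomic
#' position are dropped (with a message); chromosomes with fewer than
#' `min_genes_per_chrom` positioned genes are excluded. Rows come back
#' ordered by (chromosome, start).
#'
#' @param counts genes x cells count matrix.
#' @param positions gene position table (see [read_gene_positions()]).
#' @param reference_cells barcodes of the reference (non-malignant) cells;
#'   must be a subset of the matrix columns.
#' @param clip symmetric clipping bound on the centred log2 ratio
#'   (default 1.0).
#' @param min_genes_per_chrom minimum positioned genes per analyzed
#'   chromosome (default 5).
#' @return genes x cells matrix of clipped log2 ratios with a `positions`
#'   attribute (the retained, ordered position rows).
#' @export
compute_relative_expression <- function(counts, positions, reference_cells,
                                        clip = 1.0, min_genes_per_chrom = 5) {
  if (!length(reference_cells))
    stop_named("reference_error", "reference cell set is empty")
  missing_ref <- setdiff(reference_cells, colnames(counts))
  if (length(missing_ref))
    stop_named("reference_error", "reference barcodes absent from matrix: %s",
               paste(head(missing_ref, 5), collapse = ", "))
  positions <- validate_gene_positions(positions)
  positions <- positions[positions$gene %in% rownames(counts), , drop = FALSE]
  dropped <- nrow(counts) - nrow(positions)
  if (dropped > 0)
    message(sprintf("%d gene(s) without genomic position dropped", dropped))
  keep_chrom <- names(which(table(positions$chrom) >= min_genes_per_chrom))
  positions <- positions[positions$chrom %in% keep_chrom, , drop = FALSE]
  if (!nrow(positions))
    stop_named("position_error", "no positioned genes left to analyze")
  lg <- log_cp10k(counts[positions$gene, , drop = FALSE])
  centred <- lg - rowMeans(lg[, reference_cells, drop = FALSE])
  centred[centred > clip] <- clip
  centred[centred < -clip] <- -clip
  attr(centred, "positions") <- positions
  centred
}

#' Positionally smooth log ratios into a CNV profile
#'
#' Per chromosome independently, a centred moving average over
#' position-ordered genes with windows that shrink at chromosome edges, then
#' per-cell median centring (subtracting each cell's median smoothed value)
#' to remove residual library-size offsets that would mimic whole-genome
#' gains.
#'
#' @param log_ratios output of [compute_relative_expression()].
#' @param window odd window width in genes (default 101).
#' @return `cnv_profile` object: list with `values` (genes x cells smoothed
#'   matrix), `positions`, and `window`.
#' @export
smooth_by_position <- function(log_ratios, window = 101) {
  if (window < 1 || window %% 2 == 0)
    stop_named("window_error", "window must be odd and >= 1")
  positions <- attr(log_ratios, "positions")
  if (is.null(positions))
    stop_named("window_error", "log_ratios must come from compute_relative_expression")
  h <- (window - 1) / 2
  out <- log_ratios
  for (ch in unique(positions$chrom)) {
    rows <- which(positions$chrom == ch)
    g <- length(rows)
    if (window > 2 * g)
      warning(sprintf("window %d exceeds 2x gene count on %s; shrunk", window, ch))
    x <- log_ratios[rows, , drop = FALSE]
    cs <- rbind(0, apply(x, 2, cumsum))
    i <- seq_len(g)
    lo <- pmax(i - h, 1); hi <- pmin(i + h, g)
    out[rows, ] <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1)
  }
  out <- sweep(out, 2, apply(out, 2, median))
  structure(list(values = out, positions = positions, window = window),
            class = "cnv_profile")
}

#' Call chromosome-level gains and losses per cell
#'
#' A chromosome is called gained in a cell when the fraction of its smoothed
#' windows above `gain_threshold` exceeds `min_window_fraction` (losses
#' symmetric below `loss_threshold`). When both directions exceed the
#' support requirement, the larger supporting fraction wins; an exact tie is
#' neutral.
#'
#' @param profile a `cnv_profile`.
#' @param gain_threshold,loss_threshold log2-ratio thresholds
#'   (defaults +0.1 / -0.1; gain must exceed loss).
#' @param min_window_fraction required fraction of supporting windows
#'   (default 0.5).
#' @return data.frame barcode, chrom, state, frac_gain, frac_loss.
#' @export
call_chromosome_cnv <- function(profile, gain_threshold = 0.1,
                                loss_threshold = -0.1,
                                min_window_fraction = 0.5) {
  if (gain_threshold <= loss_threshold)
    stop_named("threshold_error", "gain threshold must exceed loss threshold")
  v <- profile$values
  chroms <- unique(profile$positions$chrom)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    rows <- profile$positions$chrom == ch
    fg <- colMeans(v[rows, , drop = FALSE] > gain_threshold)
    fl <- colMeans(v[rows, , drop = FALSE] < loss_threshold)
    state <- rep("neutral", ncol(v))
    state[fg > min_window_fraction & fg > fl] <- "gain"
    state[fl > min_window_fraction & fl > fg] <- "loss"
    data.frame(barcode = colnames(v), chrom = ch, state = state,
               frac_gain = unname(fg), frac_loss = unname(fl),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-cell CNV aberrance score
#'
#' The mean over windows of the squared smoothed log2 ratio; zero iff the
#' profile is exactly neutral everywhere, and strictly increasing in any
#' window's absolute deviation.
#'
#' @param profile a `cnv_profile`.
#' @return data.frame barcode, score.
#' @export
cnv_score <- function(profile) {
  data.frame(barcode = colnames(profile$values),
             score = unname(colMeans(profile$values^2)),
             stringsAsFactors = FALSE)
}

#' Group cells into CNV subclones
#'
#' Ward-linkage hierarchical clustering on Euclidean distances between
#' smoothed profiles, cut into `k` groups. Deterministic given input order.
#'
#' @param profile a `cnv_profile`.
#' @param k number of subclones.
#' @return named integer vector of subclone labels per barcode.
#' @export
cluster_subclones <- function(profile, k) {
  n <- ncol(profile$values)
  if (n < 2) stop_named("cluster_error", "need at least 2 cells")
  if (k > n) stop_named("cluster_error", "k exceeds the number of cells")
  hc <- hclust(dist(t(profile$values)), method = "ward.D2")
  cutree(hc, k = k)
}

#' Mean CNV profile per subclone
#'
#' @param profile a `cnv_profile`.
#' @param labels per-cell subclone labels (named by barcode or aligned).
#' @return subclones x genes matrix of mean smoothed values.
#' @export
subclone_profiles <- function(profile, labels) {
  t(vapply(split(seq_len(ncol(profile$values)), labels),
           function(idx) rowMeans(profile$values[, idx, drop = FALSE]),
           numeric(nrow(profile$values))))
}

#' Build a CNV clone tree
#'
#' Neighbor-joining on pairwise Euclidean distances among subclone mean
#' profiles plus a synthetic all-neutral profile, rooted at the neutral
#' node.
#'
#' @param mean_profiles subclones x genes matrix (see [subclone_profiles()]).
#' @param root_label tip label for the neutral root (default "neutral").
#' @return rooted `phylo` tree with one tip per subclone plus the root tip.
#' @export
build_clone_tree <- function(mean_profiles, root_label = "neutral") {
  if (is.null(rownames(mean_profiles)))
    rownames(mean_profiles) <- paste0("subclone", seq_len(nrow(mean_profiles)))
  prof <- rbind(mean_profiles, matrix(0, 1, ncol(mean_profiles),
                                      dimnames = list(root_label, NULL)))
  d <- dist(prof)
  n <- nrow(prof)
  if (n == 2) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = rep(as.numeric(d) / 2, 2),
                 tip.label = rownames(prof), Nnode = 1L)
    class(tree) <- "phylo"
  } else {
    tree <- ape::nj(d)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  ape::root(tree, outgroup = root_label, resolve.root = TRUE)
}
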