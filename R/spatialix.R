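#' Build per-image neighbor graphs from a spatial cell table
#'
#' Radius rule: undirected edge iff Euclidean distance <= r micrometres
#' (default 15, roughly one cell-diameter ring). k-nearest rule: directed
#' k-nearest edges, symmetrized by union. No self edges.
#'
#' @param cells spatial cell table (image_id, x_um, y_um, cell_type).
#' @param rule "radius" or "knn".
#' @param param radius in micrometres, or k.
#' @return `neighbor_graph`: list of per-image lists with `adj` (sparse
#'   logical adjacency), `types`, `image_id`.
#' @export
build_neighbor_graph <- function(cells, rule = c("radius", "knn"), param = 15) {
  rule <- match.arg(rule)
  if (rule == "radius" && param <= 0)
    stop_named("graph_error", "radius must be > 0")
  if (rule == "knn" && param < 1)
    stop_named("graph_error", "k must be >= 1")
  images <- split(cells, cells$image_id)
  graphs <- lapply(images, function(d) {
    n <- nrow(d)
    if (n < 2) stop_named("graph_error", "image %s has fewer than 2 cells",
                          d$image_id[1])
    dm <- as.matrix(dist(cbind(d$x_um, d$y_um)))
    if (rule == "radius") {
      adj <- dm <= param
      diag(adj) <- FALSE
    } else {
      k <- min(param, n - 1)
      adj <- matrix(FALSE, n, n)
      for (i in seq_len(n)) {
        nb <- order(dm[i, ])[2:(k + 1)]
        adj[i, nb] <- TRUE
      }
      adj <- adj | t(adj)
    }
    list(adj = Matrix::Matrix(adj, sparse = TRUE), types = d$cell_type,
         image_id = d$image_id[1])
  })
  structure(graphs, class = "neighbor_graph")
}

score_one_image <- function(g, type_a, type_b, n_perm, alpha) {
  ind_a <- g$types == type_a
  ind_b <- g$types == type_b
  n_a <- sum(ind_a)
  observed <- sum(g$adj[ind_a, , drop = FALSE] %*% ind_b) / n_a
  n <- length(g$types)
  perm_a <- matrix(FALSE, n, n_perm)
  perm_b <- matrix(0, n, n_perm)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n)
    perm_a[, p] <- ind_a[ord]
    perm_b[, p] <- ind_b[ord]
  }
  counts <- as.matrix(g$adj %*% perm_b)
  null_stats <- colSums(counts * perm_a) / n_a
  null_mean <- mean(null_stats)
  null_sd <- sd(null_stats)
  p_att <- (1 + sum(null_stats >= observed - 1e-12)) / (n_perm + 1)
  p_avo <- (1 + sum(null_stats <= observed + 1e-12)) / (n_perm + 1)
  if (is.na(null_sd) || null_sd == 0) {
    z <- NA_real_
    classification <- "none"
    degenerate <- TRUE
  } else {
    z <- (observed - null_mean) / null_sd
    classification <- if (p_att <= alpha) "interaction"
      else if (p_avo <= alpha) "avoidance" else "none"
    degenerate <- FALSE
  }
  data.frame(image_id = g$image_id, type_a = type_a, type_b = type_b,
             observed = observed, null_mean = null_mean, null_sd = null_sd,
             z = z, p_attraction = p_att, p_avoidance = p_avo,
             classification = classification, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Neighborhood interaction score with a label-permutation null
#'
#' The observed statistic is the mean number of type-B neighbors per type-A
#' cell. The null shuffles all cell-type labels jointly within each image
#' (the graph stays fixed, type abundances are preserved); z is the
#' standardized deviation from the null, and the one-sided empirical
#' p-values use the add-one convention `(1 + #{perm >= obs}) / (n_perm + 1)`.
#' Higher scores indicate closer proximity (interaction), lower scores
#' avoidance. Images lacking either type are skipped.
#'
#' @param graph a `neighbor_graph`.
#' @param type_a,type_b the ordered cell-type pair.
#' @param n_perm permutations (default 1000).
#' @param seed optional RNG seed for reproducible permutations.
#' @param alpha significance level for classification (default 0.01).
#' @return data.frame with one row per scored image (see `score_one_image`
#'   fields); `degenerate` flags images whose null SD was zero.
#' @export
interaction_score <- function(graph, type_a, type_b, n_perm = 1000,
                              seed = NULL, alpha = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  keep <- vapply(graph, function(g)
    any(g$types == type_a) && any(g$types == type_b), logical(1))
  if (!any(keep))
    stop_named("spatial_error", "no image contains both %s and %s",
               type_a, type_b)
  out <- do.call(rbind, lapply(graph[keep], score_one_image,
                               type_a = type_a, type_b = type_b,
                               n_perm = n_perm, alpha = alpha))
  rownames(out) <- NULL
  out
}

#' Summarize interaction results across images
#'
#' @param results row-bound [interaction_score()] outputs, possibly for
#'   several type pairs.
#' @return data.frame per ordered pair: mean z across images, fraction of
#'   images significant as interaction / avoidance, image count.
#' @export
summarize_across_images <- function(results) {
  if (!nrow(results)) stop_named("empty_input_error", "no results")
  pair <- paste(results$type_a, results$type_b, sep = "|")
  out <- do.call(rbind, lapply(split(results, pair), function(d) {
    data.frame(type_a = d$type_a[1], type_b = d$type_b[1],
               n_images = nrow(d), mean_z = mean(d$z, na.rm = TRUE),
               frac_interaction = mean(d$classification == "interaction"),
               frac_avoidance = mean(d$classification == "avoidance"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
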