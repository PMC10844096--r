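#' Two-sided Wilcoxon rank-sum test
#'
#' The comparison engine used throughout the package. When both groups have
#' at most `exact_max` observations the two-sided p-value is computed by full
#' enumeration of all C(n1+n2, n1) group assignments of the pooled average
#' ranks (so ties are handled exactly); otherwise the normal approximation
#' with the usual tie correction and a 0.5 continuity correction is used.
#'
#' @param x,y numeric vectors of scores for the two groups.
#' @param exact_max use exact enumeration when both group sizes are <= this
#'   (default 10).
#' @return list with `statistic` (Mann-Whitney U of `x`), `p.value`, and
#'   `method` ("exact" or "normal").
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop_named("empty_group_error", "both groups must be nonempty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  u_obs <- w_obs - n1 * (n1 + 1) / 2
  mu <- n1 * (n1 + n2 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    # permutation distribution of the rank sum over all group assignments
    combos <- combn(n1 + n2, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    dev <- abs(sums - mu)
    p <- mean(dev >= abs(w_obs - mu) - 1e-9)
    return(list(statistic = u_obs, p.value = p, method = "exact"))
  }
  n <- n1 + n2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(list(statistic = u_obs, p.value = 1, method = "normal"))
  z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(statistic = u_obs, p.value = p, method = "normal")
}

#' Library-size normalization to counts-per-10k, log2 scale
#'
#' @param counts genes x cells matrix (sparse or dense).
#' @return dense matrix of log2(CP10K + 1) values.
#' @export
log_cp10k <- function(counts) {
  libs <- Matrix::colSums(counts)
  libs[libs == 0] <- 1
  m <- as.matrix(counts)
  log2(sweep(m, 2, libs, "/") * 1e4 + 1)
}
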