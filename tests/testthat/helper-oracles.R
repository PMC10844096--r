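# Independent oracles used to verify the package's implementations.
# These deliberately take different computational routes than the package.

# Exact two-sided rank-sum p by enumerating group assignments and counting
# Mann-Whitney pair wins directly from the raw values (no ranks).
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Textbook neighbor joining from the Q-matrix definition.
oracle_nj <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  nodes <- as.list(labels)
  # patristic distance bookkeeping: accumulate leaf-to-leaf tree distances
  leaf_names <- labels
  patristic <- matrix(0, length(leaf_names), length(leaf_names),
                      dimnames = list(leaf_names, leaf_names))
  depth <- setNames(as.list(lapply(labels, function(l) setNames(0, l))), labels)
  active <- labels
  while (length(active) > 2) {
    m <- length(active)
    dd <- d[active, active]
    r <- rowSums(dd)
    q <- (m - 2) * dd - outer(r, r, "+")
    diag(q) <- Inf
    ij <- which(q == min(q), arr.ind = TRUE)[1, ]
    i <- active[ij[1]]; j <- active[ij[2]]
    li <- 0.5 * dd[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dd[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new <- paste0("(", i, ",", j, ")")
    di <- depth[[i]] + li
    dj <- depth[[j]] + lj
    for (a in names(di)) for (b in names(dj)) {
      patristic[a, b] <- patristic[b, a] <- di[a] + dj[b]
    }
    depth[[new]] <- c(di, dj)
    dnew <- setNames(0.5 * (d[i, active] + d[j, active] - dd[i, j]), active)
    d <- rbind(cbind(d, 0), 0)
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- new
    d[new, active] <- d[active, new] <- dnew
    active <- c(setdiff(active, c(i, j)), new)
  }
  i <- active[1]; j <- active[2]
  lij <- d[i, j]
  for (a in names(depth[[i]])) for (b in names(depth[[j]])) {
    patristic[a, b] <- patristic[b, a] <- depth[[i]][a] + depth[[j]][b] + lij
  }
  patristic
}

# Adjusted Rand index, standard pair-counting formula.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Brute-force centred moving average with shrinking edge windows.
oracle_moving_average <- function(x, window) {
  h <- (window - 1) / 2
  g <- length(x)
  vapply(seq_len(g), function(i) mean(x[max(1, i - h):min(g, i + h)]),
         numeric(1))
}

# Small shared simulation setups --------------------------------------------

tiny_genome <- function(genes_per_chrom = 20,
                        chroms = c("chr1", "chr2", "chr5")) {
  default_genome(chroms, genes_per_chrom)
}

tiny_tumor_config <- function(seed = 1, n_tumor = 100, n_bg = 100,
                              single_chain = 0, ...) {
  sim_config(
    populations = list(
      population_spec("tumor", n_tumor, is_tumor = TRUE),
      population_spec("CD4", n_bg)),
    tumor_clone_specs = list(list(id = "clone1", fraction = 1,
                                  single_chain_fraction = single_chain)),
    genome = tiny_genome(), seed = seed, ...)
}
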