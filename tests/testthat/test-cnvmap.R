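toy_positions <- function(n = 12, chrom = "chr1") {
  data.frame(gene = sprintf("%s_t%02d", chrom, 1:n), chrom = chrom,
             start = seq_len(n) * 1000, end = seq_len(n) * 1000 + 10)
}

test_that("a query cell equal to the reference mean centres to zero", {
  pos <- toy_positions(10)
  m <- Matrix::Matrix(matrix(5, 10, 4, dimnames = list(pos$gene,
                                                       c("r1", "r2", "q1", "q2"))),
                      sparse = TRUE)
  rel <- compute_relative_expression(m, pos, c("r1", "r2"))
  expect_true(all(abs(rel) < 1e-12))
})

test_that("noiseless equal-library dosage 1.5 recovers log2(1.5) on chr5", {
  pos <- rbind(toy_positions(40, "chr1"), toy_positions(20, "chr5"))
  n_other <- 40; n_chr5 <- 20
  # query libraries equal to reference by compensating non-chr5 genes
  ref_val <- 100
  q_other <- (ref_val * (n_other + n_chr5) - 1.5 * ref_val * n_chr5) / n_other
  m <- cbind(matrix(ref_val, 60, 2),
             c(rep(q_other, n_other), rep(1.5 * ref_val, n_chr5)))
  dimnames(m) <- list(pos$gene, c("r1", "r2", "q"))
  rel <- compute_relative_expression(Matrix::Matrix(m, sparse = TRUE), pos,
                                     c("r1", "r2"))
  chr5_vals <- rel[attr(rel, "positions")$chrom == "chr5", "q"]
  expect_equal(unname(chr5_vals), rep(log2(1.5), n_chr5), tolerance = 0.01)
})

test_that("centred ratios are clipped to the bound", {
  pos <- toy_positions(10)
  m <- matrix(10, 10, 3, dimnames = list(pos$gene, c("r1", "r2", "q")))
  m[, "q"] <- 10 * 2^5   # raw ratio far beyond the clip
  rel <- compute_relative_expression(Matrix::Matrix(m, sparse = TRUE), pos,
                                     c("r1", "r2"), clip = 1.0)
  expect_true(all(rel[, "q"] <= 1.0 + 1e-12))
  expect_error(compute_relative_expression(m, pos, character()),
               class = "reference_error")
})

test_that("smoothing matches a brute-force moving average and centres medians", {
  pos <- toy_positions(30)
  set.seed(5)
  vals <- rnorm(30)
  m <- matrix(vals, 30, 1, dimnames = list(pos$gene, "q"))
  attr(m, "positions") <- pos
  prof <- smooth_by_position(m, window = 7)
  expected <- oracle_moving_average(vals, 7)
  expected <- expected - median(expected)
  expect_equal(unname(prof$values[, 1]), expected, tolerance = 1e-12)
  # constant input -> all zero after median centring
  mc <- matrix(3, 30, 1, dimnames = list(pos$gene, "q"))
  attr(mc, "positions") <- pos
  expect_true(all(smooth_by_position(mc, 7)$values == 0))
  # window 1 on median-zero input is the identity
  v0 <- vals - median(vals)
  m0 <- matrix(v0, 30, 1, dimnames = list(pos$gene, "q"))
  attr(m0, "positions") <- pos
  expect_equal(unname(smooth_by_position(m0, 1)$values[, 1]), v0)
  # step input produces the brute-force ramp
  step <- rep(c(0, 1), each = 15)
  ms <- matrix(step, 30, 1, dimnames = list(pos$gene, "q"))
  attr(ms, "positions") <- pos
  ramp <- oracle_moving_average(step, 9)
  expect_equal(unname(smooth_by_position(ms, 9)$values[, 1]),
               ramp - median(ramp), tolerance = 1e-12)
  expect_error(smooth_by_position(m, 4), class = "window_error")
  expect_warning(smooth_by_position(m, 101), "shrunk")
})

test_that("chromosome calls follow the window-support rule symmetrically", {
  pos <- toy_positions(10)
  mk_prof <- function(vals) {
    m <- matrix(vals, 10, 1, dimnames = list(pos$gene, "q"))
    structure(list(values = m, positions = pos, window = 1),
              class = "cnv_profile")
  }
  expect_equal(call_chromosome_cnv(mk_prof(rep(0, 10)))$state, "neutral")
  expect_equal(call_chromosome_cnv(mk_prof(c(rep(0.3, 6), rep(0, 4))))$state,
               "gain")
  expect_equal(call_chromosome_cnv(mk_prof(c(rep(-0.3, 6), rep(0, 4))))$state,
               "loss")
  # equal support both ways is neutral
  expect_equal(call_chromosome_cnv(mk_prof(c(rep(0.3, 5), rep(-0.3, 5))),
                                   min_window_fraction = 0.4)$state, "neutral")
  expect_error(call_chromosome_cnv(mk_prof(rep(0, 10)), gain_threshold = -0.2,
                                   loss_threshold = 0.2),
               class = "threshold_error")
})

test_that("cnv score is the mean squared deviation and is monotone", {
  pos <- toy_positions(10)
  prof <- structure(list(values = matrix(c(rep(0, 10), rep(0.2, 10)), 10, 2,
                                         dimnames = list(pos$gene, c("a", "b"))),
                         positions = pos, window = 1), class = "cnv_profile")
  sc <- cnv_score(prof)
  expect_equal(sc$score, c(0, 0.04))
  prof$values[3, "a"] <- 0.5
  expect_gt(cnv_score(prof)$score[1], 0)
})

test_that("planted gain/neutral groups cluster with high agreement at k=2", {
  # nb_mean 3 puts libraries at typical droplet depth, where carrier and
  # neutral profiles are well separated; hard clustering blurs at
  # shallower depth even though per-cell calls stay accurate
  cfg <- sim_config(
    populations = list(population_spec("tumor", 400, is_tumor = TRUE),
                       population_spec("ref", 200)),
    tumor_clone_specs = list(list(id = "c", fraction = 1,
                                  single_chain_fraction = 0)),
    cnv_events = list(list(chrom = "chr5", multiplier = 1.5, fraction = 0.5)),
    nb_mean = 3, seed = 61)
  sim <- generate_expression(cfg)
  tr <- sim$truth
  rel <- compute_relative_expression(sim$counts, cfg$genome,
                                     tr$barcode[!tr$is_tumor])
  prof <- smooth_by_position(rel, 101)
  tum <- tr$barcode[tr$is_tumor]
  tp <- prof; tp$values <- prof$values[, tum]
  labels <- cluster_subclones(tp, k = 2)
  truth <- tr$cnv_chr5[match(tum, tr$barcode)]
  expect_gte(oracle_ari(labels, truth), 0.9)
  expect_error(cluster_subclones(tp, k = 10000), class = "cluster_error")
  expect_equal(unique(cluster_subclones(tp, k = 1)), 1L)
  # duplicating the dataset preserves the partition structure
  tp2 <- tp
  tp2$values <- cbind(tp$values, tp$values)
  colnames(tp2$values) <- c(paste0(tum, "_1"), paste0(tum, "_2"))
  labels2 <- cluster_subclones(tp2, k = 2)
  expect_gte(oracle_ari(labels2[seq_along(tum)], labels), 0.99)
})

test_that("clone trees reproduce oracle NJ distances and planted topology", {
  set.seed(71)
  profs <- matrix(rnorm(4 * 30), 4, 30,
                  dimnames = list(paste0("s", 1:4), NULL))
  tree <- build_clone_tree(profs)
  d_in <- as.matrix(dist(rbind(profs, neutral = rep(0, 30))))
  pat_oracle <- oracle_nj(as.dist(d_in))
  pat_impl <- cophenetic(tree)
  nm <- rownames(pat_oracle)
  err_impl <- sum((pat_impl[nm, nm] - d_in[nm, nm])^2)
  err_oracle <- sum((pat_oracle - d_in[nm, nm])^2)
  expect_equal(err_impl, err_oracle, tolerance = 1e-6)
  expect_equal(pat_impl[nm, nm], pat_oracle, tolerance = 1e-6)

  # single subclone: a root-leaf tree whose length is its distance to neutral
  single <- matrix(c(3, 4), 1, 2, dimnames = list("s1", NULL))
  t1 <- build_clone_tree(single)
  expect_setequal(t1$tip.label, c("s1", "neutral"))
  expect_equal(sum(t1$edge.length), 5)

  # chr5+chr21 subclone attaches within the chr5 branch
  g <- 60
  neutral_like <- rep(0, g)
  chr5 <- c(rep(0.5, 20), rep(0, 40))
  chr5_21 <- c(rep(0.5, 20), rep(0.5, 20), rep(0, 20))
  mp <- rbind(neutral_like = neutral_like + rnorm(g, 0, 0.01),
              chr5 = chr5, chr5_21 = chr5_21)
  t3 <- build_clone_tree(mp)
  expect_true(ape::is.monophyletic(t3, c("chr5", "chr5_21")))
  expect_false(ape::is.monophyletic(t3, c("neutral_like", "chr5_21")))
})

test_that("reference cells centre to near-zero mean per gene", {
  cfg <- tiny_tumor_config(seed = 81, n_tumor = 50, n_bg = 100)
  sim <- generate_expression(cfg)
  ref <- sim$truth$barcode[!sim$truth$is_tumor]
  rel <- compute_relative_expression(sim$counts, cfg$genome, ref, clip = 10)
  expect_lt(max(abs(rowMeans(rel[, ref]))), 1e-10)
})
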