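test_that("identical config and seed give byte-identical outputs", {
  cfg <- tiny_tumor_config(seed = 5, single_chain = 0.3,
                           mutation_specs = list(list(
                             locus = "L1", mutant_patient = TRUE,
                             capture = 0.5, mean_coverage = 4)))
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth, b$truth)
  expect_identical(generate_contigs(cfg, a$truth), generate_contigs(cfg, b$truth))
  expect_identical(generate_pileups(cfg, a$truth), generate_pileups(cfg, b$truth))
})

test_that("cell counts and truth cover every population exactly once", {
  cfg <- tiny_tumor_config(seed = 2, n_tumor = 40, n_bg = 60)
  sim <- generate_expression(cfg)
  expect_equal(ncol(sim$counts), 100)
  expect_equal(anyDuplicated(sim$truth$barcode), 0)
  expect_equal(as.vector(table(sim$truth$population)[c("tumor", "CD4")]),
               c(40, 60))
})

test_that("config validation rejects bad programs, fractions and dosages", {
  expect_error(sim_config(populations = list()), class = "config_error")
  expect_error(
    sim_config(populations = list(population_spec("a", 5, "NOT_A_GENE", 2)),
               genome = tiny_genome()),
    "NOT_A_GENE", class = "config_error")
  expect_error(
    tiny_tumor_config(single_chain = 1.4), class = "config_error")
  expect_error(
    sim_config(populations = list(population_spec("a", 5)),
               cnv_events = list(list(chrom = "chr1", multiplier = -1,
                                      fraction = 0.5)),
               genome = tiny_genome()),
    class = "config_error")
})

test_that("dosage 1.0 leaves carrier and non-carrier chr5 expression equal", {
  cfg <- tiny_tumor_config(seed = 3, n_tumor = 500, n_bg = 500,
                           cnv_events = list(list(chrom = "chr5",
                                                  multiplier = 1.0,
                                                  fraction = 0.5)))
  sim <- generate_expression(cfg)
  rows <- cfg$genome$chrom == "chr5"
  carrier <- sim$truth$cnv_chr5
  ratio <- mean(as.matrix(sim$counts[rows, carrier])) /
    mean(as.matrix(sim$counts[rows, !carrier]))
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("dosage 1.5 in the Poisson limit recovers the 1.5 mean ratio", {
  cfg <- sim_config(
    populations = list(population_spec("tumor", 2000, is_tumor = TRUE),
                       population_spec("bg", 2000)),
    tumor_clone_specs = list(list(id = "c", fraction = 1,
                                  single_chain_fraction = 0)),
    cnv_events = list(list(chrom = "chr5", multiplier = 1.5, fraction = 1)),
    nb_dispersion = Inf, genome = tiny_genome(), seed = 11)
  sim <- generate_expression(cfg)
  rows <- cfg$genome$chrom == "chr5"
  carrier <- sim$truth$cnv_chr5
  n_draws <- sum(rows) * sum(carrier)
  # carrier mean 1.5, variance 1.5/n; delta-method SE on the ratio
  se <- sqrt(1.5 / n_draws + 1.5^2 * 1 / (sum(rows) * sum(!carrier)))
  base_mean <- mean(as.matrix(sim$counts[rows, !carrier]))
  ratio <- mean(as.matrix(sim$counts[rows, carrier])) / base_mean
  expect_lt(abs(ratio - 1.5), 2 * se / base_mean * 1.5 + 0.02)
  expect_lt(abs(ratio - 1.5), 0.05)
})

test_that("marker genes are elevated only in tumor cells", {
  cfg <- tiny_tumor_config(seed = 7, n_tumor = 300, n_bg = 300,
                           marker_genes = "chr2_g001", marker_fc = 8)
  sim <- generate_expression(cfg)
  tum <- sim$truth$is_tumor
  expect_gt(mean(sim$counts["chr2_g001", tum]), 4)
  expect_lt(mean(sim$counts["chr2_g001", !tum]), 2)
})

test_that("single_chain_fraction zero yields exactly one TRA and one TRB per tumor cell", {
  cfg <- tiny_tumor_config(seed = 4, single_chain = 0)
  tr <- sim_truth(cfg)
  ct <- generate_contigs(cfg, tr)
  tum <- ct[ct$barcode %in% tr$barcode[tr$is_tumor], ]
  per <- table(tum$barcode, tum$chain)
  expect_true(all(per[, "TRA"] == 1))
  expect_true(all(per[, "TRB"] == 1))
})

test_that("two clones with identical TRB and distinct TRA share one TRB string", {
  trb <- strrep("ACG", 12)
  cfg <- sim_config(
    populations = list(population_spec("tumor", 200, is_tumor = TRUE)),
    tumor_clone_specs = list(
      list(id = "c1", fraction = 0.5, single_chain_fraction = 0,
           cdr3_nt_trb = trb),
      list(id = "c2", fraction = 0.5, single_chain_fraction = 0,
           cdr3_nt_trb = trb)),
    genome = tiny_genome(), seed = 8)
  tr <- sim_truth(cfg)
  ct <- generate_contigs(cfg, tr)
  keys <- assemble_clonotypes(ct)$key
  expect_equal(length(unique(keys)), 2)
  expect_true(all(grepl(trb, unique(keys), fixed = TRUE)))
  tras <- unique(ct$cdr3_nt[ct$chain == "TRA"])
  expect_equal(length(tras), 2)
})

test_that("single-chain counts are binomial with the configured rate", {
  # one draw is reproducible under its seed; the mean over seeds matches
  # n * p within 3 standard errors of the binomial mean
  n_seeds <- 60
  counts <- vapply(seq_len(n_seeds), function(s) {
    tr <- sim_truth(tiny_tumor_config(seed = 1000 + s, n_tumor = 1000,
                                      n_bg = 10, single_chain = 0.3))
    sum(tr$single_chain)
  }, numeric(1))
  se_mean <- sqrt(1000 * 0.3 * 0.7 / n_seeds)
  expect_lt(abs(mean(counts) - 300), 3 * se_mean)
  tr1 <- sim_truth(tiny_tumor_config(seed = 1001, n_tumor = 1000, n_bg = 10,
                                     single_chain = 0.3))
  expect_equal(sum(tr1$single_chain), counts[1])
})

test_that("pileups honour capture probability limits", {
  base <- function(capture, seed) tiny_tumor_config(
    seed = seed, n_tumor = 200, n_bg = 50,
    mutation_specs = list(list(locus = "L1", mutant_patient = TRUE,
                               capture = capture, mean_coverage = 50)))
  cfg <- base(1, 21)
  tr <- sim_truth(cfg)
  p <- generate_pileups(cfg, tr)
  mut_cov <- p$barcode %in% tr$barcode[tr$mut_L1] & p$total > 0
  expect_true(all(p$alt_reads[mut_cov] >= 1))
  cfg0 <- base(0, 22)
  p0 <- generate_pileups(cfg0, sim_truth(cfg0))
  expect_true(all(p0$alt_reads == 0))
  non_mut <- p$barcode %in% tr$barcode[!tr$mut_L1]
  expect_true(all(p$alt_reads[non_mut] == 0))
})

test_that("mutant detection rate matches the Bernoulli x Poisson closed form", {
  cfg <- tiny_tumor_config(
    seed = 23, n_tumor = 500, n_bg = 10,
    mutation_specs = list(list(locus = "L1", mutant_patient = TRUE,
                               capture = 0.6, mean_coverage = 3)))
  tr <- sim_truth(cfg)
  p <- generate_pileups(cfg, tr)
  mut <- p[p$barcode %in% tr$barcode[tr$mut_L1], ]
  expected <- 0.6 * (1 - exp(-3))
  obs <- mean(mut$alt_reads >= 1)
  se <- sqrt(expected * (1 - expected) / nrow(mut))
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("spatial generator plants CSR, attraction and avoidance as configured", {
  spat_cfg <- function(att, avo, seed) sim_config(
    populations = list(population_spec("x", 1)),
    spatial_spec = list(n_images = 3, field_um = 400,
                        intensity = c(A = 5e-4, B = 5e-4),
                        attraction_pairs = att, avoidance_pairs = avo),
    genome = tiny_genome(), seed = seed)
  # attraction: nearest A-B distances shrink below a CSR Monte-Carlo null
  cfg_att <- spat_cfg(list(list(a = "A", b = "B", radius = 20,
                                n_parents = 12, offspring_per_parent = 4)),
                      list(), 31)
  sp <- generate_spatial(cfg_att)
  one <- sp$cells[sp$cells$image_id == "img01", ]
  a <- one[one$cell_type == "A", ]; b <- one[one$cell_type == "B", ]
  dmat <- sqrt(outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2)
  obs_nn <- mean(apply(dmat, 1, min))
  csr_nn <- replicate(50, {
    bx <- runif(nrow(b), 0, 400); by <- runif(nrow(b), 0, 400)
    d2 <- sqrt(outer(a$x_um, bx, "-")^2 + outer(a$y_um, by, "-")^2)
    mean(apply(d2, 1, min))
  })
  expect_lt(obs_nn, quantile(csr_nn, 0.01))
  # avoidance halves: no cross neighbors below field/4
  cfg_avo <- spat_cfg(list(), list(list(a = "A", b = "B")), 32)
  sp2 <- generate_spatial(cfg_avo)
  one2 <- sp2$cells[sp2$cells$image_id == "img01", ]
  a2 <- one2[one2$cell_type == "A", ]; b2 <- one2[one2$cell_type == "B", ]
  d2 <- sqrt(outer(a2$x_um, b2$x_um, "-")^2 + outer(a2$y_um, b2$y_um, "-")^2)
  expect_true(all(d2 >= 100) || min(d2) >= 100)
  # contradictory spec rejected
  expect_error(spat_cfg(list(list(a = "A", b = "B", radius = 20,
                                  n_parents = 2, offspring_per_parent = 2)),
                        list(list(a = "B", b = "A")), 33),
               class = "config_error")
})

test_that("a written fixture set reads back consistently", {
  dir <- withr::local_tempdir()
  cfg <- tiny_tumor_config(
    seed = 41, n_tumor = 50, n_bg = 50,
    mutation_specs = list(list(locus = "L1", mutant_patient = TRUE,
                               capture = 0.5, mean_coverage = 4)))
  write_synthetic_dataset(cfg, dir)
  counts <- read_count_matrix(dir)
  meta <- read_cellmeta(file.path(dir, "cells.tsv"))
  contigs <- read_contigs(file.path(dir, "filtered_contig_annotations.csv"))
  expect_equal(ncol(counts), 100)
  expect_setequal(meta$barcode, colnames(counts))
  expect_true(all(contigs$barcode %in% meta$barcode))
  expect_true(file.exists(file.path(dir, "truth.json")))
})
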