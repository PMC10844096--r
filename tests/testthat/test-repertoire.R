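contig_row <- function(barcode, chain, cdr3_nt, v = "V1", j = "J1",
                       productive = TRUE, umis = 5) {
  chain_v <- if (chain %in% c("TRA", "TRB")) paste0(substr(chain, 1, 3), "V1") else v
  data.frame(barcode = barcode, chain = chain, v_gene = v, j_gene = j,
             cdr3 = "CASX", cdr3_nt = cdr3_nt, productive = productive,
             umis = umis, stringsAsFactors = FALSE)
}

test_that("clonotype keys are canonical under contig input order", {
  rows <- rbind(contig_row("c1", "TRA", "AAA"), contig_row("c1", "TRB", "CCC"),
                contig_row("c2", "TRB", "CCC"), contig_row("c2", "TRA", "AAA"))
  asn <- assemble_clonotypes(rows)
  expect_equal(asn$key[asn$barcode == "c1"], asn$key[asn$barcode == "c2"])
  # matches an explicit sorted-tuple construction
  expected <- paste(sort(c("TRA:V1:J1:AAA", "TRB:V1:J1:CCC")), collapse = ";")
  expect_equal(unique(asn$key), expected)
})

test_that("chain configurations follow the productive chain census", {
  rows <- rbind(
    contig_row("paired", "TRA", "AAA"), contig_row("paired", "TRB", "BBB"),
    contig_row("alpha", "TRA", "AAA"),
    contig_row("beta", "TRB", "BBB"),
    contig_row("multi", "TRA", "AAA"), contig_row("multi", "TRA", "GGG"),
    contig_row("multi", "TRB", "BBB"),
    contig_row("nonprod", "TRB", "BBB", productive = FALSE))
  asn <- assemble_clonotypes(rows)
  cfg <- setNames(asn$chain_config, asn$barcode)
  expect_equal(cfg[["paired"]], "paired")
  expect_equal(cfg[["alpha"]], "single_alpha")
  expect_equal(cfg[["beta"]], "single_beta")
  expect_equal(cfg[["multi"]], "multi")
  expect_false("nonprod" %in% asn$barcode)
})

test_that("duplicate identical tuples collapse; distinct ones persist", {
  rows <- rbind(contig_row("c1", "TRB", "BBB", umis = 9),
                contig_row("c1", "TRB", "BBB", umis = 2),
                contig_row("c1", "TRA", "AAA"))
  asn <- assemble_clonotypes(rows)
  expect_equal(asn$chain_config, "paired")
  expect_equal(asn$n_chains, 2L)
})

test_that("clone sizes match a brute-force counter", {
  set.seed(9)
  keys <- sample(sprintf("k%02d", 1:10), 100, replace = TRUE)
  asn <- data.frame(barcode = sprintf("c%03d", 1:100), key = keys,
                    stringsAsFactors = FALSE)
  sizes <- clone_sizes(asn)
  brute <- sort(table(keys), decreasing = TRUE)
  expect_equal(sum(sizes$size), 100)
  expect_equal(setNames(sizes$size, sizes$key)[names(brute)],
               setNames(as.integer(brute), names(brute)))
})

test_that("a 40-cell clone among singletons is the major clone at fraction 0.40", {
  asn <- data.frame(
    barcode = sprintf("c%03d", 1:100),
    key = c(rep("TRA:V:J:AAA;TRB:V:J:BBB", 40), sprintf("solo%02d", 1:60)),
    chain_config = "paired",
    tra_cdr3_nt = c(rep("AAA", 40), sprintf("a%02d", 1:60)),
    trb_cdr3_nt = c(rep("BBB", 40), sprintf("b%02d", 1:60)),
    stringsAsFactors = FALSE)
  res <- call_tumor_clones(asn)
  expect_equal(res$tumor_fraction, 0.40)
  major <- res$clonotypes[res$clonotypes$label == "major", ]
  expect_equal(major$size, 40L)
})

test_that("all-singleton repertoires produce no tumor clone", {
  asn <- data.frame(barcode = sprintf("c%02d", 1:50),
                    key = sprintf("k%02d", 1:50), chain_config = "paired",
                    tra_cdr3_nt = sprintf("a%02d", 1:50),
                    trb_cdr3_nt = sprintf("b%02d", 1:50),
                    stringsAsFactors = FALSE)
  res <- call_tumor_clones(asn)
  expect_equal(res$tumor_fraction, 0)
  expect_true(all(res$clonotypes$label == "none"))
})

test_that("clones sharing a TRB merge into one tumor group", {
  asn <- data.frame(
    barcode = sprintf("c%03d", 1:100),
    key = c(rep("kA", 30), rep("kB", 20), sprintf("solo%02d", 1:50)),
    chain_config = "paired",
    tra_cdr3_nt = c(rep("TRA1", 30), rep("TRA2", 20), sprintf("a%02d", 1:50)),
    trb_cdr3_nt = c(rep("SHARED", 50), sprintf("b%02d", 1:50)),
    stringsAsFactors = FALSE)
  res <- call_tumor_clones(asn)
  labs <- res$clonotypes$label[match(c("kA", "kB"), res$clonotypes$key)]
  expect_equal(labs, c("major", "major"))
  expect_equal(length(res$related_groups[[1]]), 2)
  expect_equal(res$tumor_fraction, 0.5)
})

test_that("tumor calling is invariant to duplicating every cell", {
  asn <- data.frame(
    barcode = sprintf("c%03d", 1:60),
    key = c(rep("kA", 12), sprintf("solo%02d", 1:48)),
    chain_config = "paired",
    tra_cdr3_nt = c(rep("TA", 12), sprintf("a%02d", 1:48)),
    trb_cdr3_nt = c(rep("TB", 12), sprintf("b%02d", 1:48)),
    stringsAsFactors = FALSE)
  doubled <- asn[rep(seq_len(60), 2), ]
  doubled$barcode <- sprintf("c%03d", 1:120)
  r1 <- call_tumor_clones(asn)
  r2 <- call_tumor_clones(doubled)
  expect_equal(r1$clonotypes$label[order(r1$clonotypes$key)],
               r2$clonotypes$label[order(r2$clonotypes$key)])
  expect_equal(r1$tumor_fraction, r2$tumor_fraction)
})

test_that("overlap indices match hand values and their identities", {
  expect_equal(repertoire_overlap(c("a", "b"), c("a", "b"), "jaccard"), 1)
  expect_equal(repertoire_overlap(c("a", "b"), c("a", "b"), "morisita"), 1)
  expect_equal(repertoire_overlap(c("a"), c("b"), "public"), 0)
  expect_equal(repertoire_overlap(c("a"), c("b"), "jaccard"), 0)
  expect_equal(repertoire_overlap(c("a"), c("b"), "morisita"), 0)
  a <- c("k1", "k1", "k2"); b <- c("k1", "k3")
  expect_equal(repertoire_overlap(a, b, "jaccard"), 1 / 3)
  expect_equal(repertoire_overlap(a, b, "morisita"), 12 / 19)
  # symmetry and order invariance
  expect_equal(repertoire_overlap(b, a, "morisita"),
               repertoire_overlap(a, b, "morisita"))
  expect_equal(repertoire_overlap(sample(a), sample(b), "morisita"),
               repertoire_overlap(a, b, "morisita"))
  expect_error(repertoire_overlap(a, b, "cosine"))
})

test_that("cross-compartment sharing equals the intersection of clone sizes", {
  asn_ln <- data.frame(barcode = sprintf("l%02d", 1:7),
                       key = c("k1", "k1", "k1", "k2", "k2", "k3", "k4"),
                       stringsAsFactors = FALSE)
  asn_pb <- data.frame(barcode = sprintf("p%02d", 1:4),
                       key = c("k1", "k2", "k2", "k9"),
                       stringsAsFactors = FALSE)
  sh <- cross_compartment_sharing(asn_ln, asn_pb)
  expect_setequal(sh$key, c("k1", "k2"))
  expect_equal(sh$size_a[sh$key == "k1"], 3L)
  expect_equal(sh$size_b[sh$key == "k2"], 2L)
  none <- cross_compartment_sharing(
    data.frame(barcode = "x", key = "only_ln"),
    data.frame(barcode = "y", key = "only_pb"))
  expect_equal(nrow(none), 0)
})
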