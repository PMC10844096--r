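#' Default simulation configuration: the study conditions
#'
#' The conditions every stage is exercised under: 2,000 T cells plus a small
#' B-cell population; one dominant tumor clone covering all tumor cells
#' (40% of T cells) with 30% single-chain cells and an expanded bystander
#' CD8 clone; a chr5 dosage-1.5 gain in half the tumor cells with a nested
#' chr21 gain in a fifth; one hotspot mutation captured per cell with
#' probability 0.9 at mean coverage 5; three tumor-restricted marker genes;
#' a TFH-like tumor gene program over a background of unit-mean
#' negative-binomial counts (size 2); and a spatial field where tumor cells
#' co-cluster with dysfunctional CD8 cells while effector CD8 and B cells
#' occupy disjoint halves.
#'
#' @param seed RNG seed.
#' @return a [sim_config()] object.
#' @export
default_sim_config <- function(seed = 1L) {
  genome <- default_genome()
  tfh_program <- sprintf("chr2_g%03d", seq(10, 115, by = 15))
  cd4_program <- sprintf("chr1_g%03d", seq(12, 117, by = 15))
  cd8_program <- sprintf("chr7_g%03d", seq(14, 104, by = 15))
  markers <- c("chr1_g120", "chr19_g120", "chr21_g120")
  sim_config(
    populations = list(
      population_spec("tumor", 800, tfh_program, program_fc = 4,
                      is_tumor = TRUE),
      population_spec("CD4", 700, cd4_program, program_fc = 2),
      population_spec("CD8", 500, cd8_program, program_fc = 2),
      population_spec("B", 200, lineage = "B")),
    tumor_clone_specs = list(list(id = "tumor_clone_1", fraction = 1,
                                  single_chain_fraction = 0.3)),
    expanded_clone_specs = list(list(id = "cd8_exp_1", population = "CD8",
                                     n_cells = 30)),
    cnv_events = list(list(chrom = "chr5", multiplier = 1.5, fraction = 0.5),
                      list(chrom = "chr21", multiplier = 1.5, fraction = 0.2)),
    mutation_specs = list(list(locus = "RHOA_G17V", mutant_patient = TRUE,
                               capture = 0.9, mean_coverage = 5)),
    marker_genes = markers, marker_fc = 8,
    nb_mean = 1, nb_dispersion = 2, genome = genome,
    spatial_spec = list(
      n_images = 4, field_um = 500,
      intensity = c(CD8_EFF = 3e-4, B = 3e-4, Other = 4e-4),
      attraction_pairs = list(list(a = "Tumor", b = "CD8_DYS", radius = 20,
                                   n_parents = 15, offspring_per_parent = 4)),
      avoidance_pairs = list(list(a = "CD8_EFF", b = "B"))),
    seed = seed)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic pipeline
#'
#' Generates (or loads) a dataset, then runs clonotype tumor calling,
#' per-cell genotyping, CNV inference with subclone tree, signature scoring
#' and genotype/score association, spatial interaction analysis and
#' ligand-receptor crosstalk, writing each stage's tables plus a run
#' manifest under `out_dir`. All randomness derives from `config$seed`.
#'
#' @param config list with `out_dir`, optional `seed` (default 1), optional
#'   `sim` (a [sim_config()]; default [default_sim_config()]), and optional
#'   `params` overrides (`cnv_window`, `n_perm`, `radius_um`).
#'   A path to a YAML file with the same fields is also accepted
#'   (its `sim` block, when present, is passed to [default_sim_config()]'s
#'   seed only).
#' @param stages character subset of
#'   c("simulate","repertoire","genotyper","cnvmap","sigscore","spatialix",
#'   "crosstalk") to run; earlier outputs are reused when a stage is
#'   skipped.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config, stages = c("simulate", "repertoire",
                                            "genotyper", "cnvmap", "sigscore",
                                            "spatialix", "crosstalk")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config$out_dir))
    stop_named("config_error", "pipeline config lacks required block: out_dir")
  seed <- as.integer(config$seed %||% 1L)
  sim <- config$sim %||% default_sim_config(seed)
  params <- config$params %||% list()
  out <- config$out_dir
  data_dir <- file.path(out, "data")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  run_stage("simulate", function() write_synthetic_dataset(sim, data_dir))

  counts <- read_count_matrix(data_dir)
  meta <- read_cellmeta(file.path(data_dir, "cells.tsv"))
  contigs <- read_contigs(file.path(data_dir, "filtered_contig_annotations.csv"))
  positions <- read_gene_positions(file.path(data_dir, "gene_positions.tsv"))

  assign <- assemble_clonotypes(contigs)
  calls <- NULL
  run_stage("repertoire", function() {
    calls <<- call_tumor_clones(assign)
    write_tsv(calls$clonotypes, file.path(out, "clonotypes.tsv"))
    write_tsv(calls$cells, file.path(out, "tumor_calls.tsv"))
  })
  if (is.null(calls)) calls <- call_tumor_clones(assign)
  tumor_bc <- calls$cells$barcode[calls$cells$is_tumor]
  normal_t <- setdiff(assign$barcode, tumor_bc)

  run_stage("genotyper", function() {
    pile <- read_pileup(file.path(data_dir, "pileup.tsv"))
    loci <- filter_loci(pile)
    write_tsv(loci, file.path(out, "locus_summary.tsv"))
    kept <- pile[pile$locus %in% loci$locus[loci$retained], , drop = FALSE]
    if (nrow(kept)) {
      gcalls <- call_cell_genotype(kept, "mutant_by_WES")
      write_tsv(gcalls, file.path(out, "genotype_calls.tsv"))
      tum <- gcalls[gcalls$barcode %in% tumor_bc, , drop = FALSE]
      write_tsv(genotype_fraction_summary(tum),
                file.path(out, "genotype_fractions.tsv"))
    }
  })

  profile <- NULL
  run_stage("cnvmap", function() {
    rel <- compute_relative_expression(counts, positions, normal_t)
    profile <<- smooth_by_position(rel, params$cnv_window %||% 101)
    write_tsv(call_chromosome_cnv(profile), file.path(out, "cnv_calls.tsv"))
    write_tsv(cnv_score(profile), file.path(out, "cnv_scores.tsv"))
    tum_prof <- profile
    tum_prof$values <- profile$values[, intersect(colnames(counts), tumor_bc),
                                      drop = FALSE]
    labels <- cluster_subclones(tum_prof, k = min(3, ncol(tum_prof$values)))
    tree <- build_clone_tree(subclone_profiles(tum_prof, labels))
    ape::write.tree(tree, file.path(out, "clone_tree.nwk"))
  })

  run_stage("sigscore", function() {
    tfh_set <- sim$populations[[1]]$program_genes
    sc <- signature_score(counts, tfh_set, "TFH-like program")
    write_tsv(data.frame(barcode = names(sc), tfh_score = unname(sc)),
              file.path(out, "scores.tsv"))
    pile <- read_pileup(file.path(data_dir, "pileup.tsv"))
    gcalls <- call_cell_genotype(pile, "mutant_by_WES")
    mut_sc <- sc[gcalls$barcode[gcalls$status == "MUT"]]
    unk_sc <- sc[gcalls$barcode[gcalls$status == "unknown"]]
    assoc <- wilcoxon_rank_sum(mut_sc, unk_sc)
    write_tsv(data.frame(comparison = "MUT_vs_unknown_tfh_score",
                         statistic = assoc$statistic, p = assoc$p.value),
              file.path(out, "genotype_score_association.tsv"))
  })

  run_stage("spatialix", function() {
    if (is.null(sim$spatial_spec)) return(invisible(NULL))
    spat <- read_spatial(file.path(data_dir, "spatial_cells.csv"))
    graph <- build_neighbor_graph(spat, "radius", params$radius_um %||% 15)
    res <- rbind(
      interaction_score(graph, "Tumor", "CD8_DYS",
                        n_perm = params$n_perm %||% 1000, seed = seed + 10),
      interaction_score(graph, "CD8_EFF", "B",
                        n_perm = params$n_perm %||% 1000, seed = seed + 11))
    write_tsv(res, file.path(out, "per_image_results.tsv"))
    write_tsv(summarize_across_images(res),
              file.path(out, "interaction_matrix.tsv"))
  })

  run_stage("crosstalk", function() {
    lig <- if (length(sim$marker_genes)) sim$marker_genes[1] else
      sim$genome$gene[2]
    pair <- list(pair_id = "marker_to_background",
                 ligand = lig, receptor = sim$genome$gene[1])
    perm <- lr_permutation_p(counts, meta$cluster, pair,
                             sim$populations[[1]]$name,
                             sim$populations[[2]]$name,
                             n_perm = params$n_perm %||% 1000,
                             seed = seed + 12)
    write_tsv(data.frame(pair_id = pair$pair_id, observed = perm$observed,
                         null_mean = perm$null_mean, p = perm$p.value),
              file.path(out, "crosstalk.tsv"))
  })

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package = "tfhlscape",
    version = as.character(utils::packageVersion("tfhlscape")),
    seed = seed, stages = stages,
    params = params,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
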