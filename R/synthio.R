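# Built-in V/J segment names; only string identity matters downstream.
TRAV_GENES <- paste0("TRAV", c(1, 8, 12, 17, 21, 29))
TRAJ_GENES <- paste0("TRAJ", c(4, 9, 23, 33, 44))
TRBV_GENES <- paste0("TRBV", c(2, 5, 7, 9, 20, 28))
TRBJ_GENES <- paste0("TRBJ", c("1-1", "1-5", "2-1", "2-7"))

random_cdr3_nt <- function(n) {
  lens <- sample(seq(30, 45, by = 3), n, replace = TRUE)
  vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

random_cdr3_aa <- function(nt) {
  vapply(nchar(nt) / 3, function(l)
    paste0("C", paste(sample(LETTERS[LETTERS != "J"], l - 1, replace = TRUE),
                      collapse = "")), character(1))
}

#' Default synthetic genome for the simulator
#'
#' A compact gene-position table: a handful of chromosomes, each carrying a
#' fixed number of evenly spaced genes named `<chrom>_g<idx>`. Dense enough
#' per chromosome that position-smoothed CNV inference at its default window
#' is exercised, small enough to simulate quickly.
#'
#' @param chroms chromosome names.
#' @param genes_per_chrom genes placed on each chromosome.
#' @return gene position data.frame (gene, chrom, start, end).
#' @export
default_genome <- function(chroms = c("chr1", "chr2", "chr5", "chr7", "chr19", "chr21"),
                           genes_per_chrom = 250) {
  do.call(rbind, lapply(chroms, function(ch) {
    idx <- seq_len(genes_per_chrom)
    data.frame(gene = sprintf("%s_g%03d", ch, idx), chrom = ch,
               start = (idx - 1) * 100000 + 1,
               end = (idx - 1) * 100000 + 1000,
               stringsAsFactors = FALSE)
  }))
}

#' Define a synthetic population
#'
#' @param name population label (becomes the cluster label in metadata).
#' @param n_cells cells to simulate.
#' @param program_genes genes whose mean is scaled by `program_fc` in this
#'   population.
#' @param program_fc fold-change applied to `program_genes`.
#' @param is_tumor logical; tumor populations receive clonotypes from
#'   `tumor_clone_specs`, marker-gene upregulation, CNV events and planted
#'   mutations.
#' @param lineage "T", "B" or "other"; controls receptor-contig generation.
#' @return population spec list.
#' @export
population_spec <- function(name, n_cells, program_genes = character(),
                            program_fc = 1, is_tumor = FALSE, lineage = "T") {
  list(name = name, n_cells = as.integer(n_cells),
       program_genes = program_genes, program_fc = program_fc,
       is_tumor = is_tumor, lineage = lineage)
}

#' Build and validate a simulation configuration
#'
#' The generator plants, with ground truth: tumor TCR clones (optionally
#' sharing a TRB chain), single-chain tumor cells, expanded bystander
#' clonotypes, chromosome-level dosage events in a tumor subpopulation,
#' point mutations with per-cell capture dropout, tumor-restricted marker
#' genes, gene-program gradients, and spatial attraction/avoidance between
#' cell types.
#'
#' CNV carriers are taken from the head of the tumor-cell list, so an event
#' with a smaller affected fraction nests inside a larger one — emulating
#' sequential acquisition of copy-number changes within a clone.
#'
#' @param populations list of [population_spec()] entries.
#' @param tumor_clone_specs list of lists with fields `id`, `fraction`
#'   (of tumor cells), `single_chain_fraction`, and optional `cdr3_nt_tra`
#'   / `cdr3_nt_trb` (random 30-45-mers when absent).
#' @param expanded_clone_specs list of lists with `id`, `population`,
#'   `n_cells`: bystander clones shared across that many cells.
#' @param cnv_events list of lists with `chrom`, `multiplier` (>= 0) and
#'   `fraction` of tumor cells affected.
#' @param mutation_specs list of lists with `locus`, `mutant_patient`
#'   (logical), `capture` in \[0,1\] and `mean_coverage`; true-mutant cells
#'   are the tumor cells when `mutant_patient` is TRUE.
#' @param marker_genes tumor-specific marker genes: near-silent outside
#'   tumor cells (baseline mean scaled by `marker_background_frac`) and
#'   scaled by `marker_fc` within them.
#' @param marker_fc fold-change for marker genes in tumor cells.
#' @param marker_background_frac fraction of the baseline mean that marker
#'   genes keep in non-tumor cells (default 0.05), emulating
#'   tumor-restricted expression.
#' @param nb_mean baseline negative-binomial mean per gene.
#' @param nb_dispersion negative-binomial size (shape) parameter; variance is
#'   `mu + mu^2/size`, so `Inf` gives the Poisson limit.
#' @param genome gene-position table; see [default_genome()].
#' @param spatial_spec list with `n_images`, `field_um`, `intensity` (named
#'   per-type intensity per square micrometre), `attraction_pairs` (lists
#'   with `a`, `b`, `radius`, `n_parents`, `offspring_per_parent`) and
#'   `avoidance_pairs` (lists with `a`, `b`): avoidance pairs are placed in
#'   disjoint half-fields.
#' @param seed integer; fixing it makes every generator output identical.
#' @return validated `sim_config` object.
#' @export
sim_config <- function(populations,
                       tumor_clone_specs = list(),
                       expanded_clone_specs = list(),
                       cnv_events = list(),
                       mutation_specs = list(),
                       marker_genes = character(),
                       marker_fc = 8,
                       marker_background_frac = 0.05,
                       nb_mean = 1,
                       nb_dispersion = 2,
                       genome = default_genome(),
                       spatial_spec = NULL,
                       seed = 1L) {
  if (!length(populations))
    stop_named("config_error", "population list must be nonempty")
  genome <- validate_gene_positions(genome)
  known <- genome$gene
  for (p in populations) {
    bad <- setdiff(p$program_genes, known)
    if (length(bad))
      stop_named("config_error", "unknown program gene(s) in population %s: %s",
                 p$name, paste(bad, collapse = ", "))
  }
  bad <- setdiff(marker_genes, known)
  if (length(bad))
    stop_named("config_error", "unknown marker gene(s): %s",
               paste(bad, collapse = ", "))
  fr <- c(vapply(tumor_clone_specs, function(s) s$fraction, numeric(1)),
          vapply(tumor_clone_specs, function(s) s$single_chain_fraction, numeric(1)),
          vapply(cnv_events, function(s) s$fraction, numeric(1)),
          vapply(mutation_specs, function(s) s$capture, numeric(1)))
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    stop_named("config_error", "all fractions/probabilities must lie in [0, 1]")
  mult <- vapply(cnv_events, function(s) s$multiplier, numeric(1))
  if (length(mult) && any(mult < 0))
    stop_named("config_error", "dosage multipliers must be >= 0")
  if (!is.null(spatial_spec)) {
    pair_key <- function(p) paste(sort(c(p$a, p$b)), collapse = "|")
    att <- vapply(spatial_spec$attraction_pairs %||% list(), pair_key, character(1))
    avo <- vapply(spatial_spec$avoidance_pairs %||% list(), pair_key, character(1))
    if (length(intersect(att, avo)))
      stop_named("config_error", "pair(s) both attracted and avoided: %s",
                 paste(intersect(att, avo), collapse = "; "))
    if (is.null(spatial_spec$field_um) || spatial_spec$field_um <= 0)
      stop_named("config_error", "spatial field size must be > 0")
  }
  structure(list(populations = populations,
                 tumor_clone_specs = tumor_clone_specs,
                 expanded_clone_specs = expanded_clone_specs,
                 cnv_events = cnv_events,
                 mutation_specs = mutation_specs,
                 marker_genes = marker_genes, marker_fc = marker_fc,
                 marker_background_frac = marker_background_frac,
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 genome = genome, spatial_spec = spatial_spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw the per-cell ground truth for a configuration
#'
#' Assigns barcodes, population labels, tumor flags, clonotype identities
#' (tumor clones, expanded bystander clones, unique singletons), the
#' single-chain decision per tumor cell, CNV carrier flags and true mutation
#' status. Deterministic given the config seed.
#'
#' @param config a [sim_config()] object.
#' @return `sim_truth` object: a data.frame of per-cell truth with a
#'   `clones` attribute describing each planted clone's chains.
#' @export
sim_truth <- function(config) {
  set.seed(config$seed)
  pops <- config$populations
  cells <- do.call(rbind, lapply(pops, function(p)
    data.frame(population = p$name, is_tumor = p$is_tumor, lineage = p$lineage,
               stringsAsFactors = FALSE)[rep(1, p$n_cells), , drop = FALSE]))
  n <- nrow(cells)
  cells$barcode <- sprintf("BC%05d", seq_len(n))
  rownames(cells) <- NULL

  # tumor clone assignment: counts by fraction, remainder to the first clone
  cells$clonotype_id <- NA_character_
  cells$single_chain <- FALSE
  cells$dropped_chain <- NA_character_
  tumor_idx <- which(cells$is_tumor & cells$lineage == "T")
  specs <- config$tumor_clone_specs
  clone_rows <- list()
  if (length(specs) && length(tumor_idx)) {
    counts <- floor(vapply(specs, function(s) s$fraction, numeric(1)) * length(tumor_idx))
    counts[1] <- counts[1] + length(tumor_idx) - sum(counts)
    at <- tumor_idx
    for (k in seq_along(specs)) {
      take <- at[seq_len(counts[k])]
      at <- at[-seq_len(counts[k])]
      cells$clonotype_id[take] <- specs[[k]]$id
      sc <- runif(length(take)) < specs[[k]]$single_chain_fraction
      cells$single_chain[take] <- sc
      cells$dropped_chain[take][sc] <- sample(c("TRA", "TRB"),
                                              sum(sc), replace = TRUE)
      clone_rows[[k]] <- data.frame(
        clone_id = specs[[k]]$id,
        cdr3_nt_tra = specs[[k]]$cdr3_nt_tra %||% random_cdr3_nt(1),
        cdr3_nt_trb = specs[[k]]$cdr3_nt_trb %||% random_cdr3_nt(1),
        stringsAsFactors = FALSE)
    }
  }
  # expanded bystander clones inside named non-tumor populations
  for (s in config$expanded_clone_specs) {
    pool <- which(cells$population == s$population & is.na(cells$clonotype_id) &
                    cells$lineage == "T")
    take <- pool[seq_len(min(s$n_cells, length(pool)))]
    cells$clonotype_id[take] <- s$id
    clone_rows[[length(clone_rows) + 1]] <- data.frame(
      clone_id = s$id, cdr3_nt_tra = random_cdr3_nt(1),
      cdr3_nt_trb = random_cdr3_nt(1), stringsAsFactors = FALSE)
  }
  # remaining T cells: unique singleton clonotypes
  single <- which(is.na(cells$clonotype_id) & cells$lineage == "T")
  if (length(single)) {
    ids <- sprintf("bg%05d", seq_along(single))
    cells$clonotype_id[single] <- ids
    clone_rows[[length(clone_rows) + 1]] <- data.frame(
      clone_id = ids, cdr3_nt_tra = random_cdr3_nt(length(single)),
      cdr3_nt_trb = random_cdr3_nt(length(single)), stringsAsFactors = FALSE)
  }
  clones <- do.call(rbind, clone_rows)
  if (!is.null(clones)) {
    clones$cdr3_aa_tra <- random_cdr3_aa(clones$cdr3_nt_tra)
    clones$cdr3_aa_trb <- random_cdr3_aa(clones$cdr3_nt_trb)
    clones$tra_v <- sample(TRAV_GENES, nrow(clones), replace = TRUE)
    clones$tra_j <- sample(TRAJ_GENES, nrow(clones), replace = TRUE)
    clones$trb_v <- sample(TRBV_GENES, nrow(clones), replace = TRUE)
    clones$trb_j <- sample(TRBJ_GENES, nrow(clones), replace = TRUE)
  }

  # CNV carriers: head of the tumor-cell list, so smaller events nest
  all_tumor <- which(cells$is_tumor)
  for (ev in config$cnv_events) {
    col <- paste0("cnv_", ev$chrom)
    cells[[col]] <- FALSE
    cells[[col]][all_tumor[seq_len(round(ev$fraction * length(all_tumor)))]] <- TRUE
  }
  for (ms in config$mutation_specs) {
    cells[[paste0("mut_", ms$locus)]] <- isTRUE(ms$mutant_patient) & cells$is_tumor
  }
  structure(cells, clones = clones, class = c("sim_truth", "data.frame"))
}

#' Simulate the UMI count matrix
#'
#' Per-gene, per-cell negative-binomial counts with mean
#' `nb_mean x program fold-change x dosage multiplier x marker fold-change`
#' and size `nb_dispersion` (Poisson when infinite). Genes on a gained
#' chromosome in carrier cells have their mean scaled by the event's dosage
#' multiplier; marker genes are elevated only in tumor populations.
#'
#' @param config a [sim_config()] object.
#' @param truth optional precomputed [sim_truth()]; drawn from the config
#'   when absent.
#' @return list with `counts` (sparse genes x cells matrix) and `truth`.
#' @export
generate_expression <- function(config, truth = sim_truth(config)) {
  set.seed(config$seed + 1L)
  genome <- config$genome
  n_genes <- nrow(genome)
  n_cells <- nrow(truth)
  mu <- matrix(config$nb_mean, n_genes, n_cells,
               dimnames = list(genome$gene, truth$barcode))
  for (p in config$populations) {
    if (!length(p$program_genes) || p$program_fc == 1) next
    cols <- truth$population == p$name
    mu[p$program_genes, cols] <- mu[p$program_genes, cols] * p$program_fc
  }
  if (length(config$marker_genes)) {
    tum <- truth$is_tumor
    mu[config$marker_genes, tum] <- mu[config$marker_genes, tum] * config$marker_fc
    mu[config$marker_genes, !tum] <- mu[config$marker_genes, !tum] *
      (config$marker_background_frac %||% 1)
  }
  for (ev in config$cnv_events) {
    rows <- genome$chrom == ev$chrom
    cols <- truth[[paste0("cnv_", ev$chrom)]]
    mu[rows, cols] <- mu[rows, cols] * ev$multiplier
  }
  draws <- if (is.infinite(config$nb_dispersion)) {
    rpois(length(mu), lambda = mu)
  } else {
    rnbinom(length(mu), mu = mu, size = config$nb_dispersion)
  }
  counts <- matrix(draws, n_genes, n_cells, dimnames = dimnames(mu))
  list(counts = as(as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
                   "generalMatrix"),
       truth = truth)
}

#' Simulate receptor contigs for the truth's clonotypes
#'
#' Tumor cells of a clone share identical productive TRA/TRB CDR3 nucleotide
#' strings; cells flagged single-chain in the truth lack one chain;
#' non-tumor T cells carry their (unique or expanded) clone's chains.
#'
#' @param config a [sim_config()] object.
#' @param truth [sim_truth()] output.
#' @return contig table in the 10x column dialect (see [read_contigs()]).
#' @export
generate_contigs <- function(config, truth) {
  set.seed(config$seed + 2L)
  clones <- attr(truth, "clones")
  tcells <- truth[!is.na(truth$clonotype_id), , drop = FALSE]
  if (!nrow(tcells))
    return(data.frame(barcode = character(), chain = character(),
                      v_gene = character(), j_gene = character(),
                      cdr3 = character(), cdr3_nt = character(),
                      productive = logical(), umis = integer()))
  ci <- match(tcells$clonotype_id, clones$clone_id)
  make_chain <- function(chain) {
    keep <- is.na(tcells$dropped_chain) | tcells$dropped_chain != chain
    k <- which(keep)
    if (chain == "TRA") {
      data.frame(barcode = tcells$barcode[k], chain = "TRA",
                 v_gene = clones$tra_v[ci[k]], j_gene = clones$tra_j[ci[k]],
                 cdr3 = clones$cdr3_aa_tra[ci[k]],
                 cdr3_nt = clones$cdr3_nt_tra[ci[k]],
                 productive = TRUE, umis = rpois(length(k), 3) + 1L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(barcode = tcells$barcode[k], chain = "TRB",
                 v_gene = clones$trb_v[ci[k]], j_gene = clones$trb_j[ci[k]],
                 cdr3 = clones$cdr3_aa_trb[ci[k]],
                 cdr3_nt = clones$cdr3_nt_trb[ci[k]],
                 productive = TRUE, umis = rpois(length(k), 3) + 1L,
                 stringsAsFactors = FALSE)
    }
  }
  out <- rbind(make_chain("TRA"), make_chain("TRB"))
  out <- out[order(match(out$barcode, truth$barcode), out$chain), ]
  rownames(out) <- NULL
  validate_contigs(out)
}

#' Simulate per-cell read pileups at the configured mutation loci
#'
#' Coverage is Poisson with the spec's mean. A true-mutant cell yields
#' alternate reads only when an independent capture event (probability
#' `capture`) succeeds and coverage is positive, in which case at least one
#' of its reads is alternate; non-mutant cells never receive alternate reads.
#'
#' @param config a [sim_config()] object.
#' @param truth [sim_truth()] output.
#' @return pileup data.frame (barcode, locus, ref_reads, alt_reads, total).
#' @export
generate_pileups <- function(config, truth) {
  if (!length(config$mutation_specs))
    stop_named("config_error", "mutation_specs is empty")
  set.seed(config$seed + 3L)
  out <- lapply(config$mutation_specs, function(ms) {
    n <- nrow(truth)
    total <- rpois(n, ms$mean_coverage)
    mutant <- truth[[paste0("mut_", ms$locus)]]
    captured <- runif(n) < ms$capture
    has_alt <- mutant & captured & total > 0
    alt <- integer(n)
    alt[has_alt] <- 1L + rbinom(sum(has_alt), pmax(total[has_alt] - 1L, 0L), 0.5)
    data.frame(barcode = truth$barcode, locus = ms$locus,
               ref_reads = total - alt, alt_reads = alt, total = total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a segmented-cell spatial table
#'
#' Baseline types follow a homogeneous Poisson point process on the square
#' field. Attraction pairs are generated by a Neyman-Scott parent-offspring
#' process: shared parents are placed uniformly and both types scatter
#' uniformly within the cluster radius around them. Avoidance pairs are
#' placed in disjoint half-fields separated by a central gap of a quarter
#' field, so cross-pair neighbors are absent at any radius below field/4.
#' Types named in an attraction pair get no baseline points of their own.
#'
#' @param config a [sim_config()] object whose `spatial_spec` is set.
#' @return list with `cells` (image_id, x_um, y_um, cell_type) and `truth`
#'   (per-cell parent/attraction group, NA for baseline cells).
#' @export
generate_spatial <- function(config) {
  sp <- config$spatial_spec
  if (is.null(sp)) stop_named("config_error", "spatial_spec is not set")
  set.seed(config$seed + 4L)
  field <- sp$field_um
  att <- sp$attraction_pairs %||% list()
  avo <- sp$avoidance_pairs %||% list()
  att_types <- unique(unlist(lapply(att, function(p) c(p$a, p$b))))
  avo_left <- vapply(avo, function(p) p$a, character(1))
  avo_right <- vapply(avo, function(p) p$b, character(1))
  rows <- list()
  for (img in seq_len(sp$n_images)) {
    id <- sprintf("img%02d", img)
    for (ty in names(sp$intensity)) {
      if (ty %in% att_types) next
      n <- rpois(1, sp$intensity[[ty]] * field^2)
      if (!n) next
      x <- runif(n, 0, field); y <- runif(n, 0, field)
      if (ty %in% avo_left) x <- x * 0.375
      if (ty %in% avo_right) x <- field * 0.625 + x * 0.375
      rows[[length(rows) + 1]] <- data.frame(
        image_id = id, x_um = x, y_um = y, cell_type = ty,
        group = NA_character_, stringsAsFactors = FALSE)
    }
    for (k in seq_along(att)) {
      p <- att[[k]]
      for (parent in seq_len(p$n_parents)) {
        px <- runif(1, 0, field); py <- runif(1, 0, field)
        gid <- sprintf("%s_att%d_p%d", id, k, parent)
        for (ty in c(p$a, p$b)) {
          m <- rpois(1, p$offspring_per_parent)
          if (!m) next
          ang <- runif(m, 0, 2 * pi)
          rad <- p$radius * sqrt(runif(m))
          rows[[length(rows) + 1]] <- data.frame(
            image_id = id,
            x_um = pmin(pmax(px + rad * cos(ang), 0), field),
            y_um = pmin(pmax(py + rad * sin(ang), 0), field),
            cell_type = ty, group = gid, stringsAsFactors = FALSE)
        }
      }
    }
  }
  cells <- do.call(rbind, rows)
  list(cells = cells[c("image_id", "x_um", "y_um", "cell_type")],
       truth = cells["group"])
}

#' Write a full synthetic fixture set to disk
#'
#' Emits matrix.mtx/barcodes.tsv/features.tsv, filtered_contig_annotations.csv,
#' pileup.tsv, gene_positions.tsv, cells.tsv, spatial_cells.csv (when a
#' spatial spec is configured) and truth.json.
#'
#' @param config a [sim_config()] object.
#' @param dir output directory.
#' @param sample_id,tissue,status metadata fields written to cells.tsv.
#' @return the directory, invisibly.
#' @export
write_synthetic_dataset <- function(config, dir, sample_id = "SIM1",
                                    tissue = "LN", status = "ND") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_expression(config)
  truth <- sim$truth
  write_count_matrix(sim$counts, dir)
  write_contigs(generate_contigs(config, truth),
                file.path(dir, "filtered_contig_annotations.csv"))
  if (length(config$mutation_specs))
    write_pileup(generate_pileups(config, truth), file.path(dir, "pileup.tsv"))
  write_gene_positions(config$genome, file.path(dir, "gene_positions.tsv"))
  meta <- data.frame(barcode = truth$barcode, sample = sample_id,
                     patient = sample_id, tissue = tissue, status = status,
                     cluster = truth$population, stringsAsFactors = FALSE)
  write_cellmeta(meta, file.path(dir, "cells.tsv"))
  if (!is.null(config$spatial_spec)) {
    spat <- generate_spatial(config)
    write_spatial(spat$cells, file.path(dir, "spatial_cells.csv"))
  }
  jsonlite::write_json(
    list(cells = truth[, setdiff(names(truth), "dropped_chain")],
         clones = attr(truth, "clones")),
    file.path(dir, "truth.json"))
  invisible(dir)
}
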