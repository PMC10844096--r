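#!/usr/bin/env Rscript
# Tumor-specific marker discovery cascade across simulated patients: per
# sample, genes up in tumor cells vs all non-malignant MNCs and (in LN) vs
# normal TFH cells; keep genes recurrent in >= 2 samples per compartment;
# intersect LN and PB candidates; apply the background-specificity filter.
# Four LN and four PB samples share three pan-compartment markers; each
# compartment also carries its own decoy marker.

library(tfhlscape)

genome <- default_genome(genes_per_chrom = 20)
pan <- c("chr1_g010", "chr5_g010", "chr2_g018")
make_sample <- function(seed, tissue) {
  mk <- c(pan, if (tissue == "LN") "chr5_g015" else "chr1_g015")
  pops <- list(population_spec("tumor", 150, is_tumor = TRUE),
               population_spec("CD4", 120), population_spec("CD8", 80))
  if (tissue == "LN") pops <- c(pops, list(population_spec("TFH_norm", 60)))
  cfg <- sim_config(pops,
                    tumor_clone_specs = list(list(id = "c", fraction = 1,
                                                  single_chain_fraction = 0)),
                    marker_genes = mk, genome = genome, seed = seed)
  sim <- generate_expression(cfg)
  tr <- sim$truth
  tfh <- tr$barcode[tr$population == "TFH_norm"]
  list(deg = per_sample_tumor_deg(sim$counts, tr$barcode[tr$is_tumor],
                                  tr$barcode[!tr$is_tumor],
                                  if (length(tfh)) tfh else NULL),
       counts = sim$counts, truth = tr)
}

ln <- lapply(1:4, function(i) make_sample(500 + i, "LN"))
pb <- lapply(1:4, function(i) suppressWarnings(make_sample(600 + i, "PB")))
cand <- intersect_compartments(
  recurrence_filter(lapply(ln, `[[`, "deg"), require_tfh = TRUE),
  recurrence_filter(lapply(pb, `[[`, "deg")))
write.table(cand, "results/marker_candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
final <- cand$gene[cand$final_candidate]

pooled <- do.call(cbind, lapply(seq_along(ln), function(i) {
  m <- ln[[i]]$counts
  colnames(m) <- paste0("s", i, "_", colnames(m))
  m
}))
nonmal <- unlist(lapply(seq_along(ln), function(i)
  paste0("s", i, "_", ln[[i]]$truth$barcode[!ln[[i]]$truth$is_tumor])))
final <- marker_specificity_filter(pooled, nonmal, final)
message(sprintf("final candidates after specificity filter: %s (planted: %s)",
                paste(final, collapse = ", "), paste(pan, collapse = ", ")))
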