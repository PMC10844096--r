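#!/usr/bin/env Rscript
# Per-cell somatic genotyping: locus filtering (aggregate coverage >= 100x,
# mutant cells > 20), MUT/unknown calls under allelic dropout, fraction
# summaries, and association of genotype with the TFH-like signature score.

library(tfhlscape)

pile <- read_pileup("results/data/pileup.tsv")
counts <- read_count_matrix("results/data")
tumor <- read.delim("results/tumor_calls.tsv")

loci <- filter_loci(pile)
write.table(loci, "results/locus_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("retained %d of %d loci", sum(loci$retained), nrow(loci)))

kept <- pile[pile$locus %in% loci$locus[loci$retained], ]
calls <- call_cell_genotype(kept, "mutant_by_WES")
write.table(calls, "results/genotype_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tum_calls <- calls[calls$barcode %in% tumor$barcode[tumor$is_tumor], ]
fs <- genotype_fraction_summary(tum_calls)
write.table(fs, "results/genotype_fractions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("tumor cells: %.1f%% MUT, %.1f%% no mutant read, %.1f%% no coverage",
                100 * fs$frac_mut, 100 * fs$frac_no_mut_read,
                100 * fs$frac_no_coverage))

# MUT vs unknown tumor cells on the TFH-like program score
cfg <- default_sim_config(seed = 1)
score <- signature_score(counts, cfg$populations[[1]]$program_genes,
                         "TFH-like program")
mut <- score[tum_calls$barcode[tum_calls$status == "MUT"]]
unk <- score[tum_calls$barcode[tum_calls$status == "unknown"]]
w <- wilcoxon_rank_sum(mut, unk)
message(sprintf("TFH score MUT vs unknown: U = %.0f, p = %.3g (dropout is random, so no shift expected)",
                w$statistic, w$p.value))
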