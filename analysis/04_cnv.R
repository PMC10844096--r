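#!/usr/bin/env Rscript
# Expression-based CNV inference: reference-centred log ratios, positional
# smoothing, chromosome-level gain/loss calls, per-cell CNV scores, CNV
# subclones and their neighbor-joining clone tree rooted at a neutral
# profile.

library(tfhlscape)

counts <- read_count_matrix("results/data")
positions <- read_gene_positions("results/data/gene_positions.tsv")
meta <- read_cellmeta("results/data/cells.tsv")
tumor <- read.delim("results/tumor_calls.tsv")

tumor_bc <- tumor$barcode[tumor$is_tumor]
ref_bc <- meta$barcode[meta$cluster %in% c("CD4", "CD8") &
                         !meta$barcode %in% tumor_bc]
rel <- compute_relative_expression(counts, positions, ref_bc)
prof <- smooth_by_position(rel, window = 101)

calls <- call_chromosome_cnv(prof)
write.table(calls, "results/cnv_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
gain5 <- calls[calls$chrom == "chr5" & calls$barcode %in% tumor_bc, ]
message(sprintf("chr5 gain called in %.1f%% of tumor cells",
                100 * mean(gain5$state == "gain")))

scores <- cnv_score(prof)
write.table(scores, "results/cnv_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
w <- wilcoxon_rank_sum(scores$score[scores$barcode %in% tumor_bc],
                       scores$score[!scores$barcode %in% tumor_bc])
message(sprintf("CNV score tumor vs non-tumor: p = %.3g", w$p.value))

tp <- prof
tp$values <- prof$values[, tumor_bc]
labels <- cluster_subclones(tp, k = 3)
write.table(data.frame(barcode = names(labels), subclone = labels),
            "results/cnv_subclones.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
tree <- build_clone_tree(subclone_profiles(tp, labels))
ape::write.tree(tree, "results/clone_tree.nwk")
message(sprintf("subclone sizes: %s; tree written",
                paste(table(labels), collapse = "/")))
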