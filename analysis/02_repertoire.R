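#!/usr/bin/env Rscript
# Clonotype assembly and tumor-cell calling from the simulated TCR contigs:
# per-cell clonotypes with chain-configuration classes, major/minor tumor
# clone designation by clonal fraction with related-clone merging, clone
# sizes, and repertoire overlap between the non-malignant compartments.

library(tfhlscape)

contigs <- read_contigs("results/data/filtered_contig_annotations.csv")
meta <- read_cellmeta("results/data/cells.tsv")

asn <- assemble_clonotypes(contigs)
res <- call_tumor_clones(asn)
write.table(res$clonotypes, "results/clonotypes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$cells, "results/tumor_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("assigned %d cells; tumor fraction %.3f; %d single-chain tumor cells",
                nrow(asn), res$tumor_fraction,
                sum(asn$chain_config != "paired" &
                      asn$barcode %in% res$cells$barcode[res$cells$is_tumor])))

# overlap between the two largest non-malignant clusters
nm <- merge(asn, meta, by = "barcode")
nm <- nm[!nm$barcode %in% res$cells$barcode[res$cells$is_tumor], ]
cl <- names(sort(table(nm$cluster), decreasing = TRUE))[1:2]
ov <- vapply(c("public", "jaccard", "morisita"), function(m)
  repertoire_overlap(nm$key[nm$cluster == cl[1]],
                     nm$key[nm$cluster == cl[2]], m), numeric(1))
write.table(data.frame(cluster_a = cl[1], cluster_b = cl[2], t(ov)),
            "results/repertoire_overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("overlap %s vs %s: public %d, jaccard %.3f, morisita %.3f",
                cl[1], cl[2], ov["public"], ov["jaccard"], ov["morisita"]))
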