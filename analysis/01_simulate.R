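#!/usr/bin/env Rscript
# Generate the synthetic study dataset: 2,000 T cells (one dominant tumor
# clone at 40% with 30% single-chain cells, an expanded bystander CD8
# clone), 200 B cells, a subclonal chr5 x1.5 gain with a nested chr21 gain,
# one hotspot mutation with per-cell capture dropout, three tumor-specific
# marker genes, and a spatial field with planted attraction and avoidance.
# Writes the on-disk fixture set every later step consumes.

library(tfhlscape)

out <- "results/data"
cfg <- default_sim_config(seed = 1)
write_synthetic_dataset(cfg, out, sample_id = "SIM1", tissue = "LN")

truth <- sim_truth(cfg)
message(sprintf("simulated %d cells (%d tumor) over %d genes; fixtures in %s",
                nrow(truth), sum(truth$is_tumor), nrow(cfg$genome), out))
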