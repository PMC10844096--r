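# tfhlscape

Single-cell analytics for T-follicular-helper-cell lymphoma (TFHL)
studies, re-implemented as a tested R package plus a numbered analysis
workflow. It serves computational biologists who need the bespoke steps of
TFHL single-cell papers — tumor calling from TCR clonality, per-cell
mutation genotyping under allelic dropout, expression-based copy-number
inference, marker discovery, repertoire overlap, and spatial neighborhood
statistics — as reproducible, parameter-explicit functions rather than
one-off notebook code. Because primary patient data of such studies are
deposit-restricted, the package includes a first-class synthetic-data
generator that plants every structure the pipeline must recover, with
ground truth, so every stage is verifiable end to end.

## What it computes

- **Tumor calling from clonality** — clonotypes keyed by productive
  `(chain, V, J, CDR3-nt)` tuples; chain configurations (`paired`,
  `single_alpha`, `single_beta`, `multi`); major/minor tumor clones at
  configurable clonal fractions (defaults 5% / 1%) with related-clone
  merging via shared chains; Morisita–Horn / Jaccard / public-clone overlap
  (Morisita–Horn: 2 Σᵢ pᵢqᵢ / (Σᵢ pᵢ² + Σᵢ qᵢ²)).
- **Genotyping** — locus filters (aggregate coverage ≥ 100×, mutant cells
  > 20); per-cell `MUT` / `unknown` / `WT` status where `unknown` encodes
  "no mutant reads or no coverage" under allelic dropout.
- **CNV inference** — CP10K → log2 → reference centring → ±1 clip →
  101-gene positional smoothing → per-cell median centring; chromosome
  gain/loss calls at ±0.1 with 50% window support; CNV score = mean squared
  smoothed value; Ward subclones and a neighbor-joining clone tree rooted
  at an all-neutral profile.
- **Signature scoring** — bounded mean-rank per-cell score
  (mean rank of set − (N+1)/2) / ((N−1)/2); cell-cycle phasing; Wilcoxon
  rank-sum differential expression (exact enumeration for small groups,
  tie- and continuity-corrected normal approximation otherwise) with
  Bonferroni/BH correction.
- **Marker cascade** — per-sample tumor-vs-MNC and tumor-vs-normal-TFH DEG,
  ≥2-sample recurrence per compartment, LN ∩ PB intersection, background
  specificity filter.
- **Spatial & crosstalk** — radius/k-NN neighbor graphs per image;
  label-permutation z-scores and add-one empirical p-values for
  interaction/avoidance; CellPhoneDB-style minimum-member ligand–receptor
  scores with permutation nulls.
- **Cohort summaries** — recurrence as count/total/percent (half-up, one
  decimal) and cluster-proportion comparisons between clinical groups.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (each writes tables under `results/`):

```sh
Rscript analysis/01_simulate.R     # 2,200 cells, planted clone/CNV/mutation
Rscript analysis/02_repertoire.R
Rscript analysis/03_genotype.R
Rscript analysis/04_cnv.R
# ... through 09_cohort.R
```

Output of the run (seed 1):

```
simulated 2200 cells (800 tumor) over 1500 genes
assigned 2000 cells; tumor fraction 0.400; 225 single-chain tumor cells
tumor cells: 89.8% MUT, 9.2% no mutant read, 1.0% no coverage
chr5 gain called in 46.4% of tumor cells
CNV score tumor vs non-tumor: p = 5.5e-61
final candidates after specificity filter: chr1_g010, chr2_g018, chr5_g010
Tumor -> CD8_DYS: mean z +17.10, interaction in 100% of images
CD8_EFF -> B: mean z -5.16, avoidance in 100% of images
```

Reading: the planted 40%-of-T-cells tumor clone is recovered exactly
(fraction 0.400), the hotspot mutation is seen in ~90% of tumor cells with
the remainder split between dropout and no coverage (capture 0.9 at mean
coverage 5 predicts 89.4%), the subclonal chr5 gain planted in half the
tumor cells is called in 46.4%, the three planted pan-compartment markers
are returned exactly, and the planted spatial attraction/avoidance pairs
classify correctly in every image.

A minimal in-R session:

```r
library(tfhlscape)
cfg <- default_sim_config(seed = 1)
truth <- sim_truth(cfg)
asn <- assemble_clonotypes(generate_contigs(cfg, truth))
res <- call_tumor_clones(asn)
res$tumor_fraction
#> [1] 0.4
```

## Layout

- `R/` — the package (generator, IO, repertoire, genotyper, CNV, scoring,
  markers, spatial, crosstalk, cohort stats, pipeline orchestration).
- `analysis/` — numbered narrative drivers over the package.
- `vignettes/tfhlscape-methods.Rmd` — the models, parameter choices and
  their rationale, and what the synthetic tests do and do not show.
- `tests/testthat/` — unit, property and end-to-end recovery tests with
  independent oracles.
- `inst/extdata/` — small plain-text fixtures (synthetic cohort tables,
  synthetic cell-cycle gene sets, a starter ligand–receptor list).
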