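---
title: "Methods: single-cell analytics for T-follicular-helper lymphoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell analytics for T-follicular-helper lymphoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfhlscape)
```

# Scope

`tfhlscape` re-implements, as a tested and reusable pipeline, the analytical
core of single-cell studies of nodal T-follicular-helper-cell lymphoma
(TFHL): calling tumor cells from TCR clonality, genotyping somatic hotspot
mutations per cell under allelic dropout, inferring chromosome-level copy
number from expression, scoring gene programs per cell, discovering
tumor-specific markers across patients and compartments, quantifying
repertoire overlap, and testing spatial co-localization of cell types in
segmented imaging mass cytometry (IMC) data. Primary patient data of such
studies sit in restricted archives, so the package ships a synthetic-data
generator that plants every structure the pipeline is supposed to recover,
with full ground truth; all claims the test suite makes are claims about
recovery of planted structure, not about any patient dataset.

Cluster labels, embeddings and cell-type annotation are consumed as inputs
and never computed here.

# Tumor-cell calling from TCR clonality

A clonotype is the exact set of productive receptor chains of a cell, keyed
by the sorted tuples `(chain, V gene, J gene, CDR3 nucleotide sequence)`.
Identity is nucleotide-level because the biology requires distinguishing
clones that share a TCRβ chain while differing in TCRα. Cells are classed
`paired` (one productive TRA + one TRB), `single_alpha` / `single_beta`
(tumor cells frequently express only one productive chain), or `multi`
(more than one distinct chain at a locus; such cells are kept and flagged
rather than dropped).

Tumor calling is fraction-based: clonotypes holding at least
`min_major_fraction` (default 5%) of a sample's assigned cells are major
candidates; candidates that share an identical same-locus CDR3 nucleotide
sequence are merged into one related-clone group, and the group with the
largest summed fraction is the sample's single major tumor group.
Clonotypes between `min_minor_fraction` (default 1%) and the major cutoff
that share a chain with the major group are minor. The published
definitions behind "clonality-based" major/minor designation are not public,
so both cutoffs are explicit configuration.

A deliberate design choice: relatedness is sharing of *any* identical
same-locus chain, not only TRB. The TRB-sharing case (two clones, same β,
different α) is covered, and so are the single-chain variants of a clone —
a single-α cell of the major clone shares its TRA and nothing else, and a
β-only rule would leave such cells uncalled forever. Under a planted clone
with 30% single-chain cells this rule yields tumor recall and precision of
1.0; a TRB-only rule caps recall near 0.85.

Repertoire overlap offers the count of shared clonotypes, the Jaccard index
on clonotype sets, and the Morisita–Horn index
$2\sum_i p_i q_i / (\sum_i p_i^2 + \sum_i q_i^2)$ on clonotype frequency
vectors.

# Per-cell somatic genotyping

Loci are retained when aggregate read coverage across the analyzed cells is
at least 100× and more than 20 cells carry a mutant read. The "more than
20" boundary is read strictly (21 keeps, 20 drops); since an inclusive
reading is equally defensible, `strict = FALSE` switches to ≥. The coverage
filter is applied across the analyzed cell set; per-sample application is a
matter of subsetting the pileup first.

Per cell: in patients whose bulk exome carries the mutation, a cell with at
least one alternate read is `MUT` and any other cell — covered but without
mutant reads, or not covered at all — is `unknown`, since allelic dropout
makes absence of evidence uninformative in scRNA-seq. Cells of patients
without the mutation by WES are `WT`. No error model is applied (presence /
absence of the alternate allele is the published convention); a
`min_alt_reads` parameter exists for stricter calling.

Under the generator's dropout model — capture succeeds per cell with
probability $c$, coverage is Poisson($\lambda$), and a captured, covered
mutant cell always shows at least one alternate read — the expected MUT
fraction among true mutant cells is $c\,(1 - e^{-\lambda})$, which the test
suite verifies at $c \in \{0.3, 0.6, 0.9\}$.

# Copy-number inference from expression

The inference follows the standard expression-CNV recipe: counts are
normalized to CP10K, transformed as $\log_2(x+1)$, centred per gene on the
mean over a reference set of non-malignant cells, clipped to ±1, smoothed
along each chromosome with a centred 101-gene moving average (windows
shrink at chromosome ends), and finally median-centred per cell — without
that last step, residual library-size effects masquerade as whole-genome
gains.

A chromosome is called gained in a cell when more than half of its windows
exceed +0.1 (losses symmetric at −0.1); when both directions clear the
support bar the larger support wins and exact ties stay neutral. Only
whole-chromosome calls are made — the recurrent TFHL events are
chromosome-scale (chr5, 7, 19, 21, 22q) — and sub-chromosomal segmentation
is out of scope. The per-cell CNV score is the mean squared smoothed value
across windows: zero iff the profile is exactly neutral and strictly
increasing in any window's aberrance. The published score this emulates is
not specified formula-level anywhere public; mean-of-squares is our
documented stand-in.

Subclones come from Ward-linkage hierarchical clustering on Euclidean
distances between smoothed profiles, and the clone tree is neighbor joining
over subclone mean profiles plus an all-neutral synthetic profile at which
the tree is rooted. With a planted chr5 gain and a nested chr5+chr21
subclone, the chr5+chr21 leaf attaches within the chr5 branch, never the
neutral one.

Separation between carrier and neutral cells depends on sequencing depth:
at ~1,500 UMI/cell a 1.5× dosage step is ≈2.4σ of the per-chromosome noise
— per-cell calls remain accurate (sensitivity ≥ 0.9, false-gain ≤ 0.05),
but hard clustering of cells blurs. The clustering tests therefore run at
typical droplet depth (~4,500 UMI/cell), where the groups are
well-separated and the adjusted Rand index against truth is ≈0.98.

# Signature scoring and group statistics

Per-cell gene-set scoring uses a bounded mean-rank score: with $N$ genes
ranked per cell (ties averaged), a set $S$ scores
$\big(\overline{\operatorname{rank}}_S - \tfrac{N+1}{2}\big) \big/
\tfrac{N-1}{2} \in (-1, 1]$. This replaces a GSVA-style kernel estimator
deliberately: it is rank-based (invariant under any strictly monotone
transform of a cell's expression), exactly testable by hand, and
order-isomorphic to GSVA for the downstream use, which is comparing score
distributions between groups. It is *not* numerically GSVA. Cell-cycle
phase is G1 when both S and G2M scores are ≤ 0, otherwise the larger
positive score wins, ties to S; the bundled S/G2M gene sets are synthetic
editable fixtures, since real set choices are study-specific.

The comparison engine is a two-sided Wilcoxon rank-sum test, written
in-package because its exact behaviour is pinned: full enumeration of all
$\binom{n_1+n_2}{n_1}$ assignments of the pooled average ranks when both
groups have ≤ 10 observations (exact even under ties, which base R's exact
path refuses), and the normal approximation with tie correction and a 0.5
continuity correction otherwise. The test suite checks it against a
value-level enumeration oracle over hundreds of random small instances and
against `wilcox.test` on tie-free cases. Differential expression runs this
per gene on log2(CP10K+1) values with Bonferroni (or BH) correction over
tested genes; genes expressed in fewer than 3 cells are not tested.
Cluster-versus-pooled-mean comparisons use the one-sample Wilcoxon
signed-rank test with BH adjustment across clusters.

# Marker discovery cascade

Per sample, genes significantly up in tumor cells (Bonferroni-adjusted
p < 0.05, log2 fold-change > 0.25) versus two backgrounds: all
non-malignant mononuclear cells and, in lymph-node samples, normal TFH
cells — the second background removes genes that merely mark the TFH state.
A gene survives a compartment when recurrent in ≥ 2 samples (for LN, in
both backgrounds), and final candidates are the LN ∩ PB intersection. The
original workflow ends in manual inspection of embeddings; we substitute a
reproducible specificity rule — a candidate must be expressed in < 10% of
pooled non-malignant cells. The fold-change gate and the specificity rule
are our own documented choices where the published thresholds are unstated.

# Spatial neighborhood analysis

Cells within an image are joined by an edge when within radius
$r = 15\,\mu m$ (≈ one cell-diameter ring; a k-nearest rule is available).
The statistic for an ordered type pair (A, B) is the mean number of type-B
neighbors per type-A cell. The null shuffles all type labels jointly within
the image — graph fixed, abundances preserved — and the one-sided empirical
p-values use the add-one convention $(1 + \#\{perm \ge obs\})/(n_{perm}+1)$,
so they are valid at finite permutation counts. Classification at
α = 0.01: interaction when attraction is significant, avoidance when the
other side is. Degenerate nulls (SD 0) are flagged, not classified. The
published analysis names no radius, permutation count or threshold; the
defaults here follow common neighborhood-analysis practice and are all
configuration.

# Ligand–receptor crosstalk

Complex expression per cluster is the minimum over member genes of mean
log2(CP10K+1); the pair score is the mean of ligand-in-sender and
receptor-in-receiver values, reported only when every member gene is
expressed in ≥ 10% of its cluster's cells. Significance comes from the same
add-one permutation scheme over cluster labels. These are the established
mean-of-means and minimum-member conventions, stated explicitly because the
source analysis only names the tool it used.

# Cohort summaries

Recurrence is reported as count, total and percent rounded half-up to one
decimal — half-up because that is how clinical cohort tables print
percentages (11/14 → 78.6, 6/9 → 66.7), where banker's rounding would
disagree on exact halves. Cluster-proportion comparisons are per-sample
fractions of non-malignant cells, compared between clinical groups by
rank-sum test with BH adjustment across clusters; groups with fewer than
two samples are flagged and skipped. The bundled cohort tables are
synthetic reconstructions that encode published recurrence counts
patient-by-patient in arbitrary order; they exist for regression testing of
the summarizer, not as data.

# The synthetic-data generator

Counts are negative binomial with mean
`baseline × program FC × dosage × marker FC` and size (shape) parameter
`nb_dispersion` (variance $\mu + \mu^2/\theta$; $\theta = \infty$ is the
Poisson limit). Defaults: baseline mean 1 per gene, dispersion 2 — typical
droplet-data magnitudes. The synthetic genome holds 6 chromosomes × 250
genes: a real expression-CNV analysis retains roughly 250–450 expressed
genes per chromosome after filtering, and positional smoothing draws its
power from that density. Marker genes keep 5% of baseline mean outside
tumor cells, emulating tumor-restricted expression of the kind a
marker-discovery cascade is meant to find. CNV carriers are taken from the
head of the tumor-cell list so events with smaller affected fractions nest
inside larger ones, emulating sequential acquisition; mutation truth is
carried by all tumor cells of a mutant patient. CDR3s are random 30–45-mer
nucleotide strings (multiples of 3) with V/J names from a small built-in
list — only string identity matters downstream. Spatial fields are square,
coordinates continuous in µm: baseline types follow homogeneous Poisson
processes, attracting pairs a shared-parent Neyman–Scott process, and
avoiding pairs occupy opposite 37.5% slabs of the field with a central gap
of a quarter field, which guarantees zero cross-pair neighbors at any
radius below field/4.

What the generator does **not** emulate: transcriptome-wide co-expression
structure, doublets, ambient RNA, batch effects, read-level errors, or
somatic hypermutation. Passing tests therefore demonstrate that each
algorithm recovers the structure it targets under clean, independent-gene
noise of realistic magnitude — not robustness to every artefact of real
data.

All generator stages draw from seeds derived deterministically from the
config seed (truth, counts, contigs, pileups and spatial fields use fixed
offsets), so a fixed config reproduces byte-identical outputs while stages
remain independent of each other's random stream.

# Numerical and testing choices

Problem sizes in the test and acceptance runs are chosen to make each
planted effect decisively detectable while keeping a full run inside a few
minutes on one core: 2,000 T cells for clonotype recovery; 2,000 mutant
cells for the dropout closed form; 1,500 cells / 1,500 genes for CNV
recovery; four samples per compartment for the marker cascade; 200 images
for spatial type-I calibration (199 permutations, which bounds p resolution
at 1/200) and 40 images at 999 permutations for power; 200 null runs and 60
powered runs for crosstalk. Permutation p-values are never exactly zero by
construction. Ties in comparisons of clone groups break toward the larger
summed fraction, then lexically smallest key; hierarchical clustering is
deterministic given input order.

# Known limitations

- Clonotype relatedness is exact string matching; no somatic-hypermutation
  clustering for BCRs, no fuzzy CDR3 matching.
- CNV calls are whole-chromosome; arm-level or segmental events will dilute
  support fractions.
- The mean-rank signature score is a GSVA stand-in, comparable across
  groups but not numerically interchangeable with GSVA output.
- The Wilcoxon normal approximation is used above group size 10; for
  heavily tied data at moderate sizes its p-values are approximate (the
  exact path covers the small-sample regime).
- Spatial analysis treats images as independent and ignores cell size and
  shape; the radius rule uses centroids only.
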