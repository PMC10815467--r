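---
title: "Constructing and pruning intercellular gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and pruning intercellular gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Immune cells at a tumor's invasive front signal into adjacent malignant
cells. igrnet reconstructs that signaling as a directed multilayer network:
a ligand expressed by a *sender* population (for example macrophages) binds
a receptor on a *receiver* malignant subcluster, the receptor links to a
transcription factor (TF) through pathway priors, and the TF regulates
target genes inside the receiver. The package builds a permissive
*preliminary* network from prior knowledge and expression gates, then
*prunes* it with two orthogonal, data-driven filters — regulon activity and
differential expression — so that only signals with intracellular support
survive. The same workflow needs supporting stages, all included here: cell
quality control, normalization, expression-derived copy-number (CNV)
profiling to identify malignant subclusters, and spatial K-distance
statistics to identify which subclusters sit at the invasive front.

```{r, eval = FALSE}
library(igrnet)
bundle <- fixture_small()
res <- run_pipeline(pipeline_config(bundle = bundle, seed = 1,
                                    min_genes = 50))
res$results[["macrophage->m1"]]$pruned
```

## Model and procedure

**Quality control.** Cells are kept when the mitochondrial UMI fraction is
at most 0.20, the total UMI count lies in [200, 60000], and strictly more
than 200 genes are detected. The gene-count bound is read as exclusive and
the UMI bounds as inclusive — the thresholds are conventional for human 10x
data, and mitochondrial genes are recognized by the "MT-" symbol prefix
(configurable). On synthetic genomes far smaller than a real transcriptome
the detected-gene bound must be rescaled with the genome (the packaged
examples use `min_genes = 50` on a 200-gene fixture); the defaults describe
real data, not a property of the algorithm.

**Normalization.** `value = ln(1 + count * scale_factor / total)` with
`scale_factor = 10000`, the standard library-size log-normalization. Cells
with zero totals map to zero columns and the zero pattern is preserved
exactly, which downstream expressed-fraction gates rely on. Per-gene
z-scoring is a separate, opt-in step. Highly variable genes are ranked by
standardized variance against a loess mean-variance trend with clipped
z-scores (a vst-style dispersion); ties break lexicographically so the
ranking is deterministic and invariant to cell order. When the trend fit
degenerates (possible on toy inputs with a handful of distinct means) the
fallback trend is the Poisson expectation `variance = mean`.

**Differential expression.** One-vs-rest Wilcoxon rank-sum within the
receiver compartment (all cells sharing the focal subcluster's cell type).
The exact null distribution is used whenever there are no ties and both
groups have fewer than 50 cells; otherwise the normal approximation with
tie and continuity corrections. The screen keeps genes with raw
`p < 0.05` and natural-log fold change `> 0.15`; the fold change is
computed Seurat-style from back-transformed group means with pseudocount 1,
since the 0.15 threshold was tuned in that ecosystem on natural-log values.
The threshold applies to the raw p-value (matching the screening parameter
it reproduces); BH-adjusted p-values are reported alongside for inspection.

**CNV profiling and malignancy.** Genes with mean raw expression below 0.1
are dropped; log-normalized expression is centered on the reference-cell
mean per gene, clamped to [-3, 3], smoothed by a 101-gene moving average
within each chromosome (the window shrinks at chromosome ends and never
crosses a boundary), re-centered on each cell's median, and finally
centered on the reference cells' post-smoothing mean profile — so the
reference mean residual profile is exactly zero by construction. The
per-cell CNV score is the cumulative deviation of this profile, taken as
the sum of squared residuals over all retained genes ("cumulative" is not
defined more precisely by the upstream tooling; an absolute-sum variant is
exposed for sensitivity analysis, and no attempt is made to segment the
profile into discrete CNV regions). A subcluster is malignant when a
one-sided rank-sum test finds its scores significantly higher than the
reference scores (`p < 0.05`) *and* its median exceeds the reference
median — the claim is directional, hence the one-sided test. Subcluster
relatedness is summarized by Spearman correlation of mean residual
profiles; chromosome order is taken from the declared order of the
position file, never alphabetically, so chr10 cannot sort before chr2.

**Spatial statistics.** `kdist` is the mean Euclidean distance from a query
cell to its k nearest reference cells (k = 10 by default) in native
coordinate units; ties in distance break by reference order for
determinism. The invasive front is not defined quantitatively by the
upstream literature, which infers it from trajectory position and visual
inspection; this package substitutes an explicit rule: a malignant
subcluster is a *front* subcluster when its kdist-to-immune distribution is
significantly lower (one-sided rank-sum, `p < 0.05`) than the pooled
kdist of the other malignant subclusters. Externally supplied trajectory
labels can restrict the candidate set. This is an operationalization, not a
reconstruction, and is documented as such.

**Ligand-receptor scoring.** For each prior L-R pair whose ligand is
expressed in more than 10% of sender cells and whose receptor is expressed
in more than 10% of receiver cells, the interaction score is the mean of
the two population means of normalized expression. Significance comes from
jointly permuting the sender/receiver partition of the pooled cells:
`p = (1 + #[permuted score >= observed]) / (n_perm + 1)` with
`n_perm = 1000`, so p can never drop below `1/(n_perm + 1)`. The
permutation stream is seeded locally, making every run reproducible.

**Regulons and activity.** TF-target co-expression is scored by the
absolute Spearman correlation across receiver cells — a deterministic,
assumption-light statistic chosen over gradient-boosting importances; pairs
below 0.1 are dropped, and surviving pairs are intersected with
motif-supported TF-target priors to form regulons. Per-cell activity is the
area under the recovery curve of a regulon's targets within the top 5% of
that cell's expression ranking (ties broken lexicographically), normalized
so a regulon whose targets fill the top ranks scores exactly 1. A TF is
*active* when more than 25% of receiver cells exceed that regulon's
activity threshold of mean + 2 standard deviations across all cells (the
standard binarization family for this statistic; the 0.05 window and 0.25
fraction are the conventional defaults).

**Assembly and pruning.** The preliminary network takes ligands significant
in the permutation screen (`p < 0.05`), their prior receptors expressed in
the receiver, prior TFs of those receptors expressed in the receiver, and
all prior targets of those TFs. Pruning then keeps a TF only if it is an
active-regulon TF and keeps a TF-target edge only if the pair lies in that
TF's motif-pruned regulon *and* the target passed the DEG screen. After
every construction or pruning step the network is validated: any node or
edge not on a complete ligand-receptor-TF-target path is removed, so the
pruned edge set is always a subset of the preliminary edge set and every
reported node lies on at least one complete path. "Signal" counts are
reported as edges per layer (with node and path counts alongside, since
the upstream reduction figure does not say which it counts).

## The synthetic study design

`generate_synth()` emulates the structure of the real study inputs — a
tumor and a normal sample, two immune sender populations, malignant
receiver subclusters, a normal epithelial reference — with fully known
ground truth:

- **Counts** are negative binomial with dispersion 0.3 and lognormal(0, 1)
  baseline gene means, the standard noise family for droplet scRNA-seq.
  Genes carrying planted structure get baseline mean 3 so that
  expressed-fraction gates behave as they do for moderately expressed real
  genes.
- **Cascades** (5 by default, effect log-FC 1.0, landing in subcluster m1):
  the ligand is shifted by `exp(effect)` in its sender; receptor, TF and
  targets are jointly shifted by `exp(2 * effect)` in the latent-active
  half of receiver cells (per-cell Bernoulli(0.5) activity shared within a
  cascade), so the mean log shift equals `effect` and Spearman-based
  regulon scoring has recoverable within-cell correlation.
- **Decoys** (20 prior edges by default) come in two forms: TF-target
  priors hanging off planted TFs, whose targets carry no signal — these
  enter the preliminary network and must be pruned — and complete decoy
  chains over signal-free genes, which exercise the L-R and activity gates.
- **CNV segments**: 1.8-fold expected-count gains over 60 contiguous
  position-ordered genes, one segment per malignant subcluster on distinct
  chromosomes.
- **Spatial layout**: an idealized disc (core subcluster m1) / annulus
  (front subcluster m2) / ring (immune cells) geometry that makes front
  calls analytically unambiguous; a uniform layout is available for null
  calibration.
- **Markers**: 5 genes per population shifted by `exp(1)`, supporting
  spot-composition checks.

The packaged `fixture_small()` (200 genes, 400 cells, 2 cascades, pinned
seed 42) uses effect 1.5: with only 200 genes the activity window is 10
ranks, and the fixture is meant to be an unambiguous documentation and
smoke-test object, in the same spirit as the idealized geometry. The
default 600-gene design keeps the spec of effect 1.0.

What the generator does **not** emulate: doublets, ambient RNA, batch
effects, realistic chromosome-scale gene density, Visium spot gridding, or
cell-type compositional ambiguity. Passing recovery tests therefore shows
the pipeline's statistical machinery is correct and calibrated under its
stated noise model — not that thresholds tuned for real 10x data are
optimal on any particular dataset.

## Numerical choices and degenerate inputs

- Duplicate gene symbols are collapsed by summing rows (preserves counts)
  and logged; symbols are harmonized by upper-casing only — no alias
  dictionary, for determinism.
- MatrixMarket input is 1-based on disk; all internal structures are
  addressed by name, never by raw index.
- Complete ties in the rank-sum test return p = 1 (the statistic is
  degenerate, not an error).
- Constant genes get co-expression score 0 and undefined correlations in
  cluster similarity are reported as `NA`, not errors.
- A zero-target regulon (after matrix intersection) is an error; an empty
  prior table is a warning.
- Ties everywhere that ordering matters (HVG ranks, expression ranks,
  nearest-neighbor distances, path enumeration) break lexicographically or
  by declared input order, so identical inputs and seed give byte-identical
  outputs.
- Per-stage permutation seeds are derived deterministically from the single
  pipeline seed.

## Problem sizes

The packaged tests and the acceptance script run the full design at 600
genes x 750 cells (5 cascades, 20 decoy priors, 1000 L-R permutations),
the fixture at 200 genes x 400 cells, and null calibration at 300 genes x
320 cells with 199 permutations — sizes chosen so the whole suite completes
in a couple of minutes on a single core while leaving every statistical
margin intact.

## Known limitations

- Prior knowledge is user-supplied; the package ships no L-R, pathway or
  motif databases, and results inherit the priors' biases.
- The co-expression statistic is pairwise |Spearman|; it cannot separate
  direct from indirect regulation the way ensemble importances attempt to.
- The front rule compares subclusters against each other, so it needs at
  least two malignant subclusters and reports `NA` otherwise; a tissue
  where every subcluster touches immune cells will dilute the contrast.
- CNV scoring detects broad expression-level dosage effects; it does not
  call discrete states or breakpoints.
- The L-R permutation test shares the usual limitation of its family: a
  receptor strongly enriched in the receiver can render pairs significant
  even when the ligand is uniformly expressed.
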