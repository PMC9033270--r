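---
title: "Quantifying radial organization in micropatterned neuruloid colonies"
author: "neurquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radial organization in micropatterned neuruloid colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurquant)
```

## The measurement problem

Human embryonic stem cells confined to 500-µm circular micropatterned islands
and pushed toward ectoderm self-organize into *neuruloids*: concentric tissues
with neural ectoderm (NE, PAX6+) at the center, neural crest (NC,
SOX10/FOXD3+) in a ring, and non-neural/early epidermal tissue (TFAP2A/KRT18+)
at the rim. Because the geometry is stereotyped, the biology can be read out
as a handful of scalar metrics per colony — how far a marker domain extends,
what fraction of the colony it covers, how strongly a nuclear signal is
expressed at a given radius — and those metrics can be compared across
genotypes (wild-type vs a CAG-expanded Huntington's disease line) and drug
conditions (e.g. LATS-kinase inhibition, which de-represses YAP). This package
implements that quantification pipeline end to end, together with the
single-cell RNA-seq arm used to ask which lineage carries YAP transcriptional
activity, and a synthetic-data module that generates ground-truthed inputs so
every stage is testable without any microscope or sequencer.

## Imaging model and pipeline

**Stacks and projection.** Input images are multi-channel z-stacks; all
colony-level metrics are computed on the maximum-intensity projection (MIP).
`max_intensity_projection()` is the exact per-pixel maximum over z; the z
count is recorded but not constrained (real acquisitions project four or more
slices). Per-z-slice segmentation is possible by running the segmenter on a
single-slice stack; the MIP route is the default because every downstream
colony metric consumes the MIP.

**Colony detection.** Colonies are bright disks on a dark background in the
DAPI channel, so `detect_colonies()` thresholds by Otsu, fills holes, and
keeps connected components whose equivalent diameter is within ±20% of the
nominal island diameter (500 µm). Detections are returned in row-major grid
order. Coordinates are 1-based `(row, col)` with floating-point centers, the
native R convention.

**Nuclear segmentation.** Nuclei are segmented from DAPI in three steps.
(1) Pixel classification into nucleus/background: Otsu by default, with an
optional trainable per-pixel logistic classifier (features: intensity, two
Gaussian-smoothed intensities, gradient magnitude) for images where a single
global threshold fails — e.g. a confluent colony whose cytoplasmic/dim DAPI
floor sits between background and nuclei. An optional pre-smoothing
(`pre_smooth_sigma`, 1 px in the `segment_colony()` pipeline) suppresses shot
noise that otherwise frays mask boundaries. (2) Seed detection with a
normalized disk matched filter ("sphere filter" in 2-D) of radius equal to
the expected nucleus radius; local maxima above a threshold are kept with a
minimum separation of one filter radius. The threshold is configuration — the
original interactive procedure set it by hand — and defaults to Otsu on the
filter response. (3) Seeded watershed: a priority flood (compiled) over the
negated, lightly smoothed DAPI intensity, constrained to the mask, so that
two adjacent nuclei split on the intensity valley between them. Flooding ties
are broken by insertion order, which makes the labeling deterministic.
`measure_nuclei()` then records, per nucleus, the centroid, area, radial
distance from the colony center, and the *median* intensity in every channel;
medians, not means, so a few bright or dark pixels cannot dominate.

**Radial profiles and domain metrics.** `radial_profile()` bins pixels (or
nucleus centroids, for nuclear-signal profiles) by distance from the colony
center, default bin width 5 µm, and averages intensity per bin, in arbitrary
fluorescence units. The colony center is the centroid of the hole-filled DAPI
mask — robust to crop placement; with ~100 nuclei the residual center error
displaces a ring boundary only at second order. From a profile the package
derives:

- `edge_average()`: the pixel-weighted mean over bins whose centers lie in
  the outermost fraction of the radius (default 10%); the window is a
  parameter because the figure convention does not pin it down.
- `half_max_radius()`: the radius where the smoothed profile first reaches
  halfway between baseline and maximum, reading the *rising (inner) flank* of
  a peripheral domain such as the SOX10 ring — i.e. the boundary between the
  central territory and the ring. The baseline is the minimum over bins
  interior to the maximum; crossing position is linearly interpolated between
  bin centers; profiles whose contrast is below 10% of the maximum are
  declared to have no domain (NA with a reason). Smoothing is a 3-bin moving
  average: enough to suppress single-bin noise, and it shifts a 15-µm-scale
  Gaussian flank by under 1 µm (the smoothed sigma is
  $\sqrt{\sigma^2 + w^2/12}$ with $w = 15$ µm).
- `positive_area_fraction()` and `central_domain_fraction()`: marker-positive
  area normalized to the DAPI-occupied area, and the area of the central
  connected marker component relative to the whole colony disk. The second
  ignores detached peripheral specks and is the "PAX6+ central region"
  readout.
- `normalize_nuclear_signal()`: per-nucleus marker medians divided by the
  colony's median nuclear DAPI (default) or z-scored within colony. The
  normalization is a package choice — division by nuclear DAPI makes values
  exposure-invariant, which the scale-invariance test checks — and the method
  used is recorded on the output.
- `mitotic_index()`: the fraction of nuclei whose pH3 median exceeds a
  threshold (fixed or Otsu over the medians).

Cross-colony aggregation (`aggregate_profiles()`) rescales radii to the
fractional colony radius before averaging, since detected diameters vary
within tolerance.

## The synthetic colony generator

`colony_truth()` + `make_colony_image()` define the study conditions for
every imaging test. A colony is a 500-µm disk (2 µm/px by default) holding:

- *Nuclei*: isotropic 2-D Gaussian blobs (σ = 6 µm) truncated at 3σ, placed
  by dart throwing with a minimum center separation (default 3σ, which
  guarantees watershed separability and is the regime the recovery guarantee
  addresses). A `"disk"` shape renders nuclei as flat plateaus instead; the
  idealized "exact Otsu separation" property only makes sense for sharp
  supports, so that is how it is tested. Non-DAPI nuclear channels (YAP-like,
  pH3-like) are always flat plateaus at the planted level, so the true
  per-nucleus median is well defined.
- A *central marker disk* (PAX6-like) of chosen radius and a *peripheral
  Gaussian annulus* (SOX10-like; center 175 µm, σ 15 µm by default).
- Optional *mitotic* nuclei carrying a high pH3 plateau.
- An optional uniform DAPI plateau over the colony disk
  (`confluent_dapi_level`), emulating a confluent epithelium where DAPI
  effectively tiles the colony; used where colony *detection* needs disk-like
  support.
- Per-channel background and either Poisson (photon-count, the default) or
  additive Gaussian noise. Real image noise levels are not documented for
  this assay, so noise is a calibration parameter: tests state their own
  signal-to-noise ratio, e.g. SNR 5 meaning noise SD = peak/5.

Fixed seed and parameters give byte-identical images. What the generator does
*not* emulate — optics (PSF), illumination gradients, z-structure, chromatin
texture, nucleus shape variation — bounds what passing tests show about real
data: they validate the *computational* pipeline (geometry, statistics,
recovery under stated noise), not robustness to optical artifacts.

`make_colony_array()` tiles jittered colonies on a grid (pitch > diameter
enforced) for detection and cropping tests.

## Single-cell arm

**QC.** `qc_filter()` applies strict cutoffs — total counts > 6000, detected
genes > 2600, 3% < mitochondrial fraction < 11% — the standard gate for these
neuruloid dissociates. Boundary cells (exactly 6000 counts, exactly 3% mito)
fail, and the synthetic generator plants violators exactly on those
boundaries to pin the inequalities down.

**Normalization and residualization.** Counts are library-size scaled to
10^4 and log10-transformed (`normalize_log()`); log10, not the more common
log2, to match the study convention, and fold changes downstream are
therefore log10 fold changes (stated on the output). `regress_covariates()`
removes cell-cycle and mitochondrial effects by per-gene least squares,
re-centered at the gene mean. Cell-cycle phase *scoring* is out of scope; the
generator emits a synthetic per-cell cell-cycle scalar so the residualization
stage is testable.

**Lineage annotation.** Instead of graph clustering and cross-sample anchor
integration (out of scope), cells are labeled by marker signatures:
per-lineage score = mean normalized expression of the lineage's markers minus
a size-matched random background (fixed seed), label = argmax, with an
ambiguity margin. On the generator's three-cluster matrices this is ≥ 95%
accurate; sample effects are instead handled inside the DE model via the
contrast. This is a documented simplification: on real data, signature
scoring can blur continuous or doublet populations that graph clustering
would isolate.

**Hurdle differential expression.** `hurdle_de()` implements a two-part
model per gene: logistic regression of detection on group and a Gaussian
linear model of the positive log-expression on group, each with the cellular
detection rate (CDR) as covariate by default (the convention for hurdle
models on droplet data; toggleable). The test statistic is the sum of the two
likelihood-ratio χ² statistics with summed degrees of freedom; degenerate
components (all-or-none detection, single-group positives) contribute zero
with zero df, and genes detected in fewer than 3 cells are untestable
(p = 1). This is deliberately the *unpenalized* two-part model — no variance
shrinkage or Bayesian regularization — which captures the hurdle structure
while staying dependency-light; the calibration suite (type-I error within
[0.03, 0.07] at α = 0.05, KS-uniform null p-values, power ≥ 0.9 for 2-fold
shifts at 300 cells/group) is the evidence that the simplification is
adequate at these sample sizes. Multiple testing is Benjamini–Hochberg
throughout.

**Gene-set enrichment.** `gene_set_enrichment()` scores a set as the mean
signed z-statistic (from the hurdle p-values, signed by fold change) over the
set's genes, and compares it against `n_perm ≥ 999` size-matched random gene
sets — a competitive null over gene labels, fixed seed, with the +1
correction so p is never 0. Exact ties between null and observed scores count
half, so the degenerate "set = all genes" case sits mid-scale instead of at
1; for any non-degenerate set ties have probability zero and the convention
is inert. `enrichment_by_cluster()` runs the contrast (e.g. HD vs WT) within
each lineage and adjusts across (set, cluster) pairs. The 364-gene planted
"YAP-target" set mirrors the size of the curated target list used in the
original analysis; the real list identity is user input (GMT), not shipped.

**Synthetic counts.** `counts_truth()`/`make_counts()` draw
negative-binomial counts per gene with per-cluster marker folds and
per-(cluster, sample) planted set shifts; genes are independent, which is
sufficient for calibrating per-gene tests and competitive set enrichment.
Defaults (4000 genes, NB size 3, lognormal means around 2.5) put a typical
cell at ~17k counts and ~3000 detected genes — comfortably inside the QC
window, as the dissociates this emulates were after filtering. Problem sizes
in the test and acceptance suites (2000 genes, 250–300 cells per group, 999
permutations, 20 colonies per condition) were chosen as the smallest sizes at
which the planted effects and calibration bands are stable; they are the
package's study conditions, not tuned quantities.

## Group statistics

`compare_groups()` provides the caption-level tests: Welch's t (the default
reading of an "unpaired t-test" — the equal-variance Student variant is
available since the original captions do not specify), Mann–Whitney U as the
"nonparametric t-test" (exact for small tie-free samples), and a permutation
test on the difference of means (exhaustive when the label space is small,
otherwise 10^4 random permutations with the +1 correction).
`two_way_anova()` uses type-II sums of squares for the lineage × genotype
designs. `condition_report()` assembles the ratio-to-control tables used for
multi-condition summaries. All tests hold their nominal size within
[0.03, 0.07] at α = 0.05 under the null — this is asserted by the acceptance
suite, not assumed.

## Numerical and I/O choices

- TIFF stacks are written 16-bit (camera-count convention); integer
  intensities in 0–65535 round-trip bit-exactly. The installed TIFF writer
  does not persist description tags, so channel names, z order and pixel size
  travel in a JSON sidecar, with an explicit `channel_map` fallback for
  foreign files; a missing pixel size falls back to 1 µm/px with a warning.
- Count matrices are MTX triplets (`matrix.mtx`, `genes.tsv`,
  `barcodes.tsv`) or dense TSV; gene sets are GMT.
- Crops are squares of side `2*ceiling(radius*(1+pad)) + 1`; the extra center
  pixel keeps the colony disk strictly inside the crop.
- Watershed tie-breaks, seed ordering, background-gene draws and permutation
  draws are all seeded or deterministic; every generator and every
  permutation test takes an explicit seed.

## Known limitations

Segmentation is 2-D on the MIP; overlapping nuclei closer than ~3σ are not
guaranteed to split correctly, and the recovery guarantee (≥ 98% matched at
SNR ≥ 5) is stated only for the separation regime the generator enforces.
The hurdle model omits variance shrinkage, so very small groups (tens of
cells) will be noisier than a regularized implementation. Enrichment uses a
competitive gene-label null, not a cell-permutation null: it asks whether the
set is more shifted than random genes, which matches the planted-signature
question but does not propagate cell-cell correlation. The condition report
treats colonies as independent units; no hierarchical (colony-within-batch)
modeling is attempted.
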