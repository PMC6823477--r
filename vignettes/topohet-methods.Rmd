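---
title: "Methods: multi-scale heterogeneity analysis of PDX immunofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale heterogeneity analysis of PDX immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topohet)
```

# Overview

`topohet` quantifies how the phenotype of a patient-derived xenograft (PDX)
tumor varies across spatial scales — from sub-cellular texture inside one
immunofluorescence (IF) section up to differences between whole PDX models —
and what that structure implies for how many tissue samples an experiment
needs. The cohort hierarchy is

    dataset > model > tumor > sector > section image
            > region > microenvironment > cellular > subcellular

where a *sector* is one of three anatomical subdivisions of a harvested
tumor and a *sample* (one sector of one tumor) is the unit profiled by the
molecular assays. The reference design is 4 models x 3 replicate tumors x 3
sectors = 36 samples, with 3 replicate section images per sample, imaged at
0.4619 µm/px.

The pipeline has six analysis stages, each exercised end-to-end against a
synthetic cohort whose ground truth is known exactly at every scale.

# The synthetic cohort generator

The generator is first-class, tested code, not a fixture: every downstream
stage is validated by parameter recovery against it.

**Images.** A section image has a DAPI channel (randomly placed elliptical
nuclei with Gaussian intensity falloff), a vimentin channel (a thresholded
smooth random field marking contiguous stroma), and one or more phenotype
channels. Phenotype intensity is built *additively*:

    I = dataset mean + model offset + tumor offset + sector offset
        + image offset + region field + microenvironment field
        + cellular field + subcellular noise

Group offsets are drawn once per group (every image of a model sees the
same model offset) with the standard deviations in `scale_effects()`.
Within-image fields are white noise smoothed at characteristic lengths
(defaults 1000, 100, 10 px, i.e. 462, 46, 4.6 µm) and standardized, chosen
to coincide with the analysis ladder's Gaussian widths so that parameter
recovery is well posed. Tissue occupies a central ellipse (~75% of each
axis) so that artifact estimation always has tissue-free image regions, as
real slide scans do. Nuclei cover ~40% of the tissue area. The
distributional choices (marker intensity distributions, nucleus shape,
stromal geometry) are conventions a practitioner would call plausible, not
reproductions of real histology.

Clipping to the 16-bit range [0, 65535] and the tissue envelope are
absorbed into the stored subcellular residual, so the per-scale
contributions always sum to the generated channel *exactly*. This keeps the
decomposition oracle exact while allowing physical intensity bounds.

**Molecular tables.** RNA counts follow a negative-binomial model whose
log-mean carries gene, model, tumor and sector effects, sequenced on 4
replicate chips per sample. The variant table designates a subset of loci
as mutant in pure mouse; their allele frequencies equal a per-locus scale
times the sample's mouse-contamination factor (plus small noise), so
contamination induces the co-variation the filtering rule looks for.

**Growth curves.** Volumes follow `V0 * 2^(t / doubling)` with
multiplicative lognormal noise, measured every 3.5 days until the true
volume reaches 600 mm³ (the harvest endpoint).

**Reproducibility.** All randomness flows through `derive_seed()`, which
hashes a `(seed, tag...)` path and applies two multiply/xor-fold
finalization rounds. The finalizer matters: without it, adjacent tags (e.g.
sectors 1, 2, 3) produce adjacent raw hash values, and first draws from
`set.seed` on adjacent integers can be visibly correlated — we observed
sector offsets drawn nearly identical through exactly this route. Streams
are split per `(key, stage)`, so adding images does not perturb the
molecular simulation.

# Image restoration

The observation model is `observed = (true + B) * S`: a slowly varying
additive background `B` plus a multiplicative stripe profile `S`, constant
along y, periodic along x with a 1560 px period (a scanner artifact).

* `estimate_background()` averages intensity in large tissue-free blocks
  (480 px tall, one period wide — the mean-one stripe cancels within each
  block), infills tissue-covered blocks by iterative harmonic diffusion
  (the smooth, edge-free limit of Mumford–Shah-style inpainting,
  convergence at relative change < 1e-6 or 10,000 iterations), and
  upsamples block means to pixel resolution bilinearly with linear
  end-slope extrapolation.
* `estimate_stripes()` averages `observed / B` over non-tissue pixels at
  each phase modulo the period, interpolates empty phases circularly, and
  rescales to mean 1.
* `correct_image()` inverts the model: `observed / S - B`, clamped at 0
  (physical non-negativity).

Estimation order is B first, then S, mirroring the well-posedness argument
above. `estimate_artifacts()` adds refinement passes (default 6): once a
stripe estimate exists, the de-striped image no longer ties the block width
to the period, so the background can be re-estimated on a much finer block
grid, and the stripe re-estimated from the better background. On images
spanning only two or three stripe periods this reduces both errors several
fold; it converges because each pass solves a well-posed sub-problem with
the other factor fixed.

**Known limitation.** When an image spans very few stripe periods, a
smooth background error aliases into the phase average at the stripe's own
frequencies; the two factors are then not fully separable from one image,
and residual stripe error tracks residual background error. Wider scans
(many periods) decouple them.

The tissue mask used *for artifact estimation* is a coarse Otsu threshold
on the channel itself plus a generous dilation — deliberately independent
of the downstream cellular mask. DAPI exposure is rescaled linearly to the
125 ms reference, and `normalize_replicates()` maps each replicate section
by the unique linear transform sending its 25th/75th tissue percentiles to
the across-section average of those percentiles (idempotent by
construction; degenerate contrast, p75 <= p25, is an error).

# Tissue masks

Nuclear pixels are DAPI above a locally adaptive threshold
(`local Gaussian-weighted mean * (1 + offset)`), with connected components
below 20 px removed; the cellular mask closes the nuclear mask with a 10 px
disc (~4.6 µm, the cellular length scale); the stromal mask applies the
same operation to vimentin; and `tumor = cellular & !stromal` exactly.

The adaptive-threshold defaults are window 101 px and offset 0.25. A zero
offset is unusable in the presence of background noise — with a mean-zero
noise background roughly half of all background pixels sit above their
local mean, and morphological closing then floods the image — so a strictly
positive relative offset is required; 101/0.25 recovers generator nuclei
and stroma at IoU > 0.7 while remaining insensitive to the nucleus radius.
Both parameters are exposed.

# Multi-scale variance decomposition

`decompose_scales()` expresses each analyzed (nuclear) pixel's intensity as
an exact sum of per-scale contributions, obtained by recursive
residualization from coarse to fine:

1. subtract the grand mean over all analyzed pixels (dataset);
2. for each above-image level (model, tumor, sector), subtract each
   group's mean residual — computed as the *unweighted* mean across the
   group's member images of the image-mean residual, regardless of
   nuclear-pixel counts (a group whose images have unequal tissue content
   is therefore not pixel-weighted; with balanced cohorts the two
   conventions nearly coincide);
3. within each image, for Gaussian widths σ = Inf, 1000, 100, 10 px
   (image, region, microenvironment, cellular), subtract the
   mask-normalized Gaussian local mean of the residual — numerator and
   denominator are both convolved with the same zero-padded kernel, so no
   intensity is reflected or leaked across the nuclear-mask boundary;
   σ = Inf is computed exactly as the image mean over analyzed pixels;
4. the final residual is the subcellular contribution.

`variance_table()` reports the population variance of each contribution
over all analyzed pixels and its fraction of the total variance. Fractions
are *not* renormalized to sum to one: the contributions are not orthogonal,
so their variances need not partition the total (they do exactly in the
special case of pure group-mean decomposition, where the construction
coincides with classical nested ANOVA — a property pinned by test).

Because group means are removed recursively, variance injected at one
level partially surfaces one level up (e.g. the mean of three sector
offsets becomes tumor-level signal, leaving ~2/3 of the injected variance
at the sector level in expectation). This is a property of the estimator,
not a bug; with only three sectors per tumor the attribution can
occasionally tip to the parent level for unlucky draws.

# Block-based phenotype profiling

A two-stage clustering describes sub-cellular phenotype composition:
channels are rescaled by fixed bounds (0, 35000) and clipped to [0, 1];
foreground pixels (any channel > 0.20) are k-means clustered into 10 pixel
types; each foreground block (20 px tile with >= 20% foreground pixels;
partial edge blocks discarded) is summarized by its pixel-type composition;
block summaries are k-means clustered into K = 30 block types. An image's
profile is the frequency vector of block types over its foreground blocks,
weighted by the foreground block count. The pixel-vs-block foreground rule
(any-channel pixel rule, 20% block rule) and the 10 pixel types are
package conventions, exposed in the interface.

k-means uses seeded Lloyd iterations (5 starts), so a fit is a pure
function of its seed; when there are fewer distinct feature vectors than
requested centres, the distinct vectors become centres (cyclically padded —
padded duplicates can never win the first-index tie-break, so spurious
types stay at zero frequency).

Sub-image grids (`grid_subimages()`, default 1300 px ≈ 0.6 mm at 0.4619
µm/px, the size of a tissue-microarray core) keep the truncated remainder
in edge cells; aggregation over any profile set is the tissue-weighted mean
renormalized to sum 1.

# Sampling-design confidence

For one PDX model, the *true* profile is the tissue-weighted aggregate over
every sub-image (all tumors, sectors, sections). A sampling run draws `n`
sub-images under one of five strategies — within model, tumor, sector,
sample, or section, each first picking its unit uniformly at random —
without replacement (with replacement only when the pool is smaller than
`n`; zero-tissue sub-images are excluded from all pools). A run is *good*
when the mean absolute deviation across the K block types between sample
and true profile is strictly below 0.01; confidence is the fraction of good
runs out of 1000, averaged over 40 block-model refits when seeding
variability matters. The run substream is derived from `(seed, n, run,
refit)` but not the strategy, so curves are paired across strategies.
Saturation confidence is the curve's maximum over the evaluated `n`.

# Molecular side-pipeline

QC gates are strict thresholds: DNA passes at mapped reads > 1e6 AND
on-amplicon > 85%; RNA at mean read length > 100 AND genes mapped > 45%.
RPM normalization scales each chip to one million total reads and averages
the replicate chips. Loci called mutant in pure mouse are removed entirely.
The spike-in statistic is `2(x - y)/(x + y)` on non-low genes (pair mean
RPM > 10 by default, a package convention); since either orientation of
the comparison can be of interest, both signed exceedances are reported
and the absolute value > 0.5 is the default flag.
Growth is fit by OLS of log volume on days with doubling time
`log(2)/slope` (any log base gives the same doubling time; natural log is
used); one-way ANOVA of doubling times across models uses classical sums
of squares, with zero within-group variance reported as a degenerate
infinite F. Scale-stratified correlation z-scores each readout across all
samples (constant readouts removed) and averages pairwise Pearson r over
all sample pairs sharing the given hierarchy level.

# Numerical choices and problem sizes

* Gaussian smoothing is separable zero-padded convolution via FFT (padded
  to composite lengths, chunked to bound memory); masked statistics divide
  the smoothed masked image by the smoothed mask.
* Harmonic infilling relaxes missing block cells to the mean of their
  4-neighbours; known cells are fixed.
* Ties in nearest-centroid assignment break to the lowest index.
* An empty tumor mask yields `NA` (the statistic is undefined, never 0).

The test and acceptance workloads run on reduced problem sizes chosen as
the package's own defaults for desk-scale validation: single sections of
400 x 360 px with a 120 px stripe period (three periods per image, the
same period-to-width ratio regime as full scans), decomposition cohorts of
18 images at 96–192 px with ladder widths (Inf, 64, 16, 4) px and matching
generator field lengths, and a sampling model of 3 tumors x 3 sectors x 2
sections with 80 px sub-images (162 cores). Generator defaults remain at
full scale (4096 x 3120 px, 1560 px period).

# What passing tests do and do not show

The generator emulates hierarchical intensity structure, the stated
artifact model, nuclear/stromal geometry, replicate count chips with
contamination-driven variant co-variation, and exponential growth. It does
not emulate real histology (no H&E morphology, no necrosis, no
segmentation-hostile nucleus clumping), scanner noise beyond additive
Gaussian, registration error between replicate sections, or read-level
sequencing artifacts. Parameter-recovery results therefore validate the
*estimators* under their stated models; they do not certify performance on
real slides, where model misspecification (e.g. a stripe that varies along
y, or tissue with no artifact-free margin) would dominate.
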