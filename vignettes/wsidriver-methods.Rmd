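---
title: "Methods: automated tile extraction and mutation-class prediction from whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated tile extraction and mutation-class prediction from whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wsidriver)
```

## The problem

Papillary thyroid carcinoma (PTC) is driven almost exclusively by one of
two mutually exclusive driver mutations, `BRAF` V600E or a `RAS` hotspot
mutation, and the two groups differ in downstream signalling, prognosis
and radioactive-iodine response. The mutation state is ordinarily
established by molecular testing; H&E histology, however, carries enough
morphologic signal (classical papillary architecture versus
follicular-variant growth, nuclear crowding and shape) that a
convolutional network trained on image tiles can predict the driver class
directly from a scanned slide.

`wsidriver` implements the full automated workflow: quality-controlled
tile extraction from pyramidal whole-slide images (WSIs), colour
machinery (optical density, H&E deconvolution, Reinhard normalization),
nuclei-based patch selection, a leakage-free patient-level split, CNN
training with dihedral augmentation, and tumor-level aggregation through
the percRAS statistic with a full evaluation suite. A seeded synthetic
slide generator with exact ground truth makes every stage testable
without any external image.

## The percRAS decision rule

The classifier emits, per 512×512 tile at 20×, the softmax probability
`p_RAS` that the tile comes from a RAS-mutant tumor. A tile is *called*
RAS when `p_RAS >= 0.5` (inclusive). For a tumor with `n` tiles,

```
percRAS = #{tiles with p_RAS >= 0.5} / n
```

and the tumor is called RAS when `percRAS > 0.75`, BRAF V600E when
`percRAS < 0.25`, and left *not predicted* inside the band — both band
edges fall in the band (the calls are strict inequalities, the tile
cutoff is inclusive). These three constants live in one place,
`aggregation_config()`, and nowhere else. Because the literature is
ambiguous about whether headline accuracies count unpredicted tumors in
the denominator, `evaluate_predictions()` always reports both: accuracy
over called tumors and accuracy over all tumors, alongside the count of
unpredicted cases.

## Cohort bookkeeping

`filter_cohort()` drops dual-mutant samples and keeps every RAS sample;
`match_braf_subsample()` draws a BRAF subset of size `n_RAS + 1`
(52 for 51) stratified to the RAS histology distribution by
largest-remainder apportionment, backfilling from the remaining pool with
a warning when a stratum is too small — the matching procedure is this
package's design choice; only a "general match" is required of it.

`split_patients()` assigns patients (never tiles) to train/validation/
test. Training receives `floor(0.6 N)`; the remainder splits as evenly as
possible with validation taking the odd extra; within those totals,
per-class counts are apportioned by controlled rounding so both classes
appear in every role. This remainder rule is chosen so that 103 patients
yield 61/21/21, which together with 200 patches per sample and 2
augmented variants reproduces the canonical patch ledger
24,400 / 4,200 / 4,200 and, at batch size 8 over 200 epochs,
610,000 iterations (`compute_training_plan()`; incomplete trailing
batches are dropped, which is what makes the iteration arithmetic exact).

## Tile extraction

Candidates are enumerated on a non-overlapping 512-px grid in scan order
(stride is a config knob; no overlap is the default because nothing in
the source protocol requires one). Per tile:

1. the usable-tissue fraction comes from the slide-level quality mask;
   tiles under 0.5 are skipped;
2. the hematoxylin density map is obtained by stain deconvolution and
   segmented (Otsu threshold with a 0.15 fallback on collapsed
   histograms, hole filling, distance-transform watershed, area gate
   40–3000 px);
3. the patch features — nucleus count, mean hematoxylin density over
   nuclei, mean/max major-minor axis ratio — feed an inclusive
   conjunction: count ≥ 20, density in [0.15, 1.2], mean ratio ≤ 4,
   tissue ≥ 0.5. Thresholds are inclusive so ties break
   deterministically; all of them are configuration because the original
   protocol's exact values are not public. "Dimension ratio" is read as
   the per-nucleus major/minor axis ratio.

Acceptance stops at 300 per slide, first-come in scan order (a seeded
random cap is available behind `cap_random`). For training, 200 patches
per sample are drawn without replacement, and each drawn patch
contributes 2 of the 8 dihedral variants (identity eligible, drawn
without replacement); validation and test tiles are never augmented, and
that invariant is asserted on every emitted manifest.

## Quality control

QC decisions are made on a coarse grid (default 1/32 of level 0) but
*detected* at a finer scale (default 1/4) where region boundaries are
thin and blur is measurable, then pooled. Tissue is saturation above an
Otsu-refined threshold (fixed fallback 0.08 when the histogram is
unimodal — a blank or uniformly stained thumbnail) inside a non-white
luminance band, hole-filled and speck-cleaned. Artifacts:

* **pen** — hue in ink windows, saturated, and poorly reconstructed by a
  nonnegative H&E mixture (marker ink is not a stain combination; stained
  tissue reconstructs to < 0.01 OD error, inks to > 0.09, threshold
  0.05);
* **blood** — red-channel dominance over both green and blue;
* **blur** — local Laplacian variance below a floor, within tissue;
* **bubble** — bright blobs enclosed by tissue (not border-connected
  glass), dilated and hull-filled to absorb the rim.

The usable mask is `tissue AND NOT any-artifact`, exactly, by
construction.

## Colour machinery

Optical density is `-log10((i+1)/256)` per 8-bit channel; deconvolution
inverts the standard published H&E vector matrix (overridable), clipping
negative densities. Normalization is Reinhard-style mean/variance
matching in CIELAB over tissue pixels only, chosen over iterative
stain-estimation methods for determinism; which normalization the source
protocol used is unknown, so the method and reference are configuration
(the reference defaults to the first training slide). The synthetic
generator renders through the same Beer–Lambert forward model, which is
what makes deconvolution exactly testable: `deconvolve(forward(d)) = d`
up to 8-bit quantization.

## The classifier

No deep-learning framework is part of this package's dependency
footprint; the network is implemented in-package with im2col
convolutions, inception-style parallel-branch blocks (1×1 / 1×1→3×3 /
1×1→5×5), max pooling, global average pooling and a 2-way softmax head,
trained with a hand-written Adam (lr 0.001, β 0.9/0.999) at batch size 8.
Per epoch the validation log-loss and accuracy are recorded; the final
model is the checkpoint with the lowest validation cross-entropy, first
epoch on ties, and the last-epoch weights are kept alongside.

Two scales share that vocabulary. `small` (default, ≈ 5k parameters)
pools the 512×512 input to 64×64 in a fixed stem and trains end-to-end on
one CPU in minutes; it is the tested surface. `full` operates at 256×256
with four inception blocks (≈ 10⁶ parameters); it is constructed and
runs forward in tests but is not trained there — the published training
scale (hundreds of thousands of iterations) is not a desk-scale target,
and a literal replica of the named published topology would add
parameters, not testable behaviour.

Inputs are scaled to [-1, 1] and then standardized per tile inside the
preprocessing step. The standardization matters: the near-constant eosin
background otherwise dominates every activation, and at the fixed
learning rate the small model needs far more than desk-scale iterations
to move — with whitening, a 40-tile separable set is fit to training
accuracy 1.0 within 30 epochs. Because the stem's block pooling commutes
with the dihedral group and with affine intensity maps, pipelines may
pool tiles once and augment the pooled copies with no numerical change.

Activation maps use occlusion saliency (the method behind the published
activation figures is unstated; occlusion is this package's choice): a
gray square is slid across the tile and the drop in the predicted-class
probability recorded, min-max normalized unless the total response is
negligible (range < 0.05), in which case the raw clipped drops are
returned so a flat map stays flat.

## Evaluation

Tile and tumor AUC use the mid-rank Mann–Whitney formulation (ties count
half) with a seeded 2000-replicate percentile bootstrap for the 95%
interval. Fisher's exact test (two-sided, on the called-tumor 2×2) and
Spearman correlation are delegated to `stats`; the test suite cross-checks
all of them against independent oracles — all-pairs concordance,
hypergeometric enumeration, the Σd² closed form — to 1e-9. The BRS
(BRAF–RAS score) is consumed as input in [-1, 1]; its sign defines
BRAF-like/RAS-like, records at exactly 0 are excluded from the
cross-tabulation and counted. The Spearman against BRS uses the
continuous percRAS score, not the discrete calls.

## The synthetic generator

Slides are rendered from hematoxylin/eosin density fields: polygonal
tissue regions with noisy eosin, elliptical soft-edged nuclei with
per-nucleus jittered geometry and staining, per-slide lognormal stain
jitter, and a near-white glass background; artifacts (green/blue pen,
blood blobs, Gaussian blur, bubbles with rims) are stamped with exact
masks. The pyramid is base plus a 4× level, 8-bit quantized so that the
write–read round trip is bit-exact. Everything is a pure function of
(spec, seed).

The two phenotype presets encode the class contrast: BRAF — 90 nuclei
per 512² patch, axis ratio 1.15, radius 7 px, clustered; RAS — 45,
1.9, 8 px, arranged on ring perimeters. These defaults were chosen once
as a caricature of classical versus follicular-variant morphology:
densities put both classes safely above the 20-nucleus acceptance floor,
and ring/cluster geometry keeps neighbouring nuclei separable by
watershed (~420 px² per nucleus in clusters, ~13 px spacing along
rings). A single separability knob interpolates the numeric parameters
toward their midpoint, weakens the spatial arrangement (30% of nuclei
are uniform even at full contrast, so no tile is starved by clustering),
and mixes the synthetic BRS between sign-consistent and
label-independent; at 0 the classes are statistically identical.

What the generator does *not* emulate: chromatin texture, nucleoli,
stromal architecture, scanner compression, out-of-focus gradients, or
the intra-tumoral heterogeneity of real PTC. Passing tests therefore
demonstrate that the machinery is correct and that the learning loop can
extract a morphologic signal it is pointed at — not that the pipeline
reaches any particular accuracy on real TCGA slides.

## Problem sizes and numerical choices

The test and acceptance suites run at sizes chosen as the package's own
desk-scale defaults: 1024–2048 px slides for I/O and QC, a 10240×8192 px
dense slide for the 300-cap check (a 20×16 tile grid, > 300 qualifying),
and a 20-patient separability-1.0 cohort on 1536 px slides (9 tiles
each, 12/4/4 patient split, 30 epochs) for the end-to-end learning
check. Degenerate inputs are defined rather than accidental: empty tissue
masks return a warning and the unchanged tile (normalization) or an empty
record set (extraction); Otsu collapse falls back to fixed thresholds;
zero-nucleus patches carry zero aggregates and fail the count rule first;
band edges and feature thresholds have the tie behaviour stated above.
Dual-mutant exclusion, split leakage and augmentation leakage are
asserted, not assumed.

## Known limitations

Real-SVS reading is out of scope (the TIFF reader covers the synthetic
and generic multi-page pyramidal case; magnification metadata travels in
a JSON sidecar because the TIFF writer used cannot set description
tags). The full-scale network is inception-style but not a literal
published topology. QC thresholds are calibrated on the synthetic suite,
not on scanner data. None of the headline numbers from any real cohort
are reproduced here; the package reproduces the *bookkeeping* exactly
and the *behaviour* on controlled synthetic data.
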