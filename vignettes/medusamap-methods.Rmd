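---
title: "Object-based detection of medusahead patches: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based detection of medusahead patches: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Medusahead (*Elymus caput-medusae*) is an invasive annual grass that stays
green after the dominant annual grasses of Californian rangelands have
senesced. At a late-spring acquisition date this phenological contrast makes
it detectable in very-high-resolution (0.15 m) visible/near-infrared aerial
imagery — but several co-occurring species are also still green, some
spectrally close to medusahead (barbed goatgrass), some distinguished only
by their local spatial pattern (canarygrass tufts, heterogeneous
vetch/clover/ryegrass mosaics), and medusahead itself occurs at low density
in the understorey of taller senescent grasses. `medusamap` implements an
object-based image analysis (OBIA) workflow for this setting: the image is
first segmented into spectrally homogeneous objects, the objects carry
spectral and texture attributes, and unsupervised, single-run supervised and
knowledge-based hierarchical classifiers compete on the same object base.
Because the imagery and field data of the motivating field campaign are not
publicly deposited, the package ships a seeded synthetic-scene generator
that emulates the site's class structure, and every pipeline stage is
validated end-to-end against that generator's ground truth.

## The synthetic scene generator

`generate_scene()` draws elliptical patches per vegetation class over a
senescent-grass matrix. The defaults are the package's fixed study
conditions:

* **Patch sizes.** Patch diameters are drawn log-uniformly within four
  length categories (≤0.5, 0.5–2, 2–7, >7 m). For the invaders the smallest
  category carries three times the weight of either middle category,
  reproducing the right-skewed field patch-size distribution; community
  classes (clover-brome, canarygrass, vetch, wild oat) weight the larger
  categories.
* **Cover fractions.** Each patch contributes a soft-edged cover fraction
  (edge ramp ≈ one pixel); per pixel, green fractions are normalized to
  share the unit and the matrix takes the remainder, so fractions sum to 1
  everywhere (tolerance 1e-9). The dominant label is the per-pixel argmax.
* **Reflectance.** Bands are unitless reflectance in [0, 1]; sensor
  calibration is not modelled. Per-class means are free parameters (the
  field study reports no per-class statistics); the defaults put medusahead
  at NIR 0.55 over a 0.30 matrix, goatgrass deliberately close to
  medusahead, clover-brome at intermediate greenness, and vetch brightest.
* **Texture archetypes.** `uniform` classes carry only noise; `clumped`
  renders green clumps over matrix-coloured gaps at ~0.45 m;
  `fine_mosaic` is a correlated bright/dark mosaic; `speckle` is
  pixel-scale iid variation with a flat marginal. Canarygrass (green-band
  speckle) and vetch (NIR-band speckle) are the texture-distinct
  confusers. Class noise itself is spatially correlated (a smoothed field
  plus a small iid sensor component), and a scene-wide multiplicative
  brightness field (sd 12%, few-metre correlation) emulates biomass and
  illumination variation. Both choices matter for texture features: with
  per-object min–max quantization (below), a large object of *pure iid*
  noise would be maximally entropic, which real senescent canopy is not.
* **Understorey mixing.** A configurable fraction of clover-brome,
  ryegrass and wild-oat patches carries sub-dominant medusahead cover
  (default 5–35%); under wild oat the medusahead contribution is pulled
  toward the matrix colour (subcanopy attenuation 0.6), emulating plants
  that "do not appear green enough" below a senesced canopy.

The simulated field survey places 20 transects (five groups of three, one
group of four, one single transect) with ten 0.5 m plots at 10 m intervals,
reads plot cover from the truth, and extracts medusahead patch segments
along each transect, merging runs separated by ≤ 20 cm (the field
convention). Recorded positions carry uniform-in-disk GPS jitter of radius
≤ 0.3 m. Reference "location samples" beyond the plots are drawn stratified
by window-dominant class; the mixed-plot stratum (medusahead acceptable but
sub-dominant) is restricted to vegetated host classes because a mixed field
plot is medusahead inside other vegetation, not the soft edge of its own
patch. `designate_sample_sets()` then reproduces the sample design: 50
training samples each of medusahead, clover-brome, ryegrass-brome and
vetch, 40 of wild oat and 30 each of goatgrass and canarygrass (300 total),
plus a 150-sample test set stratified 50/50/50 into medusahead-best,
non-medusahead, and non-medusahead-with-medusahead-acceptable.

What the generator does **not** emulate: radiative transfer, topography and
illumination geometry, phenological time series, and the full continuum of
real mixed-species textures. Passing the validation suite therefore shows
that the pipeline recovers a *known* class structure under controlled noise,
mixing and geolocation error — not that any particular accuracy level will
transfer to real imagery.

## Derived layers

NDVI is `(nir − red)/(nir + red)`, undefined where the denominator is zero.
Local Moran's I uses a 3×3 window with binary weights over the 8
neighbours, global mean and population variance (`I_i = (x_i − x̄)/s² ·
Σ_j (x_j − x̄)`); edge pixels use their available neighbours. A
row-standardized variant is available behind a flag. One consequence of the
8-neighbour convention worth knowing: on an exact two-value checkerboard the
four rook neighbours and four diagonal neighbours cancel and interior I is
0, not negative; anti-correlation appears for patterns (stripes, isolated
bright pixels) where opposite-valued neighbours dominate. Which layer
Moran's I feeds on is configurable; the default is NDVI.

Multi-level Otsu thresholding (1 or 2 thresholds) maximizes between-class
variance over a 256-bin histogram of the observed range, evaluated
exhaustively via cumulative moments; ties break toward the smallest
threshold tuple. The three greenness tiers of the hierarchical workflow use
one two-threshold run per association group, not two sequential binary
runs, so the optimum is a single well-defined quantity.

## Segmentation

`multiresolution_segment()` implements bottom-up region merging under the
published fusion criterion: merge cost
`f = (1 − w_shape)·Δh_colour + w_shape·Δh_shape`, where the colour term is
the layer-weighted increase in size-weighted standard deviation and the
shape term blends compactness (`perimeter/√n`) and smoothness
(`perimeter / bounding-box perimeter`) deviations; a merge executes only if
`f < scale²`, and only for mutually best-fitting pairs, scanned in
ascending object id with the smaller id surviving — runs are deterministic
without a seed. Objects are 4-connected; masked pixels (trees, wetland)
belong to no object. Exact object-for-object agreement with any commercial
segmenter is not a goal; the scale semantics follow the published
formulation.

Two numerical choices deserve emphasis:

* **Layer standardization.** Layers are z-scored over unmasked pixels
  before the cost computation (`standardize = TRUE`). With raw equal
  weights the local Moran's I layer — unbounded, with within-scene
  standard deviation two orders of magnitude above the reflectance bands
  wherever texture exists — silently dominates the colour term and stalls
  merging inside every textured region. With standardization the scale
  parameter is expressed in within-scene standard-deviation units uniformly
  across layers. The per-layer weights remain 1 and remain configurable.
* **Scale values.** The motivating workflow used scales 10/176/390 on
  8-bit digital-number imagery. Those magnitudes do not transfer to
  standardized reflectance units; the package's defaults — 5 (primitive
  objects), 16 (vegetation communities), 28 (landscape units) — were
  calibrated once on the packaged fixture scene (`scene_config(seed = 42)`)
  and then frozen. The local-variance scan (`esp_scan()`), which segments
  at each candidate scale and tracks the mean within-object standard
  deviation and its percent rate of change, is run on that fixture by
  `analysis/02_segment_features.R`; its flagged scales support the
  primitive-scale choice.

`segment_hierarchy()` builds the nested levels bottom-up: the finest scale
is segmented from pixels and each coarser level continues merging from the
finer labels. Nesting (fine boundaries never crossing coarse boundaries,
total single-parent maps) therefore holds by construction.

## Object attributes and feature sets

Per object: means of all input layers, standard deviations of the blue and
green bands, all-direction GLCM entropy of the NIR and green bands, area
and perimeter. GLCM entropy quantizes the object's values to 64 grey
levels (min–max over the object), accumulates a symmetric co-occurrence
matrix over the four distance-1 offsets restricted to within-object pairs
(pairs straddling the boundary are discarded so texture never leaks
neighbouring objects), and returns `−Σ p ln p`. Min–max quantization makes
the statistic invariant to affine rescaling of the layer — texture is
pattern, not amplitude — but it also ties the entropy estimate to object
size: more pixel pairs occupy more co-occurrence cells. The hierarchical
thresholds below were calibrated with this behaviour in view.

The `spectral` feature set is the object means of the four camera bands
plus NDVI. Moran's I remains a segmentation layer only: it is itself a
texture statistic, and keeping it out of `spectral` keeps the
spectral-vs-texture contrast interpretable. `spectral_texture` adds
sd(blue), sd(green) and the two GLCM entropies.

Training objects are the primitive objects containing the (GPS-jittered)
training sample locations; same-class duplicates collapse, conflicting
labels exclude the object with a warning rather than a majority vote. An
optional truth-verified curation step (`attach_training(..., truth = )`)
emulates the analyst's sample-editor inspection by dropping labelled
objects whose dominant true class contradicts the sample — in the
benchmark conditions this removes the handful of matrix objects that 0.3 m
jitter mislabels, which otherwise poison the 1-NN classifier in
particular. The default experiment keeps curation off (realistic survey
conditions).

## Classifiers

* **k-means** (stats::kmeans, 10 seeded restarts) on globally standardized
  features; the cluster-count scan records total within-cluster variance
  for k = 10…30 and flags curvature peaks of the decline. Clusters
  containing at least θ = 5% of the medusahead training samples are
  labelled medusahead — an explicit numeric stand-in for the original
  visual cluster selection, and intentionally permissive (overprediction
  is the documented behaviour of the unsupervised route).
* **KNN** (class::knn, k = 1 by default, configurable).
* **Bayes**: Gaussian class-conditionals with diagonal covariance and
  *equal* priors, implemented directly — the training quotas are
  design-balanced, not prevalence estimates, so frequency priors would be
  wrong; e1071::naiveBayes serves as an independent cross-check in the
  tests on balanced fixtures.
* **Linear SVM** (e1071::svm, cost 1, one-vs-one), on features
  standardized by the training statistics (the original workflow does not
  state whether it standardized; standardization is adopted and recorded).

Both class schemes are supported: the detailed seven-class vocabulary and
the three-class collapse (medusahead / other green / other non-green; wild
oat and the matrix count as non-green).

## The hierarchical workflow

`run_hierarchy()` composes five steps over the nested levels, recording for
every primitive object the step that fixed its label:

1. **Coarse exclusion** — landscape units with mean NDVI below 0.2 *and*
   farther than 20 m from any medusahead training sample (nearest-pixel
   distance, so a unit containing a sample is never excluded).
2. **Mosaic isolation** — coarse objects with NIR GLCM entropy ≥ 7.4 are
   the bright heterogeneous vetch/clover/ryegrass mosaic, removed from all
   later medusahead candidacy (the field mosaic carried no medusahead).
3. **Associations** — mid-level objects with green GLCM entropy ≥ 7.2 are
   the canarygrass association; objects inside the optional storksbill
   mask are labelled verbatim (the manually delineated areas are taken as
   input); the rest split into medusahead-with-wild-oat vs
   medusahead-with-clover-brome by the configured supervised algorithm on
   band means plus blue/green standard deviations.
4. **Greenness tiers** — two-threshold Otsu on primitive-object NDVI means
   per association; the least green tier is non-medusahead, mid and high
   tiers proceed (degenerate associations pass through flagged).
5. **Final split** — supervised classification into medusahead, barbed
   goatgrass and other, on exactly mean(red), mean(NDVI) and GLCM
   entropy(NIR); without goatgrass training the step degrades to a binary
   split with a warning.

All thresholds are explicit configuration calibrated once on the packaged
fixture scenes and then frozen. The entropy thresholds deserve a caveat:
because sample entropy grows with object size, the isolation rules separate
the mosaic cleanly when the mosaic forms large coarse objects (the
spillover benchmark scene is constructed that way, and the validation
suite's containment check exercises exactly that regime); on scenes where
the mosaic fragments, isolation is partial, which mirrors the original
workflow's sensitivity to its manual thresholds. Step-2/3 unit fixtures therefore exercise the rules on
constructed objects, while the scene-level guarantee that is asserted
everywhere is structural: excluded and isolated regions are absent from
the medusahead extent of every hierarchical run.

## Accuracy assessment

`evaluate_fuzzy()` converts test samples to 1 m × 1 m squares centred on
the recorded points. A sample counts as "classified medusahead" if the
class at its centre pixel is medusahead (the square-straddling decision
rule is not stated in the original protocol; the centre-pixel rule is
adopted and configurable), while producer's accuracy uses
any-pixel-in-square support, matching the protocol's asymmetric phrasing.
MAX is the proportion of classified-medusahead samples with medusahead
best; RIGHT additionally accepts samples listing medusahead as acceptable
(≥ 5% cover); their difference measures the gain from fuzzy class
membership; producer's accuracy is the proportion of medusahead-best
squares containing any classified medusahead. With zero
classified-medusahead samples, MAX and RIGHT are NA (0/0), never 0 — the
audit trail must distinguish absence from failure. RIGHT ≥ MAX is asserted
on every evaluation. `evaluate_combined()` merges medusahead and barbed
goatgrass in predictions and reference alike, quantifying how much of the
error is mutual confusion of the two invaders.

## Transect validation

Classified extents are sampled along each transect at half-pixel steps
(Nyquist for 0.15 m pixels); maximal medusahead runs merge across gaps
≤ 20 cm for comparability with the field convention. Two views are
computed per method: intersection with the field patch segments
(under-prediction) and with the full transect lines (over-prediction),
each summarized as counts and mean lengths in the four categories with
closed upper bounds (0.5, 2 and 7 m fall in the lower category, matching
the printed "≤0.5 m" label). On noisy classifications the pipeline
reproduces the documented signature: the smallest classified pieces are on
average longer than the smallest field patches (the tiniest patches are
missed outright) while the largest patches fragment and are under-counted.

## Problem sizes and reproducibility

The default scene is 120 m × 120 m (800 × 800 pixels, matching the
transect layout); the validation suite uses ten such scenes for detection
recovery, three for the texture contrast, one 512 × 512 scene for the
segmentation invariants and small constructed fixtures elsewhere — sizes
chosen as the package's own balance between statistical stability of the
reported means and a test suite that a maintainer will actually run.
Every stochastic stage derives a child seed from one master seed via a
fixed affine hash, so each method's result is reproducible independently
of roster order, and fixed (config, seed) pairs reproduce scenes
bit-identically.

## Known limitations

* The segmenter is a faithful implementation of the published fusion
  criterion, not a replica of any proprietary tool; object boundaries will
  differ from commercial output on the same data.
* GLCM entropy under per-object min–max quantization confounds texture
  with object size; rules built on it are calibrated to a segmentation
  scale and do not transfer across scales unchanged.
* The generator's classes are internally homogeneous by construction;
  real vegetation grades continuously, so real MAX/RIGHT values sit well
  below the clean-benchmark figures (the default, mixed-cover scene
  produces the realistic regime: MAX rarely above ~0.7, RIGHT 0.7–1.0,
  strong unsupervised overprediction).
* Single date only; the phenological-contrast assumption is an input, not
  something the package can verify.
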