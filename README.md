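# medusamap

Object-based detection of invasive **medusahead** (*Elymus caput-medusae*)
patches in mixed-cover grasslands from very-high-resolution (0.15 m)
visible/near-infrared imagery.

Medusahead stays green after the dominant annual grasses of Californian
rangelands senesce, which makes it detectable in late-spring VNIR imagery —
except that several co-occurring species are also still green: barbed
goatgrass is spectrally almost identical, canarygrass and the
vetch/clover/ryegrass mosaics differ only in their local spatial pattern,
and medusahead itself hides at low density under taller senescent grasses.
`medusamap` implements the full object-based image analysis (OBIA) workflow
for this setting and validates it end-to-end on seeded synthetic scenes
with known ground truth:

* **Synthetic scenes + field survey** — a generator for 4-band grassland
  scenes (senescent matrix, seven vegetation classes with per-class
  texture archetypes, sub-canopy medusahead mixing, per-pixel cover
  fractions summing to 1) and a simulated survey: 20 transects with
  0.5 m plots, medusahead patch segments under the 20 cm separation rule,
  GPS jitter ≤ 0.3 m, and the 300-training / 150-test reference-sample
  design.
* **Derived layers** — NDVI, local Moran's I (3×3 window, 8-neighbour
  binary weights), multi-level Otsu thresholding (exhaustive optimum).
* **Segmentation** — multiresolution region merging (colour + shape
  heterogeneity, merge admissible iff `f < scale²`, mutual best fitting;
  Rcpp core), a local-variance scale scan, and nested multi-scale levels
  with parent maps.
* **Object features** — per-object band means, sd(blue/green), and
  all-direction GLCM entropy (64-level per-object min–max quantization,
  boundary pairs discarded).
* **Classifiers** — unsupervised k-means with a cluster-count scan and
  training-overlap labelling; single-run KNN, diagonal-Gaussian Bayes
  (equal priors) and linear SVM under three-class and seven-class schemes
  with spectral or spectral+texture features; and a five-step
  knowledge-based hierarchical workflow (coarse NDVI/distance exclusion,
  NIR-entropy mosaic isolation, association classing, per-association
  Otsu greenness tiers, final invasive split) with full label provenance.
* **Validation** — fuzzy thematic accuracy on 1 m reference squares (MAX,
  RIGHT, RIGHT−MAX, producer's accuracy; combined medusahead+goatgrass
  reporting) and patch-length validation against field transect segments
  in four length categories (≤0.5, 0.5–2, 2–7, >7 m).

The core metrics, for a classification `C` and test samples `s`:

* `MAX  = #{s : C(s) = medusahead ∧ best(s) = medusahead} / #{s : C(s) = medusahead}`
* `RIGHT = #{s : C(s) = medusahead ∧ medusahead ∈ {best(s)} ∪ acceptable(s)} / #{s : C(s) = medusahead}`
* `producer = #{s : best(s) = medusahead ∧ square(s) contains classified medusahead} / #{s : best(s) = medusahead}`

with `acceptable(s)` the classes at ≥ 5% cover in the 0.5 m field plot.

## Worked example

The `analysis/` scripts run the full study pipeline; the core of it fits in
a few lines:

```r
library(medusamap)

scene <- generate_scene(scene_config(seed = 42))     # 120 m x 120 m
survey <- simulate_field_survey(scene$truth, seed = 2)
samples <- sample_reference_points(scene$truth, seed = 1)
sets <- designate_sample_sets(samples, seed = 3)     # 300 training / 150 test

levels <- segment_hierarchy(scene$stack, scales = c(28, 16, 5))
tab <- build_object_table(levels$scale_5, scene$stack)
training <- attach_training(tab, levels$scale_5, scene$stack, sets$training)

res <- train_predict(tab, training, "bayes", class_scheme("seven_class"),
                     feature_set("spectral_texture"), levels$scale_5,
                     scene$stack)
evaluate_fuzzy(res, sets$test)
#> <fuzzy_accuracy_report> supervised_bayes: MAX 0.81  RIGHT 0.97  diff 0.16  producer 0.70 ...
```

or, for the whole 19-method comparison grid (`Rscript
analysis/03_classify_all_methods.R`):

```
                                method         features  max right diff producer
                      unsupervised_k12         spectral 0.49  0.83 0.34     1.00
                  unsupervised_k12_tex spectral_texture 0.59  0.89 0.30     1.00
          supervised_bayes_three_class         spectral 0.56  0.89 0.33     0.96
          supervised_bayes_seven_class         spectral 0.71  0.93 0.21     0.40
 supervised_svm_linear_seven_class_tex spectral_texture 0.87  0.97 0.10     0.92
      supervised_bayes_seven_class_tex spectral_texture 0.81  0.97 0.16     0.70
        hierarchical_knn_hierarchy_tex spectral_texture 0.75  0.94 0.19     0.74
      hierarchical_bayes_hierarchy_tex spectral_texture 0.76  0.97 0.22     0.72
 ...
```

Read: the unsupervised routes find essentially every medusahead sample
(producer 1.0) by flooding the scene with predictions (MAX ~0.5 —
half the predicted samples are not medusahead-dominated), supervised
methods trade omission against commission, RIGHT exceeds MAX everywhere
(many "wrong" detections still sit on plots where medusahead is present
sub-dominantly), and the hierarchical runs contain the spillover into the
heterogeneous mosaic at a small cost in producer's accuracy.
`analysis/04_transect_match.R` adds the patch-structure view: nearly every
method under-detects the >7 m patches along the transects while the
smallest classified pieces are longer on average than the smallest field
patches.

The `analysis/` scripts in order: `01_simulate_scene.R` (scene, survey,
sample designation), `02_segment_features.R` (scale scan, nested
segmentation, object tables), `03_classify_all_methods.R` (the 19-method
grid plus combined-class accuracies), `04_transect_match.R` (length-category
validation), `05_benchmarks.R` (controlled detection-recovery,
texture-necessity and spillover-containment conditions). All artifacts are
plain text (CSV/GeoJSON/JSON/YAML) plus float TIFF rasters under
`results/`.

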