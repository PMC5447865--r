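#!/usr/bin/env Rscript
# Simulate the study scene and field survey.
#
# Generates the default 120 m x 120 m synthetic grassland (senescent
# matrix, medusahead and co-occurring green/confuser classes), runs the
# 20-transect plot survey with GPS jitter, draws the supplementary
# reference location samples and designates the 300-training/150-test
# sample sets.  Artifacts go to results/scene/.

suppressMessages(library(medusamap))

seed <- 42L
out <- "results/scene"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- scene_config(seed = seed)
write_scene_config(cfg, file.path(out, "scene_config.yaml"))
scene <- generate_scene(cfg)
cat("scene:", paste(dim(scene$stack), collapse = " x "), "px;",
    nrow(scene$truth$patches), "patches\n")

write_band_stack(scene$stack, file.path(out, "scene.tif"))
write_truth_polygons(scene$truth, file.path(out, "truth_patches.geojson"))

survey <- simulate_field_survey(scene$truth, seed = child_seed(seed, 2))
cat("survey:", nrow(survey$transects), "transects,",
    nrow(survey$plots), "plots,", nrow(survey$segments),
    "field patch segments\n")
write_survey_geojson(survey, file.path(out, "survey.geojson"))
write.csv(survey$segments, file.path(out, "field_segments.csv"),
          row.names = FALSE)

samples <- sample_reference_points(scene$truth,
                                   seed = child_seed(seed, 1))
sets <- designate_sample_sets(samples, seed = child_seed(seed, 3))
cat("samples:", nrow(sets$training), "training /", nrow(sets$test),
    "test (strata:",
    paste(table(sets$test$stratum), collapse = "/"), ")\n")
write_samples_geojson(rbind(sets$training,
                            sets$test[, names(sets$training)]),
                      file.path(out, "reference_samples.geojson"))
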