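# Knowledge-based hierarchical workflow: exclusion, mosaic isolation,
# associations, greenness tiers and the final invasive split.

test_that("coarse exclusion needs both low NDVI and distance", {
  st <- toy_stack(20, 20, noise = 0.001, seed = 2)
  level <- trivial_level(20, 20)
  level$labels <- matrix(rep(1:2, each = 200), 20, 20)
  level$n_objects <- 2L
  tab <- data.frame(object_id = 1:2, mean_ndvi = c(0.6, 0.05))
  cfg <- hierarchy_config(ndvi_exclusion_threshold = 0.2,
                          distance_exclusion_m = 1)
  # one training sample inside object 1 (left half)
  far_samples <- make_samples(x = 0.5, y = 1.5, best = "medusahead")
  excl <- coarse_exclude(tab, level, st, far_samples, cfg)
  expect_false(excl[1])     # green: candidate regardless of distance
  expect_true(excl[2])      # low NDVI and > 1 m from the sample
  # a sample inside the low-NDVI object keeps it a candidate
  near <- make_samples(x = 2.5, y = 1.5, best = "medusahead")
  excl2 <- coarse_exclude(tab, level, st, near, cfg)
  expect_false(excl2[2])
  # no samples: distance criterion disabled with a warning
  expect_warning(excl3 <- coarse_exclude(tab, level, st,
                                         far_samples[0, ], cfg),
                 "disabled")
  expect_false(any(excl3))
})

test_that("the NIR-entropy rule isolates the heterogeneous mosaic", {
  set.seed(3)
  # constructed objects: flat-speckle NIR (vetch mosaic) vs smooth NIR
  speckled <- matrix(runif(900, 0.3, 0.9), 30, 30)
  smooth <- matrix(0.5, 30, 30) + 0.02 * row(matrix(0, 30, 30)) / 30
  e_hi <- glcm_entropy_region(speckled, matrix(TRUE, 30, 30))
  e_lo <- glcm_entropy_region(smooth, matrix(TRUE, 30, 30))
  expect_gt(e_hi, e_lo)
  tab <- data.frame(object_id = 1:2, glcm_entropy_nir = c(e_hi, e_lo))
  thr <- (e_hi + e_lo) / 2
  cfg <- hierarchy_config(entropy_nir_threshold = thr)
  expect_equal(isolate_vetch_mosaic(tab, cfg), c(TRUE, FALSE))
  cfg_inf <- hierarchy_config(entropy_nir_threshold = Inf)
  expect_false(any(isolate_vetch_mosaic(tab, cfg_inf)))
})

test_that("association classing: entropy rule, mask precedence, split", {
  set.seed(7)
  ncol_f <- c("mean_red", "mean_green", "mean_blue", "mean_nir",
              "sd_blue", "sd_green")
  mk_row <- function(id, ent_green, nir, sds = 0.02) {
    out <- data.frame(object_id = id, glcm_entropy_green = ent_green,
                      mean_red = 0.12, mean_green = 0.17, mean_blue = 0.06,
                      mean_nir = nir, sd_blue = sds, sd_green = sds)
    out
  }
  tab <- rbind(mk_row(1, 7.9, 0.5),          # clumped-texture canarygrass
               mk_row(2, 3.0, 0.5),          # storksbill-masked object
               mk_row(3, 3.0, 0.52),         # bright green, low texture
               mk_row(4, 3.0, 0.33))
  training <- rbind(mk_row(10, 3, 0.50), mk_row(11, 3, 0.33))
  training$assigned_class <- c("medusahead", "wild_oat")
  cfg <- hierarchy_config(entropy_green_threshold = 7.2,
                          supervised_algorithm = "knn")
  out <- classify_associations(tab, training, cfg, storksbill_ids = 2L)
  expect_equal(out[1], "canarygrass_assoc")
  expect_equal(out[2], "storksbill")        # mask beats features
  expect_equal(out[3], "mh_clover_brome_assoc")
  expect_equal(out[4], "mh_wild_oat_assoc")
  expect_message(
    classify_associations(tab[3:4, ], training, cfg),
    "storksbill mask")
})

test_that("greenness tiers split at the exhaustive Otsu thresholds", {
  ndvi <- c(rep(0.1, 20), rep(0.45, 20), rep(0.8, 20)) +
    rep(seq(-0.01, 0.01, length.out = 20), 3)
  tiers <- greenness_tiers(ndvi)
  expect_false(tiers$degenerate)
  expect_true(tiers$thresholds[1] > 0.11 && tiers$thresholds[1] < 0.44)
  expect_true(tiers$thresholds[2] > 0.46 && tiers$thresholds[2] < 0.79)
  expect_equal(tiers$thresholds, naive_otsu(ndvi, 3L, 256L),
               tolerance = 1e-10)
  expect_equal(unique(tiers$tier[1:20]), 1L)
  expect_equal(unique(tiers$tier[41:60]), 3L)
  # degenerate association passes through flagged
  flat <- greenness_tiers(rep(0.5, 10))
  expect_true(flat$degenerate)
  expect_equal(flat$tier, rep(2L, 10))
})

test_that("the final invasive split behaves across fixture regimes", {
  set.seed(11)
  feats <- c("mean_red", "mean_ndvi", "glcm_entropy_nir")
  mk <- function(n, red, ndvi, ent, cls) {
    out <- data.frame(object_id = seq_len(n),
                      mean_red = rnorm(n, red, 0.01),
                      mean_ndvi = rnorm(n, ndvi, 0.02),
                      glcm_entropy_nir = rnorm(n, ent, 0.1))
    out$assigned_class <- cls
    out
  }
  cfg <- hierarchy_config(supervised_algorithm = "bayes")
  # distinct invasives: both recovered at >= 0.85 recall
  tr <- rbind(mk(30, 0.10, 0.70, 2, "medusahead"),
              mk(30, 0.16, 0.55, 4, "barbed_goatgrass"),
              mk(30, 0.28, 0.10, 3, "wild_oat"))
  tr$object_id <- seq_len(nrow(tr))
  pred <- final_invasive_split(tr, tr, cfg)
  expect_gte(mean(pred[1:30] == "medusahead"), 0.85)
  expect_gte(mean(pred[31:60] == "barbed_goatgrass"), 0.85)
  # indistinguishable invasives: near-chance split between the two
  tr2 <- rbind(mk(100, 0.10, 0.70, 2, "medusahead"),
               mk(100, 0.10, 0.70, 2, "barbed_goatgrass"))
  tr2$object_id <- seq_len(nrow(tr2))
  pred2 <- final_invasive_split(tr2, tr2, cfg)
  acc <- (mean(pred2[1:100] == "medusahead") +
            mean(pred2[101:200] == "barbed_goatgrass")) / 2
  expect_lt(abs(acc - 0.5), 0.25)
  # goatgrass-free training falls back to binary with a warning
  tr3 <- rbind(mk(20, 0.10, 0.70, 2, "medusahead"),
               mk(20, 0.28, 0.10, 3, "wild_oat"))
  tr3$object_id <- seq_len(nrow(tr3))
  expect_warning(pred3 <- final_invasive_split(tr3, tr3, cfg),
                 "goatgrass")
  expect_true(all(pred3 %in% c("medusahead", "other_nonmedusahead")))
})

test_that("the full hierarchy labels every object with one provenance step", {
  cfg <- spillover_benchmark_config(5, extent_m = c(60, 60))
  cfg$patch_model$n_patches <- cfg$patch_model$n_patches * 4  # keep density
  sc <- generate_scene(cfg)
  samples <- sample_reference_points(sc$truth, n_mixed_target = 0,
                                     seed = 6)
  sets <- designate_sample_sets(
    samples, counts = c(medusahead = 30, clover_brome = 30,
                        ryegrass_brome = 20, vetch = 30, wild_oat = 25,
                        barbed_goatgrass = 20, canarygrass = 20),
    test_strata = c(10, 10, 0), seed = 7)
  levels <- segment_hierarchy(sc$stack, scales = c(28, 16, 5))
  tabs <- lapply(levels, build_object_table, stack = sc$stack)
  res <- suppressMessages(suppressWarnings(
    run_hierarchy(levels, tabs, sc$stack, sets$training,
                  hierarchy_config())))
  prov <- res$provenance
  expect_equal(nrow(prov), levels[[3]]$n_objects)
  expect_false(any(is.na(prov$step)))
  expect_false(any(is.na(prov$class)))
  expect_false(anyDuplicated(prov$object_id) > 0)
  # excluded and isolated coarse regions never contain medusahead
  coarse <- levels[[1]]
  iso <- coarse$labels %in% c(res$coarse_excluded, res$coarse_vetch)
  expect_equal(sum(target_mask(res) & iso), 0L)
  # the storksbill mask is honoured verbatim
  mask <- matrix(FALSE, nrow(coarse$labels), ncol(coarse$labels))
  mask[1:40, 1:40] <- TRUE
  res2 <- suppressMessages(suppressWarnings(
    run_hierarchy(levels, tabs, sc$stack, sets$training,
                  hierarchy_config(), storksbill_mask = mask)))
  expect_equal(sum(target_mask(res2) & mask), 0L)
})

test_that("an invader-free scene yields no medusahead", {
  pm <- default_patch_model()
  pm$n_patches <- ifelse(pm$class %in% c("clover_brome", "wild_oat",
                                         "vetch"), 80, 0)
  pm$subcover_frac <- 0
  cfg <- scene_config(extent_m = c(36, 36), patch_model = pm, seed = 9)
  sc <- generate_scene(cfg)
  levels <- segment_hierarchy(sc$stack, scales = c(28, 16, 5))
  tabs <- lapply(levels, build_object_table, stack = sc$stack)
  # training samples exist only off-scene classes; degenerate: no
  # medusahead training at all -> final split cannot run; the workflow
  # must fail loudly rather than invent detections
  samples <- sample_reference_points(
    sc$truth, n_per_class = c(senescent_matrix = 30, clover_brome = 30,
                              wild_oat = 20), n_mixed_target = 0,
    seed = 10)
  samples$role <- "training"
  expect_error(suppressMessages(suppressWarnings(
    run_hierarchy(levels, tabs, sc$stack, samples, hierarchy_config()))),
    "medusahead")
})
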