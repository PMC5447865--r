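# Synthetic scene generation and the simulated field survey.

small_cfg <- function(seed = 1, extent = c(30, 30)) {
  scene_config(extent_m = extent, seed = seed)
}

test_that("cover fractions sum to one and dominant label is their argmax", {
  sc <- generate_scene(small_cfg(3), render_bands = FALSE)
  tot <- Reduce(`+`, sc$truth$cover)
  expect_lt(max(abs(tot - 1)), 1e-9)
  cm <- vapply(sc$truth$cover, as.vector,
               numeric(length(sc$truth$dominant)))
  expect_equal(as.vector(sc$truth$dominant),
               max.col(cm, ties.method = "first"))
})

test_that("scene generation is bit-identical for a fixed (config, seed)", {
  a <- generate_scene(small_cfg(9))
  b <- generate_scene(small_cfg(9))
  expect_identical(a$stack$bands, b$stack$bands)
  expect_identical(a$truth$cover, b$truth$cover)
  c <- generate_scene(small_cfg(10))
  expect_false(identical(a$stack$bands$nir, c$stack$bands$nir))
})

test_that("a scene with no patches is pure senescent matrix", {
  pm <- default_patch_model()
  pm$n_patches <- 0
  sc <- generate_scene(scene_config(extent_m = c(10, 10),
                                    patch_model = pm, seed = 1),
                       render_bands = FALSE)
  expect_true(all(sc$truth$dominant == 1L))
  expect_true(all(sc$truth$cover$senescent_matrix == 1))
})

test_that("patch pixels carry the configured palette mean", {
  # medusahead mean NIR 0.55 over a 0.25-0.30 NIR matrix, noise sd 0.02:
  # the sample mean over interior patch pixels stays within 3 sd/sqrt(n)
  pal <- default_palette()
  pm <- default_patch_model()
  pm$n_patches <- ifelse(pm$class == "medusahead", 60, 0)
  pm$cover_min <- 1; pm$cover_max <- 1
  pm[pm$class == "medusahead", c("w1", "w2", "w3", "w4")] <- c(0, 0, 1, 0)
  sc <- generate_scene(scene_config(extent_m = c(40, 40),
                                    class_palette = pal, patch_model = pm,
                                    seed = 5))
  interior <- sc$truth$cover$medusahead == 1
  expect_gt(sum(interior), 500)
  n <- sum(interior)
  samp_mean <- mean(sc$stack$bands$nir[interior])
  # brightness modulation adds scene-scale variance beyond the pixel noise
  expect_lt(abs(samp_mean - 0.55), 3 * sqrt(0.02^2 + (0.12 * 0.55)^2))
})

test_that("a palette missing a configured class is a configuration error", {
  pal <- default_palette()
  pal <- pal[pal$class != "vetch", ]
  expect_error(scene_config(class_palette = pal), "vetch")
})

test_that("field patch segments obey the 20 cm separation rule", {
  # two medusahead runs on one horizontal transect, constructed exactly:
  # 5 cm pixels so a 25 cm gap (5 px) and a 15 cm gap (3 px) are on-grid
  px <- 0.05
  nr <- 20; nc <- 200
  mh <- matrix(0, nr, nc)
  mh[, 21:60] <- 1            # run 1: 1.0-3.0 m
  mh[, 66:100] <- 1           # gap 0.25 m, run 2
  truth <- scene_truth(list(senescent_matrix = 1 - mh, medusahead = mh),
                       pixel_size_m = px)
  tidx <- match("medusahead", truth$classes)
  y <- nr / 2 * px
  seg <- medusamap:::runs_along_line(truth$dominant, truth$classes, px,
                                     x0 = 0.5, y0 = y, ux = 1, uy = 0,
                                     length_m = 8, target = tidx)
  expect_equal(nrow(seg), 2L)

  mh2 <- matrix(0, nr, nc)
  mh2[, 21:60] <- 1
  mh2[, 64:100] <- 1          # gap 0.15 m -> merged
  truth2 <- scene_truth(list(senescent_matrix = 1 - mh2,
                             medusahead = mh2), pixel_size_m = px)
  seg2 <- medusamap:::runs_along_line(truth2$dominant, truth2$classes, px,
                                      x0 = 0.5, y0 = y, ux = 1, uy = 0,
                                      length_m = 8, target = tidx)
  expect_equal(nrow(seg2), 1L)
})

test_that("the default survey layout yields 20 transects and 200 plots", {
  sc <- generate_scene(scene_config(seed = 4), render_bands = FALSE)
  sv <- simulate_field_survey(sc$truth, seed = 2)
  expect_equal(nrow(sv$transects), 20L)
  expect_equal(nrow(sv$plots), 200L)
  expect_equal(unname(table(sv$plots$transect_id))[1], 10L)
  # 10 m plot spacing along each transect
  d <- sv$plots$distance_m[sv$plots$transect_id == 1]
  expect_equal(diff(d), rep(10, 9))
  # positional noise bounded by the GPS error
  expect_true(all(sv$plots$noise_m <= 0.3 + 1e-12))
  # field segments never overlap and gaps exceed the merge rule
  for (tid in unique(sv$segments$transect_id)) {
    s <- sv$segments[sv$segments$transect_id == tid, ]
    s <- s[order(s$start_m), ]
    if (nrow(s) > 1)
      expect_true(all(s$start_m[-1] - s$end_m[-nrow(s)] > 0.2))
  }
})

test_that("transects that cannot fit raise an out-of-extent error", {
  sc <- generate_scene(small_cfg(1, extent = c(20, 20)),
                       render_bands = FALSE)
  expect_error(simulate_field_survey(sc$truth, seed = 1),
               "out-of-extent")
})

test_that("the acceptable-class rule switches exactly at 5% cover", {
  cov <- rbind(c(senescent_matrix = 0.95, medusahead = 0.05),
               c(senescent_matrix = 0.951, medusahead = 0.049))
  lab <- medusamap:::fuzzy_labels(cov)
  expect_equal(lab$best, c("senescent_matrix", "senescent_matrix"))
  expect_equal(lab$acceptable[[1]], "medusahead")
  expect_equal(lab$acceptable[[2]], character(0))
})

test_that("designate_sample_sets reproduces the 300/150 sample design", {
  sc <- generate_scene(scene_config(seed = 6), render_bands = FALSE)
  samples <- sample_reference_points(sc$truth, seed = 8)
  sets <- designate_sample_sets(samples, seed = 9)
  expect_equal(nrow(sets$training), 300L)
  expect_equal(nrow(sets$test), 150L)
  expect_length(intersect(sets$training$sample_id, sets$test$sample_id), 0L)
  expect_equal(as.vector(table(sets$test$stratum)[
    c("target_best", "non_target", "target_acceptable")]),
    c(50L, 50L, 50L))
  tr_counts <- table(sets$training$best_class)
  expect_equal(unname(tr_counts["medusahead"]), 50L)
  expect_equal(unname(tr_counts["wild_oat"]), 40L)
  expect_equal(unname(tr_counts["canarygrass"]), 30L)
})

test_that("insufficient candidates fail naming the deficient class", {
  samples <- make_samples(runif(20), runif(20),
                          best = rep("medusahead", 20))
  expect_error(designate_sample_sets(samples), "class medusahead")
})
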