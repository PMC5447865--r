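# Per-object attributes: GLCM entropy, the object table, training labels.

test_that("GLCM entropy of simple patterns matches hand counts", {
  expect_equal(glcm_entropy_region(matrix(0.5, 6, 6),
                                   matrix(TRUE, 6, 6)), 0)
  # 2-level checkerboard, horizontal pairs only: p(1,2) = p(2,1) = 0.5
  cb <- matrix(rep_len(c(0, 1), 36), 6, 6)
  expect_equal(glcm_entropy_region(cb, matrix(TRUE, 6, 6),
                                   directions = "0"),
               log(2), tolerance = 1e-12)
  expect_error(glcm_entropy_region(cb, matrix(FALSE, 6, 6)),
               "empty-region")
})

test_that("GLCM entropy equals naive pair enumeration on small regions", {
  set.seed(41)
  for (i in 1:5) {
    nr <- sample(5:20, 1); nc <- sample(5:20, 1)
    layer <- matrix(rnorm(nr * nc), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.7, nr, nc)  # ragged region
    if (!any(mask)) mask[1] <- TRUE
    expect_equal(glcm_entropy_region(layer, mask),
                 naive_glcm_entropy(layer, mask), tolerance = 1e-10)
    expect_equal(glcm_entropy_region(layer, mask, directions = c("0", "90")),
                 naive_glcm_entropy(layer, mask, directions = c("0", "90")),
                 tolerance = 1e-10)
  }
})

test_that("GLCM entropy is invariant to affine rescaling of the layer", {
  set.seed(43)
  layer <- matrix(rnorm(100), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  e0 <- glcm_entropy_region(layer, mask)
  expect_equal(glcm_entropy_region(3.7 * layer + 12, mask), e0,
               tolerance = 1e-12)
})

test_that("the bulk per-object entropy agrees with the region operator", {
  sc <- generate_scene(scene_config(extent_m = c(12, 12), seed = 19))
  seg <- multiresolution_segment(sc$stack, scale = 5)
  tab <- build_object_table(seg, sc$stack)
  labels <- seg$labels
  for (id in sample(seq_len(seg$n_objects), min(25, seg$n_objects))) {
    mask <- labels == id
    expect_equal(tab$glcm_entropy_nir[id],
                 glcm_entropy_region(sc$stack$bands$nir, mask),
                 tolerance = 1e-10)
  }
})

test_that("object attributes conserve the pixel statistics", {
  sc <- generate_scene(scene_config(extent_m = c(12, 12), seed = 23))
  seg <- multiresolution_segment(sc$stack, scale = 5)
  tab <- build_object_table(seg, sc$stack)
  expect_equal(nrow(tab), seg$n_objects)
  # pixel-count-weighted mean of object means = global layer mean
  for (ly in c("nir", "ndvi")) {
    expect_equal(sum(tab[[paste0("mean_", ly)]] * tab$n_px) / sum(tab$n_px),
                 mean(sc$stack$bands[[ly]]), tolerance = 1e-9)
  }
  # total object area = scene area
  expect_equal(sum(tab$area_m2),
               prod(dim(sc$stack)) * sc$stack$pixel_size_m^2,
               tolerance = 1e-9)
  # object mean equals direct per-object averaging
  id <- which.max(tab$n_px)
  expect_equal(tab$mean_ndvi[id],
               mean(sc$stack$bands$ndvi[seg$labels == id]),
               tolerance = 1e-12)
  expect_true(all(tab$glcm_entropy_nir >= 0))
  expect_true(all(tab$glcm_entropy_green >= 0))
})

test_that("a one-object constant scene has zero sd and entropy", {
  st <- toy_stack(8, 8)            # constant bands; derived layers not
  tab <- build_object_table(trivial_level(8, 8), st)   # needed here
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$sd_blue, 0)
  expect_equal(tab$glcm_entropy_nir, 0)
  expect_equal(tab$mean_nir, 0.5)
  expect_equal(tab$perimeter_m, 4 * 8 * 0.15)
})

test_that("grid mismatches are alignment errors", {
  st <- toy_stack(8, 8)
  expect_error(build_object_table(trivial_level(6, 6), st), "alignment")
})

test_that("training samples label, deduplicate and exclude on conflict", {
  st <- toy_stack(10, 10)
  labels <- matrix(1L, 10, 10)
  labels[, 6:10] <- 2L
  level <- trivial_level(10, 10)
  level$labels <- labels; level$n_objects <- 2L
  tab <- build_object_table(level, st)

  # two same-class samples in object 1 -> one training object
  s <- make_samples(x = c(0.2, 0.5), y = c(0.8, 0.4),
                    best = c("medusahead", "medusahead"))
  tr <- attach_training(tab, level, st, s)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$assigned_class, "medusahead")

  # conflicting labels in object 1 (cols 1-5, x < 0.75 m) exclude it;
  # the clover sample in object 2 survives
  s2 <- make_samples(x = c(0.2, 0.5, 1.2), y = c(0.8, 0.4, 1.2),
                     best = c("medusahead", "vetch", "clover_brome"))
  expect_warning(tr2 <- attach_training(tab, level, st, s2),
                 "conflicting")
  expect_equal(tr2$object_id, 2L)
  expect_equal(tr2$assigned_class, "clover_brome")
  # both conflicting samples in the sole labelled object -> empty training
  s3 <- make_samples(x = c(0.2, 0.5), y = c(0.8, 0.4),
                     best = c("medusahead", "vetch"))
  expect_warning(tr3 <- attach_training(tab, level, st, s3),
                 "conflicting")
  expect_equal(nrow(tr3), 0L)

  # outside the extent -> geometry error
  s4 <- make_samples(x = 99, y = 0.5, best = "medusahead")
  expect_error(attach_training(tab, level, st, s4), "geometry")
})

test_that("truth curation drops training objects contradicting the truth", {
  st <- toy_stack(10, 10)
  level <- trivial_level(10, 10)
  level$labels <- matrix(rep(1:2, each = 50), 10, 10)
  level$n_objects <- 2L
  tab <- build_object_table(level, st)
  mh <- matrix(0, 10, 10); mh[, 1:5] <- 1   # object 1 is truly medusahead
  truth <- scene_truth(list(senescent_matrix = 1 - mh, medusahead = mh))
  s <- make_samples(x = c(0.3, 1.2), y = c(0.8, 0.8),
                    best = c("medusahead", "medusahead"))
  # sample 2 lies in object 2 (matrix): curation drops that object
  tr <- attach_training(tab, level, st, s, truth = truth)
  expect_equal(tr$object_id, 1L)
  expect_equal(attr(tr, "n_curated"), 1L)
})
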