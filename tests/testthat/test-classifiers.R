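# Class schemes, feature sets, the k-means scan and the three single-run
# supervised algorithms.

make_table <- function(x, classes = NULL) {
  # minimal object table around a feature matrix
  tab <- as.data.frame(x)
  tab$object_id <- seq_len(nrow(tab))
  if (!is.null(classes)) tab$assigned_class <- classes
  tab
}

fake_geometry <- function(n) {
  lv <- trivial_level(1, n)
  lv$labels <- matrix(seq_len(n), 1, n)
  lv$n_objects <- n
  st <- band_stack(list(x = matrix(0, 1, n)))
  list(level = lv, stack = st)
}

gauss_blobs <- function(n, centers, sd = 0.05, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    cbind(rnorm(n, centers[k, 1], sd), rnorm(n, centers[k, 2], sd))))
}

test_that("schemes and feature sets have the stated structure", {
  s3 <- class_scheme("three_class")
  expect_equal(s3$classes, c("medusahead", "other_green",
                             "other_nongreen"))
  s7 <- class_scheme("seven_class")
  expect_length(s7$classes, 7L)
  expect_true(all(c("medusahead", "barbed_goatgrass", "vetch",
                    "canarygrass", "wild_oat") %in% s7$classes))
  fs <- feature_set("spectral")
  ft <- feature_set("spectral_texture")
  expect_true(all(fs$columns %in% ft$columns))   # spectral is a subset
  expect_true(all(c("sd_blue", "glcm_entropy_nir") %in%
                    setdiff(ft$columns, fs$columns)))
  # scheme collapse maps every detailed class to a valid coarse class
  mapped <- collapse_to_three(c(s7$classes, "senescent_matrix"))
  expect_true(all(mapped %in% s3$classes))
  expect_equal(collapse_to_three("medusahead"), "medusahead")
  expect_equal(collapse_to_three("wild_oat"), "other_nongreen")
  expect_equal(collapse_to_three("vetch"), "other_green")
})

test_that("k-means scan: variance hits zero at k = n and never rises", {
  x <- gauss_blobs(10, rbind(c(0, 0), c(5, 5)), seed = 3)
  colnames(x) <- c("f1", "f2")
  tab <- make_table(x)
  feats <- list(name = "toy", columns = c("f1", "f2"))
  scan <- kmeans_scan(tab, feats, k_range = c(2, 5, 10, 20), seed = 1)
  expect_true(all(diff(scan$within_var) <= 1e-8))
  scan20 <- kmeans_scan(tab, feats, k_range = c(19, 20), seed = 1)
  expect_lt(scan20$within_var[2], 1e-20)
  expect_error(kmeans_scan(tab, feats, k_range = c(2, 50)), "parameter")
})

test_that("two well-separated blobs make the 1->2 drop dominate", {
  x <- gauss_blobs(40, rbind(c(0, 0), c(8, 8)), seed = 5)
  colnames(x) <- c("f1", "f2")
  scan <- kmeans_scan(make_table(x),
                      list(name = "toy", columns = c("f1", "f2")),
                      k_range = 1:4, seed = 2)
  d12 <- scan$within_var[1] - scan$within_var[2]
  d23 <- scan$within_var[2] - scan$within_var[3]
  expect_gt(d12, 10 * max(d23, 1e-12))
  expect_true(scan$flagged[2])  # curvature anomaly right at the true k
})

test_that("cluster labelling follows the training-overlap rule", {
  x <- gauss_blobs(20, rbind(c(0, 0), c(6, 0), c(0, 6)), seed = 7)
  colnames(x) <- c("f1", "f2")
  tab <- make_table(x)
  feats <- list(name = "toy", columns = c("f1", "f2"))
  geo <- fake_geometry(nrow(tab))
  # all medusahead training objects in blob 1
  training <- data.frame(object_id = 1:8,
                         assigned_class = "medusahead")
  res <- kmeans_classify(tab, feats, k = 3, training, geo$level,
                         geo$stack, seed = 1)
  expect_equal(sum(res$diagnostics$labelled), 1L)
  expect_true(all(res$assignments$class[1:20] == "medusahead"))
  expect_true(!any(res$assignments$class[21:60] == "medusahead"))

  # samples spread over all three blobs above theta -> 3 labelled clusters
  training2 <- data.frame(object_id = c(1:4, 21:24, 41:44),
                          assigned_class = "medusahead")
  res2 <- kmeans_classify(tab, feats, k = 3, training2, geo$level,
                          geo$stack, seed = 1)
  expect_equal(sum(res2$diagnostics$labelled), 3L)

  # theta = 1 with split samples -> nothing labelled, warning
  expect_warning(
    res3 <- kmeans_classify(tab, feats, k = 3, training2, geo$level,
                            geo$stack, seed = 1, theta = 1),
    "empty-detection")
  expect_equal(sum(res3$diagnostics$labelled), 0L)
  expect_equal(sum(target_mask(res3)), 0L)
})

test_that("1-NN reproduces its training labels exactly", {
  x <- gauss_blobs(15, rbind(c(0, 0), c(3, 3), c(0, 3)), sd = 0.3,
                   seed = 9)
  colnames(x) <- c("f1", "f2")
  cls <- rep(c("medusahead", "clover_brome", "vetch"), each = 15)
  tab <- make_table(x, cls)
  geo <- fake_geometry(nrow(tab))
  scheme <- list(name = "toy3",
                 classes = c("medusahead", "clover_brome", "vetch"))
  res <- train_predict(tab, tab, "knn", scheme,
                       list(name = "toy", columns = c("f1", "f2")),
                       geo$level, geo$stack)
  expect_equal(res$assignments$class, cls)
})

test_that("the diagonal Gaussian splits 1-D classes at the midpoint", {
  # equal variance, equal priors: closed-form boundary at (mu1+mu2)/2
  set.seed(13)
  f1 <- c(rnorm(200, 0, 1), rnorm(200, 6, 1))
  tab <- make_table(cbind(f1 = f1, f2 = rep(0.5, 400) + rnorm(400, 0, 1)),
                    rep(c("medusahead", "vetch"), each = 200))
  probe <- make_table(cbind(f1 = seq(-2, 8, by = 0.25), f2 = 0.5))
  geo <- fake_geometry(nrow(probe))
  scheme <- list(name = "toy2", classes = c("medusahead", "vetch"))
  res <- train_predict(probe, tab, "bayes", scheme,
                       list(name = "toy", columns = c("f1", "f2")),
                       geo$level, geo$stack)
  mid <- (mean(f1[1:200]) + mean(f1[201:400])) / 2
  pred_mid <- ifelse(probe$f1 < mid - 0.3, "medusahead",
                     ifelse(probe$f1 > mid + 0.3, "vetch", NA))
  ok <- !is.na(pred_mid)
  expect_equal(res$assignments$class[ok], pred_mid[ok])
})

test_that("the Gaussian classifier agrees with naiveBayes on balanced data", {
  # e1071::naiveBayes is the independent route: with balanced classes its
  # frequency priors equal our design priors
  set.seed(17)
  x <- gauss_blobs(60, rbind(c(0, 0), c(2, 1), c(-1, 2)), sd = 0.8,
                   seed = 17)
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("a", "b", "c"), each = 60))
  xnew <- gauss_blobs(30, rbind(c(0, 0), c(2, 1), c(-1, 2)), sd = 1.2,
                      seed = 18)
  colnames(xnew) <- c("f1", "f2")
  ours <- medusamap:::bayes_diag_predict(x, y, xnew)
  nb <- e1071::naiveBayes(x, y)
  theirs <- as.character(predict(nb, as.data.frame(xnew)))
  # naiveBayes uses the unbiased variance; agreement up to boundary cases
  expect_gt(mean(ours == theirs), 0.95)
})

test_that("the linear SVM separates a separable fixture without error", {
  x <- gauss_blobs(30, rbind(c(0, 0), c(5, 5)), sd = 0.3, seed = 19)
  colnames(x) <- c("f1", "f2")
  cls <- rep(c("medusahead", "vetch"), each = 30)
  tab <- make_table(x, cls)
  geo <- fake_geometry(nrow(tab))
  scheme <- list(name = "toy2", classes = c("medusahead", "vetch"))
  res <- train_predict(tab, tab, "svm_linear", scheme,
                       list(name = "toy", columns = c("f1", "f2")),
                       geo$level, geo$stack)
  expect_equal(res$assignments$class, cls)
})

test_that("a scheme class without training objects is a training error", {
  x <- gauss_blobs(10, rbind(c(0, 0)), seed = 21)
  colnames(x) <- c("f1", "f2")
  tab <- make_table(x, rep("medusahead", 10))
  geo <- fake_geometry(10)
  expect_error(
    train_predict(tab, tab, "knn", class_scheme("three_class"),
                  list(name = "toy", columns = c("f1", "f2")),
                  geo$level, geo$stack),
    "other_green")
})

test_that("collapsing seven-class output gives a valid three-class result", {
  sc <- generate_scene(scene_config(extent_m = c(15, 15), seed = 25))
  seg <- multiresolution_segment(sc$stack, scale = 6)
  tab <- build_object_table(seg, sc$stack)
  sel <- seg$labels > 0
  dom <- sc$truth$classes[sc$truth$dominant]
  objdom <- tapply(dom[sel], seg$labels[sel],
                   function(z) names(which.max(table(z))))
  tab$assigned_class <- unname(objdom[as.character(tab$object_id)])
  tr <- tab[tab$assigned_class != "senescent_matrix", ]
  # need every scheme class present; skip classes absent from the tiny scene
  present <- unique(tr$assigned_class)
  scheme7 <- list(name = "seven_class", classes = present)
  res7 <- train_predict(tab, tr, "knn", scheme7, feature_set("spectral"),
                        seg, sc$stack)
  mapped <- collapse_to_three(res7$assignments$class)
  expect_true(all(mapped %in% class_scheme("three_class")$classes))
  expect_equal(mapped == "medusahead",
               res7$assignments$class == "medusahead")
})
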