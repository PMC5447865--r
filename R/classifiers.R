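# Unsupervised k-means scan and the three single-run supervised
# algorithms (KNN, diagonal-Gaussian Bayes, linear SVM) under both class
# schemes and both feature sets.

#' Classification schemes
#'
#' `three_class` collapses the vegetation into medusahead / other green /
#' other non-green; `seven_class` keeps the detailed categories.
#'
#' @param name `"three_class"` or `"seven_class"`.
#' @return list with `name` and ordered `classes`.
#' @export
class_scheme <- function(name = c("seven_class", "three_class")) {
  name <- match.arg(name)
  classes <- if (name == "three_class") {
    c("medusahead", "other_green", "other_nongreen")
  } else {
    c("medusahead", "clover_brome", "ryegrass_brome", "canarygrass",
      "vetch", "barbed_goatgrass", "wild_oat")
  }
  list(name = name, classes = classes)
}

#' Map detailed class labels onto the three-class scheme
#'
#' Green vegetation classes collapse to `other_green`; wild oat and the
#' senescent matrix to `other_nongreen`; medusahead stays itself.
#'
#' @param classes character vector of detailed class names.
#' @return character vector in the three-class vocabulary.
#' @export
collapse_to_three <- function(classes) {
  green <- c("clover_brome", "ryegrass_brome", "canarygrass", "vetch",
             "barbed_goatgrass")
  out <- ifelse(classes == "medusahead", "medusahead",
                ifelse(classes %in% green, "other_green",
                       "other_nongreen"))
  out
}

#' Feature sets
#'
#' `spectral` uses the object means of the four camera bands plus NDVI
#' (greenness); `spectral_texture` adds the simple (sd of blue and green)
#' and GLCM (all-direction entropy of NIR and green) texture attributes.
#' The local Moran's I layer drives segmentation but is not an object
#' feature: it is itself a texture statistic, and keeping it out of the
#' spectral set keeps the spectral/texture contrast clean.
#'
#' @param name `"spectral"` or `"spectral_texture"`.
#' @return list with `name` and `columns`.
#' @export
feature_set <- function(name = c("spectral", "spectral_texture")) {
  name <- match.arg(name)
  spectral <- c("mean_blue", "mean_green", "mean_red", "mean_nir",
                "mean_ndvi")
  texture <- c("sd_blue", "sd_green", "glcm_entropy_nir",
               "glcm_entropy_green")
  list(name = name,
       columns = if (name == "spectral") spectral else
         c(spectral, texture))
}

feature_matrix <- function(table, features) {
  miss <- setdiff(features$columns, names(table))
  if (length(miss))
    stop("object table lacks feature column(s): ",
         paste(miss, collapse = ", "))
  as.matrix(table[, features$columns, drop = FALSE])
}

standardize_by <- function(x, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Classification result
#'
#' Realizes an object-to-class assignment as a class raster plus the
#' medusahead extent mask.
#'
#' @param method method identifier string.
#' @param scheme_name scheme or workflow name.
#' @param features_name feature-set name.
#' @param assignments data frame with `object_id`, `class`.
#' @param level `segmentation_level` the objects come from.
#' @param stack the [band_stack()] (georeference).
#' @param target target class (default `"medusahead"`).
#' @return object of class `classification_result`: assignments, `classes`
#'   (levels), `class_raster` (integer matrix indexing `classes`, 0 =
#'   masked), `target`, `pixel_size_m`, `origin`.
#' @export
classification_result <- function(method, scheme_name, features_name,
                                  assignments, level, stack,
                                  target = "medusahead") {
  if (anyDuplicated(assignments$object_id))
    stop("an object was assigned more than one class")
  classes <- sort(unique(assignments$class))
  cls_idx <- integer(level$n_objects)
  cls_idx[assignments$object_id] <- match(assignments$class, classes)
  raster <- matrix(0L, nrow(level$labels), ncol(level$labels))
  sel <- level$labels > 0
  raster[sel] <- cls_idx[level$labels[sel]]
  structure(
    list(method = method, scheme = scheme_name, features = features_name,
         assignments = assignments, classes = classes,
         class_raster = raster, target = target,
         pixel_size_m = stack$pixel_size_m, origin = stack$origin),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s (%s, %s): %d objects, %d classes\n",
              x$method, x$scheme, x$features, nrow(x$assignments),
              length(x$classes)))
  invisible(x)
}

#' Logical raster of the target-class extent
#'
#' @param result a [classification_result()].
#' @return logical matrix, `TRUE` where the classified class is the target.
#' @export
target_mask <- function(result) {
  ti <- match(result$target, result$classes)
  if (is.na(ti)) return(result$class_raster < 0)  # all FALSE
  result$class_raster == ti
}

#' k-means cluster-number scan
#'
#' Runs seeded best-of-restarts k-means for each candidate cluster count
#' on globally standardized features and records the total within-cluster
#' variance.  The curve declines with k; candidate "meaningful" cluster
#' counts are flagged where the discrete second difference of the curve
#' turns negative (a local deviation from the convex decline).
#'
#' @param table object table.
#' @param features a [feature_set()].
#' @param k_range integer vector of cluster counts (default `10:30`).
#' @param seed integer seed.
#' @param restarts k-means restarts per k.
#' @return data frame with `k`, `within_var`, `second_diff`, `flagged`.
#' @export
kmeans_scan <- function(table, features, k_range = 10:30, seed = 1L,
                        restarts = 10L) {
  x <- feature_matrix(table, features)
  if (max(k_range) > nrow(x))
    stop("parameter error: k exceeds the number of objects")
  x <- standardize_by(x, colMeans(x), apply(x, 2, stats::sd))
  wv <- vapply(seq_along(k_range), function(i) {
    if (k_range[i] >= nrow(x)) return(0)   # one object per cluster
    set.seed(child_seed(seed, i))
    stats::kmeans(x, centers = k_range[i], nstart = restarts,
                  iter.max = 100L)$tot.withinss
  }, numeric(1))
  sd2 <- c(NA, diff(diff(wv)), NA)        # second difference, centred
  # a "meaningful" cluster count shows up as a local peak in curvature:
  # the decline flattens abruptly after it
  flagged <- vapply(seq_along(sd2), function(i) {
    if (is.na(sd2[i])) return(FALSE)
    left <- if (i > 1 && !is.na(sd2[i - 1])) sd2[i] > sd2[i - 1] else TRUE
    right <- if (i < length(sd2) && !is.na(sd2[i + 1]))
      sd2[i] >= sd2[i + 1] else TRUE
    left && right
  }, logical(1))
  data.frame(k = k_range, within_var = wv, second_diff = sd2,
             flagged = flagged)
}

#' Unsupervised k-means classification of medusahead
#'
#' Clusters the objects and labels as medusahead every cluster containing
#' at least a fraction `theta` of the medusahead training samples (spatial
#' overlap rule); other clusters keep their cluster identity.  The original
#' workflow selected clusters visually; this explicit numeric rule replaces
#' that irreproducible step and is flagged as such in reports.
#'
#' @inheritParams kmeans_scan
#' @param k number of clusters.
#' @param training labelled training objects (rows of the object table
#'   with `assigned_class`).
#' @param level,stack passed to [classification_result()].
#' @param theta minimum fraction of target training samples a cluster
#'   must contain (default 0.05).
#' @param target target class.
#' @return a [classification_result()]; its `diagnostics` element maps
#'   clusters to training-sample overlap.
#' @export
kmeans_classify <- function(table, features, k, training, level, stack,
                            seed = 1L, restarts = 10L, theta = 0.05,
                            target = "medusahead") {
  x <- feature_matrix(table, features)
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  x <- standardize_by(x, ctr, scl)
  set.seed(child_seed(seed, 0L))
  km <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100L)
  cl <- km$cluster
  mh_objects <- training$object_id[training$assigned_class == target]
  n_mh <- length(mh_objects)
  overlap <- vapply(seq_len(k), function(j) {
    sum(mh_objects %in% table$object_id[cl == j])
  }, numeric(1))
  frac <- if (n_mh > 0) overlap / n_mh else rep(0, k)
  labelled <- frac >= theta & overlap > 0
  if (!any(labelled))
    warning("empty-detection: no cluster overlaps the ", target,
            " training samples at theta = ", theta)
  cls <- ifelse(labelled[cl], target, sprintf("cluster_%02d", cl))
  res <- classification_result(
    method = sprintf("unsupervised_k%d", k), scheme_name = "clusters",
    features_name = features$name,
    assignments = data.frame(object_id = table$object_id, class = cls,
                             stringsAsFactors = FALSE),
    level = level, stack = stack, target = target)
  res$diagnostics <- data.frame(cluster = seq_len(k),
                                n_objects = tabulate(cl, k),
                                target_samples = overlap,
                                target_fraction = frac,
                                labelled = labelled)
  res
}

#' Single-run supervised classification
#'
#' Trains one of the three algorithms on the labelled training objects and
#' assigns every object a class.  Features are standardized by the
#' training statistics.  `knn` is majority vote over the `k` nearest
#' training objects in Euclidean feature space (default `k = 1`); `bayes`
#' is a Gaussian class-conditional classifier with diagonal covariance and
#' equal priors (training quotas are design-balanced, not prevalence
#' estimates); `svm_linear` is a one-vs-one soft-margin linear SVM with
#' cost 1.
#'
#' @param table object table (all objects to classify).
#' @param training labelled training objects (subset of `table` rows with
#'   `assigned_class` in the detailed vocabulary).
#' @param algorithm `"knn"`, `"bayes"` or `"svm_linear"`.
#' @param scheme a [class_scheme()]; detailed training labels are
#'   collapsed automatically for `three_class`.
#' @param features a [feature_set()].
#' @param level,stack passed to [classification_result()].
#' @param seed integer seed (SVM training is deterministic; the seed keys
#'   the method id and any downstream sampling).
#' @param knn_k neighbours for KNN.
#' @return a [classification_result()].
#' @export
train_predict <- function(table, training,
                          algorithm = c("knn", "bayes", "svm_linear"),
                          scheme = class_scheme("seven_class"),
                          features = feature_set("spectral"),
                          level, stack, seed = 1L, knn_k = 1L) {
  algorithm <- match.arg(algorithm)
  y <- training$assigned_class
  if (scheme$name == "three_class") y <- collapse_to_three(y)
  missing <- setdiff(scheme$classes, unique(y))
  if (length(missing))
    stop("training error: no training objects for class(es): ",
         paste(missing, collapse = ", "))
  xtr <- feature_matrix(training, features)
  ctr <- colMeans(xtr); scl <- apply(xtr, 2, stats::sd)
  xtr <- standardize_by(xtr, ctr, scl)
  xall <- standardize_by(feature_matrix(table, features), ctr, scl)
  yf <- factor(y, levels = scheme$classes)
  pred <- switch(
    algorithm,
    knn = as.character(class::knn(xtr, xall, yf, k = knn_k)),
    bayes = bayes_diag_predict(xtr, yf, xall),
    svm_linear = {
      fit <- e1071::svm(xtr, yf, kernel = "linear", cost = 1,
                        scale = FALSE)
      as.character(stats::predict(fit, xall))
    })
  classification_result(
    method = sprintf("supervised_%s", algorithm),
    scheme_name = scheme$name, features_name = features$name,
    assignments = data.frame(object_id = table$object_id, class = pred,
                             stringsAsFactors = FALSE),
    level = level, stack = stack)
}

# Gaussian class-conditionals with diagonal covariance and equal priors.
bayes_diag_predict <- function(xtr, y, xnew, var_floor = 1e-9) {
  classes <- levels(droplevels(y))
  scores <- vapply(classes, function(cl) {
    xi <- xtr[y == cl, , drop = FALSE]
    mu <- colMeans(xi)
    v <- apply(xi, 2, function(col) stats::var(col) * (length(col) - 1) /
                 max(1, length(col)))          # population variance
    v <- pmax(v, var_floor)
    colSums(dnorm_log_t(t(xnew), mu, sqrt(v)))
  }, numeric(nrow(xnew)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  classes[max.col(scores, ties.method = "first")]
}

dnorm_log_t <- function(tx, mu, sd) {
  # tx: features x observations; returns same shape of log densities
  stats::dnorm(tx, mean = mu, sd = sd, log = TRUE)
}
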