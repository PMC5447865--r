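# Orchestration of the full method-comparison experiment: simulate a
# scene and survey, segment, build features, run every roster method,
# evaluate fuzzy accuracy and transect match.

#' Deterministic child seed
#'
#' Derives a per-method/per-stage seed from the master seed by a fixed
#' affine hash modulo 2^31 - 1, so each method's result is reproducible
#' independently of roster order.
#'
#' @param master master seed (integer).
#' @param index non-negative stage index.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, index) {
  m <- 2147483647
  as.integer((as.numeric(master) %% m * 48271 +
                as.numeric(index) * 104729 + 1) %% m)
}

#' Default method roster
#'
#' The 19-method comparison grid: unsupervised k-means with 12 and 18
#' clusters, each with spectral and spectral+texture features; the three
#' supervised algorithms under the 3- and 7-class schemes with both
#' feature sets; and the hierarchical workflow with each supervised
#' algorithm (texture always on).
#'
#' @return data frame with columns `method`, `algorithm`, `scheme`,
#'   `texture`, `k`.
#' @export
default_roster <- function() {
  unsup <- expand.grid(k = c(12L, 18L), texture = c(FALSE, TRUE))
  sup <- expand.grid(algorithm = c("knn", "svm_linear", "bayes"),
                     scheme = c("three_class", "seven_class"),
                     texture = c(FALSE, TRUE), stringsAsFactors = FALSE)
  rbind(
    data.frame(method = "unsupervised", algorithm = "kmeans",
               scheme = "clusters", texture = unsup$texture, k = unsup$k),
    data.frame(method = "supervised", algorithm = sup$algorithm,
               scheme = sup$scheme, texture = sup$texture, k = NA_integer_),
    data.frame(method = "hierarchical",
               algorithm = c("knn", "svm_linear", "bayes"),
               scheme = "hierarchy", texture = TRUE, k = NA_integer_))
}

#' Run the full classification experiment on a synthetic scene
#'
#' Generates the scene and field survey, segments the nested levels,
#' builds the object tables, designates training/test samples, runs every
#' roster method, and evaluates each with the fuzzy accuracy metrics and
#' (optionally) the transect length-category match.
#'
#' @param config a [scene_config()].
#' @param scales segmentation scale parameters, coarse to fine (in
#'   reflectance units for the synthetic palettes).
#' @param roster method roster as [default_roster()].
#' @param seed master seed; every stage derives its own child seed.
#' @param layout a [survey_layout()]; `NULL` skips the transect survey
#'   (reference samples only).
#' @param counts,test_strata passed to [designate_sample_sets()].
#' @param hierarchy_cfg base [hierarchy_config()]; its algorithm is
#'   overridden per roster row.
#' @param transect_match evaluate the per-length-category transect match
#'   for each method.
#' @param out_dir optional directory for CSV artifacts.
#' @return list: `comparison` (methods table), `reports`, `results`,
#'   `transect_stats`, `scene`, `survey`, `sets`, `manifest`.
#' @export
run_experiment <- function(config, scales = c(28, 16, 5),
                           roster = default_roster(), seed = 1L,
                           layout = survey_layout(),
                           counts = NULL, test_strata = c(50, 50, 50),
                           hierarchy_cfg = hierarchy_config(),
                           transect_match = TRUE, out_dir = NULL) {
  if (!nrow(roster)) stop("roster must be non-empty")
  scene <- generate_scene(config)
  stack <- scene$stack; truth <- scene$truth

  survey <- NULL; segments <- NULL
  samples <- sample_reference_points(truth, seed = child_seed(seed, 1L),
                                     gps_error_m = config$gps_error_m)
  if (!is.null(layout)) {
    survey <- simulate_field_survey(truth, layout,
                                    seed = child_seed(seed, 2L),
                                    gps_error_m = config$gps_error_m)
    segments <- survey$segments
    survey$plots$sample_id <- survey$plots$sample_id + nrow(samples)
    common <- intersect(names(samples), names(survey$plots))
    samples <- rbind(samples[, common], survey$plots[, common])
  }
  if (is.null(counts)) {
    sets <- designate_sample_sets(samples, test_strata = test_strata,
                                  seed = child_seed(seed, 3L))
  } else {
    sets <- designate_sample_sets(samples, counts = counts,
                                  test_strata = test_strata,
                                  seed = child_seed(seed, 3L))
  }

  levels <- segment_hierarchy(stack, scales = scales)
  tables <- lapply(levels, build_object_table, stack = stack)
  fine <- levels[[length(levels)]]
  tab_f <- tables[[length(tables)]]
  training <- attach_training(tab_f, fine, stack, sets$training)

  reports <- list(); results <- list(); tstats <- list()
  for (i in seq_len(nrow(roster))) {
    row <- roster[i, ]
    mseed <- child_seed(seed, 100L + i)
    res <- if (row$method == "unsupervised") {
      kmeans_classify(tab_f, feature_set(
        if (row$texture) "spectral_texture" else "spectral"),
        k = row$k, training = training, level = fine, stack = stack,
        seed = mseed)
    } else if (row$method == "supervised") {
      train_predict(tab_f, training, algorithm = row$algorithm,
                    scheme = class_scheme(row$scheme),
                    features = feature_set(
                      if (row$texture) "spectral_texture" else "spectral"),
                    level = fine, stack = stack, seed = mseed)
    } else {
      cfg <- hierarchy_cfg
      cfg$supervised_algorithm <- if (row$algorithm == "svm_linear")
        "svm_linear" else row$algorithm
      run_hierarchy(levels, tables, stack, sets$training, cfg)
    }
    id <- sprintf("%s_%s_%s%s", row$method, row$algorithm, row$scheme,
                  if (row$texture) "_tex" else "")
    if (row$method == "unsupervised")
      id <- sprintf("unsupervised_k%d%s", row$k,
                    if (row$texture) "_tex" else "")
    res$method <- id
    rep <- evaluate_fuzzy(res, sets$test)
    results[[id]] <- res
    reports[[id]] <- rep
    if (transect_match && !is.null(survey) && nrow(segments)) {
      runs <- classified_runs_along(res, survey$transects)
      tstats[[id]] <- list(
        vs_segments = intersect_with_segments(runs, segments),
        vs_transects = intersect_with_transects(runs, segments))
    }
  }
  comparison <- tabulate_methods(reports)
  comparison$texture <- roster$texture
  manifest <- list(seed = seed, scales = scales,
                   n_objects = vapply(levels, function(l) l$n_objects,
                                      numeric(1)),
                   n_training = nrow(sets$training),
                   n_test = nrow(sets$test),
                   config_seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(comparison = comparison, reports = reports, results = results,
       transect_stats = tstats, scene = scene, survey = survey,
       sets = sets, manifest = manifest)
}
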