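# Knowledge-based hierarchical classification: coarse exclusion by
# NDVI/distance, texture-based isolation of the vetch mosaic and
# canarygrass, association classing, Otsu greenness tiers and the final
# invasive-grass split.

#' Hierarchical-workflow configuration
#'
#' Explicit numeric thresholds for every knowledge-based step (the
#' original workflow derived them by trial-and-error; here they are
#' configuration with defaults calibrated once on the packaged fixture
#' scene).
#'
#' @param ndvi_exclusion_threshold coarse objects with mean NDVI below
#'   this AND far from training samples are excluded.
#' @param distance_exclusion_m exclusion distance from the nearest
#'   medusahead training sample (m).
#' @param entropy_nir_threshold NIR GLCM entropy at/above which a coarse
#'   object is the vetch/ryegrass heterogeneous mosaic.
#' @param entropy_green_threshold green GLCM entropy at/above which a
#'   mid-level object is canarygrass.
#' @param supervised_algorithm algorithm for the association and final
#'   splits.
#' @param knn_k neighbours when the algorithm is KNN.
#' @return list of class `hierarchy_config`.
#' @export
hierarchy_config <- function(ndvi_exclusion_threshold = 0.2,
                             distance_exclusion_m = 20,
                             entropy_nir_threshold = 7.4,
                             entropy_green_threshold = 7.2,
                             supervised_algorithm = c("bayes", "knn",
                                                      "svm_linear"),
                             knn_k = 1L) {
  supervised_algorithm <- match.arg(supervised_algorithm)
  structure(list(ndvi_exclusion_threshold = ndvi_exclusion_threshold,
                 distance_exclusion_m = distance_exclusion_m,
                 entropy_nir_threshold = entropy_nir_threshold,
                 entropy_green_threshold = entropy_green_threshold,
                 supervised_algorithm = supervised_algorithm,
                 knn_k = as.integer(knn_k)),
            class = "hierarchy_config")
}

#' Coarse exclusion of unlikely-medusahead landscape units
#'
#' A coarse object is excluded iff its mean NDVI is below the threshold
#' AND its distance to the nearest medusahead training sample exceeds the
#' exclusion distance (distance from the object's nearest pixel, so an
#' object containing a sample has distance 0).  With no training samples
#' the distance criterion is disabled with a warning and nothing is
#' excluded by distance alone.
#'
#' @param table coarse-level object table.
#' @param level the coarse `segmentation_level`.
#' @param stack the [band_stack()].
#' @param mh_samples medusahead training samples (rows with `x`, `y`).
#' @param config a [hierarchy_config()].
#' @return logical vector along `table` rows: `TRUE` = excluded.
#' @export
coarse_exclude <- function(table, level, stack, mh_samples, config) {
  low_ndvi <- table$mean_ndvi < config$ndvi_exclusion_threshold
  if (is.null(mh_samples) || nrow(mh_samples) == 0) {
    warning("no medusahead training samples: distance criterion disabled")
    return(rep(FALSE, nrow(table)))
  }
  labels <- level$labels
  px <- stack$pixel_size_m
  sel <- labels > 0
  xy <- rc_to_world(stack, row(labels)[sel], col(labels)[sel])
  dmin <- rep(Inf, sum(sel))
  for (i in seq_len(nrow(mh_samples))) {
    d2 <- (xy[, 1] - mh_samples$x[i])^2 + (xy[, 2] - mh_samples$y[i])^2
    dmin <- pmin(dmin, d2)
  }
  obj_dmin <- sqrt(tapply(dmin, labels[sel], min))
  dist_far <- obj_dmin[as.character(table$object_id)] >
    config$distance_exclusion_m
  low_ndvi & unname(dist_far)
}

#' Isolate the heterogeneous vetch/ryegrass mosaic by NIR texture
#'
#' Coarse objects whose all-direction NIR GLCM entropy reaches the
#' threshold are the bright heterogeneous mosaic (vetch within
#' clover-brome/ryegrass); these areas carried no medusahead in the field
#' and are removed from all later candidacy.
#'
#' @param table coarse-level object table (candidates only).
#' @param config a [hierarchy_config()].
#' @return logical vector: `TRUE` = vetch mosaic.
#' @export
isolate_vetch_mosaic <- function(table, config) {
  table$glcm_entropy_nir >= config$entropy_nir_threshold
}

#' Classify mid-level objects into broad associations
#'
#' Within the remaining candidate area: objects whose green-band GLCM
#' entropy reaches the threshold are the canarygrass clump association
#' (spectrally inseparable from medusahead mixtures; texture is the only
#' discriminator); objects inside the optional storksbill mask are
#' labelled storksbill verbatim (the manually delineated subcanopy-forb
#' areas); the rest are split into the medusahead-with-wild-oat and
#' medusahead-with-clover-brome associations by the configured supervised
#' algorithm on band means plus blue/green standard deviations.
#'
#' @param table mid-level object table (candidate objects only).
#' @param training labelled training objects at the mid level (detailed
#'   classes; mapped internally to the two associations: wild oat to the
#'   oat association, the green mixture classes to the clover-brome
#'   association).
#' @param config a [hierarchy_config()].
#' @param storksbill_ids optional object ids inside the storksbill mask.
#' @return character vector along `table` rows: `canarygrass_assoc`,
#'   `storksbill`, `mh_wild_oat_assoc` or `mh_clover_brome_assoc`.
#' @export
classify_associations <- function(table, training, config,
                                  storksbill_ids = NULL) {
  out <- rep(NA_character_, nrow(table))
  canary <- table$glcm_entropy_green >= config$entropy_green_threshold
  out[canary] <- "canarygrass_assoc"
  if (is.null(storksbill_ids)) {
    message("no storksbill mask provided: manual-labelling step skipped")
  } else {
    out[table$object_id %in% storksbill_ids] <- "storksbill"
  }
  rest <- is.na(out)
  if (any(rest)) {
    assoc_of <- function(cls) ifelse(cls == "wild_oat",
                                     "mh_wild_oat_assoc",
                                     "mh_clover_brome_assoc")
    tr <- training[training$assigned_class != "senescent_matrix", ,
                   drop = FALSE]
    tr$assigned_class <- assoc_of(tr$assigned_class)
    feats <- list(name = "association",
                  columns = c("mean_red", "mean_green", "mean_blue",
                              "mean_nir", "sd_blue", "sd_green"))
    out[rest] <- supervised_subset(table[rest, , drop = FALSE], tr,
                                   feats, config)
  }
  out
}

#' Split association objects into NDVI greenness tiers
#'
#' Runs a single two-threshold Otsu on the object NDVI means of each
#' association group; the least green tier is non-medusahead, the mid and
#' high tiers proceed to the final split.  A degenerate association
#' (fewer than 3 distinct NDVI means) passes through un-tiered and is
#' flagged.
#'
#' @param ndvi_means numeric vector of object NDVI means for ONE
#'   association.
#' @return list with `tier` (integer 1 = low, 2 = mid, 3 = high along the
#'   input) and `degenerate` flag.
#' @export
greenness_tiers <- function(ndvi_means) {
  if (length(unique(ndvi_means)) < 3L) {
    return(list(tier = rep(2L, length(ndvi_means)), degenerate = TRUE))
  }
  thr <- otsu_thresholds(ndvi_means, n_classes = 3L)
  tier <- findInterval(ndvi_means, thr) + 1L
  list(tier = as.integer(tier), thresholds = thr, degenerate = FALSE)
}

#' Final split of the invasive-grass candidates
#'
#' Classifies the mid/high-greenness objects into medusahead, barbed
#' goatgrass and other non-medusahead using exactly the three stated
#' features: object means of the red and NDVI bands and the NIR GLCM
#' entropy.  With no goatgrass training objects the split degrades to
#' binary medusahead/other with a warning.
#'
#' @param table fine-level object table (mid/high-tier objects only).
#' @param training labelled fine-level training objects (detailed
#'   classes; medusahead and barbed goatgrass kept, everything else
#'   mapped to `other_nonmedusahead`).
#' @param config a [hierarchy_config()].
#' @return character vector along `table` rows.
#' @export
final_invasive_split <- function(table, training, config) {
  tr <- training
  tr$assigned_class <- ifelse(
    tr$assigned_class %in% c("medusahead", "barbed_goatgrass"),
    tr$assigned_class, "other_nonmedusahead")
  if (!any(tr$assigned_class == "medusahead"))
    stop("training error: no training objects for class medusahead")
  if (!any(tr$assigned_class == "barbed_goatgrass"))
    warning("no barbed goatgrass training objects: ",
            "falling back to binary medusahead/other split")
  feats <- list(name = "final_split",
                columns = c("mean_red", "mean_ndvi", "glcm_entropy_nir"))
  supervised_subset(table, tr, feats, config)
}

# shared supervised step on an explicit feature list and training labels
supervised_subset <- function(table, training, feats, config) {
  y <- factor(training$assigned_class)
  xtr <- feature_matrix(training, feats)
  ctr <- colMeans(xtr); scl <- apply(xtr, 2, stats::sd)
  xtr <- standardize_by(xtr, ctr, scl)
  xall <- standardize_by(feature_matrix(table, feats), ctr, scl)
  if (nlevels(droplevels(y)) < 2L)
    return(rep(as.character(y[1]), nrow(table)))
  switch(config$supervised_algorithm,
         knn = as.character(class::knn(xtr, xall, y, k = config$knn_k)),
         bayes = bayes_diag_predict(xtr, y, xall),
         svm_linear = {
           fit <- e1071::svm(xtr, y, kernel = "linear", cost = 1,
                             scale = FALSE)
           as.character(stats::predict(fit, xall))
         })
}

#' Run the full hierarchical classification
#'
#' Composes the five steps over a nested segmentation (coarse landscape
#' units, vegetation communities, primitive objects): coarse exclusion,
#' vetch-mosaic isolation, association classing, per-association NDVI
#' tiers, final invasive split.  Every fine-level object receives a
#' terminal label and the step that fixed it is recorded in the
#' provenance table; excluded and vetch-mosaic areas can never contain
#' classified medusahead.
#'
#' @param levels named list from [segment_hierarchy()] (coarse first).
#' @param tables object tables for the same levels (same order).
#' @param stack the [band_stack()].
#' @param training_samples training reference samples (rows with `x`,
#'   `y`, `best_class`).
#' @param config a [hierarchy_config()].
#' @param storksbill_mask optional logical matrix marking the manually
#'   delineated storksbill area.
#' @return a [classification_result()] on the fine level with an extra
#'   `provenance` data frame (`object_id`, `step`, `class`).
#' @export
run_hierarchy <- function(levels, tables, stack, training_samples,
                          config = hierarchy_config(),
                          storksbill_mask = NULL) {
  stopifnot(length(levels) == 3L, length(tables) == 3L)
  coarse <- levels[[1]]; mid <- levels[[2]]; fine <- levels[[3]]
  tab_c <- tables[[1]]; tab_m <- tables[[2]]; tab_f <- tables[[3]]
  # ancestor chains: fine -> mid -> coarse
  mid_parent <- mid$parent_map
  fine_parent <- fine$parent_map

  mh_tr <- training_samples[training_samples$best_class == "medusahead", ,
                            drop = FALSE]
  excl <- coarse_exclude(tab_c, coarse, stack, mh_tr, config)
  vetch <- rep(FALSE, nrow(tab_c))
  vetch[!excl] <- isolate_vetch_mosaic(tab_c[!excl, , drop = FALSE],
                                       config)

  # provenance on fine objects
  prov_step <- rep(NA_character_, nrow(tab_f))
  prov_class <- rep(NA_character_, nrow(tab_f))
  f_coarse <- mid_parent[fine_parent[tab_f$object_id]]
  is_excl <- excl[f_coarse]
  is_vetch <- vetch[f_coarse]
  prov_step[is_excl] <- "coarse_exclude"
  prov_class[is_excl] <- "excluded"
  prov_step[is_vetch] <- "vetch_mosaic"
  prov_class[is_vetch] <- "vetch_mosaic"

  # mid-level association classing inside the candidate area
  m_coarse <- mid_parent[tab_m$object_id]
  cand_m <- !excl[m_coarse] & !vetch[m_coarse]
  tr_mid <- attach_training(tab_m, mid, stack, training_samples)
  sb_ids <- NULL
  if (!is.null(storksbill_mask)) {
    geo <- mid$labels
    sb_ids <- unique(geo[storksbill_mask & geo > 0])
  }
  assoc <- rep(NA_character_, nrow(tab_m))
  assoc[cand_m] <- classify_associations(tab_m[cand_m, , drop = FALSE],
                                         tr_mid, config, sb_ids)

  f_mid <- fine_parent[tab_f$object_id]
  f_assoc <- assoc[f_mid]
  open <- is.na(prov_step)
  set_label <- function(mask, step, cls) {
    prov_step[open & mask] <<- step
    prov_class[open & mask] <<- cls
  }
  set_label(!is.na(f_assoc) & f_assoc == "canarygrass_assoc",
            "association", "canarygrass")
  set_label(!is.na(f_assoc) & f_assoc == "storksbill", "association",
            "storksbill")
  open <- is.na(prov_step)

  # NDVI tiers per medusahead association, on the fine objects
  for (a in c("mh_wild_oat_assoc", "mh_clover_brome_assoc")) {
    in_a <- open & !is.na(f_assoc) & f_assoc == a
    if (!any(in_a)) next
    tiers <- greenness_tiers(tab_f$mean_ndvi[in_a])
    if (tiers$degenerate) next            # flagged pass-through
    low <- which(in_a)[tiers$tier == 1L]
    prov_step[low] <- "greenness_tiers"
    prov_class[low] <- "low_greenness"
  }
  open <- is.na(prov_step)

  # final invasive split on everything still open
  if (any(open)) {
    tr_fine <- attach_training(tab_f, fine, stack, training_samples)
    cls <- final_invasive_split(tab_f[open, , drop = FALSE], tr_fine,
                                config)
    prov_step[open] <- "final_split"
    prov_class[open] <- cls
  }

  res <- classification_result(
    method = sprintf("hierarchical_%s", config$supervised_algorithm),
    scheme_name = "hierarchy", features_name = "spectral_texture",
    assignments = data.frame(object_id = tab_f$object_id,
                             class = prov_class,
                             stringsAsFactors = FALSE),
    level = fine, stack = stack)
  res$provenance <- data.frame(object_id = tab_f$object_id,
                               step = prov_step, class = prov_class,
                               stringsAsFactors = FALSE)
  res$coarse_excluded <- which(excl)
  res$coarse_vetch <- which(vetch)
  res
}
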