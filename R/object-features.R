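# Per-object attribute table: spectral means, standard deviations of the
# blue and green bands, and all-direction GLCM entropy of the NIR and green
# bands — the feature pool shared by all classifiers.

#' All-direction GLCM entropy of a masked region
#'
#' Quantizes the region's values to `levels` grey levels (min-max over the
#' region), accumulates a symmetric grey-level co-occurrence matrix over
#' the four distance-1 offsets (0, 45, 90, 135 degrees) restricted to
#' pixel pairs inside the mask (pairs straddling the region boundary are
#' discarded, so an object's texture never leaks its neighbours), and
#' returns the Shannon entropy \eqn{-\sum p \ln p} of the normalized
#' matrix.  A constant region, or one with no interior pixel pairs, has
#' entropy 0.
#'
#' @param layer numeric matrix.
#' @param mask logical matrix, `TRUE` for region pixels.
#' @param levels number of grey levels (default 64).
#' @param directions subset of `c("0", "45", "90", "135")`.
#' @return non-negative entropy (nats).
#' @export
glcm_entropy_region <- function(layer, mask, levels = 64L,
                                directions = c("0", "45", "90", "135")) {
  if (!any(mask)) stop("empty-region error: mask selects no pixels")
  vals <- layer[mask]
  rng <- range(vals)
  q <- matrix(NA_integer_, nrow(layer), ncol(layer))
  if (rng[2] > rng[1]) {
    q[mask] <- pmin(levels,
                    floor((vals - rng[1]) / (rng[2] - rng[1]) * levels) + 1L)
  } else {
    q[mask] <- 1L
  }
  offs <- list("0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(-1L, 0L),
               "135" = c(-1L, -1L))[directions]
  nr <- nrow(q); nc <- ncol(q)
  counts <- numeric(levels * levels)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    if (max(1L, 1L - dr) > min(nr, nr - dr) ||
        max(1L, 1L - dc) > min(nc, nc - dc)) next
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- q[rs, cs]
    b <- q[rs + dr, cs + dc]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) next
    ij <- c((a[keep] - 1L) * levels + b[keep],      # (a, b) and (b, a)
            (b[keep] - 1L) * levels + a[keep])
    tab <- tabulate(ij, nbins = levels * levels)
    counts <- counts + tab
  }
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Build the per-object attribute table for a segmentation level
#'
#' One row per object: per-layer means, standard deviations of the blue
#' and green bands, all-direction GLCM entropy of the NIR and green bands,
#' area and perimeter in metres, and the parent object id where the level
#' belongs to a hierarchy.  Single-pixel objects get sd 0 and entropy 0.
#'
#' @param level a `segmentation_level`.
#' @param stack a [band_stack()] on the same grid.
#' @param glcm_levels grey levels for the entropy quantization.
#' @return data frame keyed by `object_id`.
#' @export
build_object_table <- function(level, stack, glcm_levels = 64L) {
  labels <- level$labels
  if (!identical(dim(labels), dim(stack)))
    stop("alignment error: segmentation and stack grids differ")
  sel <- labels > 0
  ids <- labels[sel]
  n <- tabulate(ids, nbins = level$n_objects)
  px <- stack$pixel_size_m
  tab <- data.frame(object_id = seq_len(level$n_objects), n_px = n)
  for (ly in names(stack$bands)) {
    v <- stack$bands[[ly]][sel]
    s1 <- rowsum(v, ids)[, 1]
    tab[[paste0("mean_", ly)]] <- s1 / n
    if (ly %in% c("blue", "green")) {
      s2 <- rowsum(v * v, ids)[, 1]
      vr <- pmax(0, s2 / n - (s1 / n)^2)
      tab[[paste0("sd_", ly)]] <- sqrt(vr)
    }
  }
  # perimeter: 4-neighbourhood edges to other objects, mask or border
  pad <- matrix(0L, nrow(labels) + 2L, ncol(labels) + 2L)
  pad[2:(nrow(labels) + 1L), 2:(ncol(labels) + 1L)] <- labels
  edges <- numeric(level$n_objects)
  core <- pad[2:(nrow(labels) + 1L), 2:(ncol(labels) + 1L)]
  for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- pad[2:(nrow(labels) + 1L) + sh[1], 2:(ncol(labels) + 1L) + sh[2]]
    diff <- core > 0 & nb != core
    if (any(diff))
      edges <- edges + tabulate(core[diff], nbins = level$n_objects)
  }
  tab$area_m2 <- n * px^2
  tab$perimeter_m <- edges * px
  # GLCM entropy per object (bulk path; agrees with glcm_entropy_region
  # on every object, which the test suite asserts)
  nirm <- stack$bands$nir; greenm <- stack$bands$green
  nirm[!sel] <- 0; greenm[!sel] <- 0
  tab$glcm_entropy_nir <-
    .glcm_entropy_by_object_cpp(nirm, labels, as.integer(glcm_levels))
  tab$glcm_entropy_green <-
    .glcm_entropy_by_object_cpp(greenm, labels, as.integer(glcm_levels))
  tab$parent_id <- if (!is.null(level$parent_map))
    level$parent_map[tab$object_id] else NA_integer_
  tab$assigned_class <- NA_character_
  tab
}

#' Attach training labels to the objects containing training samples
#'
#' Each training sample labels the object containing its (recorded)
#' location.  Multiple same-class samples in one object collapse to a
#' single training object; an object receiving conflicting class labels is
#' excluded from training with a warning.
#'
#' @param table an object table from [build_object_table()].
#' @param level the `segmentation_level` the table was built from.
#' @param stack the [band_stack()] (for the georeference).
#' @param samples training reference samples (rows with `x`, `y`,
#'   `best_class`).
#' @param truth optional `scene_truth`: emulates the analyst's manual
#'   curation of training objects (the sample-editor inspection step of
#'   the original workflow) by dropping labelled objects whose dominant
#'   ground-truth class disagrees with the sample label — e.g. when GPS
#'   jitter moved a sample point onto a neighbouring matrix object.
#' @return the labelled subset of `table` with `assigned_class` filled
#'   in; attribute `n_curated` counts objects dropped by truth curation.
#' @export
attach_training <- function(table, level, stack, samples, truth = NULL) {
  rc <- world_to_rc(stack, samples$x, samples$y)
  if (anyNA(rc))
    stop("geometry error: training sample outside the raster extent")
  oid <- level$labels[rc]
  if (any(oid == 0))
    stop("geometry error: training sample falls on a masked pixel")
  lab <- tapply(samples$best_class, oid, function(cl) {
    u <- unique(cl)
    if (length(u) == 1L) u else NA_character_
  })
  conflicted <- names(lab)[is.na(lab)]
  if (length(conflicted))
    warning("objects with conflicting training labels excluded: ",
            paste(conflicted, collapse = ", "))
  lab <- lab[!is.na(lab)]
  out <- table[table$object_id %in% as.integer(names(lab)), , drop = FALSE]
  out$assigned_class <- unname(lab[as.character(out$object_id)])
  n_curated <- 0L
  if (!is.null(truth)) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      px <- level$labels == out$object_id[i]
      dom <- truth$classes[which.max(tabulate(truth$dominant[px],
                                              length(truth$classes)))]
      dom == out$assigned_class[i]
    }, logical(1))
    n_curated <- sum(!keep)
    out <- out[keep, , drop = FALSE]
  }
  attr(out, "n_curated") <- n_curated
  out
}
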