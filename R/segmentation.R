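#' Multiresolution region-merging segmentation
#'
#' Partitions a scene into primitive objects by iterative pairwise merging
#' under a heterogeneity criterion.  Starting from single-pixel objects (or
#' an initial partition), a merge of two adjacent objects is admissible when
#' its cost
#' \deqn{f = (1 - w_{shape}) \Delta h_{color} + w_{shape} \Delta h_{shape}}
#' stays below `scale^2`; merging proceeds by mutual best fitting (a pair
#' merges only when each is the other's cheapest neighbour) with a
#' deterministic ascending-id scan, so results are reproducible without a
#' seed.  The colour term is the layer-weighted increase in size-weighted
#' standard deviation; the shape term blends compactness
#' (perimeter/sqrt(area)) and smoothness (perimeter/bounding-box perimeter)
#' deviations.  Objects are 4-connected; `NA` pixels in the mask layer
#' (trees, wetland) belong to no object.
#'
#' @param layers named list of numeric matrices (typically the four camera
#'   bands plus NDVI and local Moran's I), or a [band_stack()], in which
#'   case all its layers are used.
#' @param scale positive scale parameter; merges must cost less than
#'   `scale^2`.
#' @param shape_w shape weight in `[0, 1)` (default 0.1).
#' @param cmpct_w compactness weight in `[0, 1]` (default 0.1).
#' @param weights per-layer weights (default 1 for every layer).
#' @param mask optional logical matrix; `FALSE`/`NA` pixels are excluded
#'   from every object.
#' @param init optional integer matrix of initial labels (>= 1; 0 =
#'   masked), e.g. a finer segmentation level; defaults to one object per
#'   pixel.
#' @param standardize z-score each layer over the unmasked pixels before
#'   computing merge costs (default `TRUE`).  Without it a layer with a
#'   large numeric range — local Moran's I in particular, which is
#'   unbounded — silently dominates the colour heterogeneity term; with
#'   it the scale parameter is expressed in within-scene
#'   standard-deviation units for every layer alike.
#'
#' @return a `segmentation_level`: list with `labels` (integer matrix,
#'   0 = masked), `n_objects`, `scale`, `shape_w`, `cmpct_w`, `weights`,
#'   and `parent_map` (`NULL` here; populated by [segment_hierarchy()]).
#' @export
multiresolution_segment <- function(layers, scale, shape_w = 0.1,
                                    cmpct_w = 0.1, weights = NULL,
                                    mask = NULL, init = NULL,
                                    standardize = TRUE) {
  if (inherits(layers, "band_stack")) layers <- layers$bands
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be a positive number")
  if (shape_w < 0 || shape_w >= 1) stop("`shape_w` must be in [0, 1)")
  d <- dim(layers[[1]])
  if (is.null(weights)) weights <- rep(1, length(layers))
  keep <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  if (!is.null(mask)) keep <- keep & !is.na(mask) & mask
  if (is.null(init)) {
    init <- matrix(0L, d[1], d[2])
    init[keep] <- seq_len(sum(keep))
  } else {
    init <- init * (keep * 1L)
    storage.mode(init) <- "integer"
  }
  layers0 <- lapply(layers, function(m) {
    if (standardize) {
      mu <- mean(m[keep]); s <- stats::sd(m[keep])
      if (is.na(s) || s == 0) s <- 1
      m <- (m - mu) / s
    }
    m[!keep] <- 0
    m
  })
  labels <- .mrs_segment_cpp(layers0, as.numeric(weights), scale,
                             shape_w, cmpct_w, init)
  structure(
    list(labels = labels, n_objects = max(labels), scale = scale,
         shape_w = shape_w, cmpct_w = cmpct_w, weights = weights,
         parent_map = NULL),
    class = "segmentation_level")
}

#' @export
print.segmentation_level <- function(x, ...) {
  cat(sprintf("<segmentation_level> scale %g: %d objects on %d x %d px\n",
              x$scale, x$n_objects, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Object adjacency graph of a segmentation level
#'
#' @param level a `segmentation_level`.
#' @return two-column integer matrix of adjacent (4-neighbourhood) object
#'   id pairs, `from < to`, each pair once.
#' @export
level_adjacency <- function(level) {
  l <- level$labels
  pairs <- rbind(
    cbind(as.vector(l[-nrow(l), ]), as.vector(l[-1, ])),
    cbind(as.vector(l[, -ncol(l)]), as.vector(l[, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- cbind(from = pmin(pairs[, 1], pairs[, 2]),
                 to = pmax(pairs[, 1], pairs[, 2]))
  unique(pairs)
}

#' Local-variance scan over candidate scales
#'
#' Segments the scene at each scale and records the mean within-object
#' standard deviation (averaged over layers) — the local variance (LV) —
#' and its percent rate of change, the diagnostic used to pick scale
#' parameters (coarse landscape units appear as local maxima of the rate
#' of change).
#'
#' @inheritParams multiresolution_segment
#' @param scales strictly increasing numeric vector (>= 2 scales).
#' @return data frame with columns `scale`, `lv`, `roc_lv`, `n_objects`,
#'   `peak` (logical; local maxima of `roc_lv`).
#' @export
esp_scan <- function(layers, scales, shape_w = 0.1, cmpct_w = 0.1,
                     weights = NULL, mask = NULL, standardize = TRUE) {
  if (length(scales) < 2L || is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be >= 2 strictly increasing values")
  if (inherits(layers, "band_stack")) layers <- layers$bands
  lv <- numeric(length(scales))
  nob <- integer(length(scales))
  init <- NULL
  for (i in seq_along(scales)) {
    seg <- multiresolution_segment(layers, scales[i], shape_w, cmpct_w,
                                   weights, mask, standardize = standardize)
    keep <- seg$labels > 0
    layers0 <- lapply(layers, function(m) { m[!keep] <- 0; m })
    lv[i] <- .object_lv_cpp(layers0, seg$labels)
    nob[i] <- seg$n_objects
  }
  roc <- c(NA_real_, 100 * diff(lv) / head(lv, -1))
  roc[!is.finite(roc)] <- NA_real_
  peak <- rep(FALSE, length(scales))
  for (i in seq_along(scales)) {
    if (i < 2L || is.na(roc[i])) next
    left <- if (i == 2L) TRUE else !is.na(roc[i - 1]) && roc[i] > roc[i - 1]
    right <- i == length(scales) || (!is.na(roc[i + 1]) && roc[i] > roc[i + 1])
    peak[i] <- left && right
  }
  data.frame(scale = scales, lv = lv, roc_lv = roc, n_objects = nob,
             peak = peak)
}

#' Nested multi-scale segmentation
#'
#' Builds a hierarchy of segmentation levels for the given scales
#' (decreasing, coarse to fine).  The finest scale is segmented from single
#' pixels; each coarser level continues region merging from the next finer
#' level's objects, so fine-object boundaries never cross coarse-object
#' boundaries and every fine object has exactly one parent.
#'
#' @inheritParams multiresolution_segment
#' @param scales strictly decreasing scale parameters, coarse to fine
#'   (default `c(390, 176, 10)`, suited to 8-bit digital-number imagery;
#'   reflectance-scaled scenes need proportionally smaller values).
#' @return named list of `segmentation_level`s (names `"scale_<s>"`, coarse
#'   first); every level except the coarsest has `parent_map`, an integer
#'   vector mapping its object ids to the parent ids one level up.
#' @export
segment_hierarchy <- function(layers, scales = c(390, 176, 10),
                              shape_w = 0.1, cmpct_w = 0.1,
                              weights = NULL, mask = NULL,
                              standardize = TRUE) {
  if (any(diff(scales) >= 0))
    stop("`scales` must be strictly decreasing (coarse to fine)")
  asc <- rev(scales)
  levels <- vector("list", length(asc))
  init <- NULL
  for (i in seq_along(asc)) {
    levels[[i]] <- multiresolution_segment(layers, asc[i], shape_w,
                                           cmpct_w, weights, mask,
                                           init = init,
                                           standardize = standardize)
    init <- levels[[i]]$labels
  }
  # parent map: fine object id -> coarse object id at the next level up
  for (i in seq_along(asc)) {
    if (i == length(asc)) next
    fine <- levels[[i]]$labels
    coarse <- levels[[i + 1]]$labels
    sel <- fine > 0
    pm <- integer(levels[[i]]$n_objects)
    pm[fine[sel]] <- coarse[sel]   # last write wins; all writes identical
    levels[[i]]$parent_map <- pm
  }
  levels <- rev(levels)
  names(levels) <- paste0("scale_", scales)
  levels
}

#' Check the partition/connectivity invariants of a segmentation level
#'
#' Every unmasked pixel must carry exactly one object id, ids must be
#' contiguous `1..n`, and every object must be 4-connected.
#'
#' @param level a `segmentation_level`.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
check_segmentation <- function(level) {
  l <- level$labels
  ids <- sort(unique(as.vector(l[l > 0])))
  if (length(ids) && !identical(as.integer(ids),
                                seq_len(level$n_objects)))
    stop("labels are not contiguous 1..n_objects")
  .check_partition_cpp(l)
  invisible(TRUE)
}
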