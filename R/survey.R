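# Simulated field survey: transects with plots, medusahead patch segments
# along transects, and reference location samples with fuzzy class labels.

#' Construct a scene truth from cover-fraction rasters
#'
#' Builds the `scene_truth` container from per-class cover matrices (used
#' by [generate_scene()] internally and by tests constructing exact
#' fixtures).  Fractions are checked to sum to 1 per pixel; the dominant
#' label is the per-pixel argmax (first class wins ties).
#'
#' @param cover named list of cover-fraction matrices (same dimensions).
#' @param pixel_size_m grid spacing in metres.
#' @return a `scene_truth`.
#' @export
scene_truth <- function(cover, pixel_size_m = 0.15) {
  nr <- nrow(cover[[1]]); nc <- ncol(cover[[1]])
  tot <- Reduce(`+`, cover)
  if (max(abs(tot - 1)) > 1e-9)
    stop("cover fractions must sum to 1 per pixel")
  cm <- vapply(cover, as.vector, numeric(nr * nc))
  dominant <- matrix(max.col(cm, ties.method = "first"), nr, nc)
  structure(
    list(cover = cover, dominant = dominant, classes = names(cover),
         patches = data.frame(), pixel_size_m = pixel_size_m,
         origin = c(0, 0),
         extent_m = c(nc, nr) * pixel_size_m),
    class = "scene_truth")
}

#' Survey layout
#'
#' The field design: transects placed as groups of parallel lines, each
#' transect carrying equally spaced square plots.  The default reproduces
#' the study design — 20 transects as five groups of three, one group of
#' four and one separate transect, ten 0.5 m plots per transect at 10 m
#' spacing.
#'
#' @param group_sizes transects per group.
#' @param plots_per_transect plots on each transect.
#' @param plot_spacing_m distance between consecutive plots (m).
#' @param plot_size_m side of the square survey plot (m).
#' @param transect_sep_m perpendicular separation of transects within a
#'   group (m).
#' @param margin_m minimum distance of any transect point from the scene
#'   edge (m).
#' @return a list of class `survey_layout`.
#' @export
survey_layout <- function(group_sizes = c(3, 3, 3, 3, 3, 4, 1),
                          plots_per_transect = 10L,
                          plot_spacing_m = 10,
                          plot_size_m = 0.5,
                          transect_sep_m = 15,
                          margin_m = 1) {
  structure(list(group_sizes = group_sizes,
                 plots_per_transect = as.integer(plots_per_transect),
                 plot_spacing_m = plot_spacing_m,
                 plot_size_m = plot_size_m,
                 transect_sep_m = transect_sep_m,
                 margin_m = margin_m),
            class = "survey_layout")
}

# mean cover per class in a square window centred on (x, y)
cover_at_points <- function(truth, x, y, window_m = 0.5) {
  nr <- nrow(truth$dominant); nc <- ncol(truth$dominant)
  px <- truth$pixel_size_m
  half <- floor((window_m / 2) / px + 0.5)
  rc <- world_to_rc(truth, x, y)
  out <- matrix(NA_real_, length(x), length(truth$classes),
                dimnames = list(NULL, truth$classes))
  for (i in seq_along(x)) {
    if (is.na(rc[i, 1])) next
    rows <- max(1L, rc[i, 1] - half):min(nr, rc[i, 1] + half)
    cols <- max(1L, rc[i, 2] - half):min(nc, rc[i, 2] + half)
    out[i, ] <- vapply(truth$cover,
                       function(m) mean(m[rows, cols]), numeric(1))
  }
  out
}

# fuzzy labels from a cover row: best = max cover; acceptable = any other
# class with cover >= threshold
fuzzy_labels <- function(cov, acceptable_threshold = 0.05) {
  best <- colnames(cov)[max.col(cov, ties.method = "first")]
  acceptable <- lapply(seq_len(nrow(cov)), function(i) {
    cls <- colnames(cov)[cov[i, ] >= acceptable_threshold]
    setdiff(cls, best[i])
  })
  list(best = best, acceptable = acceptable)
}

# uniform jitter within a disk of radius r
disk_jitter <- function(n, r) {
  rad <- r * sqrt(stats::runif(n))
  ang <- stats::runif(n, 0, 2 * pi)
  cbind(dx = rad * cos(ang), dy = rad * sin(ang), r = rad)
}

# extract presence runs of the target class along a transect line
runs_along_line <- function(class_raster, classes, px, x0, y0, ux, uy,
                            length_m, target, step = px / 2,
                            merge_gap_m = 0.2) {
  d <- seq(0, length_m, by = step)
  xs <- x0 + d * ux; ys <- y0 + d * uy
  fake <- list(pixel_size_m = px, origin = c(0, 0))
  dimfun <- dim(class_raster)
  rc <- world_to_rc(structure(list(bands = list(class_raster),
                                   pixel_size_m = px, origin = c(0, 0)),
                              class = "band_stack"), xs, ys)
  if (anyNA(rc))
    stop("out-of-extent: transect exits the raster")
  vals <- class_raster[cbind(rc[, 1], rc[, 2])]
  pres <- !is.na(vals) & vals == target
  if (!any(pres)) return(data.frame(start_m = numeric(),
                                    end_m = numeric(),
                                    length_m = numeric()))
  r <- rle(pres)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start_m = d[starts[r$values]],
                    end_m = d[ends[r$values]])
  # merge runs separated by gaps <= merge_gap_m
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) for (i in 2:nrow(seg)) {
    gap <- seg$start_m[i] - merged$end_m[nrow(merged)]
    if (gap <= merge_gap_m) merged$end_m[nrow(merged)] <- seg$end_m[i]
    else merged <- rbind(merged, seg[i, ])
  }
  merged$length_m <- merged$end_m - merged$start_m
  merged[merged$length_m > 0, , drop = FALSE]
}

#' Simulate the transect/plot field survey over a ground truth
#'
#' Places the transect groups randomly (seeded) inside the scene, reads
#' plot cover from the truth in 0.5 m windows, extracts medusahead patch
#' segments along each transect (runs of medusahead-dominant cover;
#' consecutive runs separated by gaps of at most 0.2 m are merged into one
#' patch segment, matching the field convention that patches > 20 cm apart
#' are separate), and jitters recorded plot locations by GPS noise
#' (uniform within a disk of the configured radius).
#'
#' @param truth a `scene_truth`.
#' @param layout a [survey_layout()].
#' @param seed integer seed.
#' @param gps_error_m positional-noise radius (m).
#' @param target class surveyed for patch segments.
#' @param acceptable_threshold minimum cover for a class to be listed as
#'   an acceptable (non-best) candidate.
#' @return list with `transects` (data frame: id, group_id, x0, y0, ux,
#'   uy, length_m), `plots` (reference samples: one row per plot),
#'   `segments` (data frame: transect_id, start_m, end_m, length_m).
#' @export
simulate_field_survey <- function(truth, layout = survey_layout(),
                                  seed = 1L, gps_error_m = 0.3,
                                  target = "medusahead",
                                  acceptable_threshold = 0.05) {
  set.seed(seed)
  ext <- truth$extent_m
  len <- layout$plot_spacing_m * (layout$plots_per_transect - 1L)
  m <- layout$margin_m
  if (len + 2 * m > min(ext))
    stop("out-of-extent: transects of ", len,
         " m do not fit in the scene extent")
  transects <- list()
  tid <- 0L
  for (g in seq_along(layout$group_sizes)) {
    ng <- layout$group_sizes[g]
    ok <- FALSE
    for (try in 1:2000) {
      ang <- stats::runif(1, 0, 2 * pi)
      ux <- cos(ang); uy <- sin(ang)
      vx <- -uy; vy <- ux                      # perpendicular offset
      x0 <- stats::runif(1, m, ext[1] - m)
      y0 <- stats::runif(1, m, ext[2] - m)
      off <- (seq_len(ng) - 1) * layout$transect_sep_m
      xs <- c(x0 + off * vx, x0 + off * vx + len * ux)
      ys <- c(y0 + off * vy, y0 + off * vy + len * uy)
      if (all(xs >= m & xs <= ext[1] - m & ys >= m & ys <= ext[2] - m)) {
        for (k in seq_len(ng)) {
          tid <- tid + 1L
          transects[[tid]] <- data.frame(
            id = tid, group_id = g, x0 = x0 + off[k] * vx,
            y0 = y0 + off[k] * vy, ux = ux, uy = uy, length_m = len)
        }
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("out-of-extent: could not place transect group ", g)
  }
  transects <- do.call(rbind, transects)

  target_idx <- match(target, truth$classes)
  plots <- list(); segments <- list()
  for (i in seq_len(nrow(transects))) {
    tr <- transects[i, ]
    d <- (seq_len(layout$plots_per_transect) - 1L) * layout$plot_spacing_m
    xt <- tr$x0 + d * tr$ux; yt <- tr$y0 + d * tr$uy
    cov <- cover_at_points(truth, xt, yt, layout$plot_size_m)
    lab <- fuzzy_labels(cov, acceptable_threshold)
    jit <- disk_jitter(length(d), gps_error_m)
    plots[[i]] <- data.frame(
      transect_id = tr$id, plot_index = seq_along(d), distance_m = d,
      x = xt + jit[, "dx"], y = yt + jit[, "dy"],
      x_true = xt, y_true = yt,
      best_class = lab$best, noise_m = jit[, "r"],
      stringsAsFactors = FALSE)
    plots[[i]]$acceptable <- lab$acceptable
    plots[[i]]$cover <- lapply(seq_along(d), function(j) cov[j, ])
    seg <- runs_along_line(truth$dominant, truth$classes,
                           truth$pixel_size_m, tr$x0, tr$y0, tr$ux,
                           tr$uy, tr$length_m, target_idx)
    if (nrow(seg)) {
      seg$transect_id <- tr$id
      segments[[length(segments) + 1L]] <- seg
    }
  }
  plots <- do.call(rbind, plots)
  plots$sample_id <- seq_len(nrow(plots))
  plots$role <- NA_character_
  segments <- if (length(segments)) do.call(rbind, segments) else
    data.frame(start_m = numeric(), end_m = numeric(),
               length_m = numeric(), transect_id = integer())
  list(transects = transects, plots = plots,
       segments = segments[, c("transect_id", "start_m", "end_m",
                               "length_m")])
}

#' Sample additional reference location points from the truth
#'
#' Emulates the walking surveys that supplemented the transect plots:
#' random locations stratified by best (window-dominant) class, plus a
#' dedicated stratum of mixed-cover points where medusahead is present at
#' acceptable (>= 5%) but sub-dominant cover.  Recorded locations carry
#' GPS jitter; cover is read at the true location in a 0.5 m window.
#'
#' @param truth a `scene_truth`.
#' @param n_per_class named vector: candidate points per best class.
#' @param n_mixed_target extra candidates with the target acceptable but
#'   not best.
#' @param mixed_best_classes best classes eligible for the mixed stratum
#'   (default: every vegetation class except the target and the senescent
#'   matrix — a mixed plot is subdominant medusahead within other
#'   vegetation, not the soft edge of a medusahead patch).
#' @param target target class for the mixed stratum.
#' @param seed integer seed.
#' @param gps_error_m positional-noise radius (m).
#' @param acceptable_threshold minimum cover for "acceptable".
#' @return data frame of reference samples (same columns as survey plots).
#' @export
sample_reference_points <- function(truth,
                                    n_per_class = NULL,
                                    n_mixed_target = 60L,
                                    mixed_best_classes = NULL,
                                    target = "medusahead",
                                    seed = 1L, gps_error_m = 0.3,
                                    acceptable_threshold = 0.05) {
  set.seed(seed)
  auto_quota <- is.null(n_per_class)
  if (auto_quota) {
    # enough candidates per class for the 300/150 training/test design;
    # capped below by what the scene offers (small scenes simply yield
    # fewer candidates, and the designation step enforces its own quotas)
    n_per_class <- stats::setNames(rep(110L, length(truth$classes)),
                                   truth$classes)
  }
  # window-averaged cover rasters (0.5 m ~ 3 px box)
  wc <- lapply(truth$cover, box_smooth, times = 1L)
  nr <- nrow(truth$dominant); nc <- ncol(truth$dominant)
  cm <- vapply(wc, as.vector, numeric(nr * nc))
  best_idx <- max.col(cm, ties.method = "first")
  tcol <- match(target, truth$classes)
  if (is.null(mixed_best_classes))
    mixed_best_classes <- setdiff(truth$classes,
                                  c(target, "senescent_matrix"))
  host_idx <- match(mixed_best_classes, truth$classes)
  mixed_mask <- cm[, tcol] >= acceptable_threshold &
    best_idx %in% host_idx
  # keep a margin so 1 m accuracy squares stay on the raster
  rr <- (seq_len(nr * nc) - 1L) %% nr + 1L
  cc <- (seq_len(nr * nc) - 1L) %/% nr + 1L
  marg_px <- ceiling(1 / truth$pixel_size_m)
  inner <- rr > marg_px & rr <= nr - marg_px & cc > marg_px &
    cc <= nc - marg_px
  pick <- function(mask, n, cap = FALSE) {
    pool <- which(mask & inner)
    if (cap) n <- min(n, length(pool))
    if (length(pool) < n)
      stop("sampling error: only ", length(pool),
           " candidate pixels available where ", n, " were requested")
    if (n == 0L) return(integer(0))
    sample(pool, n)
  }
  sel <- integer()
  for (cls in names(n_per_class)) {
    k <- match(cls, truth$classes)
    if (is.na(k)) stop("unknown class '", cls, "'")
    n <- n_per_class[[cls]]
    if (n > 0) sel <- c(sel, pick(best_idx == k, n, cap = auto_quota))
  }
  if (n_mixed_target > 0)
    sel <- c(sel, pick(mixed_mask, n_mixed_target, cap = auto_quota))
  r <- (sel - 1L) %% nr + 1L
  c2 <- (sel - 1L) %/% nr + 1L
  xy <- rc_to_world(truth, r, c2)
  cov <- cm[sel, , drop = FALSE]
  colnames(cov) <- truth$classes
  lab <- fuzzy_labels(cov, acceptable_threshold)
  jit <- disk_jitter(length(sel), gps_error_m)
  out <- data.frame(
    transect_id = NA_integer_, plot_index = NA_integer_,
    distance_m = NA_real_,
    x = xy[, "x"] + jit[, "dx"], y = xy[, "y"] + jit[, "dy"],
    x_true = xy[, "x"], y_true = xy[, "y"],
    best_class = lab$best, noise_m = jit[, "r"],
    stringsAsFactors = FALSE)
  out$acceptable <- lab$acceptable
  out$cover <- lapply(seq_along(sel), function(i) cov[i, ])
  out$sample_id <- seq_len(nrow(out))
  out$role <- NA_character_
  out
}

#' Split reference samples into training and test sets
#'
#' Reproduces the sample design: a per-class training quota (default 50
#' each of medusahead, clover-brome, ryegrass-brome and vetch, 40 wild oat
#' and 30 each of barbed goatgrass and canarygrass — 300 samples) and a
#' stratified test set (default 50 medusahead-best, 50 non-medusahead and
#' 50 non-medusahead with medusahead acceptable — 150 samples), drawn
#' disjointly.
#'
#' @param samples reference samples (survey plots and/or
#'   [sample_reference_points()] rows combined with `rbind`).
#' @param counts named integer vector of training quotas per best class.
#' @param test_strata integer length-3: medusahead-best, non-medusahead,
#'   non-medusahead-with-medusahead-acceptable test counts.
#' @param target target class.
#' @param seed integer seed.
#' @return list with `training` and `test` data frames; test rows carry a
#'   `stratum` column (`target_best`, `non_target`, `target_acceptable`).
#' @export
designate_sample_sets <- function(samples,
                                  counts = c(medusahead = 50,
                                             clover_brome = 50,
                                             ryegrass_brome = 50,
                                             vetch = 50,
                                             wild_oat = 40,
                                             barbed_goatgrass = 30,
                                             canarygrass = 30),
                                  test_strata = c(50, 50, 50),
                                  target = "medusahead",
                                  seed = 1L) {
  set.seed(seed)
  samples$.row <- seq_len(nrow(samples))
  taken <- rep(FALSE, nrow(samples))
  take <- function(mask, n, what) {
    pool <- which(mask & !taken)
    if (length(pool) < n)
      stop("sampling error: insufficient candidates for ", what,
           " (have ", length(pool), ", need ", n, ")")
    sel <- if (length(pool) == n) pool else sample(pool, n)
    taken[sel] <<- TRUE
    sel
  }
  tr_rows <- integer()
  for (cls in names(counts)) {
    tr_rows <- c(tr_rows, take(samples$best_class == cls, counts[[cls]],
                               paste0("class ", cls)))
  }
  has_acc <- vapply(samples$acceptable, function(a) target %in% a,
                    logical(1))
  te_best <- take(samples$best_class == target, test_strata[1],
                  paste0("test stratum ", target, "-best"))
  te_non <- take(samples$best_class != target & !has_acc, test_strata[2],
                 "test stratum non-target")
  te_acc <- take(samples$best_class != target & has_acc, test_strata[3],
                 "test stratum target-acceptable")
  training <- samples[tr_rows, ]
  training$role <- "training"
  test <- samples[c(te_best, te_non, te_acc), ]
  test$role <- rep("test", nrow(test))
  test$stratum <- rep(c("target_best", "non_target", "target_acceptable"),
                      test_strata)
  training$.row <- NULL; test$.row <- NULL
  list(training = training, test = test)
}

#' @export
dim.scene_truth <- function(x) dim(x$dominant)
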