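# Synthetic grassland scene generation: elliptical patches with soft edges
# laid over a senescent matrix, per-pixel cover fractions normalized to 1,
# archetype texture patterns, and 4-band rendering.

draw_patch_params <- function(cls, n, pm) {
  # diameter categories (m): <=0.5, 0.5-2, 2-7, >7 (capped at 14)
  lo <- c(0.20, 0.5, 2, 7); hi <- c(0.5, 2, 7, 14)
  w <- as.numeric(pm[pm$class == cls, c("w1", "w2", "w3", "w4")])
  cat <- sample.int(4L, n, replace = TRUE, prob = w / sum(w))
  d <- exp(stats::runif(n, log(lo[cat]), log(hi[cat])))
  data.frame(
    class = cls, patch_id = seq_len(n), diameter = d,
    aspect = stats::runif(n, 0.5, 1),
    angle = stats::runif(n, 0, pi),
    cover = stats::runif(n, pm$cover_min[pm$class == cls],
                         pm$cover_max[pm$class == cls]))
}

# soft elliptical cover footprint added into `acc` (pmax accumulation)
add_ellipse <- function(acc, cx, cy, a, b, angle, cover, px, extent) {
  nr <- nrow(acc); nc <- ncol(acc)
  edge_m <- 0.15
  rmax <- max(a, b) + edge_m
  c0 <- max(1L, floor((cx - rmax) / px) + 1L)
  c1 <- min(nc, ceiling((cx + rmax) / px))
  r1 <- min(nr, nr - floor((cy - rmax) / px))
  r0 <- max(1L, nr - ceiling((cy + rmax) / px) + 1L)
  if (c0 > c1 || r0 > r1) return(acc)
  cols <- c0:c1; rows <- r0:r1
  x <- (cols - 0.5) * px; y <- (nr - rows + 0.5) * px
  dx <- outer(rep(1, length(rows)), x - cx)
  dy <- outer(y - cy, rep(1, length(cols)))
  u <- (dx * cos(angle) + dy * sin(angle)) / a
  v <- (-dx * sin(angle) + dy * cos(angle)) / b
  rho <- sqrt(u^2 + v^2)
  en <- edge_m / max(a, b)
  f <- pmin(1, pmax(0, (1 + en - rho) / en)) * cover
  acc[rows, cols] <- pmax(acc[rows, cols], f)
  acc
}

ellipse_polygon <- function(cx, cy, a, b, angle, n = 32L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- cx + a * cos(t) * cos(angle) - b * sin(t) * sin(angle)
  y <- cy + a * cos(t) * sin(angle) + b * sin(t) * cos(angle)
  cbind(x = x, y = y)
}

box_smooth <- function(m, times = 1L) {
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(times)) {
    p <- rbind(m[1, , drop = FALSE], m, m[nr, , drop = FALSE])
    p <- cbind(p[, 1, drop = FALSE], p, p[, nc, drop = FALSE])
    m <- (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
          p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] +
          p[2:(nr + 1), 3:(nc + 2)] +
          p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] +
          p[3:(nr + 2), 3:(nc + 2)]) / 9
  }
  m
}

#' Generate a synthetic 4-band grassland scene with ground truth
#'
#' Draws seeded elliptical patches per class (log-distributed diameters
#' over four length categories, the smallest dominating for the invaders),
#' assembles per-pixel cover fractions that sum to one (the senescent
#' matrix takes the remainder), renders the four camera bands as
#' cover-weighted class colours plus archetype texture (clumps for
#' canarygrass, bright fine mosaic for vetch and ryegrass) and Gaussian
#' noise, and appends the derived NDVI and local Moran's I layers.
#' Medusahead growing under wild oat is rendered with its greenness pulled
#' toward the matrix colour (subcanopy attenuation).
#'
#' @param config a [scene_config()].
#' @param render_bands set `FALSE` to skip band rendering and return only
#'   the truth (fast path for survey-only simulations).
#' @return list with elements `stack` (a [band_stack()] with layers blue,
#'   green, red, nir, ndvi, morans_i — `NULL` if `render_bands = FALSE`)
#'   and `truth` (class `scene_truth`: `cover` named list of per-class
#'   fraction matrices, `dominant` integer matrix indexing
#'   `classes`, `classes`, `patches` data frame with patch geometry and a
#'   `polygon` list-column, `pixel_size_m`, `origin`, `extent_m`).
#' @export
generate_scene <- function(config, render_bands = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  px <- config$pixel_size_m
  nc <- max(2L, round(config$extent_m[1] / px))
  nr <- max(2L, round(config$extent_m[2] / px))
  pal <- config$class_palette
  pm <- config$patch_model
  area_scale <- prod(config$extent_m) / (120 * 120)

  classes <- c("senescent_matrix", pm$class)
  cover <- stats::setNames(
    lapply(classes, function(cl) matrix(0, nr, nc)), classes)

  patches <- list()
  for (cls in pm$class) {
    n <- stats::rpois(1L, pm$n_patches[pm$class == cls] * area_scale)
    if (n == 0) next
    pp <- draw_patch_params(cls, n, pm)
    pp$cx <- stats::runif(n, 0, config$extent_m[1])
    pp$cy <- stats::runif(n, 0, config$extent_m[2])
    pp$subcover <- 0
    nsub <- round(pm$subcover_frac[pm$class == cls] * n)
    if (nsub > 0) {
      idx <- sample.int(n, nsub)
      pp$subcover[idx] <- stats::runif(nsub, config$subcover_range[1],
                                       config$subcover_range[2])
    }
    for (i in seq_len(n)) {
      a <- pp$diameter[i] / 2; b <- a * pp$aspect[i]
      cover[[cls]] <- add_ellipse(cover[[cls]], pp$cx[i], pp$cy[i], a, b,
                                  pp$angle[i], pp$cover[i], px,
                                  config$extent_m)
      if (pp$subcover[i] > 0)
        cover$medusahead <- add_ellipse(cover$medusahead, pp$cx[i],
                                        pp$cy[i], a, b, pp$angle[i],
                                        pp$subcover[i], px,
                                        config$extent_m)
    }
    pp$polygon <- lapply(seq_len(n), function(i)
      ellipse_polygon(pp$cx[i], pp$cy[i], pp$diameter[i] / 2,
                      pp$diameter[i] / 2 * pp$aspect[i], pp$angle[i]))
    patches[[cls]] <- pp
  }
  patches <- if (length(patches)) do.call(rbind, patches) else
    data.frame(class = character(), patch_id = integer())
  rownames(patches) <- NULL

  # normalize: green fractions share the pixel; matrix takes the rest
  green_total <- Reduce(`+`, cover[-1], accumulate = FALSE)
  over <- pmax(green_total, 1)
  for (cls in pm$class) cover[[cls]] <- cover[[cls]] / over
  cover$senescent_matrix <- 1 - Reduce(`+`, cover[-1])

  cm <- vapply(cover, as.vector, numeric(nr * nc))  # (nr*nc) x nclass
  dominant <- matrix(max.col(cm, ties.method = "first"), nr, nc)

  truth <- structure(
    list(cover = cover, dominant = dominant, classes = classes,
         patches = patches, pixel_size_m = px, origin = c(0, 0),
         extent_m = config$extent_m),
    class = "scene_truth")

  if (!render_bands)
    return(list(stack = NULL, truth = truth))

  # archetype pattern fields (one spatial field per non-uniform class)
  pattern <- list()
  speckle2 <- list()   # within-clump speckle for clumped classes
  for (cls in pm$class) {
    arch <- pal$archetype[pal$class == cls]
    if (arch == "clumped") {
      f <- box_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 2L)
      pattern[[cls]] <- (f > stats::quantile(f, 0.55)) * 1   # clump mask
      if (pal$mosaic_amp[pal$class == cls] > 0)
        speckle2[[cls]] <- matrix(stats::runif(nr * nc, -1.7, 1.7), nr, nc)
    } else if (arch == "fine_mosaic") {
      # short-range correlated bright/dark mosaic, unit variance
      f <- box_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 1L)
      pattern[[cls]] <- f / stats::sd(f)
    } else if (arch == "speckle") {
      # pixel-scale iid speckle with a flat marginal: raises within-object
      # variance and co-occurrence entropy without creating resolvable
      # sub-structure for the segmenter
      pattern[[cls]] <- matrix(stats::runif(nr * nc, -1.7, 1.7), nr, nc)
    }
  }

  # large-scale multiplicative brightness field (biomass/illumination
  # variation at a few metres' scale): gives smooth objects a dominant
  # gentle gradient, so their co-occurrence structure stays near-diagonal
  bf <- box_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 10L)
  bf <- 1 + 0.12 * bf / stats::sd(bf)

  oat <- if (!is.null(cover$wild_oat)) cover$wild_oat else matrix(0, nr, nc)
  att <- config$oat_attenuation * pmin(1, oat / 0.5)
  matrix_row <- pal[pal$class == "senescent_matrix", ]

  bands <- list()
  for (b in c("blue", "green", "red", "nir")) {
    img <- matrix(0, nr, nc)
    sd_eff <- matrix(0, nr, nc)
    for (cls in classes) {
      prow <- pal[pal$class == cls, ]
      mean_field <- matrix(prow[[b]], nr, nc)
      arch <- prow$archetype
      if (arch == "clumped") {
        cl <- pattern[[cls]]
        clump_col <- prow[[b]]
        mb <- if (!is.null(prow$mosaic_bands) && nzchar(prow$mosaic_bands))
          strsplit(prow$mosaic_bands, ",")[[1]] else character(0)
        if (prow$mosaic_amp > 0 && b %in% mb)
          clump_col <- clump_col * (1 + prow$mosaic_amp * speckle2[[cls]])
        mean_field <- cl * clump_col + (1 - cl) * matrix_row[[b]]
      } else if (arch %in% c("fine_mosaic", "speckle")) {
        mb <- if (!is.null(prow$mosaic_bands) && nzchar(prow$mosaic_bands))
          strsplit(prow$mosaic_bands, ",")[[1]] else
            c("blue", "green", "red", "nir")
        if (b %in% mb)
          mean_field <- prow[[b]] * (1 + prow$mosaic_amp * pattern[[cls]])
      }
      if (cls == "medusahead")
        mean_field <- (1 - att) * mean_field + att * matrix_row[[b]]
      img <- img + cover[[cls]] * mean_field
      sd_eff <- sd_eff + cover[[cls]] * prow$noise_sd
    }
    # spatially correlated canopy noise (smooth component + sensor iid):
    # vegetation brightness varies smoothly at 0.15 m; pure iid noise
    # would make every large object maximally entropic after per-object
    # quantization
    zs <- box_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 1L)
    zs <- zs / stats::sd(zs)
    zi <- matrix(stats::rnorm(nr * nc), nr, nc)
    img <- img * bf + (0.9 * zs + 0.436 * zi) * sd_eff
    bands[[b]] <- pmin(pmax(img, 0.001), 1)  # reflectance floor; keeps NDVI defined
  }

  stack <- band_stack(bands, px, origin = c(0, 0))
  stack <- add_derived_layers(stack)
  list(stack = stack, truth = truth)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %.0f x %.0f m @ %.2f m, %d patches, %d classes\n",
              x$extent_m[1], x$extent_m[2], x$pixel_size_m,
              nrow(x$patches), length(x$classes)))
  invisible(x)
}

#' Write ground-truth patch outlines as GeoJSON
#'
#' @param truth a `scene_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_polygons <- function(truth, path) {
  feats <- lapply(seq_len(nrow(truth$patches)), function(i) {
    p <- truth$patches[i, ]
    ring <- rbind(p$polygon[[1]], p$polygon[[1]][1, , drop = FALSE])
    list(type = "Feature",
         properties = list(class = p$class, patch_id = p$patch_id,
                           diameter_m = p$diameter),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(j) as.numeric(ring[j, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
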