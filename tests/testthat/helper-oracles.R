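# Independent brute-force oracles and small fixture builders shared by the
# test files.  Oracles deliberately use naive formulations (double loops,
# exhaustive enumeration) independent of the package's implementation path.

# local Moran's I by direct double-loop evaluation of the formula
naive_morans <- function(layer, window = 3L) {
  nr <- nrow(layer); nc <- ncol(layer)
  xbar <- mean(layer)
  s2 <- mean((layer - xbar)^2)
  r <- (window - 1L) %/% 2L
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc)
        acc <- acc + (layer[i2, j2] - xbar)
    }
    out[i, j] <- (layer[i, j] - xbar) / s2 * acc
  }
  out
}

# multi-level Otsu by direct evaluation of the between-class variance
# (weighted squared deviation of class means from the global mean) for
# every candidate threshold tuple
naive_otsu <- function(values, n_classes, bins) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE),
                   1L), bins)
  counts <- tabulate(idx, nbins = bins)
  mids <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  p <- counts / sum(counts)
  mu_t <- sum(p * mids)
  class_score <- function(sel) {
    w <- sum(p[sel])
    if (w == 0) return(NA_real_)
    mu <- sum(p[sel] * mids[sel]) / w
    w * (mu - mu_t)^2
  }
  best <- -Inf; best_thr <- NULL
  if (n_classes == 2L) {
    for (i in seq_len(bins - 1L)) {
      s <- class_score(1:i) + class_score((i + 1L):bins)
      if (!is.na(s) && s > best) { best <- s; best_thr <- edges[i + 1L] }
    }
  } else {
    for (i in seq_len(bins - 2L)) for (j in (i + 1L):(bins - 1L)) {
      s <- class_score(1:i) + class_score((i + 1L):j) +
        class_score((j + 1L):bins)
      if (!is.na(s) && s > best) {
        best <- s; best_thr <- edges[c(i, j) + 1L]
      }
    }
  }
  best_thr
}

# GLCM entropy by naive enumeration of every within-mask pixel pair
naive_glcm_entropy <- function(layer, mask, levels = 64L,
                               directions = c("0", "45", "90", "135")) {
  vals <- layer[mask]
  rng <- range(vals)
  q <- matrix(NA_integer_, nrow(layer), ncol(layer))
  if (rng[2] > rng[1]) {
    q[mask] <- pmin(levels,
                    floor((vals - rng[1]) / (rng[2] - rng[1]) * levels) + 1L)
  } else q[mask] <- 1L
  offs <- list("0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(-1L, 0L),
               "135" = c(-1L, -1L))[directions]
  counts <- matrix(0, levels, levels)
  nr <- nrow(layer); nc <- ncol(layer)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    for (o in offs) {
      i2 <- i + o[1]; j2 <- j + o[2]
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc || !mask[i2, j2]) next
      a <- q[i, j]; b <- q[i2, j2]
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

# mean within-object sd averaged over layers, naive
naive_object_lv <- function(layers, labels) {
  ids <- sort(unique(labels[labels > 0]))
  mean(vapply(layers, function(m) {
    mean(vapply(ids, function(id) {
      v <- m[labels == id]
      sqrt(max(0, mean(v^2) - mean(v)^2))
    }, numeric(1)))
  }, numeric(1)))
}

# a tiny band stack with specified constant bands plus optional noise
toy_stack <- function(nr = 10, nc = 10, nir = 0.5, red = 0.2,
                      green = 0.2, blue = 0.1, noise = 0, seed = 1,
                      pixel_size_m = 0.15) {
  set.seed(seed)
  mk <- function(v) matrix(v, nr, nc) +
    matrix(stats::rnorm(nr * nc, 0, noise), nr, nc)
  band_stack(list(blue = mk(blue), green = mk(green), red = mk(red),
                  nir = mk(nir)), pixel_size_m = pixel_size_m)
}

# a single-object segmentation level covering a full grid
trivial_level <- function(nr, nc) {
  structure(list(labels = matrix(1L, nr, nc), n_objects = 1L,
                 scale = 1, shape_w = 0.1, cmpct_w = 0.1,
                 weights = 1, parent_map = NULL),
            class = "segmentation_level")
}

# classification result painted directly from a class raster (integer
# matrix indexing `classes`), bypassing segmentation — for evaluation and
# transect fixtures
painted_result <- function(class_raster, classes, pixel_size_m = 0.15,
                           target = "medusahead", method = "painted") {
  structure(
    list(method = method, scheme = "fixture", features = "fixture",
         assignments = data.frame(object_id = integer(),
                                  class = character()),
         classes = classes, class_raster = class_raster,
         target = target, pixel_size_m = pixel_size_m, origin = c(0, 0)),
    class = "classification_result")
}

# reference-sample rows for evaluation fixtures
make_samples <- function(x, y, best, acceptable = NULL) {
  n <- length(x)
  if (is.null(acceptable)) acceptable <- replicate(n, character(0),
                                                   simplify = FALSE)
  df <- data.frame(sample_id = seq_len(n), x = x, y = y,
                   best_class = best, stringsAsFactors = FALSE)
  df$acceptable <- acceptable
  df
}
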