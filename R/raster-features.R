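#' Normalized difference vegetation index
#'
#' NDVI = (NIR - red) / (NIR + red), the greenness proxy used throughout the
#' workflow: green invader patches stand out against the senescent-grass
#' matrix at the late-spring acquisition date.
#'
#' @param stack a [band_stack()] with `nir` and `red` layers, or a list of
#'   two matrices named `nir` and `red`.
#' @return a matrix in `[-1, 1]`; `NA` where `nir + red == 0` or either
#'   input is nodata.
#' @export
ndvi <- function(stack) {
  bands <- if (inherits(stack, "band_stack")) stack$bands else stack
  if (is.null(bands$nir) || is.null(bands$red))
    stop("NDVI needs both 'nir' and 'red' layers")
  s <- bands$nir + bands$red
  out <- (bands$nir - bands$red) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

#' Local Moran's I in a moving window
#'
#' Per-pixel spatial autocorrelation used as a local-heterogeneity layer for
#' segmentation.  For pixel i,
#' \deqn{I_i = \frac{x_i - \bar x}{s^2} \sum_j w_{ij} (x_j - \bar x)}
#' with the mean and variance taken globally over the layer and binary
#' weights \eqn{w_{ij} = 1} for every other pixel inside the moving window
#' (the 8 neighbours for the default 3x3 window).  Edge pixels use the
#' neighbours that exist.  `s^2` is the population variance.
#'
#' Row-standardized weights (each pixel's weights summing to 1) are
#' available via `row_standardize = TRUE` for comparison with other
#' conventions.
#'
#' @param layer numeric matrix (`NA` = nodata; excluded from the global
#'   moments and from neighbour sums).
#' @param window odd window size >= 3.
#' @param row_standardize divide each neighbour sum by the number of
#'   available neighbours.
#' @return matrix of local Moran's I values; `NA` where the input is `NA`.
#' @export
local_morans_i <- function(layer, window = 3L, row_standardize = FALSE) {
  if (window %% 2L != 1L || window < 3L)
    stop("`window` must be an odd integer >= 3")
  ok <- !is.na(layer)
  xbar <- mean(layer[ok])
  s2 <- mean((layer[ok] - xbar)^2)
  if (s2 == 0)
    stop("degenerate input: layer has zero variance")
  dev <- layer - xbar
  dev0 <- dev
  dev0[!ok] <- 0
  nr <- nrow(layer); nc <- ncol(layer)
  r <- (window - 1L) %/% 2L
  nbr_sum <- matrix(0, nr, nc)
  nbr_n <- matrix(0, nr, nc)
  okn <- ok * 1
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0L && dj == 0L) next
    rs <- max(1L, 1L - di):min(nr, nr - di)   # destination rows
    cs <- max(1L, 1L - dj):min(nc, nc - dj)
    nbr_sum[rs, cs] <- nbr_sum[rs, cs] + dev0[rs + di, cs + dj]
    nbr_n[rs, cs] <- nbr_n[rs, cs] + okn[rs + di, cs + dj]
  }
  w <- if (row_standardize) ifelse(nbr_n > 0, nbr_sum / nbr_n, 0) else nbr_sum
  out <- dev / s2 * w
  out[!ok] <- NA_real_
  out
}

#' Multi-level Otsu thresholds
#'
#' Finds the 1 or 2 thresholds that maximize the between-class variance of
#' the discretized histogram — the automatic greenness thresholding used to
#' split vegetation associations into NDVI tiers.  The search is exhaustive
#' over all threshold tuples (evaluated via cumulative moment sums), so the
#' returned tuple is the global optimum; ties are broken toward the
#' smallest tuple.
#'
#' @param values numeric vector of observations, or an object of class
#'   `histogram` (as from [graphics::hist()]).
#' @param n_classes 2 or 3.
#' @param bins number of uniform histogram bins over the observed range
#'   (ignored when `values` is already a histogram).
#' @return numeric vector of `n_classes - 1` thresholds (bin-edge values),
#'   strictly inside the observed range.
#' @export
otsu_thresholds <- function(values, n_classes = 2L, bins = 256L) {
  if (!n_classes %in% c(2L, 3L))
    stop("`n_classes` must be 2 or 3")
  if (inherits(values, "histogram")) {
    counts <- values$counts
    mids <- values$mids
    edges <- values$breaks
  } else {
    values <- values[!is.na(values)]
    if (length(unique(values)) < n_classes)
      stop("degenerate input: fewer distinct values (",
           length(unique(values)), ") than classes (", n_classes, ")")
    rng <- range(values)
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    idx <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE),
                     1L), bins)
    counts <- tabulate(idx, nbins = bins)
    mids <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  }
  nb <- length(counts)
  p <- counts / sum(counts)
  cw <- cumsum(p)                 # class weight up to bin i
  cm <- cumsum(p * mids)          # first moment up to bin i
  # maximize sum_k w_k mu_k^2  ==  sum_k (m_k)^2 / w_k
  score2 <- function(i) {         # split after bin i (2 classes)
    w1 <- cw[i]; w2 <- 1 - w1
    m1 <- cm[i]; m2 <- cm[nb] - m1
    ifelse(w1 > 0 & w2 > 0, m1^2 / w1 + m2^2 / w2, -Inf)
  }
  if (n_classes == 2L) {
    sc <- score2(seq_len(nb - 1L))
    best <- which.max(sc)         # which.max returns the first (smallest) tie
    return(edges[best + 1L])
  }
  best_sc <- -Inf; best_ij <- c(NA_integer_, NA_integer_)
  for (i in seq_len(nb - 2L)) {
    w1 <- cw[i]; m1 <- cm[i]
    if (w1 == 0) next
    j <- (i + 1L):(nb - 1L)
    w2 <- cw[j] - w1; m2 <- cm[j] - m1
    w3 <- 1 - cw[j]; m3 <- cm[nb] - cm[j]
    sc <- ifelse(w2 > 0 & w3 > 0,
                 m1^2 / w1 + m2^2 / w2 + m3^2 / w3, -Inf)
    k <- which.max(sc)
    if (sc[k] > best_sc) {
      best_sc <- sc[k]
      best_ij <- c(i, j[k])
    }
  }
  if (!is.finite(best_sc))
    stop("degenerate input: histogram cannot be split into 3 classes")
  edges[best_ij + 1L]
}
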