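#' Multi-band raster container
#'
#' A `band_stack` holds co-registered raster layers (matrices sharing one
#' grid) for a very-high-resolution VNIR scene: the four camera bands
#' (`blue`, `green`, `red`, `nir`) and, once computed, the derived layers
#' `ndvi` and `morans_i`.  The grid is stored row 1 = northern edge; world
#' coordinates are metres with the origin at the lower-left corner of the
#' raster.
#'
#' @param bands named list of numeric matrices, all the same dimension.
#'   `NA` cells mark nodata (e.g. masked trees/wetland).
#' @param pixel_size_m grid spacing in metres (default 0.15).
#' @param origin numeric length-2, world coordinates (x, y) of the
#'   lower-left corner.
#'
#' @return an object of class `band_stack`.
#' @export
band_stack <- function(bands, pixel_size_m = 0.15, origin = c(0, 0)) {
  if (!is.list(bands) || is.null(names(bands)) || any(names(bands) == ""))
    stop("`bands` must be a named list of matrices")
  dims <- lapply(bands, dim)
  if (length(unique(dims)) != 1L)
    stop("all bands must share the same dimensions")
  if (!is.numeric(pixel_size_m) || pixel_size_m <= 0)
    stop("`pixel_size_m` must be positive")
  structure(
    list(bands = bands, pixel_size_m = pixel_size_m,
         origin = as.numeric(origin)),
    class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<band_stack> %d x %d px @ %.2f m  (%.1f x %.1f m)\n",
              d[1], d[2], x$pixel_size_m,
              d[2] * x$pixel_size_m, d[1] * x$pixel_size_m))
  cat("  layers:", paste(names(x$bands), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.band_stack <- function(x) dim(x$bands[[1]])

#' Extract a layer from a band stack
#'
#' @param stack a [band_stack()].
#' @param layer layer name.
#' @return the layer matrix.
#' @export
get_layer <- function(stack, layer) {
  if (!layer %in% names(stack$bands))
    stop("band stack has no layer '", layer, "'")
  stack$bands[[layer]]
}

#' Extent of a band stack in world coordinates
#'
#' @param stack a [band_stack()].
#' @return named numeric: `xmin`, `xmax`, `ymin`, `ymax` in metres.
#' @export
stack_extent <- function(stack) {
  d <- dim(stack)
  c(xmin = stack$origin[1],
    xmax = stack$origin[1] + d[2] * stack$pixel_size_m,
    ymin = stack$origin[2],
    ymax = stack$origin[2] + d[1] * stack$pixel_size_m)
}

#' Convert world coordinates to raster row/col indices
#'
#' Points on the raster boundary are clamped inward so that the extent edge
#' maps to the edge pixel.
#'
#' @param stack a [band_stack()] (or any object with `pixel_size_m`,
#'   `origin` and a `dim()`).
#' @param x,y world coordinates in metres.
#' @return a two-column integer matrix (row, col); `NA` rows for points
#'   outside the extent.
#' @export
world_to_rc <- function(stack, x, y) {
  d <- dim(stack)
  px <- stack$pixel_size_m
  col <- floor((x - stack$origin[1]) / px) + 1L
  row <- d[1] - floor((y - stack$origin[2]) / px)
  # clamp exact upper-edge coordinates into the boundary pixel
  col[x == stack$origin[1] + d[2] * px] <- d[2]
  row[y == stack$origin[2] + d[1] * px] <- 1L
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Convert raster row/col indices to world coordinates of pixel centres
#'
#' @inheritParams world_to_rc
#' @param row,col raster indices.
#' @return two-column matrix of (x, y) in metres.
#' @export
rc_to_world <- function(stack, row, col) {
  d <- dim(stack)
  px <- stack$pixel_size_m
  cbind(x = stack$origin[1] + (col - 0.5) * px,
        y = stack$origin[2] + (d[1] - row + 0.5) * px)
}

#' Append the derived NDVI and local Moran's I layers
#'
#' Adds `ndvi` and `morans_i` to the stack; these two derived layers join
#' the four camera bands as segmentation inputs.  Moran's I is computed on
#' the NDVI layer by default (configurable), in a 3x3 window.
#'
#' @param stack a [band_stack()] with the four camera bands.
#' @param morans_on layer the local Moran's I is computed on.
#' @param window odd window size for Moran's I.
#' @return the stack with `ndvi` and `morans_i` layers added.
#' @export
add_derived_layers <- function(stack, morans_on = "ndvi", window = 3L) {
  stack$bands$ndvi <- ndvi(stack)
  stack$bands$morans_i <- local_morans_i(get_layer(stack, morans_on), window)
  stack
}

#' Write a band stack to a multi-band TIFF with a georeference sidecar
#'
#' Layers are written in the order given (default B, G, R, NIR followed by
#' any derived layers) as a multi-page 32-bit float TIFF, one page per
#' layer; the pixel size, origin and band order go to `<path>.json` so the
#' stack round-trips losslessly.
#'
#' @param stack a [band_stack()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_band_stack <- function(stack, path) {
  pages <- lapply(stack$bands, function(m) { m[is.na(m)] <- -9999; m })
  # float pages may hold values outside [0,1] (Moran's I, nodata); the
  # writer warns but stores IEEE floats losslessly
  suppressWarnings(
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE))
  meta <- list(pixel_size_m = stack$pixel_size_m, origin = stack$origin,
               layers = names(stack$bands), nodata = -9999)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a band stack written by [write_band_stack()]
#'
#' @param path path to the `.tif` file.
#' @return a [band_stack()].
#' @export
read_band_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  bands <- lapply(seq_along(meta$layers), function(i) {
    m <- pages[[i]]
    m[m == meta$nodata] <- NA_real_
    m
  })
  names(bands) <- meta$layers
  band_stack(bands, meta$pixel_size_m, meta$origin)
}
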