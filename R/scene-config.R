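#' Vegetation classes of the grassland scene
#'
#' The seven vegetation categories of the detailed classification scheme
#' plus the senescent-grass matrix that dominates the site at the
#' late-spring acquisition date.
#'
#' @return character vector of class names (matrix first).
#' @export
scene_classes <- function() {
  c("senescent_matrix", "medusahead", "barbed_goatgrass", "clover_brome",
    "ryegrass_brome", "canarygrass", "vetch", "wild_oat")
}

#' Default per-class reflectance palette
#'
#' Mean reflectance per band (unitless, `[0, 1]`), within-class noise sd and
#' a texture archetype per class.  The values are free parameters chosen to
#' reproduce the qualitative structure of a late-spring Californian annual
#' grassland: a senescent matrix with near-zero NDVI; green medusahead with
#' high NIR; barbed goatgrass spectrally close to medusahead; clover-brome
#' at intermediate greenness; ryegrass-brome and vetch as heterogeneous
#' fine mosaics (vetch very bright); canarygrass as disaggregated green
#' clumps within senescent gaps; wild oat as a senescent taller grass that
#' can hide medusahead in its subcanopy.
#'
#' Texture archetypes: `uniform` (iid noise only), `clumped` (green clumps
#' alternating with matrix-coloured gaps at ~0.45 m scale) and
#' `fine_mosaic` (high-frequency bright/dark alternation).
#'
#' @return data frame with columns `class`, `blue`, `green`, `red`, `nir`,
#'   `noise_sd`, `archetype`, `mosaic_amp` (relative amplitude of the
#'   mosaic/clump pattern).
#' @export
default_palette <- function() {
  data.frame(
    class = scene_classes(),
    blue  = c(0.10, 0.05, 0.05, 0.06, 0.06, 0.05, 0.07, 0.09),
    green = c(0.22, 0.16, 0.15, 0.18, 0.17, 0.16, 0.25, 0.20),
    red   = c(0.30, 0.10, 0.11, 0.15, 0.14, 0.11, 0.12, 0.28),
    nir   = c(0.30, 0.55, 0.52, 0.45, 0.47, 0.53, 0.60, 0.33),
    noise_sd = c(0.02, 0.02, 0.02, 0.02, 0.03, 0.02, 0.03, 0.02),
    archetype = c("uniform", "uniform", "uniform", "uniform",
                  "fine_mosaic", "speckle", "speckle", "uniform"),
    mosaic_amp = c(0, 0, 0, 0, 0.35, 0.5, 0.45, 0),
    # vetch: bright flat-histogram speckle on the NIR band (high NIR GLCM
    # entropy); canarygrass tufts as a green/blue-band speckle (high green
    # GLCM entropy); empty = pattern on all four bands
    mosaic_bands = c("", "", "", "", "", "green,blue", "nir", ""),
    stringsAsFactors = FALSE)
}

#' Default patch model
#'
#' Per-class patch counts (for the default 120 m x 120 m extent; scaled by
#' area for other extents) and weights of the four patch-diameter
#' categories (<= 0.5, 0.5-2, 2-7, > 7 m).  Medusahead weights put roughly
#' three times as many patches in the smallest category as in either middle
#' category, matching the right-skewed field patch-size distribution.
#' `subcover_frac` is the fraction of a class's patches that carry
#' low-density medusahead underneath (mixed-cover plots); `cover_min/max`
#' bound the within-patch cover of the patch's own class.
#'
#' @return data frame, one row per non-matrix class.
#' @export
default_patch_model <- function() {
  data.frame(
    class = c("medusahead", "barbed_goatgrass", "clover_brome",
              "ryegrass_brome", "canarygrass", "vetch", "wild_oat"),
    n_patches = c(70, 16, 14, 8, 10, 6, 12),
    w1 = c(3, 3, 0, 0, 0, 0, 0),
    w2 = c(1, 1, 1, 1, 1, 0, 1),
    w3 = c(1, 1, 2, 2, 2, 2, 2),
    w4 = c(0.3, 0.1, 2, 1, 1, 1, 1),
    cover_min = c(0.55, 0.60, 0.70, 0.70, 0.85, 0.80, 0.75),
    cover_max = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
    subcover_frac = c(0, 0, 0.5, 0.25, 0, 0, 0.4),
    stringsAsFactors = FALSE)
}

#' Scene configuration
#'
#' Bundles everything [generate_scene()] needs: extent, grid spacing, class
#' palette, patch model, mixing rules and the seed.
#'
#' @param extent_m numeric length-2, scene width and height in metres.
#' @param pixel_size_m grid spacing in metres (default 0.15).
#' @param class_palette as [default_palette()]; must cover every class in
#'   `patch_model` plus the matrix.
#' @param patch_model as [default_patch_model()].  `n_patches` is taken as
#'   counts for a 120 x 120 m scene and scaled by relative area.
#' @param subcover_range medusahead cover range for subcanopy/mixed
#'   patches.
#' @param oat_attenuation greenness down-weighting of medusahead growing
#'   under wild oat: its rendered colour is pulled toward the matrix colour
#'   by this factor where wild oat is present.
#' @param gps_error_m positional noise radius applied to surveyed sample
#'   locations.
#' @param seed integer seed; fixed (config, seed) reproduce the scene
#'   bit-identically.
#'
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(extent_m = c(120, 120), pixel_size_m = 0.15,
                         class_palette = default_palette(),
                         patch_model = default_patch_model(),
                         subcover_range = c(0.05, 0.35),
                         oat_attenuation = 0.6,
                         gps_error_m = 0.3,
                         seed = 1L) {
  if (any(extent_m <= 0)) stop("`extent_m` must be positive")
  if (pixel_size_m <= 0) stop("`pixel_size_m` must be positive")
  missing <- setdiff(c("senescent_matrix", patch_model$class),
                     class_palette$class)
  if (length(missing))
    stop("configuration error: palette missing class(es): ",
         paste(missing, collapse = ", "))
  structure(
    list(extent_m = as.numeric(extent_m), pixel_size_m = pixel_size_m,
         class_palette = class_palette, patch_model = patch_model,
         subcover_range = subcover_range, oat_attenuation = oat_attenuation,
         gps_error_m = gps_error_m, seed = as.integer(seed)),
    class = "scene_config")
}

#' Benchmark scene configurations
#'
#' Two fixed study conditions used by the validation suite:
#' `detection_benchmark_config()` is the clean detection-recovery
#' condition — every class palette well separated (barbed goatgrass and
#' canarygrass pulled away from medusahead, canarygrass rendered uniform),
#' understory medusahead only beneath clover-brome (which supplies the
#' mixed-plot test stratum while staying spectrally distinct);
#' `texture_benchmark_config()` is the texture-necessity condition —
#' canarygrass shares medusahead's band means exactly and differs only in
#' its local pattern (pixel-scale speckle raising within-object variance),
#' so the two classes are inseparable on spectral features alone.
#'
#' @param seed integer seed.
#' @param extent_m scene extent (m).
#' @return a [scene_config()].
#' @export
detection_benchmark_config <- function(seed = 1L,
                                       extent_m = c(120, 120)) {
  pal <- default_palette()
  pal[pal$class == "barbed_goatgrass", c("red", "nir")] <- c(0.20, 0.42)
  pal[pal$class == "canarygrass", c("red", "nir")] <- c(0.16, 0.47)
  pal$archetype[pal$class == "canarygrass"] <- "uniform"
  pm <- default_patch_model()
  pm$subcover_frac <- ifelse(pm$class == "clover_brome", 0.5, 0)
  pm$cover_min <- 0.9          # dense patches: class mixtures stay mild
  scene_config(extent_m = extent_m, class_palette = pal,
               patch_model = pm, subcover_range = c(0.05, 0.15),
               seed = seed)
}

#' @rdname detection_benchmark_config
#' @export
texture_benchmark_config <- function(seed = 1L,
                                     extent_m = c(120, 120)) {
  pal <- default_palette()
  mh <- pal[pal$class == "medusahead", c("blue", "green", "red", "nir")]
  pal[pal$class == "canarygrass", c("blue", "green", "red", "nir")] <- mh
  pal$archetype[pal$class == "canarygrass"] <- "speckle"
  pal$mosaic_amp[pal$class == "canarygrass"] <- 0.4
  pal$mosaic_bands[pal$class == "canarygrass"] <- "green,blue"
  pal[pal$class == "barbed_goatgrass", c("red", "nir")] <- c(0.20, 0.42)
  pm <- default_patch_model()
  pm$subcover_frac <- 0
  pm$cover_min <- 0.95         # dense stands: texture is the only contrast
  pm[pm$class == "canarygrass", c("n_patches", "w2", "w3", "w4")] <-
    c(14, 1, 2, 1)
  scene_config(extent_m = extent_m, class_palette = pal,
               patch_model = pm, seed = seed)
}

#' Spillover benchmark configuration
#'
#' Study condition for contrasting hierarchical and single-run
#' classification: a few large (7-14 m) vetch-mosaic regions rendered as a
#' bright heterogeneous NIR mosaic whose internal bright/dark mixture
#' passes through the medusahead colour range — a single-run classifier
#' therefore places some medusahead inside the mosaic ("spillover"), while
#' the hierarchical workflow isolates the whole mosaic by its coarse-level
#' NIR entropy before any medusahead assignment.  Medusahead never
#' co-occurs with the mosaic (no understory mixing).
#'
#' @param seed integer seed.
#' @param extent_m scene extent (m).
#' @return a [scene_config()].
#' @export
spillover_benchmark_config <- function(seed = 1L,
                                       extent_m = c(120, 120)) {
  pal <- default_palette()
  pal[pal$class == "barbed_goatgrass", c("red", "nir")] <- c(0.20, 0.42)
  pal[pal$class == "canarygrass", c("red", "nir")] <- c(0.16, 0.47)
  pal$archetype[pal$class == "canarygrass"] <- "uniform"
  pal[pal$class == "vetch", "nir"] <- 0.62
  pal$archetype[pal$class == "vetch"] <- "speckle"
  pal$mosaic_amp[pal$class == "vetch"] <- 0.45
  pal$mosaic_bands[pal$class == "vetch"] <- "nir"
  pm <- default_patch_model()
  pm$subcover_frac <- 0
  pm$cover_min <- 0.9
  pm[pm$class == "vetch", c("n_patches", "w1", "w2", "w3", "w4")] <-
    c(4, 0, 0, 0, 1)
  scene_config(extent_m = extent_m, class_palette = pal,
               patch_model = pm, seed = seed)
}

#' Read or write a scene configuration as YAML
#'
#' @param config a [scene_config()].
#' @param path file path.
#' @return `write_scene_config` returns `path` invisibly;
#'   `read_scene_config` returns a `scene_config`.
#' @export
write_scene_config <- function(config, path) {
  x <- unclass(config)
  x$class_palette <- as.list(x$class_palette)
  x$patch_model <- as.list(x$patch_model)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  x <- yaml::read_yaml(path)
  scene_config(
    extent_m = unlist(x$extent_m), pixel_size_m = x$pixel_size_m,
    class_palette = as.data.frame(x$class_palette,
                                  stringsAsFactors = FALSE),
    patch_model = as.data.frame(x$patch_model, stringsAsFactors = FALSE),
    subcover_range = unlist(x$subcover_range),
    oat_attenuation = x$oat_attenuation,
    gps_error_m = x$gps_error_m, seed = x$seed)
}
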