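# Plain-text artifact writers: GeoJSON for survey geometry and classified
# extents, CSV for object tables and reports.

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

write_geojson <- function(features, path) {
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = features),
                       path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write survey transects and segments as GeoJSON
#'
#' Transects become LineString features; field segments become
#' LineString fragments positioned along their transect.
#'
#' @param survey output of [simulate_field_survey()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey_geojson <- function(survey, path) {
  tr <- survey$transects
  feats <- lapply(seq_len(nrow(tr)), function(i) {
    t <- tr[i, ]
    geojson_feature(
      list(type = "LineString",
           coordinates = list(c(t$x0, t$y0),
                              c(t$x0 + t$length_m * t$ux,
                                t$y0 + t$length_m * t$uy))),
      list(id = t$id, group_id = t$group_id, kind = "transect"))
  })
  seg <- survey$segments
  feats2 <- lapply(seq_len(nrow(seg)), function(i) {
    s <- seg[i, ]
    t <- tr[tr$id == s$transect_id, ]
    geojson_feature(
      list(type = "LineString",
           coordinates = list(c(t$x0 + s$start_m * t$ux,
                                t$y0 + s$start_m * t$uy),
                              c(t$x0 + s$end_m * t$ux,
                                t$y0 + s$end_m * t$uy))),
      list(transect_id = s$transect_id, length_m = s$length_m,
           kind = "field_segment"))
  })
  write_geojson(c(feats, feats2), path)
}

#' Write reference samples as GeoJSON points
#'
#' @param samples reference-sample data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples_geojson <- function(samples, path) {
  feats <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    geojson_feature(
      list(type = "Point", coordinates = c(s$x, s$y)),
      list(sample_id = s$sample_id, best_class = s$best_class,
           acceptable = paste(s$acceptable[[1]], collapse = ";"),
           role = s$role, noise_m = s$noise_m))
  })
  write_geojson(feats, path)
}

#' Write a classification result to disk
#'
#' The class raster goes to `<path>.tif` (integer labels as a float TIFF
#' with a JSON sidecar naming the classes), the object assignments to
#' `<path>_objects.csv` and the method metadata to `<path>.json`.
#'
#' @param result a [classification_result()].
#' @param path output path stem.
#' @return `path`, invisibly.
#' @export
write_classification <- function(result, path) {
  arr <- result$class_raster
  tiff::writeTIFF(arr / max(1, max(arr)), paste0(path, ".tif"),
                  bits.per.sample = 32L)
  utils::write.csv(result$assignments, paste0(path, "_objects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(method = result$method, scheme = result$scheme,
         features = result$features, classes = result$classes,
         target = result$target, pixel_size_m = result$pixel_size_m,
         raster_scale = max(1, max(arr))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
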