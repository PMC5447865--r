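# Validation of classified medusahead extents against field transect
# segments, by patch-length category.

length_categories <- function() {
  list(breaks = c(0, 0.5, 2, 7, Inf),
       labels = c("<=0.5", "0.5-2", "2-7", ">7"))
}

categorize_lengths <- function(lengths) {
  lc <- length_categories()
  # closed upper bounds: lengths exactly 0.5, 2, 7 fall in the lower class
  cut(lengths, breaks = lc$breaks, labels = lc$labels, right = TRUE,
      include.lowest = TRUE)
}

interval_stats <- function(lengths) {
  cat <- as.character(categorize_lengths(lengths))
  lc <- length_categories()
  data.frame(
    category = lc$labels,
    count = vapply(lc$labels, function(l) sum(cat == l), integer(1)),
    mean_length_m = vapply(lc$labels, function(l) {
      v <- lengths[cat == l]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)))
}

#' Classified target runs along a transect
#'
#' Samples the class raster along the transect line at half-pixel steps,
#' extracts maximal runs of the target class and merges runs separated by
#' gaps of at most `merge_gap_m` (the 20 cm field convention, reused on
#' the classified side for comparability).
#'
#' @param result a [classification_result()].
#' @param transects transect data frame (`x0`, `y0`, `ux`, `uy`,
#'   `length_m`, `id`) as from [simulate_field_survey()].
#' @param merge_gap_m gap below which adjacent runs merge (m).
#' @return data frame: `transect_id`, `start_m`, `end_m`, `length_m`.
#' @export
classified_runs_along <- function(result, transects, merge_gap_m = 0.2) {
  tmask <- target_mask(result)
  out <- list()
  for (i in seq_len(nrow(transects))) {
    tr <- transects[i, ]
    seg <- runs_along_line(tmask * 1L, c("no", "yes"),
                           result$pixel_size_m, tr$x0, tr$y0, tr$ux,
                           tr$uy, tr$length_m, target = 1L,
                           step = result$pixel_size_m / 2,
                           merge_gap_m = merge_gap_m)
    if (nrow(seg)) {
      seg$transect_id <- tr$id
      out[[length(out) + 1L]] <- seg
    }
  }
  if (!length(out))
    return(data.frame(transect_id = integer(), start_m = numeric(),
                      end_m = numeric(), length_m = numeric()))
  do.call(rbind, out)[, c("transect_id", "start_m", "end_m", "length_m")]
}

intersect_intervals <- function(a, b) {
  # a, b: data frames with start_m/end_m on ONE transect; returns pieces
  if (!nrow(a) || !nrow(b))
    return(data.frame(start_m = numeric(), end_m = numeric()))
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start_m[i], b$start_m)
    e <- pmin(a$end_m[i], b$end_m)
    keep <- e > s
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(start_m = s[keep],
                                            end_m = e[keep])
  }
  if (!length(out))
    return(data.frame(start_m = numeric(), end_m = numeric()))
  do.call(rbind, out)
}

#' Intersection of classified runs with field segments, by length category
#'
#' Intersects the classified target runs with the field patch segments on
#' each transect; the resulting pieces are categorized by their own length
#' (closed upper bounds at 0.5, 2 and 7 m) and compared against the field
#' statistics — the under-prediction view.
#'
#' @param runs classified runs ([classified_runs_along()] output).
#' @param segments field segments (from [simulate_field_survey()]).
#' @return object of class `length_category_stats` (mode
#'   `vs_field_segments`): per-category counts and mean lengths for the
#'   intersection pieces and the field segments, plus their differences.
#' @export
intersect_with_segments <- function(runs, segments) {
  pieces <- list()
  for (tid in unique(segments$transect_id)) {
    p <- intersect_intervals(runs[runs$transect_id == tid, , drop = FALSE],
                             segments[segments$transect_id == tid, ,
                                      drop = FALSE])
    if (nrow(p)) pieces[[length(pieces) + 1L]] <- p
  }
  lengths <- if (length(pieces)) {
    p <- do.call(rbind, pieces); p$end_m - p$start_m
  } else numeric(0)
  make_length_stats("vs_field_segments", lengths,
                    segments$length_m)
}

#' Classified runs against full transect lines, by length category
#'
#' Categorizes the classified runs directly (intersection with the full
#' transect lines) and compares them to the field statistics — the
#' over-prediction view.
#'
#' @param runs classified runs.
#' @param segments field segments (for the reference statistics).
#' @return a `length_category_stats` (mode `vs_full_transects`).
#' @export
intersect_with_transects <- function(runs, segments) {
  make_length_stats("vs_full_transects", runs$length_m,
                    segments$length_m)
}

make_length_stats <- function(mode, lengths, field_lengths) {
  st <- interval_stats(lengths)
  fs <- interval_stats(field_lengths)
  st$field_count <- fs$count
  st$field_mean_length_m <- fs$mean_length_m
  st$count_diff <- st$count - fs$count
  st$mean_length_diff_m <- st$mean_length_m - fs$mean_length_m
  structure(list(mode = mode, stats = st,
                 total_length_m = sum(lengths),
                 field_total_length_m = sum(field_lengths)),
            class = "length_category_stats")
}

#' @export
print.length_category_stats <- function(x, ...) {
  cat(sprintf("<length_category_stats> mode %s\n", x$mode))
  print(x$stats, row.names = FALSE)
  invisible(x)
}
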