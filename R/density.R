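#' Plant density estimate for one image
#'
#' @param sum_counts sum of (continuous) per-object plant counts.
#' @param segment_length_m,row_spacing_m counting window geometry.
#' @param n_rows_counted rows included in the window.
#' @param n_objects number of objects summed.
#' @param per_row optional per-row count breakdown.
#' @return An object of class `density_estimate`; `plants_per_m2 =
#'   sum_counts / (segment_length_m * row_spacing_m * n_rows_counted)`.
#' @export
density_estimate <- function(sum_counts, segment_length_m, row_spacing_m,
                             n_rows_counted, n_objects, per_row = NULL) {
  wd_assert(segment_length_m > 0 && row_spacing_m > 0 && n_rows_counted > 0,
            "wheatdens_config_error", "window area factors must be positive")
  area <- segment_length_m * row_spacing_m * n_rows_counted
  structure(list(plants_per_m2 = sum_counts / area,
                 segment_length_m = segment_length_m,
                 row_spacing_m = row_spacing_m,
                 n_rows_counted = n_rows_counted,
                 n_objects = n_objects, sum_counts = sum_counts,
                 window_area_m2 = area, per_row = per_row),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate %.1f plants/m2 (%.2f plants over %.3f m2, %d objects, %d rows)>\n",
              x$plants_per_m2, x$sum_counts, x$window_area_m2,
              x$n_objects, x$n_rows_counted))
  invisible(x)
}

#' Aggregate per-object counts to plants per square metre
#'
#' Sums the continuous predicted counts of the objects on the counted rows
#' and divides by the segment area (segment length x row spacing x number of
#' rows). With `rows_counted` smaller than the number of detected rows, only
#' the central rows are counted, mirroring the two-central-rows reference
#' protocol.
#'
#' @param feature_table feature table with `row_index` (from
#'   [extract_object_features()]).
#' @param counts per-object counts aligned with `feature_table` rows
#'   (predicted or ground truth).
#' @param rows a [row_model].
#' @param segment_length_mm,row_spacing_mm window geometry in mm.
#' @param rows_counted how many (central) rows to count; default all detected.
#' @param max_row_distance_px objects whose centroid is farther than this
#'   from every counted row line are excluded; with the default (half the
#'   sown spacing) a row that escaped detection removes both its plants and
#'   its share of the area, so the density stays consistent.
#' @return A [density_estimate].
#' @export
aggregate_density <- function(feature_table, counts, rows,
                              segment_length_mm, row_spacing_mm,
                              rows_counted = NULL,
                              max_row_distance_px = NULL) {
  wd_assert(nrow(feature_table) == length(counts), "wheatdens_config_error",
            "counts must align with the feature table")
  n_rows_all <- length(rows$rho_rows)
  use_rows <- seq_len(n_rows_all)
  if (!is.null(rows_counted)) {
    wd_assert(rows_counted >= 1 && rows_counted <= n_rows_all,
              "wheatdens_config_error", "rows_counted out of range")
    first <- ceiling((n_rows_all - rows_counted) / 2) + 1
    use_rows <- seq(first, length.out = rows_counted)
  }
  sel <- feature_table$row_index %in% use_rows
  if (!is.null(max_row_distance_px) &&
        !is.null(feature_table$row_distance_px) &&
        !anyNA(feature_table$row_distance_px)) {
    sel <- sel & feature_table$row_distance_px <= max_row_distance_px
  }
  per_row <- vapply(use_rows, function(r)
    sum(counts[feature_table$row_index == r]), numeric(1))
  density_estimate(sum_counts = sum(counts[sel]),
                   segment_length_m = segment_length_mm / 1000,
                   row_spacing_m = row_spacing_mm / 1000,
                   n_rows_counted = length(use_rows),
                   n_objects = sum(sel),
                   per_row = stats::setNames(per_row, paste0("row", use_rows)))
}

#' Relative error of a density estimate, in percent
#'
#' @param estimated,reference densities (vectorized); `reference` must be
#'   positive.
#' @return `100 * |estimated - reference| / reference`.
#' @export
relative_error <- function(estimated, reference) {
  wd_assert(all(reference > 0), "wheatdens_config_error",
            "reference density must be positive")
  100 * abs(estimated - reference) / reference
}

#' Run the full density pipeline on one image
#'
#' Segmentation, optional rectification, row detection and rotation, object
#' feature extraction, per-object count prediction, and aggregation to
#' plants per square metre.
#'
#' @param image an [rgb_image] (or a `wheat_scene`, whose truth then enables
#'   `model = "oracle"`).
#' @param model a [count_model], or `"oracle"` to substitute ground-truth
#'   counts (synthetic scenes only) for validating the geometric stages.
#' @param config list with `row_spacing_mm`, `segment_length_mm`,
#'   `resolution_mm` (of the rectified frame), and optionally `rows_counted`,
#'   `prominence`, `min_area`, `snap_deg`.
#' @param calib optional [homography] (image px -> ground mm); when supplied
#'   the mask is rectified before row detection.
#' @param out_dir optional directory for intermediate artifacts (mask PNG,
#'   rows JSON, objects CSV, result JSON).
#' @return List: `density` (a [density_estimate]), `rows`, `feature_table`,
#'   `counts`, `mask`.
#' @export
run_pipeline <- function(image, model, config, calib = NULL, out_dir = NULL) {
  scene <- NULL
  if (inherits(image, "wheat_scene")) {
    scene <- image
    image <- scene$image
  }
  for (f in c("row_spacing_mm", "segment_length_mm", "resolution_mm")) {
    wd_assert(!is.null(config[[f]]), "wheatdens_config_error",
              sprintf("config$%s is required", f))
  }
  stage <- function(name, expr) {
    tryCatch(expr, wheatdens_error = function(e) {
      wd_error(class(e)[1], sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  mask <- stage("segment", segment_green(image))
  if (!is.null(calib)) {
    mask <- stage("rectify",
                  rectify_image(mask, calib, config$resolution_mm)$raster)
  }
  spacing_px <- config$row_spacing_mm / config$resolution_mm
  rd <- stage("rows", detect_rows(mask, spacing_px,
                                  prominence = config$prominence %||% 0.3,
                                  snap_deg = config$snap_deg %||% 0.35))
  tab <- stage("objects",
               extract_object_features(rd$rotated_mask, rows = rd$model,
                                       image_id = config$image_id %||% "image",
                                       resolution_mm = config$resolution_mm,
                                       min_area = config$min_area %||% 1L,
                                       objects = rd$objects))
  counts <- if (identical(model, "oracle")) {
    wd_assert(!is.null(scene), "wheatdens_config_error",
              "oracle counts need a wheat_scene input")
    as.numeric(match_truth_counts(attr(tab, "objects"), scene$truth,
                                  mask_dim = dim(rd$rotated_mask$values),
                                  rotation_deg = rd$rotation_deg))
  } else {
    stage("predict", predict_counts(model, tab))
  }
  dens <- stage("aggregate",
                aggregate_density(tab, counts, rd$model,
                                  segment_length_mm = config$segment_length_mm,
                                  row_spacing_mm = config$row_spacing_mm,
                                  rows_counted = config$rows_counted,
                                  max_row_distance_px =
                                    config$max_row_distance_px %||% (0.5 * spacing_px)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mask_png(rd$rotated_mask, file.path(out_dir, "mask.png"))
    write_row_model(rd$model, file.path(out_dir, "rows.json"))
    tab2 <- tab
    tab2$predicted_count <- counts
    write_object_table(tab2, file.path(out_dir, "objects.csv"))
    jsonlite::write_json(list(plants_per_m2 = dens$plants_per_m2,
                              sum_counts = dens$sum_counts,
                              n_objects = dens$n_objects,
                              n_rows = dens$n_rows_counted,
                              window_area_m2 = dens$window_area_m2),
                         file.path(out_dir, "density.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(density = dens, rows = rd$model, feature_table = tab, counts = counts,
       mask = rd$rotated_mask)
}

#' Average per-image densities to a plot density
#'
#' Unweighted mean across images, mirroring the ten-images-per-plot survey
#' protocol.
#'
#' @param estimates list of [density_estimate]s.
#' @return Scalar plants per square metre.
#' @export
plot_density <- function(estimates) {
  mean(vapply(estimates, function(e) e$plants_per_m2, numeric(1)))
}
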