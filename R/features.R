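.provenance_cols <- c("crop_id", "mouse_id", "eye", "strain", "sex",
                      "age_months", "scanline", "crop_position", "replicate",
                      "image_path", "quality_grade", "n_flags",
                      "onh_dx", "onh_dy")
.id_cols <- c("crop_id", "mouse_id", "eye", "strain", "sex", "scanline",
              "image_path", "quality_grade")

#' Assemble the per-crop feature vector
#'
#' Flattens the output of [crop_metrics()] into one feature-table row with a
#' fixed, documented schema: per layer, thickness summary statistics
#' (`<layer>_thick_mean`, `_sd`, `_iqr`, `_range`, `_min`, `_max`, `_q25`,
#' `_q50`, `_q75`), normalized mean thickness (`<layer>_norm_mean`), area,
#' domain count and largest-domain ratio, bifurcations, inflection count and
#' the five inflection-angle bins; whole-crop TRT, sclera total, detachment
#' metrics and layer-wide totals; plus provenance keys and ONH offsets.
#'
#' @param metrics output of [crop_metrics()].
#' @param provenance named list; recognised keys are `crop_id`, `mouse_id`,
#'   `eye`, `strain`, `sex`, `age_months`, `scanline`, `crop_position`,
#'   `replicate`, `image_path`, `quality_grade`, `n_flags`, `onh_dx`,
#'   `onh_dy`. Missing keys are `NA`-coded.
#' @return one-row data frame.
#' @export
assemble_image_features <- function(metrics, provenance = list()) {
  sc <- layer_scheme()
  row <- list()
  for (p in .provenance_cols)
    row[[p]] <- if (!is.null(provenance[[p]])) provenance[[p]] else NA
  for (ly in sc$layers) {
    m <- metrics$layers[[ly]]
    st <- m$stats
    pre <- paste0(ly, "_")
    row[[paste0(pre, "thick_mean")]] <- st$mean
    row[[paste0(pre, "thick_sd")]] <- st$sd
    row[[paste0(pre, "thick_iqr")]] <- st$iqr
    row[[paste0(pre, "thick_range")]] <- st$range
    row[[paste0(pre, "thick_min")]] <- st$min
    row[[paste0(pre, "thick_max")]] <- st$max
    row[[paste0(pre, "thick_q25")]] <- st$q25
    row[[paste0(pre, "thick_q50")]] <- st$q50
    row[[paste0(pre, "thick_q75")]] <- st$q75
    row[[paste0(pre, "norm_mean")]] <- metrics$normalized$normalized[[ly]]
    row[[paste0(pre, "area")]] <- m$area
    row[[paste0(pre, "n_domains")]] <- m$domains$n_domains
    row[[paste0(pre, "largest_ratio")]] <-
      if (is.na(m$domains$largest_ratio) && m$area > 0) 1
      else m$domains$largest_ratio
    row[[paste0(pre, "bifurcations")]] <- m$bifurcations
    row[[paste0(pre, "n_inflections")]] <- metrics$layers[[ly]]$
      inflections$n_inflections
    bins <- metrics$layers[[ly]]$inflections$bin_counts
    for (b in seq_along(bins))
      row[[paste0(pre, "inflect_bin", b)]] <- bins[[b]]
  }
  det <- metrics$detachment
  row$trt <- metrics$normalized$trt
  row$sclera_total <- metrics$normalized$sclera_total
  row$rd_present <- as.integer(det$present)
  row$rd_area <- det$area
  row$rd_components <- det$n_components
  row$rd_fraction <- det$fraction
  row$total_bifurcations <-
    sum(vapply(metrics$layers, `[[`, 0, "bifurcations"))
  row$total_domains <-
    sum(vapply(metrics$layers, function(m) m$domains$n_domains, 0))
  row$total_area <- sum(vapply(metrics$layers, `[[`, 0, "area"))
  row$total_inflections_lt173 <-
    sum(vapply(metrics$layers, function(m)
      sum(m$inflections$bin_counts[1:3]), 0))
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Numeric feature columns of a feature table
#'
#' @param df feature data frame.
#' @return character vector of feature column names (numeric, non-provenance).
#' @export
feature_columns <- function(df) {
  cand <- setdiff(names(df), .provenance_cols)
  cand[vapply(df[cand], is.numeric, TRUE)]
}

#' Aggregate deduplicated crops of one eye
#'
#' For every image-level feature, the mean, SD and SEM (`SD/sqrt(n)`) across
#' the eye's deduplicated passing crops. Refuses eyes that fail the
#' eye-level gate (see [qc_eye()]). `NA` features are excluded pairwise.
#'
#' @param vectors data frame of image feature vectors for one eye.
#' @param cfg a [qc_config()] supplying the gate thresholds.
#' @return one-row data frame with `<feature>_mean`, `_sd`, `_sem` columns
#'   plus identity columns, `n_crops` and `n_ylocations`.
#' @export
aggregate_eye <- function(vectors, cfg = qc_config()) {
  n <- nrow(vectors)
  n_y <- length(unique(vectors$scanline))
  if (n < cfg$eye_min_passing_images)
    stop("eye gate: only ", n, " passing crops (need ",
         cfg$eye_min_passing_images, ")")
  if (n_y < cfg$eye_min_ylocations)
    stop("eye gate: only ", n_y, " scanline location(s) (need ",
         cfg$eye_min_ylocations, ")")
  fc <- feature_columns(vectors)
  out <- list(mouse_id = vectors$mouse_id[1], eye = vectors$eye[1],
              strain = vectors$strain[1], sex = vectors$sex[1],
              age_months = vectors$age_months[1],
              n_crops = n, n_ylocations = n_y)
  for (f in fc) {
    v <- vectors[[f]][is.finite(vectors[[f]])]
    k <- length(v)
    out[[paste0(f, "_mean")]] <- if (k) mean(v) else NA_real_
    out[[paste0(f, "_sd")]] <- if (k > 1L) sd(v) else if (k == 1L) 0 else
      NA_real_
    out[[paste0(f, "_sem")]] <- if (k > 1L) sd(v) / sqrt(k) else
      if (k == 1L) 0 else NA_real_
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Aggregate a mouse's eyes
#'
#' Feature-wise mean across the available passing eyes (1 or 2); with a
#' single eye the mouse value equals that eye's value.
#'
#' @param eyes data frame of [aggregate_eye()] rows for one mouse.
#' @return one-row data frame with `n_eyes`.
#' @export
aggregate_mouse <- function(eyes) {
  if (nrow(eyes) < 1L) stop("no passing eyes for this mouse")
  num <- names(eyes)[vapply(eyes, is.numeric, TRUE)]
  num <- setdiff(num, "age_months")
  out <- list(mouse_id = eyes$mouse_id[1], strain = eyes$strain[1],
              sex = eyes$sex[1], age_months = eyes$age_months[1],
              n_eyes = nrow(eyes))
  for (f in num)
    out[[f]] <- mean(eyes[[f]], na.rm = TRUE)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Spatial eye-map table for one feature
#'
#' One row per deduplicated passing crop with its ONH-relative offsets and
#' the chosen feature value; crops without registration are skipped with a
#' warning.
#'
#' @param records feature data frame including `onh_dx`, `onh_dy`.
#' @param feature feature column name.
#' @return data frame `crop_id`, `onh_dx`, `onh_dy`, `value` (fundus px).
#' @export
eye_map_table <- function(records, feature) {
  stopifnot(feature %in% names(records))
  has <- is.finite(records$onh_dx) & is.finite(records$onh_dy)
  if (any(!has))
    warning(sum(!has), " crop(s) without ONH registration skipped")
  r <- records[has, , drop = FALSE]
  data.frame(crop_id = r$crop_id, onh_dx = r$onh_dx, onh_dy = r$onh_dy,
             value = r[[feature]], stringsAsFactors = FALSE)
}
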