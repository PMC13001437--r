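#' Quality-control configuration
#'
#' Image-level rules: a crop is flagged for QC checking when any layer has 2
#' or more domains. Crops with fewer than 8 segmented layers fail when at
#' least 2 layers are multi-domain and the average largest-domain ratio
#' (largest domain area over total layer area, averaged over the
#' multi-domain layers) is below 75%. Crops with all 8 layers fail when 3 or
#' more multi-domain layers average below 98%, or exactly 2 multi-domain
#' layers average below 85%. Crops with 6 or more bifurcations across all
#' layers fail regardless. Eye-level gate: at least 5 passing crops covering
#' at least 2 distinct scanline locations.
#'
#' @param flag_min_domains domains in any layer that trigger flagging.
#' @param fewlayer_min_multidomain_layers,fewlayer_ratio_lt rule for crops
#'   with fewer than 8 layers.
#' @param eightlayer_rule_a,eightlayer_rule_b rules for 8-layer crops
#'   (lists with `min_layers`/`layers` and `ratio_lt`).
#' @param bifurcation_filter_at total bifurcation count at which a crop
#'   fails.
#' @param eye_min_passing_images,eye_min_ylocations eye-level gate.
#' @param exclude_onh_crop drop the optic-nerve-head crop (midline scanline,
#'   center position) before QC.
#' @return object of class `qc_config`.
#' @export
qc_config <- function(flag_min_domains = 2L,
                      fewlayer_min_multidomain_layers = 2L,
                      fewlayer_ratio_lt = 0.75,
                      eightlayer_rule_a = list(min_layers = 3L,
                                               ratio_lt = 0.98),
                      eightlayer_rule_b = list(layers = 2L, ratio_lt = 0.85),
                      bifurcation_filter_at = 6L,
                      eye_min_passing_images = 5L,
                      eye_min_ylocations = 2L,
                      exclude_onh_crop = TRUE) {
  structure(list(flag_min_domains = flag_min_domains,
                 fewlayer_min_multidomain_layers =
                   fewlayer_min_multidomain_layers,
                 fewlayer_ratio_lt = fewlayer_ratio_lt,
                 eightlayer_rule_a = eightlayer_rule_a,
                 eightlayer_rule_b = eightlayer_rule_b,
                 bifurcation_filter_at = bifurcation_filter_at,
                 eye_min_passing_images = eye_min_passing_images,
                 eye_min_ylocations = eye_min_ylocations,
                 exclude_onh_crop = exclude_onh_crop),
            class = "qc_config")
}

#' Image-level QC of one crop
#'
#' Applies the domain and bifurcation rules to the per-layer summaries of a
#' crop (see [qc_config()]). The average largest-domain ratio is computed
#' over the multi-domain layers only. Flagging is recorded even when the
#' crop ultimately passes, preserving the flag-then-filter audit trail.
#'
#' @param layer_summaries named list (one entry per scheme layer present in
#'   the crop) of lists with `area`, `n_domains`, `largest_ratio`,
#'   `bifurcations` — e.g. built from [crop_metrics()] via
#'   [qc_layer_summaries()].
#' @param cfg a [qc_config()].
#' @return object of class `qc_result`: list with `flagged`, `passed`,
#'   `reasons` (character), `n_layers_present`, `n_multidomain_layers`,
#'   `avg_largest_ratio` (`NA` unless at least one multi-domain layer) and
#'   `total_bifurcations`.
#' @export
qc_image <- function(layer_summaries, cfg = qc_config()) {
  if (!length(layer_summaries)) stop("no per-layer summaries supplied")
  need <- c("area", "n_domains", "largest_ratio", "bifurcations")
  for (s in layer_summaries)
    if (!all(need %in% names(s)))
      stop("layer summaries must contain: ", paste(need, collapse = ", "))
  areas <- vapply(layer_summaries, `[[`, 0, "area")
  nd <- vapply(layer_summaries, `[[`, 0, "n_domains")
  lr <- vapply(layer_summaries, `[[`, 0, "largest_ratio")
  bif <- vapply(layer_summaries, `[[`, 0, "bifurcations")

  n_layers <- sum(areas > 0)
  multi <- nd >= cfg$flag_min_domains
  n_multi <- sum(multi)
  avg_ratio <- if (n_multi >= 1L) mean(lr[multi]) else NA_real_
  total_bif <- sum(bif)

  reasons <- character()
  if (n_layers < 8L) {
    if (n_multi >= cfg$fewlayer_min_multidomain_layers &&
        !is.na(avg_ratio) && avg_ratio < cfg$fewlayer_ratio_lt)
      reasons <- c(reasons, "fewlayer_domain_ratio")
  } else {
    if (n_multi >= cfg$eightlayer_rule_a$min_layers &&
        !is.na(avg_ratio) && avg_ratio < cfg$eightlayer_rule_a$ratio_lt)
      reasons <- c(reasons, "eightlayer_domain_ratio_3plus")
    if (n_multi == cfg$eightlayer_rule_b$layers &&
        !is.na(avg_ratio) && avg_ratio < cfg$eightlayer_rule_b$ratio_lt)
      reasons <- c(reasons, "eightlayer_domain_ratio_2")
  }
  if (total_bif >= cfg$bifurcation_filter_at)
    reasons <- c(reasons, "bifurcations")

  structure(list(flagged = n_multi >= 1L,
                 passed = length(reasons) == 0L,
                 reasons = reasons,
                 n_layers_present = n_layers,
                 n_multidomain_layers = n_multi,
                 avg_largest_ratio = avg_ratio,
                 total_bifurcations = total_bif),
            class = "qc_result")
}

#' Per-layer QC summaries from crop metrics
#'
#' @param metrics output of [crop_metrics()].
#' @return named list suitable for [qc_image()].
#' @export
qc_layer_summaries <- function(metrics) {
  lapply(metrics$layers, function(m)
    list(area = m$area, n_domains = m$domains$n_domains,
         largest_ratio = if (is.na(m$domains$largest_ratio)) 1
           else m$domains$largest_ratio,
         bifurcations = m$bifurcations))
}

#' Exclude optic-nerve-head crops
#'
#' Removes the center crop (position 512 by default) of the midline
#' scanline, which images the optic nerve head; a complete eye of 3
#' scanlines x 3 positions then retains 8 crops.
#'
#' @param records data frame with `scanline` and `crop_position` columns.
#' @param onh_position center crop position (default 512).
#' @return filtered data frame.
#' @export
exclude_onh_crops <- function(records, onh_position = 512) {
  stopifnot(all(c("scanline", "crop_position") %in% names(records)))
  keep <- !(records$scanline == "midline" &
            records$crop_position == onh_position)
  records[keep, , drop = FALSE]
}

#' Eye-level QC gate
#'
#' An eye passes when at least `eye_min_passing_images` crops pass image QC
#' and those passing crops cover at least `eye_min_ylocations` distinct
#' scanline locations.
#'
#' @param passed logical vector of image QC outcomes for the eye's crops.
#' @param scanline character vector of the crops' scanline labels.
#' @param cfg a [qc_config()].
#' @return list with `passed`, `n_passing`, `n_ylocations`.
#' @export
qc_eye <- function(passed, scanline, cfg = qc_config()) {
  stopifnot(length(passed) == length(scanline))
  n_pass <- sum(passed)
  n_y <- length(unique(scanline[passed]))
  list(passed = n_pass >= cfg$eye_min_passing_images &&
         n_y >= cfg$eye_min_ylocations,
       n_passing = n_pass, n_ylocations = n_y)
}

#' Deduplicate technical replicates
#'
#' Keeps exactly one crop per (mouse, eye, timepoint, scanline,
#' crop_position): the one with the fewest QC flags, then the highest
#' quality grade (high before medium), then the lexicographically smallest
#' image path — a fully deterministic, idempotent selection.
#'
#' @param records data frame of passing crops with columns `mouse_id`,
#'   `eye`, `age_months`, `scanline`, `crop_position`, and optionally
#'   `n_flags`, `quality_grade`, `image_path`.
#' @return subset of `records` with one row per anatomical location.
#' @export
deduplicate <- function(records) {
  need <- c("mouse_id", "eye", "age_months", "scanline", "crop_position")
  stopifnot(all(need %in% names(records)))
  if (nrow(records) == 0L) return(records)
  n_flags <- if ("n_flags" %in% names(records)) records$n_flags else 0L
  grade <- if ("quality_grade" %in% names(records))
    match(records$quality_grade, c("high", "medium")) else 1L
  grade[is.na(grade)] <- 3L
  path <- if ("image_path" %in% names(records)) records$image_path else ""
  key <- do.call(paste, c(records[need], sep = "|"))
  ord <- order(key, n_flags, grade, path)
  records <- records[ord, , drop = FALSE]
  records[!duplicated(key[ord]), , drop = FALSE]
}
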