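#' Default pipeline configuration
#'
#' Nested configuration for an end-to-end run. Can be written to / read
#' from YAML losslessly by [run_pipeline()].
#'
#' @param input_dir cohort root containing `metadata.csv` and the image and
#'   mask trees.
#' @param output_dir where tables and the manifest are written.
#' @param crop_positions,crop_width,crop_height crop geometry.
#' @param tangent_window midline smoothing window, px.
#' @param x_scale fundus pixels per OCT pixel for ONH registration.
#' @param n_clusters dendrogram cut for the clustering stage.
#' @param emit_profiles also write the long-format per-pixel local profile
#'   table (`local_profiles.csv`: crop_id, layer, x, y, thickness, angle).
#' @param seed RNG seed recorded in the manifest.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = ".", output_dir = "octmorph_out",
                            crop_positions = c(256, 512, 768),
                            crop_width = 256L, crop_height = 400L,
                            tangent_window = 31L, x_scale = 1,
                            n_clusters = 4L, emit_profiles = FALSE,
                            seed = 1L) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 crop = list(positions = crop_positions,
                             width = crop_width, height = crop_height,
                             tangent_window = tangent_window),
                 registration = list(x_scale = x_scale),
                 cluster = list(n_clusters = n_clusters),
                 emit_profiles = emit_profiles,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Crop one B-scan and compute all per-crop features
#'
#' Reads the label mask (and image) of one metadata record, finds the
#' whole-tissue midline, extracts the crops perpendicular to it, runs
#' [crop_metrics()] and [qc_image()] on each, registers crop centers to the
#' ONH when fundus information is present, and returns the assembled
#' feature rows.
#'
#' @param record one metadata row (data frame).
#' @param root directory metadata paths are relative to.
#' @param config a [pipeline_config()].
#' @param acfg an [angle_config()].
#' @param qcfg a [qc_config()].
#' @return data frame of feature rows (one per crop), with QC columns
#'   `qc_passed`, `qc_reasons`, `n_flags`.
#' @export
process_record <- function(record, root, config = pipeline_config(),
                           acfg = angle_config(), qcfg = qc_config()) {
  labels <- read_labelmap(file.path(root, record$mask_path))
  image <- tryCatch(
    read_labelmap(file.path(root, record$image_path), scheme = NULL),
    error = function(e) NULL)
  reg <- NULL
  if (!is.null(record$fundus_mask_path) &&
      !is.na(record$fundus_mask_path) && nzchar(record$fundus_mask_path) &&
      !is.null(record$scanline_y) && is.finite(record$scanline_y)) {
    fundus <- read_labelmap(file.path(root, record$fundus_mask_path),
                            scheme = NULL)
    reg <- onh_registration(segment_onh(fundus), record$scanline_y,
                            config$registration$x_scale)
  }
  axis <- tissue_midline(labels != 0,
                         tangent_window = config$crop$tangent_window)
  plans <- plan_crops(axis, positions = config$crop$positions,
                      width = config$crop$width,
                      height = config$crop$height)
  rows <- list()
  for (plan in plans) {
    cr <- extract_crop(image, labels, plan)
    met <- crop_metrics(cr$labels, acfg)
    qc <- qc_image(qc_layer_summaries(met), qcfg)
    off <- if (!is.null(reg)) onh_offsets(reg, plan$center[["x"]]) else
      c(onh_dx = NA_real_, onh_dy = NA_real_)
    prov <- list(
      crop_id = paste(record$mouse_id, record$eye, record$age_months,
                      record$scanline, record$replicate, plan$position,
                      sep = "_"),
      mouse_id = record$mouse_id, eye = record$eye,
      strain = record$strain, sex = record$sex,
      age_months = record$age_months, scanline = record$scanline,
      crop_position = plan$position, replicate = record$replicate,
      image_path = record$image_path,
      quality_grade = if (!is.null(record$quality_grade))
        record$quality_grade else NA_character_,
      n_flags = as.integer(qc$flagged) + length(qc$reasons),
      onh_dx = off[["onh_dx"]], onh_dy = off[["onh_dy"]])
    fv <- assemble_image_features(met, prov)
    fv$qc_passed <- qc$passed
    fv$qc_flagged <- qc$flagged
    fv$qc_reasons <- paste(qc$reasons, collapse = ";")
    attr(fv, "profiles") <- cbind(crop_id = prov$crop_id, met$profiles)
    rows[[length(rows) + 1L]] <- fv
  }
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- do.call(rbind, lapply(rows, attr, "profiles"))
  out
}

#' Run the full pipeline on a cohort
#'
#' Stages: ingest -> crop -> metrics -> QC -> eye gate -> deduplication ->
#' eye/mouse aggregation -> statistics -> clustering. Every stage's tables
#' are written under the configured output directory together with a
#' manifest recording the configuration, seed and per-stage record counts
#' (in = kept + dropped at every filter).
#'
#' @param config a [pipeline_config()], or the path of a YAML file holding
#'   one.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg_list <- yaml::read_yaml(config)
    config <- pipeline_config()
    config[names(cfg_list)] <- cfg_list
  }
  root <- config$input_dir
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  meta <- read_metadata(file.path(root, "metadata.csv"))
  feats <- list()
  for (i in seq_len(nrow(meta)))
    feats[[i]] <- process_record(meta[i, ], root, config)
  if (isTRUE(config$emit_profiles))
    write.csv(do.call(rbind, lapply(feats, attr, "profiles")),
              file.path(out, "local_profiles.csv"), row.names = FALSE)
  feats <- do.call(rbind, feats)
  write.csv(feats, file.path(out, "image_features.csv"), row.names = FALSE)

  n_crops <- nrow(feats)
  after_onh <- exclude_onh_crops(feats)
  passing <- after_onh[after_onh$qc_passed, , drop = FALSE]
  qc_report <- after_onh[c(.id_cols[.id_cols %in% names(after_onh)],
                           "age_months", "crop_position", "replicate",
                           "qc_passed", "qc_flagged", "qc_reasons",
                           "n_flags", "total_bifurcations",
                           "total_domains")]
  write.csv(qc_report, file.path(out, "qc_report.csv"), row.names = FALSE)

  # eye gate
  eye_key <- with(passing, paste(mouse_id, eye, age_months, sep = "|"))
  gates <- lapply(split(passing, eye_key), function(df) {
    g <- qc_eye(rep(TRUE, nrow(df)), df$scanline)
    data.frame(mouse_id = df$mouse_id[1], eye = df$eye[1],
               age_months = df$age_months[1], passed = g$passed,
               n_passing = g$n_passing, n_ylocations = g$n_ylocations,
               stringsAsFactors = FALSE)
  })
  gates <- do.call(rbind, gates)
  rownames(gates) <- NULL
  write.csv(gates, file.path(out, "eye_gate.csv"), row.names = FALSE)
  ok_eyes <- gates[gates$passed, c("mouse_id", "eye", "age_months")]
  keep <- eye_key %in% with(ok_eyes, paste(mouse_id, eye, age_months,
                                           sep = "|"))
  gated <- passing[keep, , drop = FALSE]

  dedup <- deduplicate(gated)
  write.csv(dedup, file.path(out, "image_features_dedup.csv"),
            row.names = FALSE)

  eye_rows <- lapply(split(dedup, with(dedup, paste(mouse_id, eye,
                                                    age_months))),
                     aggregate_eye)
  eye_feats <- do.call(rbind, eye_rows)
  rownames(eye_feats) <- NULL
  write.csv(eye_feats, file.path(out, "eye_features.csv"),
            row.names = FALSE)

  mouse_rows <- lapply(split(eye_feats,
                             with(eye_feats, paste(mouse_id, age_months))),
                       aggregate_mouse)
  mouse_feats <- do.call(rbind, mouse_rows)
  rownames(mouse_feats) <- NULL
  write.csv(mouse_feats, file.path(out, "mouse_features.csv"),
            row.names = FALSE)

  # statistics: two-group comparison of strains at mouse level
  strains <- unique(mouse_feats$strain)
  if (length(strains) == 2L && all(table(mouse_feats$strain) >= 2L)) {
    num <- setdiff(names(mouse_feats)[vapply(mouse_feats, is.numeric,
                                             TRUE)],
                   c("age_months", "n_eyes", "n_crops", "n_ylocations"))
    res <- two_group(mouse_feats[num], mouse_feats$strain)
    build_report(res, mouse_feats[num], mouse_feats$strain,
                 file.path(out, "report_strain"))
  }

  cl <- cluster_images(dedup,
                       cluster_config(n_clusters =
                                        config$cluster$n_clusters))
  write.csv(data.frame(crop_id = dedup$crop_id, cluster = cl$labels),
            file.path(out, "clusters.csv"), row.names = FALSE)
  write.csv(cl$matrix, file.path(out, "heatmap_matrix.csv"))

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    counts = list(images_in = nrow(meta),
                  crops = n_crops,
                  crops_after_onh_exclusion = nrow(after_onh),
                  crops_onh_dropped = n_crops - nrow(after_onh),
                  crops_qc_passed = nrow(passing),
                  crops_qc_failed = nrow(after_onh) - nrow(passing),
                  eyes = nrow(gates),
                  eyes_passed = sum(gates$passed),
                  crops_after_eye_gate = nrow(gated),
                  crops_dedup = nrow(dedup),
                  mice = nrow(mouse_feats)))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}
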