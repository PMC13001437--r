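#' Ocular layer label scheme
#'
#' Integer label values for the segmented classes: background 0, the eight
#' ocular layers 1-8 in anterior-to-posterior order, and an optional retinal
#' detachment (RD) class 9. Total retinal thickness (TRT) is defined over
#' the six retina layers (IPL, INL, OPL, ONL, ELM, ISOS); the sclera total
#' over RPE plus CHR.
#'
#' @return list with `label_values` (named list), `layers` (the 8 layer
#'   names), `retina_layers`, `sclera_layers`.
#' @export
layer_scheme <- function() {
  list(label_values = list(background = 0L, IPL = 1L, INL = 2L, OPL = 3L,
                           ONL = 4L, ELM = 5L, ISOS = 6L, RPE = 7L,
                           CHR = 8L, RD = 9L),
       layers = c("IPL", "INL", "OPL", "ONL", "ELM", "ISOS", "RPE", "CHR"),
       retina_layers = c("IPL", "INL", "OPL", "ONL", "ELM", "ISOS"),
       sclera_layers = c("RPE", "CHR"))
}

#' Read a single-channel 8-bit label mask (TIFF or PNG)
#'
#' Validates that the raster is single-channel and that every pixel value is
#' a known label of the scheme.
#'
#' @param path file path, extension `.tif`/`.tiff` or `.png`.
#' @param scheme label scheme from [layer_scheme()]; set `NULL` to skip
#'   label validation (e.g. for intensity images or binary masks).
#' @return integer matrix (rows = y, columns = x).
#' @export
read_labelmap <- function(path, scheme = layer_scheme()) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = {
      a <- png::readPNG(path)
      if (is.matrix(a)) round(a * 255) else a
    },
    stop("unsupported mask format: .", ext))
  if (length(dim(arr)) != 2L)
    stop("label mask must be single-channel, got ", length(dim(arr)),
         " dimensions: ", path)
  m <- matrix(as.integer(arr), nrow = nrow(arr))
  if (!is.null(scheme)) {
    known <- unlist(scheme$label_values)
    bad <- setdiff(unique(as.vector(m)), known)
    if (length(bad))
      stop("unknown label value(s) ", paste(sort(bad), collapse = ", "),
           " in ", path)
  }
  m
}

#' Write an integer matrix as an 8-bit single-channel TIFF or PNG
#'
#' @param m integer or numeric matrix with values in 0-255.
#' @param path output path; format chosen by extension.
#' @export
write_labelmap <- function(m, path) {
  stopifnot(is.matrix(m), all(m >= 0), all(m <= 255))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m / 255, path, bits.per.sample = 8L,
                                   compression = "none"),
    png = png::writePNG(m / 255, path),
    stop("unsupported mask format: .", ext))
  invisible(path)
}

.metadata_required <- c("mouse_id", "eye", "strain", "sex", "age_months",
                        "scanline", "replicate", "image_path", "mask_path")

#' Read a cohort metadata table
#'
#' Reads the per-image metadata CSV, checks the required columns, types the
#' fields, drops rows manually graded `low` quality (the pre-QC manual
#' filter), and warns on duplicate
#' (mouse, eye, timepoint, scanline, replicate) keys without dropping them.
#'
#' @param path CSV path with header. Required columns: mouse_id, eye,
#'   strain, sex, age_months, scanline, replicate, image_path, mask_path.
#'   Optional: fundus_mask_path, scanline_y, quality_grade.
#' @return data frame of records (possibly zero rows).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.metadata_required, names(df))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(df)
  df$age_months <- as.numeric(df$age_months)
  df$replicate <- as.integer(df$replicate)
  bad_eye <- setdiff(unique(df$eye), c("L", "R"))
  if (length(bad_eye))
    stop("eye must be L or R, got: ", paste(bad_eye, collapse = ", "))
  bad_sl <- setdiff(unique(df$scanline),
                    c("superior", "midline", "inferior"))
  if (length(bad_sl))
    stop("unknown scanline value(s): ", paste(bad_sl, collapse = ", "))
  if ("quality_grade" %in% names(df)) {
    n_low <- sum(df$quality_grade == "low", na.rm = TRUE)
    if (n_low)
      message(n_low, " record(s) graded 'low' dropped before analysis")
    df <- df[is.na(df$quality_grade) | df$quality_grade != "low", ,
             drop = FALSE]
  }
  key <- do.call(paste, c(df[c("mouse_id", "eye", "age_months", "scanline",
                               "replicate")], sep = "|"))
  if (anyDuplicated(key))
    warning("duplicate metadata key(s): ",
            paste(unique(key[duplicated(key)]), collapse = "; "),
            " (all rows kept)")
  rownames(df) <- NULL
  df
}
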