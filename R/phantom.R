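#' Phantom configuration for synthetic B-scans
#'
#' Describes the geometry and photometry of a synthetic murine OCT B-scan:
#' eight stacked ocular layers (IPL, INL, OPL, ONL, ELM, ISOS, RPE, CHR)
#' beneath a smoothly curved upper boundary, with per-layer base thicknesses
#' and mean grey levels plus additive speckle noise on the intensity image
#' (never on the labels).
#'
#' @param width,height image dimensions in pixels.
#' @param layer_order character vector of exactly 8 layer names, anterior to
#'   posterior.
#' @param base_thickness named numeric vector of per-layer thickness in
#'   pixels (all >= 2).
#' @param curvature_amplitude amplitude of the sinusoidal upper boundary, px.
#' @param curvature_period period of the sinusoid, px.
#' @param top_margin mean depth of the upper tissue boundary, px.
#' @param intensity_means named per-layer mean grey level (0-255); must also
#'   contain `background` and `RD` entries.
#' @param noise_sd standard deviation of the Gaussian intensity noise, grey
#'   levels.
#' @param seed default RNG seed for [generate_bscan()].
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(width = 1024L, height = 512L,
                           layer_order = c("IPL", "INL", "OPL", "ONL",
                                           "ELM", "ISOS", "RPE", "CHR"),
                           base_thickness = c(IPL = 50, INL = 30, OPL = 15,
                                              ONL = 60, ELM = 8, ISOS = 25,
                                              RPE = 12, CHR = 40),
                           curvature_amplitude = 30,
                           curvature_period = 1024,
                           top_margin = 130,
                           intensity_means = c(background = 15, IPL = 120,
                                               INL = 70, OPL = 130, ONL = 50,
                                               ELM = 150, ISOS = 170,
                                               RPE = 200, CHR = 90, RD = 35),
                           noise_sd = 8,
                           seed = 1L) {
  if (length(layer_order) != 8L)
    stop("layer_order must have exactly 8 entries")
  if (anyDuplicated(layer_order))
    stop("layer_order entries must be unique")
  if (!all(layer_order %in% names(base_thickness)))
    stop("base_thickness must name every layer in layer_order")
  base_thickness <- base_thickness[layer_order]
  if (any(base_thickness < 2))
    stop("all base thicknesses must be >= 2 px")
  if (sum(base_thickness) + 2 * curvature_amplitude + top_margin >= height)
    stop("layer stack plus curvature exceeds image height")
  structure(list(width = as.integer(width), height = as.integer(height),
                 layer_order = layer_order, base_thickness = base_thickness,
                 curvature_amplitude = curvature_amplitude,
                 curvature_period = curvature_period,
                 top_margin = top_margin,
                 intensity_means = intensity_means, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Specify a lesion to inject into a phantom B-scan
#'
#' @param kind one of `detachment`, `focal_thinning`, `domain_break`,
#'   `bifurcation_spur`, `regional_gradient`.
#' @param target_layer layer name the lesion acts on (ignored for
#'   `detachment`, which always sits between ISOS and RPE).
#' @param center_x lesion center, x pixels.
#' @param extent lesion width along x, pixels.
#' @param magnitude pixels (detachment band height, spur length) or fraction
#'   (thinning depth, gradient end multiplier), depending on `kind`.
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(kind, target_layer = "ONL", center_x, extent,
                        magnitude) {
  kinds <- c("detachment", "focal_thinning", "domain_break",
             "bifurcation_spur", "regional_gradient")
  kind <- match.arg(kind, kinds)
  if (extent <= 0) stop("lesion extent must be > 0")
  if (magnitude <= 0) stop("lesion magnitude must be > 0")
  structure(list(kind = kind, target_layer = target_layer,
                 center_x = center_x, extent = extent, magnitude = magnitude),
            class = "lesion_spec")
}

#' Generate one synthetic B-scan with labels and ground truth
#'
#' Stacks the 8 configured layers beneath a sinusoidal upper boundary,
#' injects the requested lesions, and renders an 8-bit style intensity image
#' (per-label mean grey level plus Gaussian noise). Labels follow the scheme
#' of [layer_scheme()]: background 0, layers 1-8 anterior to posterior,
#' retinal detachment 9.
#'
#' @param config a [phantom_config()].
#' @param lesions list of [lesion_spec()] objects.
#' @param seed RNG seed; identical `(config, lesions, seed)` reproduce
#'   bit-identical output.
#' @return list with `image` (numeric matrix, 0-255), `labels` (integer
#'   matrix), and `truth` — a list holding `thickness` (long data frame
#'   `x`/`layer`/`thickness`, exact per-column label row-counts) and
#'   `lesions` (inventory data frame).
#' @export
generate_bscan <- function(config, lesions = list(), seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  for (l in lesions) {
    if (!inherits(l, "lesion_spec")) stop("lesions must be lesion_spec objects")
    if (l$center_x < 1 || l$center_x > config$width)
      stop("lesion center_x ", l$center_x, " outside image width ",
           config$width)
    if (l$kind != "detachment" && !(l$target_layer %in% config$layer_order))
      stop("lesion target layer '", l$target_layer, "' not in layer_order")
  }
  w <- config$width; h <- config$height
  layers <- config$layer_order
  x <- seq_len(w)

  # per-column thickness matrix (8 x width), before pixelation
  th <- matrix(rep(config$base_thickness, w), nrow = 8L,
               dimnames = list(layers, NULL))
  rd <- numeric(w)                      # detachment band height per column
  for (l in lesions) {
    in_ext <- abs(x - l$center_x) <= l$extent / 2
    switch(l$kind,
      focal_thinning = {
        bump <- ifelse(in_ext,
                       0.5 * (1 + cos(pi * (x - l$center_x) / (l$extent / 2))),
                       0)
        th[l$target_layer, ] <- th[l$target_layer, ] *
          (1 - pmin(l$magnitude, 1) * bump)
      },
      domain_break = {
        th[l$target_layer, in_ext] <- 0
      },
      regional_gradient = {
        ramp <- pmin(pmax((x - (l$center_x - l$extent / 2)) / l$extent, 0), 1)
        th[l$target_layer, ] <- th[l$target_layer, ] *
          (1 + (l$magnitude - 1) * ramp)
      },
      detachment = {
        rd[in_ext] <- pmax(rd[in_ext], round(l$magnitude))
      },
      bifurcation_spur = NULL)          # carved after stacking
  }
  th <- round(th)

  # upper tissue boundary
  y0 <- round(config$top_margin +
              config$curvature_amplitude *
              sin(2 * pi * (x - 1) / config$curvature_period))
  scheme <- layer_scheme()
  rd_after <- which(layers == "ISOS")   # RD band sits between ISOS and RPE

  depth <- y0 + colSums(th) + rd
  if (any(depth > h))
    stop("layer stack overflows image height (max depth ", max(depth),
         " > ", h, ")")

  labels <- matrix(0L, nrow = h, ncol = w)
  for (cx in x) {
    ytop <- y0[cx]
    for (k in seq_along(layers)) {
      tk <- th[k, cx]
      if (tk > 0)
        labels[(ytop + 1):(ytop + tk), cx] <- scheme$label_values[[layers[k]]]
      ytop <- ytop + tk
      if (k == rd_after && rd[cx] > 0) {
        labels[(ytop + 1):(ytop + rd[cx]), cx] <- scheme$label_values[["RD"]]
        ytop <- ytop + rd[cx]
      }
    }
  }

  # truth bookkeeping: per-column row counts per label
  counts <- matrix(0, nrow = 9L, ncol = w, dimnames = list(c(layers, "RD"), NULL))
  counts[seq_len(8L), ] <- th
  counts["RD", ] <- rd

  # carve bifurcation spurs: a 7-px-wide prong of the target layer extending
  # upward from its middle into the layer(s) above, so the target skeleton
  # necessarily branches
  for (l in lesions) {
    if (l$kind != "bifurcation_spur") next
    tl <- scheme$label_values[[l$target_layer]]
    k <- which(layers == l$target_layer)
    half <- max(3L, floor(min(l$extent, 7) / 2))
    cols <- max(1L, round(l$center_x) - half):min(w, round(l$center_x) + half)
    for (cx in cols) {
      top_k <- y0[cx] + if (k > 1) sum(counts[seq_len(k - 1L), cx]) else 0
      rows <- max(1L, top_k - round(l$magnitude) + 1L):top_k
      for (ry in rows) {
        old <- labels[ry, cx]
        if (old == tl) next
        old_name <- if (old == 0L) NULL else
          names(scheme$label_values)[match(old, unlist(scheme$label_values))]
        if (!is.null(old_name) && old_name %in% rownames(counts))
          counts[old_name, cx] <- counts[old_name, cx] - 1
        counts[l$target_layer, cx] <- counts[l$target_layer, cx] + 1
        labels[ry, cx] <- tl
      }
    }
  }

  # intensity rendering
  if (!is.null(seed)) set.seed(seed)
  means <- config$intensity_means
  inten <- matrix(means[["background"]], nrow = h, ncol = w)
  for (nm in c(layers, "RD")) {
    sel <- labels == scheme$label_values[[nm]]
    inten[sel] <- means[[nm]]
  }
  inten <- inten + rnorm(h * w, sd = config$noise_sd)
  inten <- round(pmin(pmax(inten, 0), 255))

  truth_th <- data.frame(x = rep(x, each = 9L),
                         layer = rep(rownames(counts), w),
                         thickness = as.vector(counts),
                         stringsAsFactors = FALSE)
  inv <- if (length(lesions)) {
    data.frame(kind = vapply(lesions, `[[`, "", "kind"),
               target_layer = vapply(lesions, `[[`, "", "target_layer"),
               center_x = vapply(lesions, `[[`, 0, "center_x"),
               extent = vapply(lesions, `[[`, 0, "extent"),
               magnitude = vapply(lesions, `[[`, 0, "magnitude"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(kind = character(), target_layer = character(),
               center_x = numeric(), extent = numeric(),
               magnitude = numeric(), stringsAsFactors = FALSE)
  }
  list(image = inten, labels = labels,
       truth = list(thickness = truth_th, lesions = inv))
}

#' Specify a synthetic cohort
#'
#' Describes a study design of groups (strains) with per-layer thickness
#' effects relative to control, technical replicates at up to three scanline
#' locations per eye, and a per-crop lesion rate.
#'
#' @param groups list of group descriptors; each a list with `name`,
#'   `n_mice`, optional `effect` (named per-layer multiplicative fraction of
#'   control thickness, default all 1) and optional `lesion_rate` in
#'   \[0, 1\].
#' @param timepoints numeric vector of ages in months.
#' @param eyes_per_mouse 1 or 2.
#' @param scanlines character subset of superior/midline/inferior.
#' @param replicates_per_scanline technical replicates per scanline.
#' @param between_mouse_sdlog log-normal SD of the per-mouse, per-layer
#'   thickness multiplier (biological variability stand-in).
#' @param within_eye_sdlog log-normal SD of the per-image multiplier
#'   (acquisition repeatability).
#' @param lesion_kind lesion kind injected at `lesion_rate` (default
#'   detachment).
#' @param base_config [phantom_config()] used for rendering.
#' @param seed integer master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, timepoints = 6,
                        eyes_per_mouse = 2L,
                        scanlines = c("superior", "midline", "inferior"),
                        replicates_per_scanline = 1L,
                        between_mouse_sdlog = 0.05,
                        within_eye_sdlog = 0.02,
                        lesion_kind = "detachment",
                        base_config = phantom_config(),
                        seed = 1L) {
  if (length(groups) < 1L) stop("cohort needs at least one group")
  for (g in groups) {
    if (is.null(g$name) || is.null(g$n_mice) || g$n_mice < 1)
      stop("each group needs a name and n_mice >= 1")
    if (!is.null(g$effect) && (any(g$effect <= 0) || any(g$effect > 2)))
      stop("effect fractions must lie in (0, 2]")
    if (!is.null(g$lesion_rate) &&
        (g$lesion_rate < 0 || g$lesion_rate > 1))
      stop("lesion_rate must lie in [0, 1]")
  }
  if (!eyes_per_mouse %in% 1:2) stop("eyes_per_mouse must be 1 or 2")
  scanlines <- match.arg(scanlines, c("superior", "midline", "inferior"),
                         several.ok = TRUE)
  structure(list(groups = groups, timepoints = timepoints,
                 eyes_per_mouse = as.integer(eyes_per_mouse),
                 scanlines = scanlines,
                 replicates_per_scanline = as.integer(replicates_per_scanline),
                 between_mouse_sdlog = between_mouse_sdlog,
                 within_eye_sdlog = within_eye_sdlog,
                 lesion_kind = lesion_kind,
                 base_config = base_config, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Plan a cohort: per-image true layer thicknesses and lesion draws
#'
#' Draws the random study design implied by a [cohort_spec()] without
#' rendering any image: one row per (mouse, eye, timepoint, scanline,
#' replicate) with the true per-layer thickness (base x group effect x
#' log-normal between-mouse multiplier x log-normal within-eye multiplier)
#' and whether a lesion is injected. This is the statistical model behind
#' [generate_cohort()] and is reusable directly for power and type-I
#' simulations.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with provenance columns, `lesion` flag, per-image
#'   seed, and one `thick_<layer>` column per layer.
#' @export
plan_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cfg <- spec$base_config
  layers <- cfg$layer_order
  rows <- list()
  mouse_counter <- 0L
  for (g in spec$groups) {
    eff <- setNames(rep(1, 8L), layers)
    if (!is.null(g$effect)) eff[names(g$effect)] <- g$effect
    rate <- if (is.null(g$lesion_rate)) 0 else g$lesion_rate
    for (m in seq_len(g$n_mice)) {
      mouse_counter <- mouse_counter + 1L
      mouse_id <- sprintf("M%03d", mouse_counter)
      sex <- if (mouse_counter %% 2L) "F" else "M"
      mouse_mult <- rlnorm(8L, 0, spec$between_mouse_sdlog)
      for (tp in spec$timepoints) {
        for (eye in c("L", "R")[seq_len(spec$eyes_per_mouse)]) {
          for (sl in spec$scanlines) {
            for (rep_i in seq_len(spec$replicates_per_scanline)) {
              img_mult <- rlnorm(8L, 0, spec$within_eye_sdlog)
              thick <- cfg$base_thickness * eff * mouse_mult * img_mult
              rows[[length(rows) + 1L]] <- data.frame(
                group = g$name, mouse_id = mouse_id, sex = sex,
                eye = eye, age_months = tp, scanline = sl,
                replicate = rep_i,
                lesion = runif(1) < rate,
                img_seed = sample.int(.Machine$integer.max %/% 2L, 1L),
                t(setNames(thick, paste0("thick_", layers))),
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic cohort on disk
#'
#' Renders every image planned by [plan_cohort()] as paired 8-bit TIFF
#' intensity image and label mask, writes a circular optic-nerve-head fundus
#' mask per eye, and emits the ingest-ready metadata CSV plus a ground-truth
#' CSV of true per-layer mean thicknesses.
#'
#' Layout: `<outdir>/images/<mouse>/<eye>/<timepoint>/<scanline>_<rep>.tif`,
#' mirrored under `<outdir>/masks/`, fundus masks under `<outdir>/fundus/`,
#' and `metadata.csv` / `ground_truth.csv` at the root. Scanlines map to
#' fundus rows 100 px above (superior), through (midline) and below
#' (inferior) the ONH center.
#'
#' @param spec a [cohort_spec()].
#' @param outdir output directory (created if needed).
#' @param fundus_size,onh_radius fundus canvas size and ONH disk radius, px.
#' @return invisibly, the metadata data frame.
#' @export
generate_cohort <- function(spec, outdir, fundus_size = 1024L,
                            onh_radius = 60L) {
  stopifnot(inherits(spec, "cohort_spec"))
  plan <- plan_cohort(spec)
  cfg <- spec$base_config
  layers <- cfg$layer_order
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("images", "masks", "fundus"))
    dir.create(file.path(outdir, d), recursive = TRUE, showWarnings = FALSE)

  onh_center <- c(fundus_size / 2, fundus_size / 2)
  fundus <- matrix(0L, fundus_size, fundus_size)
  gx <- matrix(seq_len(fundus_size), fundus_size, fundus_size, byrow = TRUE)
  gy <- matrix(seq_len(fundus_size), fundus_size, fundus_size)
  fundus[(gx - onh_center[1])^2 + (gy - onh_center[2])^2 <= onh_radius^2] <- 1L
  fundus_path <- file.path(outdir, "fundus", "onh_mask.tif")
  write_labelmap(fundus, fundus_path)
  scan_y <- c(superior = onh_center[2] - 100, midline = onh_center[2],
              inferior = onh_center[2] + 100)

  meta <- list(); truth <- list()
  for (i in seq_len(nrow(plan))) {
    r <- plan[i, ]
    rel <- file.path(r$mouse_id, r$eye, sprintf("tp%g", r$age_months))
    fn <- sprintf("%s_%d.tif", r$scanline, r$replicate)
    img_dir <- file.path(outdir, "images", rel)
    msk_dir <- file.path(outdir, "masks", rel)
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)

    cfg_i <- cfg
    cfg_i$base_thickness <- setNames(
      as.numeric(r[paste0("thick_", layers)]), layers)
    lesions <- list()
    if (r$lesion)
      lesions <- list(lesion_spec(spec$lesion_kind, target_layer = "ONL",
                                  center_x = cfg$width / 2,
                                  extent = cfg$width / 8,
                                  magnitude = if (spec$lesion_kind ==
                                                  "detachment") 25 else 0.5))
    scan <- generate_bscan(cfg_i, lesions, seed = r$img_seed)
    write_labelmap(round(scan$image), file.path(img_dir, fn))
    write_labelmap(scan$labels, file.path(msk_dir, fn))

    meta[[i]] <- data.frame(
      mouse_id = r$mouse_id, eye = r$eye, strain = r$group, sex = r$sex,
      age_months = r$age_months, scanline = r$scanline,
      replicate = r$replicate,
      image_path = file.path("images", rel, fn),
      mask_path = file.path("masks", rel, fn),
      fundus_mask_path = file.path("fundus", "onh_mask.tif"),
      scanline_y = scan_y[[r$scanline]],
      quality_grade = "high", stringsAsFactors = FALSE)
    tm <- tapply(scan$truth$thickness$thickness, scan$truth$thickness$layer,
                 mean)
    truth[[i]] <- data.frame(
      mouse_id = r$mouse_id, eye = r$eye, strain = r$group,
      age_months = r$age_months, scanline = r$scanline,
      replicate = r$replicate, layer = names(tm),
      mean_thickness = as.numeric(tm),
      lesion = r$lesion, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  truth <- do.call(rbind, truth)
  write.csv(meta, file.path(outdir, "metadata.csv"), row.names = FALSE)
  write.csv(truth, file.path(outdir, "ground_truth.csv"), row.names = FALSE)
  invisible(meta)
}
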