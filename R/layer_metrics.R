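#' Angle and inflection configuration
#'
#' Defaults follow the skeleton-profiling design: an 11-pixel least-squares
#' fit window for local angles, a 5-pixel-per-side fallback window, 11-pixel
#' flanking windows at inflections, exclusion of near-vertical events
#' (window mean absolute angle in 80-90 degrees), and five inflection-angle
#' bins `<165`, `[165,170)`, `[170,173)`, `[173,175)`, `[175,177)` degrees
#' (values >= 177 are left uncounted).
#'
#' @param fit_window odd window length for the local straight-line fit.
#' @param fallback_halfwidth pixels per side for the arctan2 fallback.
#' @param inflection_window flanking window length at an inflection.
#' @param vertical_exclusion numeric length 2; events whose flanking-window
#'   mean absolute angle falls in this closed range are excluded.
#' @param bin_edges inflection-angle bin edges (half-open on the right).
#' @return object of class `angle_config`.
#' @export
angle_config <- function(fit_window = 11L, fallback_halfwidth = 5L,
                         inflection_window = 11L,
                         vertical_exclusion = c(80, 90),
                         bin_edges = c(-Inf, 165, 170, 173, 175, 177)) {
  stopifnot(fit_window %% 2L == 1L, inflection_window %% 2L == 1L,
            !is.unsorted(bin_edges))
  structure(list(fit_window = as.integer(fit_window),
                 fallback_halfwidth = as.integer(fallback_halfwidth),
                 inflection_window = as.integer(inflection_window),
                 vertical_exclusion = vertical_exclusion,
                 bin_edges = bin_edges),
            class = "angle_config")
}

#' Pixel calibration
#'
#' @param x_anisotropy x-pixels per isotropic pixel (the scan's lateral
#'   anisotropy factor; default 1.62).
#' @param microns_per_pixel physical size of an isotropic pixel.
#' @return object of class `calibration`.
#' @export
calibration <- function(x_anisotropy = 1.62, microns_per_pixel = 1) {
  stopifnot(x_anisotropy > 0, microns_per_pixel > 0)
  structure(list(x_anisotropy = x_anisotropy,
                 microns_per_pixel = microns_per_pixel),
            class = "calibration")
}

#' Convert an anisotropic pixel displacement to microns
#'
#' Scales the x-component by the lateral anisotropy factor to isotropic
#' pixels, rederives the hypotenuse, and converts to microns.
#'
#' @param dx,dy displacement in raw image pixels.
#' @param cal a [calibration()].
#' @return length in microns.
#' @export
isotropic_microns <- function(dx, dy, cal = calibration()) {
  sqrt((dx * cal$x_anisotropy)^2 + dy^2) * cal$microns_per_pixel
}

#' Local thickness along a layer skeleton
#'
#' Thickness at each skeleton pixel is twice the Euclidean distance to the
#' nearest background pixel of the layer mask (the perpendicular half-width
#' doubled). Because topological thinning can park the axis 1-2 px off the
#' true medial line, the distance is read at the ridge of the distance
#' transform within a 7-pixel vertical window centered on the skeleton
#' pixel. Left and right image edges are treated as tissue cuts, not
#' boundaries: the mask is extended sideways by replicating its edge columns
#' before the distance transform, so a layer running off the crop keeps its
#' anatomical thickness there.
#'
#' @param skel a [layer_skeleton()] of `layer_mask`.
#' @param layer_mask the binary layer mask the skeleton came from.
#' @return list with `pixels` (data frame x, y, thickness) and `by_x`
#'   (data frame x, thickness — mean over skeleton pixels sharing x).
#' @export
local_thickness <- function(skel, layer_mask) {
  stopifnot(inherits(skel, "layer_skeleton"))
  if (nrow(skel$pixels) == 0L)
    return(list(pixels = data.frame(x = integer(), y = integer(),
                                    thickness = numeric()),
                by_x = data.frame(x = integer(), thickness = numeric())))
  m <- matrix(as.numeric(layer_mask != 0), nrow = nrow(layer_mask))
  pad <- ceiling(nrow(m) / 2) + 1L
  left <- m[, rep(1L, pad), drop = FALSE]
  right <- m[, rep(ncol(m), pad), drop = FALSE]
  mp <- cbind(left, m, right)
  mp <- rbind(0, mp, 0)                       # top/bottom are true boundaries
  dm <- as.matrix(EBImage::distmap(mp, metric = "euclidean"))
  dm <- dm[2:(nrow(m) + 1L), (pad + 1L):(pad + ncol(m)), drop = FALSE]
  nr <- nrow(dm)
  ridge <- vapply(seq_len(nrow(skel$pixels)), function(i) {
    y <- skel$pixels$y[i]; x <- skel$pixels$x[i]
    max(dm[max(1L, y - 3L):min(nr, y + 3L), x])
  }, 0)
  thick <- 2 * ridge
  px <- data.frame(x = skel$pixels$x, y = skel$pixels$y, thickness = thick)
  agg <- tapply(px$thickness, px$x, mean)
  list(pixels = px,
       by_x = data.frame(x = as.integer(names(agg)),
                         thickness = as.numeric(agg)))
}

#' Summary statistics of a thickness profile
#'
#' @param values numeric vector of local thickness readings.
#' @return list: mean, sd (population), iqr, range, min, max, q25, q50, q75
#'   (linear-interpolation quartiles). All `NA` for an empty profile.
#' @export
thickness_stats <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values))
    return(list(mean = NA_real_, sd = NA_real_, iqr = NA_real_,
                range = NA_real_, min = NA_real_, max = NA_real_,
                q25 = NA_real_, q50 = NA_real_, q75 = NA_real_))
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(mean = mean(values),
       sd = sqrt(mean((values - mean(values))^2)),
       iqr = q[3] - q[1],
       range = max(values) - min(values),
       min = min(values), max = max(values),
       q25 = q[1], q50 = q[2], q75 = q[3])
}

#' Normalized layer thicknesses
#'
#' Retina layers (IPL, INL, OPL, ONL, ELM, ISOS) are normalized by the total
#' retinal thickness (TRT, their sum); RPE and CHR by the sclera total
#' (RPE + CHR). TRT and the sclera total are returned as features in their
#' own right.
#'
#' @param layer_means named numeric vector of mean thicknesses for the 8
#'   layers (missing or `NA` layers propagate `NA`).
#' @return list with `normalized` (named vector over the 8 layers), `trt`,
#'   `sclera_total`.
#' @export
normalized_thickness <- function(layer_means) {
  sc <- layer_scheme()
  v <- setNames(rep(NA_real_, 8L), sc$layers)
  v[intersect(names(layer_means), sc$layers)] <-
    layer_means[intersect(names(layer_means), sc$layers)]
  trt <- sum(v[sc$retina_layers])
  sclera <- sum(v[sc$sclera_layers])
  norm <- setNames(rep(NA_real_, 8L), sc$layers)
  if (is.finite(trt) && trt > 0) {
    norm[sc$retina_layers] <- v[sc$retina_layers] / trt
  } else if (is.finite(trt)) {
    warning("total retinal thickness is zero; retina fractions undefined")
  }
  if (is.finite(sclera) && sclera > 0) {
    norm[sc$sclera_layers] <- v[sc$sclera_layers] / sclera
  } else if (is.finite(sclera)) {
    warning("sclera total is zero; sclera fractions undefined")
  }
  list(normalized = norm, trt = trt, sclera_total = sclera)
}

#' Local angles along a skeleton branch
#'
#' For each pixel of an ordered branch path, a straight line is fitted by
#' least squares to the surrounding window (truncated at branch ends). A
#' window with all dx = 0 is called 90 degrees; all dy = 0 returns 0
#' degrees; otherwise the angle is `atan(slope)` of y on x in degrees
#' (positive = descending in image coordinates, y down). If the fit is
#' degenerate the fallback is `atan2` of the mean displacements over
#' `fallback_halfwidth` pixels in each direction.
#'
#' @param branch data frame with ordered `x`, `y` columns (one branch of a
#'   [layer_skeleton()]).
#' @param cfg an [angle_config()].
#' @return numeric vector of angles in degrees, one per branch pixel, in
#'   \[-90, 90\].
#' @export
local_angles <- function(branch, cfg = angle_config()) {
  n <- nrow(branch)
  if (n == 0L) return(numeric())
  hw <- (cfg$fit_window - 1L) %/% 2L
  ang <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - hw); hi <- min(n, i + hw)
    xs <- branch$x[lo:hi]; ys <- branch$y[lo:hi]
    if (all(diff(xs) == 0)) { ang[i] <- 90; next }
    if (all(diff(ys) == 0)) { ang[i] <- 0; next }
    vx <- sum((xs - mean(xs))^2)
    if (vx > 0 && length(xs) >= 2L) {
      slope <- sum((xs - mean(xs)) * (ys - mean(ys))) / vx
      ang[i] <- atan(slope) * 180 / pi
    } else {
      fh <- cfg$fallback_halfwidth
      lo2 <- max(1L, i - fh); hi2 <- min(n, i + fh)
      dx <- mean(diff(branch$x[lo2:hi2]))
      dy <- mean(diff(branch$y[lo2:hi2]))
      a <- atan2(dy, dx) * 180 / pi
      if (a > 90) a <- a - 180
      if (a <= -90) a <- a + 180
      ang[i] <- a
    }
  }
  ang
}

#' Detect inflections in a per-column angle sequence
#'
#' An inflection is a sign change in the column-aggregated local angle. At
#' each sign change the mean angle of the `inflection_window` entries before
#' and after is taken; the inflection angle is
#' `180 - |mean_pre + mean_post|` degrees (a straight-through bend of equal
#' and opposite flanks scores 180). Events whose flanking windows are
#' near-vertical (mean absolute angle within `vertical_exclusion`) are
#' excluded to focus on horizontal inflections; the remaining angles are
#' counted into the configured bins (angles at or beyond the last edge stay
#' uncounted). Sign changes without a full flanking window on both sides are
#' skipped.
#'
#' @param column_angles numeric vector: per-x mean angle for one layer of
#'   one crop (`NA` columns are dropped before analysis).
#' @param cfg an [angle_config()].
#' @return list with `events` (data frame index, m_pre, m_post, angle,
#'   excluded), `n_inflections` (non-excluded events) and `bin_counts`
#'   (named integer vector over the 5 bins).
#' @export
detect_inflections <- function(column_angles, cfg = angle_config()) {
  a <- column_angles[!is.na(column_angles)]
  w <- cfg$inflection_window
  edges <- cfg$bin_edges
  bin_labels <- paste0("bin", seq_len(length(edges) - 1L))
  bins <- setNames(integer(length(edges) - 1L), bin_labels)
  events <- data.frame(index = integer(), m_pre = numeric(),
                       m_post = numeric(), angle = numeric(),
                       excluded = logical())
  if (length(a) >= 2L) {
    sgn <- sign(a)
    flips <- which(sgn[-length(a)] * sgn[-1L] < 0)
    for (i in flips) {
      if (i < w || i + w > length(a)) next      # incomplete flanking window
      m_pre <- mean(a[(i - w + 1L):i])
      m_post <- mean(a[(i + 1L):(i + w)])
      angle <- 180 - abs(m_pre + m_post)
      vex <- cfg$vertical_exclusion
      excl <- (mean(abs(a[(i - w + 1L):i])) >= vex[1] &&
               mean(abs(a[(i - w + 1L):i])) <= vex[2]) ||
              (mean(abs(a[(i + 1L):(i + w)])) >= vex[1] &&
               mean(abs(a[(i + 1L):(i + w)])) <= vex[2])
      events <- rbind(events,
                      data.frame(index = i, m_pre = m_pre, m_post = m_post,
                                 angle = angle, excluded = excl))
      if (!excl) {
        b <- findInterval(angle, edges)
        if (b >= 1L && b <= length(bins)) bins[b] <- bins[b] + 1L
      }
    }
  }
  list(events = events, n_inflections = sum(!events$excluded),
       bin_counts = bins)
}

#' Connected-domain summary of a layer mask
#'
#' Domains are 8-connected components of the layer's pixels. The largest
#' ratio (largest domain area over the sum of all domain areas) is the QC
#' quantity of interest: 1 for a single intact domain.
#'
#' @param layer_mask binary matrix.
#' @param min_size drop components smaller than this many pixels (default 0,
#'   count all).
#' @return list: `n_domains`, `areas` (decreasing), `largest_ratio` (`NA`
#'   when empty).
#' @export
count_domains <- function(layer_mask, min_size = 0L) {
  lab <- label_components(layer_mask)
  if (max(lab) == 0L)
    return(list(n_domains = 0L, areas = integer(), largest_ratio = NA_real_))
  areas <- sort(tabulate(lab[lab > 0L]), decreasing = TRUE)
  areas <- areas[areas >= min_size]
  if (!length(areas))
    return(list(n_domains = 0L, areas = integer(), largest_ratio = NA_real_))
  list(n_domains = length(areas), areas = areas,
       largest_ratio = areas[1] / sum(areas))
}

#' Retinal-detachment features of a crop label map
#'
#' @param labels integer label matrix using [layer_scheme()] values.
#' @return list: `present`, `area` (px), `n_components`, `fraction` of the
#'   crop area.
#' @export
detachment_features <- function(labels) {
  rd_val <- layer_scheme()$label_values$RD
  rd <- labels == rd_val
  area <- sum(rd)
  if (area == 0L)
    return(list(present = FALSE, area = 0L, n_components = 0L, fraction = 0))
  list(present = TRUE, area = area,
       n_components = max(label_components(rd)),
       fraction = area / length(labels))
}

#' All skeleton metrics for one cropped label map
#'
#' Runs the full per-crop metric stack: for each of the 8 scheme layers,
#' the domain summary, medial-axis skeleton, local thickness profile and
#' summary statistics, per-column angles, inflection events and bin counts,
#' and bifurcation count; plus crop-level detachment features, TRT, sclera
#' total and normalized thicknesses.
#'
#' @param labels integer label matrix for one crop.
#' @param cfg an [angle_config()].
#' @return list with `layers` (named list of per-layer metric lists),
#'   `detachment`, `normalized` (output of [normalized_thickness()]) and
#'   `profiles` (long data frame layer, x, y, thickness, angle).
#' @export
crop_metrics <- function(labels, cfg = angle_config()) {
  sc <- layer_scheme()
  per_layer <- list()
  prof <- list()
  means <- setNames(rep(NA_real_, 8L), sc$layers)
  for (ly in sc$layers) {
    mask <- labels == sc$label_values[[ly]]
    area <- sum(mask)
    if (area == 0L) {
      per_layer[[ly]] <- list(area = 0L,
                              domains = count_domains(mask),
                              stats = thickness_stats(numeric()),
                              bifurcations = 0L,
                              inflections = detect_inflections(numeric(), cfg),
                              by_x = data.frame(x = integer(),
                                                thickness = numeric(),
                                                angle = numeric()))
      next
    }
    dom <- count_domains(mask)
    skel <- layer_skeleton(mask, layer = ly)
    th <- local_thickness(skel, mask)
    st <- thickness_stats(th$pixels$thickness)
    means[ly] <- st$mean

    ang <- rep(NA_real_, nrow(skel$pixels))
    key <- paste(skel$pixels$x, skel$pixels$y)
    for (br in skel$branches) {
      a <- local_angles(br, cfg)
      ang[match(paste(br$x, br$y), key)] <- a
    }
    agg_a <- tapply(ang, skel$pixels$x, function(v) mean(v, na.rm = TRUE))
    by_x <- merge(th$by_x,
                  data.frame(x = as.integer(names(agg_a)),
                             angle = as.numeric(agg_a)),
                  by = "x", all = TRUE)
    infl <- detect_inflections(by_x$angle[order(by_x$x)], cfg)

    per_layer[[ly]] <- list(area = area, domains = dom, stats = st,
                            bifurcations = count_bifurcations(skel),
                            inflections = infl, by_x = by_x)
    prof[[ly]] <- data.frame(layer = ly, x = skel$pixels$x,
                             y = skel$pixels$y,
                             thickness = th$pixels$thickness, angle = ang)
  }
  list(layers = per_layer,
       detachment = detachment_features(labels),
       normalized = normalized_thickness(means),
       profiles = if (length(prof)) do.call(rbind, prof) else
         data.frame(layer = character(), x = integer(), y = integer(),
                    thickness = numeric(), angle = numeric()))
}
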