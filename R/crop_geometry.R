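#' Medial axis of a whole-tissue mask
#'
#' Reduces the binary tissue mask of a full B-scan to one axis pixel per x
#' column — the column centroid of the tissue, which for a vertically
#' convex tissue band coincides with its medial axis while being free of
#' thinning wiggle — then smooths the axis with a centered moving average
#' before computing per-column tangent angles by finite differences.
#'
#' @param tissue_mask binary matrix of tissue vs background.
#' @param tangent_window moving-average window (px) for axis smoothing.
#' @param min_span_frac minimum fraction of the image width the tissue must
#'   span.
#' @return object of class `midline_axis`: data frame with columns `x`, `y`
#'   (smoothed axis row) and `tangent` (degrees, positive = descending).
#' @export
tissue_midline <- function(tissue_mask, tangent_window = 31L,
                           min_span_frac = 0.5) {
  stopifnot(is.matrix(tissue_mask))
  if (!any(tissue_mask != 0)) stop("tissue mask is empty")
  lab <- label_components(tissue_mask)
  areas <- tabulate(lab[lab > 0L])
  if (length(areas) > 1L) {
    big <- which(areas >= 0.1 * max(areas))
    if (length(big) > 1L)
      stop("tissue mask has multiple large components (areas: ",
           paste(sort(areas[big], decreasing = TRUE), collapse = ", "), ")")
    tissue_mask <- lab == which.max(areas)
  }
  cols <- which(colSums(tissue_mask != 0) > 0)
  if ((max(cols) - min(cols) + 1L) < min_span_frac * ncol(tissue_mask))
    stop("tissue spans less than ", round(100 * min_span_frac),
         "% of the image width")

  idx <- which(tissue_mask != 0, arr.ind = TRUE)
  ycent <- tapply(idx[, 1], idx[, 2], mean)
  xs <- min(cols):max(cols)
  y_raw <- approx(as.integer(names(ycent)), as.numeric(ycent), xout = xs,
                  rule = 2)$y
  y_smooth <- .movmean(y_raw, tangent_window)
  # slope over a window-length baseline: adjacent-pixel differences alias
  # the 1-px staircase of the rasterized boundary
  n <- length(y_smooth)
  hw <- max(1L, (tangent_window - 1L) %/% 2L)
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  tangent <- atan((y_smooth[hi] - y_smooth[lo]) / (hi - lo)) * 180 / pi
  structure(data.frame(x = xs, y = y_smooth, tangent = tangent),
            class = c("midline_axis", "data.frame"))
}

# centered moving average with shrinking windows at the ends
.movmean <- function(v, w) {
  hw <- (w - 1L) %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Plan crops perpendicular to the tissue midline
#'
#' One plan per requested x position: the crop is centered on the axis pixel
#' at that column and rotated by the local tangent so that its width axis
#' follows the tissue and its height axis is perpendicular to it.
#'
#' @param axis a [tissue_midline()] result.
#' @param positions x columns of the crop centers (default 256, 512, 768).
#' @param width,height crop dimensions in pixels (default 256 x 400).
#' @return list of `crop_plan` objects (`center`, `rotation` degrees,
#'   `width`, `height`, `position`); positions outside the axis range are
#'   skipped with a warning.
#' @export
plan_crops <- function(axis, positions = c(256, 512, 768),
                       width = 256L, height = 400L) {
  stopifnot(inherits(axis, "midline_axis"), width > 0, height > 0)
  plans <- list()
  for (p in positions) {
    if (p < min(axis$x) || p > max(axis$x)) {
      warning("crop position ", p, " outside axis range [",
              min(axis$x), ", ", max(axis$x), "]; skipped")
      next
    }
    i <- which.min(abs(axis$x - p))
    plans[[length(plans) + 1L]] <-
      structure(list(center = c(x = axis$x[i], y = axis$y[i]),
                     rotation = axis$tangent[i],
                     width = as.integer(width), height = as.integer(height),
                     position = p),
                class = "crop_plan")
  }
  plans
}

#' Extract a rotated crop from an image and its label map
#'
#' Inverse-mapping resampler: each crop pixel is pulled from the source at
#' `center + u*t + v*n`, where `t` is the unit tangent of the midline and
#' `n` its perpendicular. Intensities are sampled bilinearly, labels by
#' nearest neighbor (so the crop can contain only label values present in
#' the source); overhang beyond the source is padded with background.
#'
#' @param image numeric intensity matrix (may be `NULL`).
#' @param labels integer label matrix.
#' @param plan a `crop_plan` from [plan_crops()].
#' @return list with `image`, `labels` (crop-sized matrices), and `plan`.
#' @export
extract_crop <- function(image, labels, plan) {
  stopifnot(inherits(plan, "crop_plan"))
  w <- plan$width; h <- plan$height
  th <- plan$rotation * pi / 180
  # integer offsets about the center pixel, so a rotation-0 crop is exact
  # slicing (no half-pixel rounding)
  u <- seq_len(w) - ((w + 1L) %/% 2L)
  v <- seq_len(h) - ((h + 1L) %/% 2L)
  # source coordinates for each crop pixel (rows = v, cols = u)
  sx <- plan$center[["x"]] + outer(v, u, function(vv, uu)
    uu * cos(th) - vv * sin(th))
  sy <- plan$center[["y"]] + outer(v, u, function(vv, uu)
    uu * sin(th) + vv * cos(th))

  nr <- nrow(labels); nc <- ncol(labels)
  ri <- round(sy); ci <- round(sx)
  inside <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  lab_crop <- matrix(0L, h, w)
  lab_crop[inside] <- labels[cbind(ri[inside], ci[inside])]

  img_crop <- NULL
  if (!is.null(image)) {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    gv <- function(r, c) {
      ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
      out <- matrix(0, h, w)
      out[ok] <- image[cbind(r[ok], c[ok])]
      out
    }
    img_crop <- (1 - fx) * (1 - fy) * gv(y0, x0) +
      fx * (1 - fy) * gv(y0, x0 + 1) +
      (1 - fx) * fy * gv(y0 + 1, x0) +
      fx * fy * gv(y0 + 1, x0 + 1)
  }
  list(image = img_crop, labels = lab_crop, plan = plan)
}

#' Optic-nerve-head registration
#'
#' @param onh_center numeric length-2 (x, y) ONH center in fundus pixels.
#' @param scanline_y fundus row of the B-scan's scanline.
#' @param x_scale fundus pixels per OCT pixel along x.
#' @return object of class `onh_registration`.
#' @export
onh_registration <- function(onh_center, scanline_y, x_scale = 1) {
  stopifnot(length(onh_center) == 2L, x_scale > 0)
  structure(list(onh_center = c(x = onh_center[[1]], y = onh_center[[2]]),
                 scanline_y = scanline_y, x_scale = x_scale),
            class = "onh_registration")
}

#' ONH-relative offsets of a crop center
#'
#' `onh_dx = x_scale * crop_center_x - onh_x`;
#' `onh_dy = scanline_y - onh_y` (both in fundus pixels, so the Euclidean
#' distance to the ONH is `sqrt(dx^2 + dy^2)`).
#'
#' @param reg an [onh_registration()].
#' @param crop_center_x crop center x in OCT pixels.
#' @return named numeric `c(onh_dx, onh_dy)`.
#' @export
onh_offsets <- function(reg, crop_center_x) {
  stopifnot(inherits(reg, "onh_registration"))
  c(onh_dx = reg$x_scale * crop_center_x - reg$onh_center[["x"]],
    onh_dy = reg$scanline_y - reg$onh_center[["y"]])
}

#' Locate the optic nerve head in a fundus mask
#'
#' Centroid of the largest 8-connected foreground component, rounded to the
#' nearest pixel.
#'
#' @param fundus_mask binary matrix.
#' @return named numeric `c(x, y)`.
#' @export
segment_onh <- function(fundus_mask) {
  if (!any(fundus_mask != 0)) stop("fundus ONH mask is empty")
  lab <- label_components(fundus_mask)
  areas <- tabulate(lab[lab > 0L])
  idx <- which(lab == which.max(areas), arr.ind = TRUE)
  c(x = round(mean(idx[, 2])), y = round(mean(idx[, 1])))
}
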