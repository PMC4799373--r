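#' Segmentation parameters
#'
#' @param threshold_method `"otsu"` (per-frame Otsu threshold; default, and
#'   invariant to positive rescaling of intensities) or `"fixed"`.
#' @param fixed_threshold intensity threshold, required when
#'   `threshold_method = "fixed"`.
#' @param min_region_area connected components smaller than this (px) are
#'   removed from the tissue mask.
#' @param closing_radius radius (px) of the disc used for morphological
#'   closing of the thresholded mask; `0` disables closing.
#' @param closure_threshold gap areas below this (um^2) count as closed.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_region_area = 50,
                                closing_radius = 3,
                                closure_threshold = 100) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    abort("fixed threshold method requires fixed_threshold")
  stopifnot(min_region_area >= 0, closing_radius >= 0, closure_threshold >= 0)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_region_area = min_region_area,
                 closing_radius = closing_radius,
                 closure_threshold = closure_threshold),
            class = "segmentation_params")
}

#' Segment tissue from background in one frame
#'
#' Brightness threshold (Otsu or fixed), then morphological closing, then
#' removal of connected components below `min_region_area`.
#'
#' @param image 2D intensity matrix.
#' @param params a [segmentation_params()].
#' @return Logical H x W tissue mask.
#' @export
segment_frame <- function(image, params = segmentation_params()) {
  stopifnot(is.matrix(image))
  th <- if (params$threshold_method == "otsu") {
    rng <- range(image)
    if (diff(rng) == 0) rng[2] + 1  # flat frame: nothing above threshold
    else EBImage::otsu(EBImage::Image(image), range = rng)
  } else params$fixed_threshold
  mask <- image > th
  if (params$closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(params$closing_radius) + 1L,
                                shape = "disc")
    mask <- EBImage::closing(EBImage::Image(mask * 1), brush) > 0.5
    mask <- matrix(as.logical(mask), nrow(image), ncol(image))
  }
  if (params$min_region_area > 0 && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- matrix(as.integer(lab), nrow(image), ncol(image))
    sizes <- tabulate(lab)
    keep <- which(sizes >= params$min_region_area)
    mask <- matrix(lab %in% keep, nrow(image), ncol(image))
  }
  mask
}

#' Extract the wound gap from a tissue mask
#'
#' Non-tissue connected components touching the image border are the space
#' "around" the tissue; components fully enclosed by tissue are holes. The
#' largest hole is the gap (a single surgical wound per tissue); when sizes
#' tie, the hole nearest `previous_centroid` wins. All holes are reported in
#' the diagnostics.
#'
#' @param mask logical tissue mask from [segment_frame()].
#' @param previous_centroid optional `(x, y)` um of the previous frame's gap,
#'   used as tie-breaker.
#' @param pixel_size um per pixel (for the diagnostics centroids).
#' @return List with `gap` (logical matrix, or `NULL` when the gap is closed)
#'   and `holes` (tibble `label`, `area_px`, `cx_um`, `cy_um`, `is_gap`).
#' @export
extract_gap_region <- function(mask, previous_centroid = NULL,
                               pixel_size = 1) {
  stopifnot(is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  empty <- list(gap = NULL,
                holes = tibble(label = integer(), area_px = integer(),
                               cx_um = numeric(), cy_um = numeric(),
                               is_gap = logical()))
  if (!any(!mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image((!mask) * 1))
  lab <- matrix(as.integer(lab), h, w)
  border_labs <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  hole_labs <- setdiff(unique(as.vector(lab)), c(0L, border_labs))
  if (length(hole_labs) == 0) return(empty)
  holes <- map_dfr(hole_labs, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    tibble(label = l, area_px = nrow(idx),
           cx_um = mean(idx[, 2] - 1) * pixel_size,
           cy_um = mean(idx[, 1] - 1) * pixel_size)
  })
  best <- which(holes$area_px == max(holes$area_px))
  if (length(best) > 1 && !is.null(previous_centroid)) {
    d2 <- (holes$cx_um[best] - previous_centroid[1])^2 +
      (holes$cy_um[best] - previous_centroid[2])^2
    best <- best[which.min(d2)]
  } else best <- best[1]
  holes$is_gap <- seq_len(nrow(holes)) == best
  list(gap = lab == holes$label[best], holes = holes)
}

# marching-squares perimeter of a binary region, in pixels; the mask is
# lightly smoothed first because contouring the raw staircase overestimates
# oblique boundaries by up to ~8%
perimeter_marching <- function(mask, sigma = 1.5) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 8, w + 8)
  pad[5:(h + 4), 5:(w + 4)] <- mask * 1
  if (sigma > 0)
    pad <- as.matrix(EBImage::gblur(EBImage::Image(pad), sigma))
  cl <- contourLines(x = seq_len(h + 8), y = seq_len(w + 8), z = pad,
                     levels = 0.5)
  sum(vapply(cl, function(cc) {
    xs <- c(cc$x, cc$x[1]); ys <- c(cc$y, cc$y[1])
    sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }, numeric(1)))
}

#' Measure gap morphometrics from a gap pixel region
#'
#' Area from the pixel count, centroid from the mean pixel position, ellipse
#' semi-axes and orientation from the second central moments (semi-axes are
#' twice the square roots of the covariance eigenvalues, the convention under
#' which a solid ellipse recovers its own axes), circularity `4*pi*A / P^2`
#' with a marching-squares perimeter (pixel-edge perimeters overestimate
#' diagonal boundaries).
#'
#' @param gap logical gap mask (or `NULL`/empty for a closed gap).
#' @param pixel_size um per pixel.
#' @param t frame time in hours.
#' @param closure_threshold um^2 below which the gap counts as closed.
#' @return One-row tibble: `t_h`, `area_um2`, `centroid_x_um`,
#'   `centroid_y_um`, `a_um`, `b_um`, `orientation_deg`, `circularity`,
#'   `closed`. Ellipse fields are `NA` for empty regions.
#' @export
measure_gap <- function(gap, pixel_size, t = NA_real_,
                        closure_threshold = 100) {
  na_row <- tibble(t_h = t, area_um2 = 0, centroid_x_um = NA_real_,
                   centroid_y_um = NA_real_, a_um = NA_real_, b_um = NA_real_,
                   orientation_deg = NA_real_, circularity = NA_real_,
                   closed = TRUE)
  if (is.null(gap) || !any(gap)) return(na_row)
  idx <- which(gap, arr.ind = TRUE)
  n <- nrow(idx)
  xs <- (idx[, 2] - 1) * pixel_size
  ys <- (idx[, 1] - 1) * pixel_size
  area <- n * pixel_size^2
  cx <- mean(xs); cy <- mean(ys)
  if (n >= 3) {
    cxx <- mean((xs - cx)^2); cyy <- mean((ys - cy)^2)
    cxy <- mean((xs - cx) * (ys - cy))
    ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
    a <- 2 * sqrt(max(ev$values[1], 0))
    b <- 2 * sqrt(max(ev$values[2], 0))
    ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
    if (ang > 90) ang <- ang - 180
    if (ang <= -90) ang <- ang + 180
  } else {
    a <- b <- 0; ang <- NA_real_
  }
  per <- perimeter_marching(gap) * pixel_size
  circ <- if (per > 0) 4 * pi * area / per^2 else NA_real_
  tibble(t_h = t, area_um2 = area, centroid_x_um = cx, centroid_y_um = cy,
         a_um = a, b_um = b, orientation_deg = ang, circularity = circ,
         closed = area < closure_threshold)
}

#' Tissue width perpendicular to the inter-cantilever axis
#'
#' For each column in the central part of the tissue's span along the
#' inter-cantilever axis, the tissue extent (outer envelope, holes included)
#' perpendicular to that axis is measured; the width is the median over those
#' columns.
#'
#' @param mask logical tissue mask.
#' @param pixel_size um per pixel.
#' @param axis_angle angle of the inter-cantilever axis in degrees
#'   (0 = image x axis); non-zero angles rotate the mask before measuring.
#' @param span central fraction of occupied columns used (default 0.5).
#' @return Width in um.
#' @export
tissue_width <- function(mask, pixel_size, axis_angle = 0, span = 0.5) {
  stopifnot(is.logical(mask))
  if (!any(mask)) abort("empty mask")
  if (axis_angle != 0) {
    rot <- EBImage::rotate(EBImage::Image(mask * 1), axis_angle)
    mask <- matrix(as.numeric(rot) > 0.5, dim(rot)[1], dim(rot)[2])
  }
  occ <- which(vapply(seq_len(ncol(mask)), function(j) any(mask[, j]),
                      logical(1)))
  mid <- occ[abs(occ - mean(range(occ))) <= span * diff(range(occ)) / 2]
  if (length(mid) == 0) mid <- occ
  widths <- vapply(mid, function(j) {
    r <- range(which(mask[, j]))
    (r[2] - r[1] + 1) * pixel_size
  }, numeric(1))
  median(widths)
}

#' Per-frame gap morphometrics of a time-lapse stack
#'
#' Segments every frame, extracts the gap (largest tissue-enclosed hole,
#' tie-broken toward the previous frame's centroid), and measures it. Once a
#' frame is closed, later frames are accepted as reopened only when their
#' area exceeds twice the closure threshold (flagged in `reopened`); smaller
#' late holes are treated as closed.
#'
#' @param stack a [frame_stack()] (tissue channel).
#' @param params a [segmentation_params()].
#' @param tissue_width_axis angle (deg) of the inter-cantilever axis.
#' @return A `morphometrics_series` tibble: one row per frame with the
#'   [measure_gap()] columns plus `frame`, `tissue_width_um` and `reopened`.
#'   Calibration and parameters are stored in attributes.
#' @export
morphometrics_series <- function(stack, params = segmentation_params(),
                                 tissue_width_axis = 0) {
  stopifnot(inherits(stack, "frame_stack"))
  times <- stack_times(stack)
  prev_centroid <- NULL
  seen_closed <- FALSE
  rows <- vector("list", n_frames(stack))
  for (i in seq_len(n_frames(stack))) {
    row <- tryCatch({
      mask <- segment_frame(get_frame(stack, i), params)
      gap <- extract_gap_region(mask, prev_centroid, stack$pixel_size)
      m <- measure_gap(gap$gap, stack$pixel_size, times[i],
                       params$closure_threshold)
      tw <- if (any(mask))
        tissue_width(mask, stack$pixel_size, tissue_width_axis) else NA_real_
      m$tissue_width_um <- tw
      m$reopened <- FALSE
      if (seen_closed && !m$closed) {
        if (m$area_um2 > 2 * params$closure_threshold) m$reopened <- TRUE
        else {
          m$closed <- TRUE
          m[c("a_um", "b_um", "orientation_deg", "circularity")] <- NA_real_
        }
      }
      if (!m$closed) prev_centroid <- c(m$centroid_x_um, m$centroid_y_um)
      seen_closed <- seen_closed || m$closed
      m
    }, error = function(e) {
      tibble(t_h = times[i], area_um2 = NA_real_, centroid_x_um = NA_real_,
             centroid_y_um = NA_real_, a_um = NA_real_, b_um = NA_real_,
             orientation_deg = NA_real_, circularity = NA_real_,
             closed = NA, tissue_width_um = NA_real_, reopened = FALSE)
    })
    rows[[i]] <- row
  }
  out <- bind_rows(rows)
  out <- tibble(frame = seq_len(nrow(out)), out)
  attr(out, "pixel_size") <- stack$pixel_size
  attr(out, "frame_interval") <- stack$frame_interval
  attr(out, "params") <- params
  class(out) <- c("morphometrics_series", class(out))
  out
}
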