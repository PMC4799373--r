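# Independent oracles and shared fixtures, kept free of the code paths they
# check.

# rasterize a filled ellipse by pixel-center membership
raster_ellipse <- function(h, w, cx, cy, a, b, angle_deg = 0) {
  co <- cos(angle_deg * pi / 180); si <- sin(angle_deg * pi / 180)
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), w), h, w)
  xr <- (x - cx) * co + (y - cy) * si
  yr <- -(x - cx) * si + (y - cy) * co
  (xr / a)^2 + (yr / b)^2 <= 1
}

# exhaustive-summation moment oracle: centroid + semi-axes + orientation
moment_oracle <- function(mask, pixel_size = 1) {
  idx <- which(mask, arr.ind = TRUE)
  xs <- (idx[, 2] - 1) * pixel_size
  ys <- (idx[, 1] - 1) * pixel_size
  n <- length(xs)
  cx <- sum(xs) / n; cy <- sum(ys) / n
  cxx <- sum((xs - cx)^2) / n
  cyy <- sum((ys - cy)^2) / n
  cxy <- sum((xs - cx) * (ys - cy)) / n
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  list(area = n * pixel_size^2, cx = cx, cy = cy,
       a = 2 * sqrt(ev$values[1]), b = 2 * sqrt(ev$values[2]),
       angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi)
}

# brute-force k x k median filter (interior pixels only)
median_oracle <- function(x, radius) {
  out <- x
  h <- nrow(x); w <- ncol(x)
  for (i in (1 + radius):(h - radius))
    for (j in (1 + radius):(w - radius))
      out[i, j] <- median(x[(i - radius):(i + radius),
                            (j - radius):(j + radius)])
  out
}

# flood fill of the FALSE region reachable from the image border (iterated
# 4-neighbour dilation); everything FALSE and unreached is an enclosed hole
border_flood_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  reached <- matrix(FALSE, h, w)
  reached[1, ] <- !mask[1, ]; reached[h, ] <- !mask[h, ]
  reached[, 1] <- !mask[, 1]; reached[, w] <- !mask[, w]
  repeat {
    grown <- reached
    grown[-1, ] <- grown[-1, ] | reached[-h, ]
    grown[-h, ] <- grown[-h, ] | reached[-1, ]
    grown[, -1] <- grown[, -1] | reached[, -w]
    grown[, -w] <- grown[, -w] | reached[, -1]
    grown <- grown & !mask
    if (identical(grown, reached)) break
    reached <- grown
  }
  !mask & !reached
}

# render a frame of Gaussian spots directly (independent of render_scene)
spot_frame <- function(h, w, xs_px, ys_px, sigma, amplitude = 1,
                       background = 0) {
  fr <- matrix(background, h, w)
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), w), h, w)
  for (i in seq_along(xs_px))
    fr <- fr + amplitude * exp(-((x - xs_px[i])^2 + (y - ys_px[i])^2) /
                                 (2 * sigma^2))
  fr
}

# small, fast scene: 300 x 300 px, 12 h, closes before the end
small_scene_config <- function(...) {
  defaults <- list(image_shape = c(300L, 300L), duration = 12,
                   initial_gap_area = 7000, closure_rate = 1000,
                   peak_time = 6, n_cells = 30L, edge_fraction = 0.3,
                   distal_distance = 40, n_beads_per_cantilever = 3L,
                   seed = 7L)
  do.call(scene_config, utils::modifyList(defaults, list(...)))
}

# scene cache so expensive renders are shared between test blocks
.scene_cache <- new.env(parent = emptyenv())
cached_scene <- function(key, maker) {
  if (is.null(.scene_cache[[key]])) .scene_cache[[key]] <- maker()
  .scene_cache[[key]]
}

# truth tracks in the column layout the tracking functions expect
truth_tracks <- function(scene) {
  tr <- scene$truth$tracks
  names(tr)[names(tr) == "cell_id"] <- "track_id"
  tr
}

# fraction of consecutive-frame links that connect the same generator cell,
# computed from link_tracks() run on the identity-stripped truth positions
link_accuracy <- function(scene, max_link_distance = 20) {
  tr <- scene$truth$tracks
  ts <- link_tracks(tr[, c("frame", "t_h", "x_um", "y_um")],
                    max_link_distance)
  key <- paste(tr$frame, round(tr$x_um, 6), round(tr$y_um, 6))
  id_map <- stats::setNames(tr$cell_id, key)
  ts$cell <- id_map[paste(ts$frame, round(ts$x_um, 6), round(ts$y_um, 6))]
  links <- do.call(rbind, lapply(split(ts, ts$track_id), function(g)
    if (nrow(g) > 1) cbind(g$cell[-nrow(g)], g$cell[-1])))
  mean(links[, 1] == links[, 2])
}
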