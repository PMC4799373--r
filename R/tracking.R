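# scale-normalized Laplacian-of-Gaussian kernel (negative center, so bright
# blobs give positive response after negation)
log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  ax <- -r:r
  g <- outer(exp(-ax^2 / (2 * sigma^2)), exp(-ax^2 / (2 * sigma^2)))
  g <- g / sum(g)
  d2 <- outer(ax^2, ax^2, "+")
  k <- g * (d2 - 2 * sigma^2) / sigma^4
  k <- k - mean(k)            # zero DC response
  -sigma^2 * k                # scale-normalized, positive at bright blobs
}

#' Detect nuclear spots in one frame
#'
#' Laplacian-of-Gaussian blob detection: local maxima of the
#' scale-normalized LoG response above `detect_threshold`, refined to
#' sub-pixel position by the intensity-weighted centroid of a local window.
#' Detections closer than one `blob_sigma` are merged, keeping the stronger.
#'
#' @param image 2D intensity matrix.
#' @param blob_sigma spot scale in pixels (> 0); match to the nuclear radius.
#' @param detect_threshold minimum LoG response (intensity units). For a
#'   Gaussian spot of matching scale the response is roughly half the spot
#'   amplitude.
#' @param pixel_size um per pixel, for the reported physical coordinates.
#' @return Tibble `x_um`, `y_um`, `x_px`, `y_px` (0-based), `response`.
#' @export
detect_nuclei <- function(image, blob_sigma = 3, detect_threshold = 0.1,
                          pixel_size = 1) {
  if (blob_sigma <= 0) abort("blob_sigma must be positive")
  stopifnot(is.matrix(image))
  resp <- as.matrix(EBImage::filter2(EBImage::Image(image),
                                     log_kernel(blob_sigma)))
  h <- nrow(resp); w <- ncol(resp)
  # strict 8-neighbour local maxima
  is_max <- resp > detect_threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    shifted[rs, cs] <- resp[rs - dr, cs - dc]
    is_max <- is_max & (resp >= shifted)
  }
  peaks <- which(is_max, arr.ind = TRUE)
  if (nrow(peaks) == 0)
    return(tibble(x_um = numeric(), y_um = numeric(), x_px = numeric(),
                  y_px = numeric(), response = numeric()))
  # sub-pixel refinement: response-weighted centroid in a local window
  rad <- ceiling(blob_sigma)
  refined <- t(apply(peaks, 1, function(p) {
    rr <- max(1, p[1] - rad):min(h, p[1] + rad)
    cc <- max(1, p[2] - rad):min(w, p[2] + rad)
    win <- pmax(resp[rr, cc, drop = FALSE], 0)
    if (sum(win) == 0) return(c(p[1], p[2]))
    c(sum(rr * rowSums(win)) / sum(win), sum(cc * colSums(win)) / sum(win))
  }))
  spots <- tibble(y_px = refined[, 1] - 1, x_px = refined[, 2] - 1,
                  response = resp[peaks])
  spots <- arrange(spots, dplyr::desc(.data$response))
  # merge duplicates within one blob_sigma, strongest first
  keep <- rep(TRUE, nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(spots)) > i)
    if (!length(later)) next
    d2 <- (spots$x_px[later] - spots$x_px[i])^2 +
      (spots$y_px[later] - spots$y_px[i])^2
    keep[later[d2 < blob_sigma^2]] <- FALSE
  }
  spots <- spots[keep, ]
  tibble(x_um = spots$x_px * pixel_size, y_um = spots$y_px * pixel_size,
         x_px = spots$x_px, y_px = spots$y_px, response = spots$response)
}

#' Detect spots in every frame of a stack
#'
#' @param stack a [frame_stack()] (nuclei channel).
#' @inheritParams detect_nuclei
#' @return Tibble with `frame`, `t_h` and the [detect_nuclei()] columns.
#' @export
detect_nuclei_series <- function(stack, blob_sigma = 3,
                                 detect_threshold = 0.1) {
  stopifnot(inherits(stack, "frame_stack"))
  times <- stack_times(stack)
  map_dfr(seq_len(n_frames(stack)), function(i) {
    s <- detect_nuclei(get_frame(stack, i), blob_sigma, detect_threshold,
                       stack$pixel_size)
    tibble(frame = i, t_h = times[i], s)
  })
}

#' Link per-frame spots into trajectories
#'
#' Greedy globally-shortest-first assignment between consecutive frames: all
#' candidate links shorter than `max_link_distance` are sorted by length and
#' accepted while both endpoints are free. Unmatched spots terminate or start
#' tracks; there is no gap closing across missing frames.
#'
#' @param spots tibble with `frame`, `x_um`, `y_um` (and optionally `t_h`).
#' @param max_link_distance um; maximum displacement linked across one frame
#'   (default 20 um per 30-min frame).
#' @return Tibble `track_id`, `frame`, `t_h` (if supplied), `x_um`, `y_um`,
#'   ordered by track and frame; class `track_set`.
#' @export
link_tracks <- function(spots, max_link_distance = 20) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(spots)))
  frames <- sort(unique(spots$frame))
  if (length(frames) < 2) abort("need spots from at least 2 frames")
  spots <- arrange(as_tibble(spots), .data$frame)
  spots$.row <- seq_len(nrow(spots))
  spots$track_id <- NA_integer_
  by_frame <- split(spots, spots$frame)
  next_id <- 0L
  first <- by_frame[[as.character(frames[1])]]
  spots$track_id[first$.row] <- seq_len(nrow(first))
  next_id <- nrow(first)
  for (fi in seq_len(length(frames) - 1)) {
    f0 <- frames[fi]; f1 <- frames[fi + 1]
    cur <- by_frame[[as.character(f0)]]
    nxt <- by_frame[[as.character(f1)]]
    cur$track_id <- spots$track_id[cur$.row]
    if (f1 - f0 == 1 && nrow(cur) > 0 && nrow(nxt) > 0) {
      d <- outer(cur$x_um, nxt$x_um, "-")^2 + outer(cur$y_um, nxt$y_um, "-")^2
      cand <- which(d <= max_link_distance^2, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        used_cur <- rep(FALSE, nrow(cur)); used_nxt <- rep(FALSE, nrow(nxt))
        for (ci in seq_len(nrow(cand))) {
          i <- cand[ci, 1]; j <- cand[ci, 2]
          if (used_cur[i] || used_nxt[j]) next
          used_cur[i] <- TRUE; used_nxt[j] <- TRUE
          spots$track_id[nxt$.row[j]] <- cur$track_id[i]
        }
      }
    }
    new <- nxt$.row[is.na(spots$track_id[nxt$.row])]
    if (length(new)) {
      spots$track_id[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
  }
  keep <- c("track_id", "frame", intersect("t_h", names(spots)),
            "x_um", "y_um")
  out <- arrange(spots[, keep], .data$track_id, .data$frame)
  class(out) <- c("track_set", class(out))
  out
}

# minimum distance from points to a boundary polygon (n x 2 matrix)
dist_to_boundary <- function(x, y, boundary) {
  if (is.null(boundary)) return(rep(NA_real_, length(x)))
  vapply(seq_along(x), function(i)
    sqrt(min((boundary[, 1] - x[i])^2 + (boundary[, 2] - y[i])^2)),
    numeric(1))
}

#' Gap geometry from a measured morphometrics series
#'
#' Converts the moment-fitted ellipses of a [morphometrics_series()] into the
#' per-frame centroid + boundary-polygon geometry consumed by
#' [migration_stats()]. Closed frames reuse the last open frame's boundary.
#'
#' @param series a [morphometrics_series()].
#' @param n_boundary polygon vertices per frame.
#' @return Tibble `frame`, `t_h`, `cx_um`, `cy_um`, `boundary` (list-column
#'   of n x 2 matrices).
#' @export
gap_geometry <- function(series, n_boundary = 360) {
  phi <- seq(0, 2 * pi, length.out = n_boundary + 1)[-(n_boundary + 1)]
  last <- NULL; last_c <- c(NA_real_, NA_real_)
  bnds <- vector("list", nrow(series))
  cxs <- cys <- numeric(nrow(series))
  for (i in seq_len(nrow(series))) {
    if (!is.na(series$a_um[i]) && !isTRUE(series$closed[i])) {
      th <- series$orientation_deg[i] * pi / 180
      ex <- series$a_um[i] * cos(phi); ey <- series$b_um[i] * sin(phi)
      last <- cbind(series$centroid_x_um[i] + ex * cos(th) - ey * sin(th),
                    series$centroid_y_um[i] + ex * sin(th) + ey * cos(th))
      last_c <- c(series$centroid_x_um[i], series$centroid_y_um[i])
    }
    bnds[[i]] <- last
    cxs[i] <- last_c[1]; cys[i] <- last_c[2]
  }
  tibble(frame = series$frame, t_h = series$t_h, cx_um = cxs, cy_um = cys,
         boundary = bnds)
}

#' Per-track migration statistics
#'
#' For each track, over the analysis interval: the net displacement; the
#' radial migration angle — the angle between the net displacement and the
#' unit vector from the track's start position toward the gap centroid,
#' folded to [0, 180] degrees (0 = toward the gap, 90 = tangential, 180 =
#' away); the location class from the track's mean distance to the gap
#' boundary (<= `edge_band` = "edge", >= `distal_distance` = "distal", else
#' "other"); and the maximum frame-to-frame speed.
#'
#' @param tracks tibble from [link_tracks()] (or ground-truth tracks with
#'   `cell_id` renamed `track_id`) with `track_id`, `frame`, `t_h`, `x_um`,
#'   `y_um`.
#' @param geometry per-frame gap geometry from [gap_geometry()] or
#'   [truth_gap_geometry()].
#' @param edge_band um; mean boundary distance below which a track is "edge".
#' @param distal_distance um; mean boundary distance above which a track is
#'   "distal" (100 um in the assay).
#' @param interval `(t0, t1)` hours; only samples inside are analysed
#'   (default the full series).
#' @return Tibble, one row per track: `track_id`, `class`, `n_samples`,
#'   `net_dx_um`, `net_dy_um`, `net_displacement_um`, `radial_angle_deg`,
#'   `max_speed_um_h`, `mean_boundary_dist_um`.
#' @export
migration_stats <- function(tracks, geometry, edge_band = 20,
                            distal_distance = 100, interval = NULL) {
  stopifnot(all(c("track_id", "frame", "t_h", "x_um", "y_um") %in%
                  names(tracks)))
  if (!is.null(interval)) {
    if (diff(range(interval)) <= 0) abort("zero-length interval")
    tracks <- tracks[tracks$t_h >= interval[1] & tracks$t_h <= interval[2], ]
  }
  if (nrow(tracks) == 0) abort("no track samples in interval")
  geom_idx <- setNames(seq_len(nrow(geometry)), geometry$frame)
  map_dfr(split(tracks, tracks$track_id), function(tr) {
    tr <- arrange(tr, .data$frame)
    n <- nrow(tr)
    gi <- geom_idx[as.character(tr$frame)]
    dists <- unlist(lapply(seq_len(n), function(i)
      dist_to_boundary(tr$x_um[i], tr$y_um[i], geometry$boundary[[gi[i]]])))
    mean_dist <- mean(dists, na.rm = TRUE)
    cls <- if (is.nan(mean_dist)) NA_character_
      else if (mean_dist <= edge_band) "edge"
      else if (mean_dist >= distal_distance) "distal" else "other"
    net <- c(tr$x_um[n] - tr$x_um[1], tr$y_um[n] - tr$y_um[1])
    nd <- sqrt(sum(net^2))
    ang <- NA_real_
    if (n >= 2 && nd > 0) {
      u <- c(geometry$cx_um[gi[1]] - tr$x_um[1],
             geometry$cy_um[gi[1]] - tr$y_um[1])
      if (sqrt(sum(u^2)) > 0) {
        cosang <- sum(net * u) / (nd * sqrt(sum(u^2)))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      }
    }
    ms <- if (n >= 2) {
      dt <- diff(tr$t_h)
      max(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) / dt)
    } else NA_real_
    tibble(track_id = tr$track_id[1], class = cls, n_samples = n,
           net_dx_um = net[1], net_dy_um = net[2], net_displacement_um = nd,
           radial_angle_deg = ang, max_speed_um_h = ms,
           mean_boundary_dist_um = mean_dist)
  })
}

#' Windrose histogram of radial migration angles
#'
#' Percentage of tracks per angular bin over [0, 180] degrees; bins are
#' anchored at 0 degrees and the last bin is closed at 180. The default
#' 20-degree width places 90 degrees at a bin center.
#'
#' @param stats annotated track table from [migration_stats()].
#' @param bin_width degrees (must divide 180).
#' @param class optional class filter (`"edge"`, `"distal"`, `"other"`).
#' @return Tibble `bin_start_deg`, `bin_end_deg`, `bin_mid_deg`, `n`,
#'   `percent`; percentages sum to 100.
#' @export
windrose <- function(stats, bin_width = 20, class = NULL) {
  stopifnot(180 %% bin_width == 0)
  if (!is.null(class)) stats <- stats[stats$class %in% class, ]
  ang <- stats$radial_angle_deg
  ang <- ang[!is.na(ang)]
  if (!length(ang)) abort("no eligible tracks")
  edges <- seq(0, 180, by = bin_width)
  bin <- pmin(floor(ang / bin_width) + 1L, length(edges) - 1L)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  tibble(bin_start_deg = edges[-length(edges)], bin_end_deg = edges[-1],
         bin_mid_deg = edges[-length(edges)] + bin_width / 2,
         n = counts, percent = 100 * counts / sum(counts))
}

#' Per-track maximum-speed table
#'
#' @param stats annotated track table from [migration_stats()].
#' @param class optional class filter.
#' @return Tibble `track_id`, `class`, `max_speed_um_h`, `n_samples`.
#' @export
speed_table <- function(stats, class = NULL) {
  if (nrow(stats) == 0) abort("empty track set")
  if (!is.null(class)) stats <- stats[stats$class %in% class, ]
  stats[, c("track_id", "class", "max_speed_um_h", "n_samples")]
}
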