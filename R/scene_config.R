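#' Configuration of a synthetic wounded-microtissue scene
#'
#' Defines the geometry, dynamics, optics and noise of a simulated time-lapse
#' experiment: a fibrocellular band anchored between two cantilever caps, an
#' elliptical gap that briefly widens and then closes at a constant areal
#' rate, nuclei migrating tangentially at the wound edge and radially inward
#' from distal positions, and cantilever-cap beads displaced in proportion to
#' a piecewise-linear tension profile through a calibrated spring constant.
#'
#' Defaults reproduce the study conditions these assays are run under:
#' 30-min frames for 24 h (49 frames), an initial gap of 30,000 um^2 closing
#' at 1,344 um^2/h after a brief ~10% widening, k = 2.67 uN/um shared between
#' two cantilevers, a tension profile that drops immediately after wounding,
#' peaks near 10 h and plateaus slightly below baseline, and a 100-um distal
#' band for migration classification.
#'
#' @param image_shape `(H, W)` in pixels.
#' @param pixel_size um per pixel.
#' @param frame_interval h between frames.
#' @param duration total imaging time in h; frames at `0, dt, ..., <= duration`.
#' @param gap_center `(x, y)` of the wound centroid in um (held stationary).
#' @param initial_gap_area um^2 immediately after the incision.
#' @param widening_fraction peak area is `(1 + f) * initial`; `f = 0` skips
#'   the widening phase entirely.
#' @param widening_duration h over which the gap widens and the rough cut edge
#'   smoothens into an ellipse.
#' @param closure_rate areal closure rate in um^2/h (> 0) after the peak.
#' @param gap_aspect_ratio major/minor semi-axis ratio (>= 1); major axis lies
#'   along the inter-cantilever (x) axis.
#' @param n_cells number of tracked nuclei.
#' @param edge_fraction fraction of cells seeded at the wound edge; the rest
#'   are seeded distal.
#' @param edge_band_width um; cells within this distance of the gap boundary
#'   are "edge" cells.
#' @param distal_distance um; cells at least this far from the boundary are
#'   "distal" (100 um in the assay).
#' @param tangential_speed,radial_speed um/h migration speeds of edge
#'   (tangential, fixed random sign per cell) and distal (inward radial) cells.
#' @param speed_noise_sd um/h s.d. of isotropic Gaussian velocity noise.
#' @param n_beads_per_cantilever fluorescent beads per cantilever cap.
#' @param n_cantilevers number of cantilevers (2 in this device).
#' @param spring_constant cantilever spring constant k in uN/um.
#' @param tension_baseline,tension_min,tension_peak,tension_plateau uN; the
#'   pre-wound baseline, the post-wound minimum (reached at the first
#'   post-wound frame), the contraction peak, and the late steady state.
#' @param peak_time h at which tension peaks.
#' @param noise_sd s.d. of additive Gaussian intensity noise (intensity units,
#'   full scale = 1).
#' @param background_level,tissue_level rendered background and tissue
#'   intensities.
#' @param nucleus_sigma,nucleus_amplitude,bead_sigma,bead_amplitude Gaussian
#'   spot size (um) and peak amplitude for the nuclei and bead channels.
#' @param roughness_amplitude relative radial boundary perturbation right
#'   after wounding; decays to 0 over `widening_duration`.
#' @param roughness_modes integer Fourier modes of the boundary perturbation.
#' @param band_margin `(x, y)` um margins between image border and the tissue
#'   band (x margin also leaves room for the cantilever caps).
#' @param seed integer; the single source of all scene randomness.
#'
#' @return A validated `scene_config` list.
#' @seealso [render_scene()], [gap_area_trajectory()], [tension_profile()]
#' @export
scene_config <- function(image_shape = c(600L, 600L),
                         pixel_size = 1.0,
                         frame_interval = 0.5,
                         duration = 24,
                         gap_center = NULL,
                         initial_gap_area = 30000,
                         widening_fraction = 0.1,
                         widening_duration = 1,
                         closure_rate = 1344,
                         gap_aspect_ratio = 1.5,
                         n_cells = 200L,
                         edge_fraction = 0.15,
                         edge_band_width = 20,
                         distal_distance = 100,
                         tangential_speed = 10,
                         radial_speed = 5,
                         speed_noise_sd = 2,
                         n_beads_per_cantilever = 4L,
                         n_cantilevers = 2L,
                         spring_constant = 2.67,
                         tension_baseline = 6,
                         tension_min = 3,
                         tension_peak = 8,
                         peak_time = 10,
                         tension_plateau = 5.5,
                         noise_sd = 0.05,
                         background_level = 0.08,
                         tissue_level = 0.55,
                         nucleus_sigma = 3,
                         nucleus_amplitude = 0.85,
                         bead_sigma = 2,
                         bead_amplitude = 0.9,
                         roughness_amplitude = 0.06,
                         roughness_modes = 3:8,
                         band_margin = c(80, 30),
                         seed = 1L) {
  cfg <- list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    frame_interval = frame_interval, duration = duration,
    gap_center = gap_center, initial_gap_area = initial_gap_area,
    widening_fraction = widening_fraction,
    widening_duration = widening_duration, closure_rate = closure_rate,
    gap_aspect_ratio = gap_aspect_ratio, n_cells = as.integer(n_cells),
    edge_fraction = edge_fraction, edge_band_width = edge_band_width,
    distal_distance = distal_distance, tangential_speed = tangential_speed,
    radial_speed = radial_speed, speed_noise_sd = speed_noise_sd,
    n_beads_per_cantilever = as.integer(n_beads_per_cantilever),
    n_cantilevers = as.integer(n_cantilevers),
    spring_constant = spring_constant,
    tension_baseline = tension_baseline, tension_min = tension_min,
    tension_peak = tension_peak, peak_time = peak_time,
    tension_plateau = tension_plateau, noise_sd = noise_sd,
    background_level = background_level, tissue_level = tissue_level,
    nucleus_sigma = nucleus_sigma, nucleus_amplitude = nucleus_amplitude,
    bead_sigma = bead_sigma, bead_amplitude = bead_amplitude,
    roughness_amplitude = roughness_amplitude,
    roughness_modes = as.integer(roughness_modes),
    band_margin = band_margin, seed = as.integer(seed)
  )
  if (is.null(cfg$gap_center)) {
    cfg$gap_center <- c(
      (cfg$image_shape[2] - 1) * cfg$pixel_size / 2,
      (cfg$image_shape[1] - 1) * cfg$pixel_size / 2
    )
  }
  stopifnot(
    cfg$closure_rate > 0, cfg$widening_fraction >= 0,
    cfg$widening_duration >= 0, cfg$peak_time <= cfg$duration,
    cfg$spring_constant > 0, cfg$pixel_size > 0, cfg$frame_interval > 0,
    cfg$gap_aspect_ratio >= 1, cfg$tangential_speed >= 0,
    cfg$radial_speed >= 0, cfg$speed_noise_sd >= 0,
    cfg$edge_fraction >= 0, cfg$edge_fraction <= 1,
    cfg$noise_sd >= 0, cfg$n_cantilevers == 2L
  )
  band <- scene_band(cfg)
  peak_a <- gap_semiaxes((1 + cfg$widening_fraction) * cfg$initial_gap_area,
                         cfg$gap_aspect_ratio)["a"]
  room <- min(cfg$gap_center[1] - band$x0, band$x1 - cfg$gap_center[1],
              cfg$gap_center[2] - band$y0, band$y1 - cfg$gap_center[2])
  if (peak_a * (1 + cfg$roughness_amplitude) >= room)
    abort("gap larger than tissue band")
  structure(cfg, class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    paste0("<scene_config> %d x %d px @ %.3g um/px, %.3g h x %.3g h frames\n",
           "  gap %.0f um^2 (+%.0f%% over %.3g h), closing at %.0f um^2/h, ",
           "aspect %.2g\n  %d cells, %d beads/cap, k = %.3g uN/um, seed %d\n"),
    x$image_shape[1], x$image_shape[2], x$pixel_size, x$duration,
    x$frame_interval, x$initial_gap_area, 100 * x$widening_fraction,
    x$widening_duration, x$closure_rate, x$gap_aspect_ratio, x$n_cells,
    x$n_beads_per_cantilever, x$spring_constant, x$seed))
  invisible(x)
}

# tissue band extents in um; caps sit just outside the band in x
scene_band <- function(cfg) {
  w_um <- (cfg$image_shape[2] - 1) * cfg$pixel_size
  h_um <- (cfg$image_shape[1] - 1) * cfg$pixel_size
  list(x0 = cfg$band_margin[1], x1 = w_um - cfg$band_margin[1],
       y0 = cfg$band_margin[2], y1 = h_um - cfg$band_margin[2],
       cap_x = c(cfg$band_margin[1] - 25, w_um - cfg$band_margin[1] + 25),
       mid_y = h_um / 2)
}

#' Frame times of a scene
#' @param config a [scene_config()].
#' @return numeric vector `0, dt, ..., <= duration` in hours.
#' @export
scene_times <- function(config) {
  n <- floor(config$duration / config$frame_interval)
  (0:n) * config$frame_interval
}

# semi-axes (a >= b) of an ellipse with given area and aspect ratio
gap_semiaxes <- function(area, aspect) {
  b <- sqrt(pmax(area, 0) / (pi * aspect))
  c(a = aspect * b, b = b)
}

#' Analytic gap-area trajectory
#'
#' Area rises linearly from `initial_gap_area` to
#' `(1 + widening_fraction) * initial_gap_area` over `widening_duration`,
#' then falls linearly at `closure_rate`, clipped at zero. When
#' `widening_fraction = 0` the decline starts at t = 0.
#'
#' @param config a [scene_config()].
#' @return Tibble with `frame`, `t_h`, `area_um2`, and the corresponding
#'   ellipse semi-axes `a_um`, `b_um`.
#' @export
gap_area_trajectory <- function(config) {
  t <- scene_times(config)
  f <- config$widening_fraction
  wd <- if (f > 0) config$widening_duration else 0
  peak <- (1 + f) * config$initial_gap_area
  area <- ifelse(
    t <= wd & wd > 0,
    config$initial_gap_area * (1 + f * t / wd),
    pmax(0, peak - config$closure_rate * (t - wd))
  )
  b <- sqrt(area / (pi * config$gap_aspect_ratio))
  tibble(frame = seq_along(t), t_h = t, area_um2 = area,
         a_um = config$gap_aspect_ratio * b, b_um = b)
}

#' Piecewise-linear tissue tension profile
#'
#' Baseline at t = 0 (the pre-wound frame), an immediate drop to the post-wound
#' minimum at the first post-wound frame, linear rise to the peak at
#' `peak_time`, then linear settling to the sub-baseline plateau at the end of
#' the recording.
#'
#' @param config a [scene_config()].
#' @return Tibble with `frame`, `t_h`, `tension_uN`.
#' @export
tension_profile <- function(config) {
  t <- scene_times(config)
  knots_t <- c(0, config$frame_interval, config$peak_time, max(t))
  knots_v <- c(config$tension_baseline, config$tension_min,
               config$tension_peak, config$tension_plateau)
  keep <- !duplicated(knots_t)
  tension <- approx(knots_t[keep], knots_v[keep], xout = t, rule = 2)$y
  tibble(frame = seq_along(t), t_h = t, tension_uN = tension)
}
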