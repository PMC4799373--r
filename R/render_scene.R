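# run code under a temporary RNG state; the caller's stream is untouched
with_scene_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# radius of an axis-aligned ellipse at polar angle phi (major axis along x)
ellipse_radius <- function(phi, a, b) {
  a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}

#' Sample ground-truth nuclear trajectories
#'
#' Edge cells are seeded just outside the initial gap boundary and take exact
#' tangential steps (perpendicular to the local radius from the gap centroid,
#' step length `tangential_speed * dt`, rotation sign fixed per cell). Distal
#' cells are seeded at least `distal_distance` from the boundary and step
#' radially inward toward the gap centroid at `radial_speed`, stopping at the
#' current boundary. Isotropic Gaussian velocity noise with s.d.
#' `speed_noise_sd` is added to both classes. Cells neither divide nor die.
#'
#' @param config a [scene_config()].
#' @param areas per-frame gap geometry as returned by
#'   [gap_area_trajectory()] (supplied so an externally modified trajectory
#'   can be used).
#' @return Tibble `cell_id`, `class` (`"edge"`/`"distal"`), `frame`, `t_h`,
#'   `x_um`, `y_um`. Deterministic given `config$seed`.
#' @export
sample_cell_tracks <- function(config, areas = gap_area_trajectory(config)) {
  if (config$n_cells <= 0) abort("n_cells must be positive")
  with_scene_seed(config$seed + 101L, {
    nt <- nrow(areas)
    dt <- config$frame_interval
    cx <- config$gap_center[1]; cy <- config$gap_center[2]
    band <- scene_band(config)
    n_edge <- round(config$edge_fraction * config$n_cells)
    n_dist <- config$n_cells - n_edge
    a1 <- areas$a_um[1]; b1 <- areas$b_um[1]
    phi_grid <- seq(0, 2 * pi, length.out = 721)[-721]
    bnd1 <- cbind(cx + ellipse_radius(phi_grid, a1, b1) * cos(phi_grid),
                  cy + ellipse_radius(phi_grid, a1, b1) * sin(phi_grid))

    # seed positions
    pos <- matrix(NA_real_, config$n_cells, 2)
    cls <- character(config$n_cells)
    sgn <- numeric(config$n_cells)
    min_sep <- 12  # um, rejection-sampled minimum seeding separation
    place <- function(idx, gen) {
      for (i in idx) {
        sep <- min_sep
        for (try in 1:1000) {
          p <- gen()
          if (is.null(p)) next
          if (i == 1L || all((pos[seq_len(i - 1), 1] - p[1])^2 +
                             (pos[seq_len(i - 1), 2] - p[2])^2 >= sep^2,
                             na.rm = TRUE)) {
            pos[i, ] <<- p
            break
          }
          if (try %% 200 == 0) sep <- sep * 0.8  # relax if region is crowded
        }
        if (is.na(pos[i, 1])) abort("could not place cells; region too crowded")
      }
    }
    gen_edge <- function() {
      phi <- runif(1, 0, 2 * pi)
      off <- runif(1, 2, max(4, config$edge_band_width * 0.5))
      r <- ellipse_radius(phi, a1, b1) + off
      c(cx + r * cos(phi), cy + r * sin(phi))
    }
    gen_dist <- function() {
      phi <- runif(1, 0, 2 * pi)
      d <- runif(1, config$distal_distance + 20, config$distal_distance + 80)
      r <- ellipse_radius(phi, a1, b1) + d
      p <- c(cx + r * cos(phi), cy + r * sin(phi))
      if (p[1] < band$x0 + 10 || p[1] > band$x1 - 10 ||
          p[2] < band$y0 + 10 || p[2] > band$y1 - 10) return(NULL)
      # true (nearest-point) distance to the boundary, not just radial
      if (min(sqrt((bnd1[, 1] - p[1])^2 + (bnd1[, 2] - p[2])^2)) <
          config$distal_distance + 10) return(NULL)
      p
    }
    if (n_edge > 0) { place(seq_len(n_edge), gen_edge); cls[seq_len(n_edge)] <- "edge" }
    if (n_dist > 0) {
      place(n_edge + seq_len(n_dist), gen_dist)
      cls[n_edge + seq_len(n_dist)] <- "distal"
    }
    sgn <- sample(c(-1, 1), config$n_cells, replace = TRUE)

    traj <- array(NA_real_, c(config$n_cells, nt, 2))
    traj[, 1, ] <- pos
    for (k in seq_len(nt - 1)) {
      dx <- traj[, k, 1] - cx; dy <- traj[, k, 2] - cy
      rr <- sqrt(dx^2 + dy^2)
      ux <- dx / rr; uy <- dy / rr
      step <- matrix(0, config$n_cells, 2)
      edge <- cls == "edge"
      step[edge, 1] <- sgn[edge] * (-uy[edge]) * config$tangential_speed * dt
      step[edge, 2] <- sgn[edge] * ( ux[edge]) * config$tangential_speed * dt
      dist <- cls == "distal"
      step[dist, 1] <- -ux[dist] * config$radial_speed * dt
      step[dist, 2] <- -uy[dist] * config$radial_speed * dt
      if (config$speed_noise_sd > 0)
        step <- step + matrix(rnorm(2 * config$n_cells,
                                    sd = config$speed_noise_sd * dt),
                              config$n_cells, 2)
      nxt <- traj[, k, ] + step
      # distal cells halt at the closing boundary instead of entering the gap
      an <- areas$a_um[k + 1]; bn <- areas$b_um[k + 1]
      if (an > 0) {
        ndx <- nxt[, 1] - cx; ndy <- nxt[, 2] - cy
        nr <- sqrt(ndx^2 + ndy^2)
        nphi <- atan2(ndy, ndx)
        rb <- ellipse_radius(nphi, an, bn)
        inside <- dist & nr < rb + 1
        if (any(inside)) {
          sc <- (rb[inside] + 1) / nr[inside]
          nxt[inside, 1] <- cx + ndx[inside] * sc
          nxt[inside, 2] <- cy + ndy[inside] * sc
        }
      }
      nxt[, 1] <- pmin(pmax(nxt[, 1], band$x0 + 2), band$x1 - 2)
      nxt[, 2] <- pmin(pmax(nxt[, 2], band$y0 + 2), band$y1 - 2)
      traj[, k + 1, ] <- nxt
    }
    tibble(
      cell_id = rep(seq_len(config$n_cells), each = nt),
      class = rep(cls, each = nt),
      frame = rep(seq_len(nt), config$n_cells),
      t_h = rep(areas$t_h, config$n_cells),
      x_um = as.vector(t(traj[, , 1])),
      y_um = as.vector(t(traj[, , 2]))
    )
  })
}

#' Rest (collagenase-baseline) positions of cantilever-cap beads
#'
#' Beads sit on the two cap surfaces just outside the tissue band, spread
#' vertically, with a small seeded placement jitter. Rest positions are the
#' zero-tension configuration the collagenase step measures in the real assay.
#'
#' @param config a [scene_config()].
#' @return Tibble `bead_id`, `cantilever` (0/1), `rest_x_um`, `rest_y_um`.
#' @export
bead_rest_positions <- function(config) {
  with_scene_seed(config$seed + 202L, {
    band <- scene_band(config)
    nb <- config$n_beads_per_cantilever
    spread <- ((seq_len(nb) - (nb + 1) / 2)) * 18
    out <- tibble(
      bead_id = seq_len(2L * nb),
      cantilever = rep(0:1, each = nb),
      rest_x_um = rep(band$cap_x, each = nb) + rnorm(2 * nb, sd = 1.5),
      rest_y_um = rep(band$mid_y + spread, 2) + rnorm(2 * nb, sd = 1.5)
    )
    out
  })
}

#' Bead positions implied by a tension series
#'
#' The total tension is split equally across the two cantilevers; each
#' cantilever's beads are rigidly displaced toward the tissue midline by
#' `tension / (2 k)`.
#'
#' @param tension tibble with `frame`, `t_h`, `tension_uN` (all >= 0), e.g.
#'   from [tension_profile()].
#' @param config a [scene_config()].
#' @param rest rest positions from [bead_rest_positions()].
#' @return Tibble `bead_id`, `cantilever`, `frame`, `t_h`, `x_um`, `y_um`,
#'   `rest_x_um`, `rest_y_um`.
#' @export
bead_positions_from_tension <- function(tension, config,
                                        rest = bead_rest_positions(config)) {
  if (config$spring_constant <= 0) abort("spring constant k must be > 0")
  if (any(tension$tension_uN < 0)) abort("tension must be >= 0")
  defl <- tension$tension_uN / (2 * config$spring_constant)
  out <- tidyr::crossing(rest, tension[, c("frame", "t_h")])
  out$x_um <- out$rest_x_um + ifelse(out$cantilever == 0L, 1, -1) *
    defl[out$frame]
  out$y_um <- out$rest_y_um
  dplyr::arrange(out[, c("bead_id", "cantilever", "frame", "t_h",
                         "x_um", "y_um", "rest_x_um", "rest_y_um")],
                 .data$bead_id, .data$frame)
}

# add Gaussian spots to a frame matrix; positions in um, sigma in um
add_spots <- function(frame, xs, ys, sigma, amplitude, pixel_size) {
  h <- nrow(frame); w <- ncol(frame)
  s_px <- sigma / pixel_size
  r <- ceiling(4 * s_px)
  for (i in seq_along(xs)) {
    c0 <- xs[i] / pixel_size + 1  # 1-based fractional pixel indices
    r0 <- ys[i] / pixel_size + 1
    cc <- max(1, floor(c0 - r)):min(w, ceiling(c0 + r))
    rr <- max(1, floor(r0 - r)):min(h, ceiling(r0 + r))
    if (length(cc) == 0 || length(rr) == 0) next
    g <- outer(exp(-(rr - r0)^2 / (2 * s_px^2)),
               exp(-(cc - c0)^2 / (2 * s_px^2)))
    frame[rr, cc] <- frame[rr, cc] + amplitude * g
  }
  frame
}

#' Render a synthetic wounded-microtissue time-lapse scene
#'
#' Produces three calibrated 16-bit-quantized channels — phase-contrast-like
#' tissue, nuclear fluorescence, and cantilever-cap bead fluorescence — plus
#' the exact ground truth they were rendered from. The tissue channel is a
#' bright band spanning the two cap positions minus an elliptical gap whose
#' area follows [gap_area_trajectory()]; the freshly cut boundary carries a
#' random radial Fourier perturbation whose amplitude decays to zero over
#' `widening_duration`, emulating the smoothing of the rough wound edge. The
#' perturbation is area-normalized so the true gap area is exactly the
#' analytic trajectory. Nuclei and beads are rendered as Gaussian spots at
#' the ground-truth positions; additive Gaussian noise is applied to every
#' channel. All randomness derives from `config$seed`; identical configs give
#' bit-identical stacks.
#'
#' @param config a [scene_config()].
#' @return A `microwound_scene`: list with [frame_stack()]s `tissue`,
#'   `nuclei`, `beads`, and `truth` (tibbles `areas`, `tracks`, `beads`,
#'   `tension`, plus the `config`).
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  areas <- gap_area_trajectory(config)
  tension <- tension_profile(config)
  tracks <- if (config$n_cells > 0) sample_cell_tracks(config, areas) else
    tibble(cell_id = integer(), class = character(), frame = integer(),
           t_h = numeric(), x_um = numeric(), y_um = numeric())
  beads <- bead_positions_from_tension(tension, config)

  h <- config$image_shape[1]; w <- config$image_shape[2]
  ps <- config$pixel_size
  nt <- nrow(areas)
  band <- scene_band(config)
  cx <- config$gap_center[1]; cy <- config$gap_center[2]

  x_um <- (seq_len(w) - 1) * ps
  y_um <- (seq_len(h) - 1) * ps
  band_rows <- which(y_um >= band$y0 & y_um <= band$y1)
  band_cols <- which(x_um >= band$x0 & x_um <= band$x1)

  # base tissue frame: background + band (no gap)
  base <- matrix(config$background_level, h, w)
  base[band_rows, band_cols] <- config$tissue_level

  # gap bounding box and polar fields, computed once
  a_max <- max(areas$a_um) * (1 + config$roughness_amplitude) + 4 * ps
  b_max <- max(areas$b_um) * (1 + config$roughness_amplitude) + 4 * ps
  bb_rows <- which(abs(y_um - cy) <= b_max)
  bb_cols <- which(abs(x_um - cx) <= a_max)
  dxm <- matrix(x_um[bb_cols] - cx, length(bb_rows), length(bb_cols),
                byrow = TRUE)
  dym <- matrix(y_um[bb_rows] - cy, length(bb_rows), length(bb_cols))
  rr <- sqrt(dxm^2 + dym^2)
  th <- atan2(dym, dxm)
  cth <- cos(th); sth <- sin(th)

  # fixed per-scene boundary roughness (Fourier modes in theta)
  nm <- length(config$roughness_modes)
  coefs <- with_scene_seed(config$seed + 303L,
                           matrix(rnorm(2 * nm, sd = 1 / sqrt(nm)), nm, 2))
  eps <- matrix(0, length(bb_rows), length(bb_cols))
  for (j in seq_len(nm)) {
    k <- config$roughness_modes[j]
    eps <- eps + coefs[j, 1] * cos(k * th) + coefs[j, 2] * sin(k * th)
  }
  eps_msq <- sum(coefs^2) / 2

  wd <- if (config$widening_fraction > 0) config$widening_duration else 0
  tissue_arr <- array(0, c(nt, h, w))
  nuc_arr <- array(0, c(nt, h, w))
  bead_arr <- array(0, c(nt, h, w))

  for (k in seq_len(nt)) {
    fr <- base
    if (areas$area_um2[k] > 0) {
      a <- areas$a_um[k]; b <- areas$b_um[k]
      amp <- if (wd > 0) config$roughness_amplitude *
        max(0, 1 - areas$t_h[k] / wd) else
          config$roughness_amplitude * (areas$t_h[k] <= 0)
      nrm <- sqrt(1 + amp^2 * eps_msq)
      rb <- (a * b / sqrt((b * cth)^2 + (a * sth)^2)) * (1 + amp * eps) / nrm
      d <- (rr - rb) / ps                     # signed px distance, + outside
      cov <- pmin(pmax(d + 0.5, 0), 1)        # 1-px anti-aliased edge
      fr[bb_rows, bb_cols] <- config$background_level +
        (config$tissue_level - config$background_level) * cov
    }
    tissue_arr[k, , ] <- fr

    nf <- matrix(config$background_level / 4, h, w)
    tk <- tracks[tracks$frame == k, ]
    if (nrow(tk) > 0)
      nf <- add_spots(nf, tk$x_um, tk$y_um, config$nucleus_sigma,
                      config$nucleus_amplitude, ps)
    nuc_arr[k, , ] <- nf

    bf <- matrix(config$background_level / 4, h, w)
    bk <- beads[beads$frame == k, ]
    bf <- add_spots(bf, bk$x_um, bk$y_um, config$bead_sigma,
                    config$bead_amplitude, ps)
    bead_arr[k, , ] <- bf
  }

  if (config$noise_sd > 0) {
    with_scene_seed(config$seed + 404L, {
      tissue_arr <- tissue_arr + rnorm(length(tissue_arr), sd = config$noise_sd)
      nuc_arr <- nuc_arr + rnorm(length(nuc_arr), sd = config$noise_sd)
      bead_arr <- bead_arr + rnorm(length(bead_arr), sd = config$noise_sd)
    })
  }
  quant16 <- function(a) round(pmin(pmax(a, 0), 1) * 65535) / 65535
  mk <- function(a, ch) frame_stack(quant16(a), pixel_size = ps,
                                    frame_interval = config$frame_interval,
                                    channel = ch)
  structure(
    list(
      tissue = mk(tissue_arr, "tissue"),
      nuclei = mk(nuc_arr, "nuclei"),
      beads = mk(bead_arr, "beads"),
      truth = list(areas = areas, tracks = tracks, beads = beads,
                   tension = tension, config = config)
    ),
    class = "microwound_scene"
  )
}

#' @export
print.microwound_scene <- function(x, ...) {
  cat("<microwound_scene>\n")
  print(x$truth$config)
  invisible(x)
}

#' Ground-truth gap geometry in the format the migration analysis consumes
#'
#' @param scene a `microwound_scene` from [render_scene()], or its `truth`.
#' @param n_boundary number of boundary polygon vertices per frame.
#' @return Tibble with `frame`, `t_h`, `cx_um`, `cy_um` and a `boundary`
#'   list-column of n x 2 matrices (um); closed frames reuse the last open
#'   boundary.
#' @export
truth_gap_geometry <- function(scene, n_boundary = 360) {
  truth <- if (inherits(scene, "microwound_scene")) scene$truth else scene
  cfg <- truth$config
  phi <- seq(0, 2 * pi, length.out = n_boundary + 1)[-(n_boundary + 1)]
  last_open <- NULL
  bnds <- vector("list", nrow(truth$areas))
  for (i in seq_len(nrow(truth$areas))) {
    a <- truth$areas$a_um[i]; b <- truth$areas$b_um[i]
    if (truth$areas$area_um2[i] > 0) {
      r <- ellipse_radius(phi, a, b)
      last_open <- cbind(cfg$gap_center[1] + r * cos(phi),
                         cfg$gap_center[2] + r * sin(phi))
    }
    bnds[[i]] <- last_open
  }
  tibble(frame = truth$areas$frame, t_h = truth$areas$t_h,
         cx_um = cfg$gap_center[1], cy_um = cfg$gap_center[2],
         boundary = bnds)
}
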