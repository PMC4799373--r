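#' Track cantilever-cap beads through a time-lapse stack
#'
#' Each bead is relocated frame by frame to the background-subtracted
#' intensity-weighted centroid of the pixels within `search_radius` of its
#' previous position. A bead whose search window loses signal is flagged lost
#' and excluded from the tension computation from that frame on.
#'
#' @param stack a [frame_stack()] (bead channel).
#' @param initial tibble with `bead_id`, `cantilever`, `x_um`, `y_um`
#'   starting positions (manual clicks in real use; ground truth in tests).
#' @param search_radius um search window half-width around the previous
#'   position.
#' @param min_peak minimum background-subtracted peak intensity below which a
#'   bead counts as lost.
#' @return Tibble `bead_id`, `cantilever`, `frame`, `t_h`, `x_um`, `y_um`,
#'   `lost`.
#' @export
track_beads <- function(stack, initial, search_radius = 6, min_peak = 0.1) {
  stopifnot(inherits(stack, "frame_stack"),
            all(c("bead_id", "cantilever", "x_um", "y_um") %in%
                  names(initial)))
  ps <- stack$pixel_size
  r_px <- search_radius / ps
  times <- stack_times(stack)
  h <- dim(stack)[2]; w <- dim(stack)[3]
  out <- vector("list", nrow(initial))
  for (b in seq_len(nrow(initial))) {
    pos <- c(initial$x_um[b], initial$y_um[b]) / ps  # 0-based px
    lost <- FALSE
    rows <- matrix(NA_real_, n_frames(stack), 3)
    for (k in seq_len(n_frames(stack))) {
      if (!lost) {
        img <- get_frame(stack, k)
        rr <- max(1, floor(pos[2] + 1 - r_px)):min(h, ceiling(pos[2] + 1 + r_px))
        cc <- max(1, floor(pos[1] + 1 - r_px)):min(w, ceiling(pos[1] + 1 + r_px))
        win <- img[rr, cc, drop = FALSE]
        wgt <- pmax(win - median(win), 0)
        if (max(wgt) < min_peak || sum(wgt) == 0) {
          lost <- TRUE
        } else {
          pos <- c(sum(colSums(wgt) * cc) / sum(wgt) - 1,
                   sum(rowSums(wgt) * rr) / sum(wgt) - 1)
        }
      }
      rows[k, ] <- c(pos * ps, lost)
    }
    out[[b]] <- tibble(bead_id = initial$bead_id[b],
                       cantilever = initial$cantilever[b],
                       frame = seq_len(n_frames(stack)), t_h = times,
                       x_um = rows[, 1], y_um = rows[, 2],
                       lost = as.logical(rows[, 3]))
  }
  bind_rows(out)
}

#' Per-cantilever deflections from bead tracks
#'
#' Deflection of each bead is its displacement from the collagenase-baseline
#' rest position, projected on the inter-cantilever axis and signed toward
#' the tissue midline (off-axis jitter is noise, not load); the per-cantilever
#' deflection is the mean over that cantilever's unlost beads.
#' `mode = "magnitude"` uses the planar displacement magnitude instead.
#'
#' @param bead_tracks tibble from [track_beads()] (columns `bead_id`,
#'   `cantilever`, `frame`, `t_h`, `x_um`, `y_um`, optional `lost`).
#' @param baseline tibble `bead_id`, `x_um`, `y_um` rest positions.
#' @param mode `"projected"` (default) or `"magnitude"`.
#' @param axis_angle inter-cantilever axis angle in degrees (0 = image x).
#' @return Tibble `frame`, `t_h`, `cantilever`, `deflection_um`.
#' @export
deflections <- function(bead_tracks, baseline,
                        mode = c("projected", "magnitude"), axis_angle = 0) {
  mode <- match.arg(mode)
  if (!all(unique(bead_tracks$bead_id) %in% baseline$bead_id))
    abort("every used bead needs a baseline position")
  if (!"lost" %in% names(bead_tracks)) bead_tracks$lost <- FALSE
  d <- left_join(bead_tracks,
                 setNames(baseline[, c("bead_id", "x_um", "y_um")],
                          c("bead_id", "bx_um", "by_um")),
                 by = "bead_id")
  d <- d[!d$lost, ]
  if (nrow(d) == 0) abort("no valid beads")
  ux <- cos(axis_angle * pi / 180); uy <- sin(axis_angle * pi / 180)
  # midline direction: cantilever 0 deflects along +axis, cantilever 1 along -
  proj <- (d$x_um - d$bx_um) * ux + (d$y_um - d$by_um) * uy
  d$defl <- if (mode == "projected")
    ifelse(d$cantilever == 0, proj, -proj)
  else sqrt((d$x_um - d$bx_um)^2 + (d$y_um - d$by_um)^2)
  cants <- sort(unique(bead_tracks$cantilever))
  out <- d |>
    group_by(.data$frame, .data$t_h, .data$cantilever) |>
    summarise(deflection_um = mean(.data$defl), .groups = "drop")
  counts <- table(out$frame)
  if (any(counts < length(cants)))
    abort("a cantilever has zero valid beads in some frame")
  arrange(out, .data$frame, .data$cantilever)
}

#' Total tissue tension from cantilever deflections
#'
#' Tension at each frame is the spring constant times the sum of the
#' per-cantilever deflections; the baseline tension is the mean over the
#' pre-wound frames (t <= 0 by default).
#'
#' @param defl tibble from [deflections()].
#' @param k cantilever spring constant in uN/um (> 0; 2.67 for this device).
#' @param baseline_window `(t0, t1)` hours over which baseline tension is
#'   averaged; default all frames with `t_h <= 0`.
#' @return A `tension_series` tibble: `frame`, `t_h`, one
#'   `deflection_c<j>_um` column per cantilever, `tension_uN`; spring
#'   constant and baseline tension stored as attributes.
#' @export
total_tension <- function(defl, k, baseline_window = NULL) {
  if (k <= 0) abort("spring constant k must be > 0")
  wide <- tidyr::pivot_wider(defl, names_from = "cantilever",
                             values_from = "deflection_um",
                             names_prefix = "deflection_c")
  names(wide) <- sub("^(deflection_c[0-9]+)$", "\\1_um", names(wide))
  dcols <- grep("^deflection_c", names(wide), value = TRUE)
  if (anyNA(wide[dcols])) abort("missing frames for some cantilever")
  wide$tension_uN <- k * rowSums(wide[, dcols, drop = FALSE])
  wide <- arrange(wide, .data$frame)
  pre <- if (is.null(baseline_window)) wide$t_h <= 0
    else wide$t_h >= baseline_window[1] & wide$t_h <= baseline_window[2]
  attr(wide, "spring_constant") <- k
  attr(wide, "baseline_tension_uN") <-
    if (any(pre)) mean(wide$tension_uN[pre]) else NA_real_
  class(wide) <- c("tension_series", class(wide))
  wide
}

#' Normalize a tension series to its pre-wound baseline
#'
#' Adds `tension_norm = tension_uN / baseline`; the pre-wound window maps to
#' about 1 and the late plateau of a healing tissue sits slightly below 1.
#'
#' @param series a `tension_series` from [total_tension()].
#' @param baseline optional baseline tension in uN, overriding the stored one.
#' @return The series with a `tension_norm` column.
#' @export
normalize_tension <- function(series, baseline = NULL) {
  if (is.null(baseline)) baseline <- attr(series, "baseline_tension_uN")
  if (is.null(baseline) || is.na(baseline) || baseline <= 0)
    abort("baseline tension must be > 0")
  series$tension_norm <- series$tension_uN / baseline
  series
}
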