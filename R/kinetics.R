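#' Detect the post-wound widening peak
#'
#' The gap briefly widens after the incision before closing. The peak is the
#' earliest maximum of area within the first `horizon` fraction of frames;
#' a monotone-decreasing series peaks at its first frame.
#'
#' @param series data frame with `t_h` and `area_um2` (e.g. a
#'   [morphometrics_series()] or ground-truth trajectory).
#' @param horizon fraction of frames searched for the peak (default 0.25).
#' @return One-row tibble `peak_area_um2`, `peak_time_h`, `peak_frame`.
#' @export
detect_widening <- function(series, horizon = 0.25) {
  stopifnot(nrow(series) >= 2)
  n <- max(2L, ceiling(horizon * nrow(series)))
  head_area <- series$area_um2[seq_len(n)]
  i <- which.max(head_area)  # earliest tie wins
  tibble(peak_area_um2 = series$area_um2[i], peak_time_h = series$t_h[i],
         peak_frame = i)
}

#' Fit the linear closure phase of a gap-area series
#'
#' Ordinary least squares on (t, area) from the detected widening peak to the
#' last frame whose area exceeds the closure threshold. The closure rate is
#' the negated slope (positive = closing), reported with its standard error
#' and R^2. Closure time is the first time the area drops below the closure
#' threshold (NA if the gap never closes).
#'
#' @param series data frame with `t_h`, `area_um2` and optionally centroid
#'   columns (used for [centroid_drift()]).
#' @param closure_threshold um^2 defining "closed"; defaults to the threshold
#'   stored by [morphometrics_series()], else 100.
#' @param horizon widening-peak search horizon, see [detect_widening()].
#' @return A `closure_kinetics` object; see [tidy()] and [glance()] methods.
#' @export
estimate_closure_rate <- function(series, closure_threshold = NULL,
                                  horizon = 0.25) {
  if (is.null(closure_threshold)) {
    p <- attr(series, "params")
    closure_threshold <- if (!is.null(p)) p$closure_threshold else 100
  }
  series <- series[!is.na(series$area_um2), ]
  if (all(series$area_um2 < closure_threshold)) abort("all-closed series")
  pk <- detect_widening(series, horizon)
  open <- which(series$area_um2 >= closure_threshold)
  fit_idx <- seq(pk$peak_frame, max(open))
  fit_idx <- fit_idx[fit_idx %in% seq_len(nrow(series))]
  if (length(fit_idx) < 4) abort("fit window shorter than 4 frames")
  dat <- series[fit_idx, ]
  fit <- lm(area_um2 ~ t_h, data = dat)
  # synthetic series can be exactly linear; the perfect-fit warning is noise
  sm <- suppressWarnings(summary(fit))
  sst <- sum((dat$area_um2 - mean(dat$area_um2))^2)
  r2 <- if (sst < .Machine$double.eps * max(1, mean(dat$area_um2)^2)) 1
    else 1 - sum(fit$residuals^2) / sst
  closed_after <- which(series$area_um2 < closure_threshold &
                          series$t_h >= pk$peak_time_h)
  drift <- tryCatch(centroid_drift(series, closure_threshold),
                    error = function(e) NA_real_)
  structure(list(
    closure_rate = -unname(coef(fit)[2]),
    rate_se = sm$coefficients[2, 2],
    fit_window = c(t_start = dat$t_h[1], t_end = dat$t_h[nrow(dat)]),
    r_squared = min(max(r2, 0), 1),
    closure_time = if (length(closed_after)) series$t_h[min(closed_after)]
      else NA_real_,
    peak_area = pk$peak_area_um2,
    peak_time = pk$peak_time_h,
    centroid_drift = drift,
    n_frames = length(fit_idx),
    closure_threshold = closure_threshold,
    fit = fit
  ), class = "closure_kinetics")
}

#' @export
print.closure_kinetics <- function(x, ...) {
  cat(sprintf(
    paste0("<closure_kinetics> rate %.1f +/- %.1f um^2/h (R^2 = %.4f)\n",
           "  fit window %.2g-%.2g h (%d frames), peak %.0f um^2 at %.2g h\n",
           "  closure time %s h, centroid drift %.2f um\n"),
    x$closure_rate, x$rate_se, x$r_squared, x$fit_window[1], x$fit_window[2],
    x$n_frames, x$peak_area, x$peak_time,
    if (is.na(x$closure_time)) "NA" else sprintf("%.2g", x$closure_time),
    x$centroid_drift))
  invisible(x)
}

#' @rdname estimate_closure_rate
#' @param x a `closure_kinetics` object.
#' @param ... unused.
#' @export
tidy.closure_kinetics <- function(x, ...) {
  tibble(term = c("closure_rate"), estimate = x$closure_rate,
         std.error = x$rate_se)
}

#' @rdname estimate_closure_rate
#' @export
glance.closure_kinetics <- function(x, ...) {
  tibble(closure_rate_um2_h = x$closure_rate, rate_se_um2_h = x$rate_se,
         r_squared = x$r_squared, closure_time_h = x$closure_time,
         peak_area_um2 = x$peak_area, peak_time_h = x$peak_time,
         centroid_drift_um = x$centroid_drift,
         fit_start_h = unname(x$fit_window[1]),
         fit_end_h = unname(x$fit_window[2]), n_frames = x$n_frames)
}

# fraction of the peak area closed by t_eval
closed_fraction <- function(series, t_eval, horizon = 0.25) {
  pk <- detect_widening(series, horizon)
  if (t_eval < pk$peak_time_h) abort("t_eval before widening peak")
  if (t_eval > max(series$t_h)) abort("series does not cover t_eval")
  a_eval <- approx(series$t_h, series$area_um2, xout = t_eval)$y
  (pk$peak_area_um2 - a_eval) / pk$peak_area_um2
}

#' Closure of a treated tissue relative to controls
#'
#' The fraction of the peak gap area closed by `t_eval`,
#' `(A_peak - A(t_eval)) / A_peak`, divided by the mean of the same fraction
#' over the control series. A series evaluated against itself gives exactly 1.
#' `method = "slope"` instead normalizes fitted closure rates
#' ([estimate_closure_rate()]) to the control mean rate.
#'
#' @param treated data frame with `t_h`, `area_um2`.
#' @param controls list of control series (same columns).
#' @param t_eval evaluation time in hours (must be at or after the widening
#'   peak of every series).
#' @param method `"fraction"` (default) or `"slope"`.
#' @return Dimensionless relative closure.
#' @export
relative_closure <- function(treated, controls, t_eval = 10,
                             method = c("fraction", "slope")) {
  method <- match.arg(method)
  if (!length(controls)) abort("at least one control series required")
  if (method == "fraction") {
    fr <- closed_fraction(treated, t_eval)
    ctrl <- mean(vapply(controls, closed_fraction, numeric(1),
                        t_eval = t_eval))
  } else {
    fr <- estimate_closure_rate(treated)$closure_rate
    ctrl <- mean(vapply(controls, function(s)
      estimate_closure_rate(s)$closure_rate, numeric(1)))
  }
  if (abs(ctrl) < 1e-9) abort("controls close nothing by t_eval")
  fr / ctrl
}

#' Maximum centroid drift of the open gap
#'
#' Maximum distance of any open-frame gap centroid from the first open
#' frame's centroid; in this assay the wound centroid stays stationary.
#'
#' @param series data frame with `area_um2`, `centroid_x_um`,
#'   `centroid_y_um`, `t_h`.
#' @param closure_threshold um^2 defining open frames.
#' @return Drift in um.
#' @export
centroid_drift <- function(series, closure_threshold = 100) {
  if (!all(c("centroid_x_um", "centroid_y_um") %in% names(series)))
    abort("series lacks centroid columns")
  open <- series[!is.na(series$area_um2) &
                   series$area_um2 >= closure_threshold &
                   !is.na(series$centroid_x_um), ]
  if (nrow(open) < 2) abort("fewer than 2 open frames")
  max(sqrt((open$centroid_x_um - open$centroid_x_um[1])^2 +
             (open$centroid_y_um - open$centroid_y_um[1])^2))
}
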