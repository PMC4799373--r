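#' Calibrated time-lapse image stack
#'
#' A `frame_stack` holds a single-channel T x H x W intensity array together
#' with its spatial and temporal calibration. Pixel coordinates are (row, col),
#' 0-based at pixel centers; physical coordinates are `pixel * pixel_size` in
#' micrometers. Time of wounding is t = 0 h; frame i is acquired at
#' `t_start + (i - 1) * frame_interval`.
#'
#' @param frames numeric T x H x W array, a single H x W matrix (T = 1), or a
#'   list of equally sized matrices. Intensities must be finite and >= 0.
#' @param pixel_size pixel edge length in micrometers per pixel (> 0).
#' @param frame_interval time between frames in hours (> 0).
#' @param channel channel label, e.g. `"tissue"`, `"nuclei"`, `"beads"`.
#' @param t_start acquisition time of the first frame in hours
#'   (0 = wounding).
#'
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size, frame_interval,
                        channel = "gray", t_start = 0) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(frames) == 0L) abort("zero frames")
    if (length(dims) != 1L || length(dims[[1]]) != 2L)
      abort("all frames must be matrices of identical shape")
    arr <- array(0, c(length(frames), dims[[1]][1], dims[[1]][2]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  } else if (is.matrix(frames)) {
    frames <- array(frames, c(1L, nrow(frames), ncol(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    abort("frames must be a T x H x W array")
  if (dim(frames)[1] < 1L) abort("zero frames")
  if (!all(is.finite(frames)) || any(frames < 0))
    abort("intensities must be finite and >= 0")
  stopifnot(pixel_size > 0, frame_interval > 0)
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, channel = channel,
         t_start = t_start),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack '%s'> %d frame(s) of %d x %d px, %.3g um/px, dt = %.3g h\n",
    x$channel, d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[1]

#' Frame acquisition times
#' @param stack a [frame_stack()].
#' @return numeric vector of times in hours, one per frame.
#' @export
stack_times <- function(stack) {
  stack$t_start + (seq_len(n_frames(stack)) - 1L) * stack$frame_interval
}

#' Extract one frame as a matrix
#' @param stack a [frame_stack()].
#' @param i frame index (1-based).
#' @return H x W numeric matrix.
#' @export
get_frame <- function(stack, i) {
  stopifnot(i >= 1, i <= n_frames(stack))
  stack$frames[i, , ]
}

#' Read a multi-frame grayscale TIFF as a calibrated stack
#'
#' Calibration is always supplied by the caller, never read from TIFF tags
#' (tag dialects vary between acquisition software).
#'
#' @inheritParams frame_stack
#' @param path path to a grayscale (single-sample) TIFF file.
#' @return A [frame_stack()]. Errors on missing files, RGB/multi-sample input
#'   or zero readable frames.
#' @export
load_stack <- function(path, pixel_size, frame_interval,
                       channel = "gray", t_start = 0) {
  if (!file.exists(path)) abort(paste0("missing file: ", path))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) == 0L) abort("zero frames")
  if (any(vapply(frames, function(f) length(dim(f)) != 2L, logical(1))))
    abort("non-grayscale input")
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) abort("frames differ in shape")
  frame_stack(frames, pixel_size = pixel_size,
              frame_interval = frame_interval,
              channel = channel, t_start = t_start)
}

#' Write a stack to a multi-frame 16-bit grayscale TIFF
#'
#' Intensities are stored as 16-bit samples, matching the bit depth of the
#' EMCCD cameras these assays are recorded with. The round trip
#' `load_stack(save_stack(s))` is bit-exact whenever intensities lie on the
#' 16-bit grid `k / 65535` in `[0, 1]` (all stacks produced by
#' [render_scene()] do).
#'
#' @param stack a [frame_stack()] with intensities in `[0, 1]`.
#' @param path output path; parent directories are created as needed.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (max(stack$frames) > 1) abort("intensities must be in [0, 1] for 16-bit storage")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  frames <- lapply(seq_len(n_frames(stack)), function(i) get_frame(stack, i))
  ok <- tryCatch(
    tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none"),
    error = function(e) abort(paste0("unwritable path: ", path))
  )
  invisible(path)
}

#' Confocal-style preprocessing: denoise, log-transform, z-project
#'
#' Each z-slice is median filtered, log(1 + x)-transformed (log chosen to keep
#' zero intensities defined), then the maximum-intensity projection over z is
#' taken and rescaled to `[0, 1]`. All steps before the final rescale are
#' pointwise monotone.
#'
#' @param zstack Z x H x W array (or a single matrix / list of matrices) of
#'   non-negative intensities.
#' @param median_radius half-width of the square median-filter window in
#'   pixels; `0` disables filtering.
#' @param rescale rescale the projection to `[0, 1]` (default); with
#'   `rescale = FALSE` the raw log-scale projection is returned (useful for
#'   checking monotonicity).
#' @return H x W matrix in `[0, 1]`. A constant projection maps to 1 (or 0 if
#'   identically zero).
#' @export
preprocess_confocal <- function(zstack, median_radius = 2, rescale = TRUE) {
  if (is.list(zstack)) {
    if (length(zstack) == 0L) abort("empty stack")
    zstack <- simplify2array(zstack)          # H x W x Z
    zstack <- aperm(zstack, c(3, 1, 2))
  } else if (is.matrix(zstack)) {
    zstack <- array(zstack, c(1L, nrow(zstack), ncol(zstack)))
  }
  if (!is.array(zstack) || length(dim(zstack)) != 3L || dim(zstack)[1] < 1L)
    abort("empty stack")
  if (any(zstack < 0)) abort("intensities must be >= 0")
  gmax <- max(zstack)
  nz <- dim(zstack)[1]
  slices <- lapply(seq_len(nz), function(z) {
    s <- zstack[z, , ]
    if (median_radius > 0 && gmax > 0) {
      # EBImage's median filter wants [0, 1] (16-bit histogram internally)
      s <- as.matrix(EBImage::medianFilter(s / gmax, as.integer(median_radius))) * gmax
    }
    log1p(s)
  })
  proj <- Reduce(pmax, slices)
  if (!rescale) return(proj)
  lo <- min(proj); hi <- max(proj)
  if (hi - lo < .Machine$double.eps * max(1, hi)) {
    out <- proj
    out[] <- if (hi > 0) 1 else 0
    return(out)
  }
  (proj - lo) / (hi - lo)
}
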