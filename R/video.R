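#' Programmed fingertip trajectory for a pointing gesture
#'
#' Builds per-frame blob centres at 30 fps for a synthetic pointing gesture:
#' rest, a minimum-jerk outward stroke of known amplitude, an optional hold
#' and return stroke. The programmed amplitude (start-to-end displacement of
#' the outward stroke, mm) and programmed mean velocity (discrete path length
#' over stroke duration, mm/ms) are stored as ground truth for recovery
#' tests.
#'
#' @param amplitude_mm Outward stroke amplitude in mm (> 0).
#' @param move_frames Number of inter-frame steps in the stroke (>= 2).
#' @param px_per_mm Image scale (px per mm).
#' @param fps Frame rate (default 30).
#' @param start_px Start centre `c(x, y)` in px.
#' @param direction_deg Stroke direction in degrees (0 = +x).
#' @param rest_frames Frames of rest before the stroke and after the last
#'   stroke (default 6).
#' @param hold_frames Frames of hold between outward and return strokes.
#' @param out_and_back If `TRUE` append a mirrored return stroke.
#' @return Object of class `video_truth`: `centers` (frame x 2 matrix),
#'   `amplitude_mm`, `mean_velocity_mm_ms`, `px_per_mm`, `fps`, and the
#'   outward-stroke frame span.
#' @export
gesture_truth <- function(amplitude_mm = 120, move_frames = 12, px_per_mm = 2,
                          fps = 30, start_px = c(60, 120), direction_deg = 0,
                          rest_frames = 6, hold_frames = 6,
                          out_and_back = FALSE) {
  if (amplitude_mm <= 0) stop("amplitude_mm must be > 0", call. = FALSE)
  if (move_frames < 2) stop("move_frames must be >= 2", call. = FALSE)
  if (px_per_mm <= 0) stop("px_per_mm must be > 0", call. = FALSE)
  amp_px <- amplitude_mm * px_per_mm
  dir <- c(cos(direction_deg * pi / 180), sin(direction_deg * pi / 180))
  tau <- seq(0, 1, length.out = move_frames + 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5  # minimum-jerk position profile
  stroke <- cbind(start_px[1] + amp_px * s * dir[1],
                  start_px[2] + amp_px * s * dir[2])
  end_px <- stroke[nrow(stroke), ]
  centers <- rbind(
    matrix(rep(start_px, each = rest_frames), ncol = 2),
    stroke,
    matrix(rep(end_px, each = hold_frames), ncol = 2))
  if (out_and_back) {
    centers <- rbind(centers, stroke[rev(seq_len(nrow(stroke) - 1L)), ],
                     matrix(rep(start_px, each = rest_frames), ncol = 2))
  } else {
    centers <- rbind(centers,
                     matrix(rep(end_px, each = max(0, rest_frames - hold_frames)),
                            ncol = 2))
  }
  duration_ms <- move_frames / fps * 1000
  path_px <- sum(sqrt(rowSums(diff(stroke)^2)))
  structure(list(
    centers = centers, px_per_mm = px_per_mm, fps = fps,
    amplitude_mm = sqrt(sum((end_px - start_px)^2)) / px_per_mm,
    mean_velocity_mm_ms = (path_px / px_per_mm) / duration_ms,
    stroke_frames = c(rest_frames, rest_frames + move_frames)),
    class = "video_truth")
}

#' @export
print.video_truth <- function(x, ...) {
  cat(sprintf("Programmed gesture: %d frames at %g fps, amplitude %.1f mm, mean velocity %.4f mm/ms\n",
              nrow(x$centers), x$fps, x$amplitude_mm, x$mean_velocity_mm_ms))
  invisible(x)
}

#' Render a gesture video as RGB frames
#'
#' Draws one coloured finger-cap disc per frame at the programmed centres of
#' a [gesture_truth()], on a grey background, with optional additive Gaussian
#' pixel noise. Frames are `height x width x 3` arrays with values in [0, 1],
#' serializable as PNG via [write_frames()]. Pixel coordinates are 0-based
#' with x along columns and y along rows (top-left origin).
#'
#' @param truth A `video_truth` (or any frame x 2 matrix of centres).
#' @param width,height Frame size in px.
#' @param radius Disc radius in px.
#' @param color `"red"` or `"blue"` (red = left index, blue = right index).
#' @param bg Background grey level.
#' @param noise_sd SD of additive Gaussian noise (clipped to [0, 1]).
#' @return List of frame arrays.
#' @export
render_gesture_video <- function(truth, width = 320, height = 240, radius = 6,
                                 color = c("red", "blue"), bg = 0.15,
                                 noise_sd = 0) {
  color <- match.arg(color)
  centers <- if (inherits(truth, "video_truth")) truth$centers else as.matrix(truth)
  if (nrow(centers) < 2) stop("need at least 2 frames", call. = FALSE)
  if (any(centers[, 1] < radius) || any(centers[, 1] > width - 1 - radius) ||
      any(centers[, 2] < radius) || any(centers[, 2] > height - 1 - radius))
    stop("blob out of frame bounds", call. = FALSE)
  rgb <- if (color == "red") c(0.9, 0.12, 0.10) else c(0.10, 0.12, 0.9)
  xs <- matrix(rep(0:(width - 1), each = height), nrow = height)
  ys <- matrix(rep(0:(height - 1), width), nrow = height)
  lapply(seq_len(nrow(centers)), function(i) {
    fr <- array(bg, dim = c(height, width, 3))
    mask <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= radius^2
    for (ch in 1:3) {
      plane <- fr[, , ch]
      plane[mask] <- rgb[ch]
      fr[, , ch] <- plane
    }
    if (noise_sd > 0) {
      fr <- fr + stats::rnorm(length(fr), 0, noise_sd)
      fr[fr < 0] <- 0
      fr[fr > 1] <- 1
    }
    fr
  })
}

#' Write / read frame sequences as PNG files
#'
#' @param frames List of `H x W x 3` arrays in [0, 1].
#' @param dir Directory for `frame_0001.png`, `frame_0002.png`, ...
#' @return `write_frames()` returns the file paths invisibly;
#'   `read_frames()` returns the list of frame arrays.
#' @export
write_frames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%04d.png", seq_along(frames)))
  for (i in seq_along(frames)) png::writePNG(frames[[i]], paths[i])
  invisible(paths)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(paths)) stop("no PNG frames in ", dir, call. = FALSE)
  lapply(paths, function(p) {
    fr <- png::readPNG(p)
    if (length(dim(fr)) == 2) fr <- array(rep(fr, 3), dim = c(dim(fr), 3))
    fr[, , 1:3, drop = FALSE]
  })
}
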