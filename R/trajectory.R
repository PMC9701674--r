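#' Segment a finger-cap blob in one frame
#'
#' Within an optional image RoI: median-filter each RGB channel, threshold
#' the three channels to intermediate binary images whose conjunction forms
#' the colour mask, label connected components, keep the largest, and shrink
#' it to a point via its centroid. Returns `NULL` when the mask is empty or
#' the largest component is below `min_area`.
#'
#' @param frame `H x W x 3` array in [0, 1].
#' @param color `"red"` or `"blue"` (selects default channel thresholds).
#' @param thresholds Named list `r`, `g`, `b` of `c(lo, hi)` inclusion
#'   ranges; defaults suit the rendered finger caps.
#' @param roi Optional `c(xmin, ymin, xmax, ymax)` crop in 0-based px
#'   (max edges exclusive).
#' @param min_area Minimum component area in px (default 5).
#' @param median_radius Radius of the median filter (default 1 = 3x3 window;
#'   0 disables).
#' @return `c(x, y)` centroid in 0-based px, or `NULL`.
#' @export
segment_fingertip <- function(frame, color = c("red", "blue"),
                              thresholds = NULL, roi = NULL, min_area = 5,
                              median_radius = 1) {
  color <- match.arg(color)
  if (length(dim(frame)) != 3 || dim(frame)[3] < 3)
    stop("frame must be an H x W x 3 RGB array", call. = FALSE)
  if (is.null(thresholds)) {
    thresholds <- if (color == "red")
      list(r = c(0.5, 1), g = c(0, 0.45), b = c(0, 0.45))
    else
      list(r = c(0, 0.45), g = c(0, 0.45), b = c(0.5, 1))
  }
  off <- c(0, 0)
  if (!is.null(roi)) {
    h <- dim(frame)[1]; w <- dim(frame)[2]
    cx <- max(0, roi[1]):min(w - 1, roi[3] - 1)
    cy <- max(0, roi[2]):min(h - 1, roi[4] - 1)
    frame <- frame[cy + 1, cx + 1, , drop = FALSE]
    off <- c(min(cx), min(cy))
  }
  masks <- lapply(1:3, function(ch) {
    plane <- frame[, , ch]
    if (median_radius > 0 && all(dim(plane) > 2 * median_radius))
      plane <- EBImage::medianFilter(plane, median_radius, cacheSize = 4096)
    rng <- thresholds[[c("r", "g", "b")[ch]]]
    plane >= rng[1] & plane <= rng[2]
  })
  mask <- masks[[1]] & masks[[2]] & masks[[3]]
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  if (!length(areas) || max(areas) < min_area) return(NULL)
  idx <- which(lab == which.max(areas), arr.ind = TRUE)
  # array rows index y, columns index x; centroid in 0-based px
  c(x = mean(idx[, 2]) - 1 + off[1], y = mean(idx[, 1]) - 1 + off[2])
}

#' Extract a fingertip trajectory from a frame sequence
#'
#' Applies [segment_fingertip()] frame by frame; frames where the blob is
#' absent (masked, out of RoI) are retained as not-present points so the
#' series length always equals the frame count.
#'
#' @param frames List of RGB frame arrays.
#' @param color `"red"` or `"blue"`.
#' @param fps Frame rate used for the time stamps (default 30).
#' @param ... Passed to [segment_fingertip()].
#' @return Data frame of `TrajectoryPoint`s: `frame` (0-based), `time_ms`,
#'   `x`, `y`, `present`.
#' @export
extract_trajectory <- function(frames, color = c("red", "blue"), fps = 30, ...) {
  color <- match.arg(color)
  if (length(frames) < 2) stop("need at least 2 frames", call. = FALSE)
  pts <- lapply(frames, segment_fingertip, color = color, ...)
  present <- !vapply(pts, is.null, TRUE)
  if (!any(present)) stop("fingertip absent in every frame", call. = FALSE)
  x <- y <- rep(NA_real_, length(frames))
  x[present] <- vapply(pts[present], `[[`, 0, 1)
  y[present] <- vapply(pts[present], `[[`, 0, 2)
  data.frame(frame = seq_along(frames) - 1L,
             time_ms = (seq_along(frames) - 1L) / fps * 1000,
             x = x, y = y, present = present)
}

#' Smooth a trajectory and segment it into movements
#'
#' Gaussian-kernel smoothing of x(t) and y(t) over frames (gaps are linearly
#' interpolated first), then frame-to-frame speed, then movement detection by
#' a double threshold: maximal runs with speed at or above
#' `rest_speed_threshold` lasting at least `min_move_frames` trigger a
#' movement, whose boundaries are extended outward while the speed stays
#' above `onset_floor_frac * rest_speed_threshold` (recovers the slow
#' initial/terminal portions of a ballistic stroke).
#'
#' @param series Data frame from [extract_trajectory()].
#' @param bandwidth Kernel bandwidth in frames (as in [stats::ksmooth()];
#'   0 disables smoothing).
#' @param rest_speed_threshold Trigger speed in px/frame (default 1).
#' @param min_move_frames Minimum supra-threshold run length (default 3).
#' @param onset_floor_frac Fraction of the trigger used for boundary
#'   extension (default 0.1).
#' @return List of movement segments, each a data frame (`frame`, `x`, `y`)
#'   of smoothed positions; the full smoothed series is attached as
#'   `attr(, "smoothed")`.
#' @export
smooth_and_segment <- function(series, bandwidth = 1,
                               rest_speed_threshold = 1, min_move_frames = 3,
                               onset_floor_frac = 0.1) {
  if (sum(series$present) < min_move_frames)
    stop("too few present points", call. = FALSE)
  fr <- series$frame
  x <- series$x; y <- series$y
  if (any(!series$present)) {
    ok <- series$present
    x <- stats::approx(fr[ok], x[ok], xout = fr, rule = 2)$y
    y <- stats::approx(fr[ok], y[ok], xout = fr, rule = 2)$y
  }
  if (bandwidth > 1e-8) {
    x <- stats::ksmooth(fr, x, kernel = "normal", bandwidth = bandwidth,
                        x.points = fr)$y
    y <- stats::ksmooth(fr, y, kernel = "normal", bandwidth = bandwidth,
                        x.points = fr)$y
  }
  smoothed <- data.frame(frame = fr, x = x, y = y)
  speed <- c(0, sqrt(diff(x)^2 + diff(y)^2))  # speed[i] = step into frame i
  trig <- runs_of(speed >= rest_speed_threshold)
  trig <- trig[(trig$end - trig$start + 1L) >= min_move_frames, , drop = FALSE]
  floor_v <- onset_floor_frac * rest_speed_threshold
  segs <- list()
  used_until <- 0L
  for (i in seq_len(nrow(trig))) {
    a <- trig$start[i]; b <- trig$end[i]
    while (a - 1L > used_until + 1L && speed[a - 1L] > floor_v) a <- a - 1L
    while (b + 1L <= length(speed) && speed[b + 1L] > floor_v) b <- b + 1L
    if (length(segs) && a <= used_until + 1L) {
      # merged with previous extension: keep segments disjoint
      a <- used_until + 1L
    }
    idx <- (a - 1L):b  # include the frame the first step starts from
    segs[[length(segs) + 1L]] <- smoothed[idx, , drop = FALSE]
    used_until <- b
  }
  attr(segs, "smoothed") <- smoothed
  segs
}

#' Kinematics of a movement segment
#'
#' Amplitude is the start-to-end Euclidean displacement of the segment (mm);
#' mean velocity is the path length divided by the segment duration (mm/ms),
#' with duration from the frame count at the given rate. Path length is
#' returned as an auxiliary output.
#'
#' @param segment A segment from [smooth_and_segment()].
#' @param px_per_mm Image scale (> 0).
#' @param fps Frame rate (default 30).
#' @return Data frame (`GestureKinematics`): onset/offset frames,
#'   `amplitude_mm`, `mean_velocity_mm_ms`, `path_mm`, `duration_ms`.
#' @export
kinematics <- function(segment, px_per_mm, fps = 30) {
  if (px_per_mm <= 0) stop("px_per_mm must be > 0", call. = FALSE)
  n <- nrow(segment)
  if (n < 2) stop("segment must span at least 2 frames", call. = FALSE)
  p <- as.matrix(segment[, c("x", "y")])
  amp <- sqrt(sum((p[n, ] - p[1, ])^2)) / px_per_mm
  path <- sum(sqrt(rowSums(diff(p)^2))) / px_per_mm
  dur <- (n - 1) / fps * 1000
  data.frame(onset_frame = segment$frame[1], offset_frame = segment$frame[n],
             amplitude_mm = amp, mean_velocity_mm_ms = path / dur,
             path_mm = path, duration_ms = dur)
}
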