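#' Parse raw gaze samples into fixation, saccade and blink events
#'
#' Offline velocity-threshold event parser for 1000 Hz gaze recordings.
#' Angular velocity is estimated per axis by a 5-point central difference on
#' degree-converted positions, combined into speed, then smoothed with a short
#' boxcar. Runs of smoothed speed at or above `velocity_threshold` (deg/s)
#' lasting at least `min_saccade_ms` become saccades; runs of invalid samples
#' (pupil lost) become blinks; saccade-like runs within `blink_pad_ms` of a
#' blink edge are absorbed into the blink; everything else is fixation. Events
#' tile the trial with half-open intervals `[onset, offset)` in ms.
#'
#' @param samples Data frame with columns `time_ms` (strictly increasing
#'   1 ms grid), `x_px`, `y_px`, `valid` (0/1 or logical; FALSE = pupil lost).
#' @param geometry A [screen_geometry()] used for the px-to-degree conversion.
#' @param velocity_threshold Saccade speed threshold in deg/s (default 30).
#' @param min_saccade_ms Minimum saccade duration in ms (default 4); shorter
#'   supra-threshold runs are treated as fixation.
#' @param smooth_ms Boxcar width in ms for speed smoothing (default 3).
#' @param blink_pad_ms Saccade runs starting or ending within this many ms of
#'   a blink are merged into the blink (default 20).
#' @return Data frame of events with columns `kind` (fixation/saccade/blink),
#'   `onset`, `offset` (ms, half-open), `start_x`, `start_y`, `end_x`,
#'   `end_y`, `cx`, `cy` (sample centroid) and `peak_vel` (deg/s, saccades;
#'   NA otherwise).
#' @examples
#' s <- data.frame(time_ms = 0:199, x_px = 960, y_px = 600, valid = 1)
#' detect_gaze_events(s)  # one 200 ms fixation
#' @export
detect_gaze_events <- function(samples, geometry = screen_geometry(),
                               velocity_threshold = 30, min_saccade_ms = 4,
                               smooth_ms = 3, blink_pad_ms = 20) {
  req <- c("time_ms", "x_px", "y_px", "valid")
  if (!all(req %in% names(samples)))
    stop("samples must have columns time_ms, x_px, y_px, valid", call. = FALSE)
  n <- nrow(samples)
  valid <- as.logical(samples$valid)
  if (sum(valid) < 3) stop("fewer than 3 valid samples", call. = FALSE)
  t <- samples$time_ms
  if (n > 1 && any(diff(t) != 1L))
    stop("samples must lie on a contiguous 1 ms grid", call. = FALSE)
  if (velocity_threshold <= 0) stop("velocity_threshold must be > 0", call. = FALSE)

  deg <- px_to_deg(cbind(samples$x_px, samples$y_px), geometry)
  speed <- .angular_speed(deg, smooth_ms)

  # classes: 0 fixation, 1 saccade, 2 blink
  cls <- integer(n)
  cls[!valid] <- 2L
  sacc_mask <- speed >= velocity_threshold & valid
  sr <- runs_of(sacc_mask)
  if (nrow(sr)) {
    sr <- sr[(sr$end - sr$start + 1L) >= min_saccade_ms, , drop = FALSE]
    for (i in seq_len(nrow(sr))) cls[sr$start[i]:sr$end[i]] <- 1L
  }
  # blink padding: saccade runs near a blink edge belong to the blink
  br <- runs_of(cls == 2L)
  if (nrow(br) && nrow(sr)) {
    for (i in seq_len(nrow(sr))) {
      a <- sr$start[i]; b <- sr$end[i]
      near <- which(br$start - b >= 1 & br$start - b <= blink_pad_ms |
                    a - br$end >= 1 & a - br$end <= blink_pad_ms)
      if (length(near)) {
        j <- near[1]
        lo <- min(a, br$start[j]); hi <- max(b, br$end[j])
        cls[lo:hi] <- 2L
      }
    }
  }

  # assemble tiling events from class runs
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  kind <- c("fixation", "saccade", "blink")[r$values + 1L]
  ev <- data.frame(
    kind = kind,
    onset = t[starts],
    offset = t[ends] + 1L,
    start_x = samples$x_px[starts], start_y = samples$y_px[starts],
    end_x = samples$x_px[ends], end_y = samples$y_px[ends],
    cx = NA_real_, cy = NA_real_, peak_vel = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(ev))) {
    idx <- starts[i]:ends[i]
    if (ev$kind[i] == "fixation") {
      ev$cx[i] <- mean(samples$x_px[idx])
      ev$cy[i] <- mean(samples$y_px[idx])
    } else if (ev$kind[i] == "saccade") {
      ev$peak_vel[i] <- max(speed[idx])
    }
  }
  ev
}

# Smoothed angular speed (deg/s) from degree positions on a 1 ms grid:
# 5-point central differences per axis, Euclidean magnitude, boxcar smoothing.
.angular_speed <- function(deg, smooth_ms = 3) {
  n <- nrow(deg)
  v <- matrix(0, n, 2)
  if (n >= 5) {
    i <- 3:(n - 2)
    for (k in 1:2)
      v[i, k] <- (deg[i - 2, k] - 8 * deg[i - 1, k] +
                  8 * deg[i + 1, k] - deg[i + 2, k]) / 12
  }
  speed <- sqrt(rowSums(v^2)) * 1000  # deg/ms -> deg/s
  w <- max(1L, as.integer(smooth_ms))
  if (w > 1) {
    sm <- stats::filter(speed, rep(1 / w, w), sides = 2)
    sm[is.na(sm)] <- speed[is.na(sm)]
    speed <- as.numeric(sm)
  }
  speed
}
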