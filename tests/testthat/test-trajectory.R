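# small frames keep the image ops fast
render_small <- function(truth, color = "red", noise_sd = 0)
  render_gesture_video(truth, width = 200, height = 120, radius = 5,
                       color = color, noise_sd = noise_sd)

test_that("a static blob yields a constant trajectory with zero variance", {
  centers <- matrix(rep(c(120, 80), each = 10), ncol = 2)
  frames <- render_gesture_video(centers, width = 200, height = 120,
                                 radius = 5, color = "red")
  traj <- extract_trajectory(frames, "red")
  expect_true(all(traj$present))
  expect_equal(var(traj$x), 0)
  expect_equal(var(traj$y), 0)
  expect_lt(abs(traj$x[1] - 120), 0.5)
  expect_lt(abs(traj$y[1] - 80), 0.5)
})

test_that("frames without the target colour give an absent centroid", {
  frames <- render_gesture_video(matrix(rep(c(50, 50), each = 3), ncol = 2),
                                 width = 120, height = 100, color = "blue")
  expect_null(segment_fingertip(frames[[1]], "red"))
  expect_error(extract_trajectory(frames, "red"), "absent in every frame")
})

test_that("the largest component wins; oracle by exhaustive labeling", {
  fr <- array(0.1, dim = c(80, 120, 3))
  disc <- function(fr, cx, cy, r, val) {
    for (row in 1:80) for (col in 1:120)
      if ((col - 1 - cx)^2 + (row - 1 - cy)^2 <= r^2) {
        fr[row, col, 1] <- val[1]; fr[row, col, 2] <- val[2]; fr[row, col, 3] <- val[3]
      }
    fr
  }
  fr <- disc(fr, 30, 30, 11, c(0.9, 0.1, 0.1))   # large red disc
  fr <- disc(fr, 90, 50, 3, c(0.9, 0.1, 0.1))    # small red disc
  got <- segment_fingertip(fr, "red")
  # oracle: exhaustive 4-connected component labeling of the threshold mask
  mask <- fr[, , 1] >= 0.5 & fr[, , 2] <= 0.45 & fr[, , 3] <= 0.45
  lab <- matrix(0L, nrow(mask), ncol(mask)); cur <- 0L
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (mask[r0, c0] && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      stack <- list(c(r0, c0))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[2] < 1 || p[1] > nrow(mask) || p[2] > ncol(mask)) next
        if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- cur
        stack <- c(stack, list(p + c(1, 0)), list(p - c(1, 0)),
                   list(p + c(0, 1)), list(p - c(0, 1)))
      }
    }
  }
  big <- which.max(tabulate(lab[lab > 0]))
  idx <- which(lab == big, arr.ind = TRUE)
  oracle <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
  expect_equal(unname(got), oracle, tolerance = 1e-6)
  expect_lt(abs(got["x"] - 30), 0.5)
})

test_that("programmed linear motion is recovered per frame within 0.5 px", {
  # linear 100 px travel at px_per_mm = 2 -> programmed amplitude 50 mm
  truth <- gesture_truth(amplitude_mm = 50, move_frames = 10, px_per_mm = 2,
                         start_px = c(30, 60))
  expect_equal(truth$amplitude_mm, 50)
  frames <- render_small(truth)
  traj <- extract_trajectory(frames, "red")
  expect_true(all(abs(traj$x - truth$centers[, 1]) < 0.5))
  expect_true(all(abs(traj$y - truth$centers[, 2]) < 0.5))
})

test_that("a dropped frame keeps series length with one not-present point", {
  truth <- gesture_truth(amplitude_mm = 50, move_frames = 10, px_per_mm = 2,
                         start_px = c(30, 60))
  frames <- render_small(truth)
  frames[[8]] <- array(0.1, dim = dim(frames[[8]]))  # masked finger cap
  traj <- extract_trajectory(frames, "red")
  expect_equal(nrow(traj), length(frames))
  expect_equal(sum(!traj$present), 1L)
  expect_false(traj$present[8])
})

test_that("programmed mean velocity agrees with a quadrature oracle", {
  truth <- gesture_truth(amplitude_mm = 80, move_frames = 12, px_per_mm = 2,
                         fps = 30, start_px = c(20, 60))
  # minimum-jerk speed profile |v|(tau) = A * 30 tau^2 (1-tau)^2 / T
  A <- 80; T_ms <- 12 / 30 * 1000
  path <- stats::integrate(function(tau) A * 30 * tau^2 * (1 - tau)^2,
                           0, 1)$value
  expect_equal(path, A, tolerance = 1e-6)       # straight min-jerk path length
  expect_equal(truth$mean_velocity_mm_ms, path / T_ms, tolerance = 0.02)
})

test_that("zero-bandwidth smoothing reproduces the raw series", {
  truth <- gesture_truth(amplitude_mm = 60, move_frames = 8, px_per_mm = 2,
                         start_px = c(30, 60))
  traj <- extract_trajectory(render_small(truth), "red")
  segs <- smooth_and_segment(traj, bandwidth = 0)
  sm <- attr(segs, "smoothed")
  expect_equal(sm$x, traj$x)
  expect_equal(sm$y, traj$y)
})

test_that("a constant series yields no movement segments", {
  centers <- matrix(rep(c(100, 60), each = 12), ncol = 2)
  traj <- extract_trajectory(render_gesture_video(centers, width = 200,
                                                  height = 120, color = "red"),
                             "red")
  expect_length(smooth_and_segment(traj), 0L)
})

test_that("an out-and-back gesture parses into two movement segments", {
  truth <- gesture_truth(amplitude_mm = 55, move_frames = 10, px_per_mm = 2,
                         start_px = c(30, 60), out_and_back = TRUE)
  traj <- extract_trajectory(render_small(truth), "red")
  segs <- smooth_and_segment(traj)
  expect_length(segs, 2L)
  k1 <- kinematics(segs[[1]], 2); k2 <- kinematics(segs[[2]], 2)
  expect_equal(k1$amplitude_mm, k2$amplitude_mm, tolerance = 0.05)
})

test_that("kinematics arithmetic on a straight segment", {
  seg <- data.frame(frame = 0:10, x = seq(0, 60, length.out = 11), y = 0)
  k <- kinematics(seg, px_per_mm = 2)
  expect_equal(k$amplitude_mm, 30)
  expect_equal(k$duration_ms, 1000 / 3, tolerance = 1e-6)
  expect_equal(round(k$mean_velocity_mm_ms, 3), 0.090)
  expect_error(kinematics(seg, px_per_mm = 0), "px_per_mm")
})

test_that("recovery from rendered video is within 2% amplitude and 5% velocity", {
  for (s in 1:3) {
    set.seed(s)
    truth <- gesture_truth(amplitude_mm = runif(1, 50, 70),
                           move_frames = sample(10:13, 1), px_per_mm = 2,
                           start_px = c(25, 30 + 20 * s),
                           direction_deg = runif(1, -15, 15))
    traj <- extract_trajectory(render_small(truth), "red")
    k <- kinematics(smooth_and_segment(traj)[[1]], 2)
    expect_lt(abs(k$amplitude_mm - truth$amplitude_mm) / truth$amplitude_mm, 0.02)
    expect_lt(abs(k$mean_velocity_mm_ms - truth$mean_velocity_mm_ms) /
                truth$mean_velocity_mm_ms, 0.05)
  }
})

test_that("amplitude and velocity are invariant to rotation and translation", {
  base <- gesture_truth(amplitude_mm = 60, move_frames = 10, px_per_mm = 2,
                        start_px = c(25, 40), direction_deg = 0)
  rot <- gesture_truth(amplitude_mm = 60, move_frames = 10, px_per_mm = 2,
                       start_px = c(40, 95), direction_deg = -35)
  k1 <- kinematics(smooth_and_segment(extract_trajectory(render_small(base), "red"))[[1]], 2)
  k2 <- kinematics(smooth_and_segment(extract_trajectory(render_small(rot), "red"))[[1]], 2)
  expect_equal(k1$amplitude_mm, k2$amplitude_mm, tolerance = 0.01)
  expect_equal(k1$mean_velocity_mm_ms, k2$mean_velocity_mm_ms, tolerance = 0.01)
})

test_that("blobs outside the frame are rejected at render time", {
  centers <- matrix(c(5, 5, 300, 60), ncol = 2, byrow = TRUE)
  expect_error(render_gesture_video(centers, width = 200, height = 120,
                                    radius = 6, color = "red"),
               "out of frame")
})

test_that("frame PNG round-trip preserves trajectories", {
  truth <- gesture_truth(amplitude_mm = 40, move_frames = 6, px_per_mm = 2,
                         start_px = c(30, 60), rest_frames = 2, hold_frames = 2)
  frames <- render_small(truth)
  dir <- withr::local_tempdir()
  write_frames(frames, dir)
  back <- read_frames(dir)
  expect_equal(length(back), length(frames))
  t1 <- extract_trajectory(frames, "red")
  t2 <- extract_trajectory(back, "red")
  expect_equal(t2$x, t1$x, tolerance = 0.1)
})
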