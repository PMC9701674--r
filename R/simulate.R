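#' Simulate a synthetic two-group gaze-and-gesture cohort
#'
#' Generates a full cohort — trial table, per-trial 1000 Hz gaze streams,
#' gesture (space-bar release) onsets, free-task channel annotations — with
#' complete ground truth: per-trial programmed gaze-shift onsets, gaze-gesture
#' delays, pathway labels, and exclusion labels for every rule of the
#' communicative gaze-shift selection algorithm. Gaze streams are synthesized
#' as piecewise fixation-saccade-fixation event geometry with saccade velocity
#' pulses well above the 30 deg/s parser threshold (see the package vignette
#' for the construction).
#'
#' Subject mean delays are drawn per group (TD mean `td_mean_delay`, ASD mean
#' `td_mean_delay + group_delay_shift`) jointly with the within-subject SD
#' from a bivariate lognormal with log-scale correlation `mean_sd_coupling`;
#' per-trial delays are Gaussian around the subject mean, truncated at 0.
#' Output is deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param signals If `TRUE` (default) build the per-trial gaze sample streams;
#'   if `FALSE` return only the trial/truth tables (fast path for statistical
#'   simulation studies that operate on delays directly).
#' @param geometry A [screen_geometry()].
#' @param map A [roi_map()].
#' @return Object of class `iaps_cohort`: list with elements `trials`
#'   (subject, group, block, trial, side, stim_onset_ms, gesture_onset_ms),
#'   `truth` (adds true_shift_onset, true_delay, pathway, exclusion, latency,
#'   subject-level parameters), `streams` (named list of gaze sample data
#'   frames, or NULL), `annotations` (free-task verbal/gesture binaries),
#'   `subjects`, plus the config, geometry and RoI map used.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_per_group = 2, n_blocks = 1,
#'                                         trials_per_block = 6, seed = 7))
#' table(cohort$truth$exclusion)
#' @export
simulate_cohort <- function(config = cohort_config(), signals = TRUE,
                            geometry = screen_geometry(), map = roi_map()) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, {
    groups <- c("ASD", "TD")
    subj_tabs <- lapply(groups, function(g) {
      p <- draw_subject_params(config, g)
      data.frame(subject = sprintf("%s%02d", substr(g, 1, 1), seq_len(config$n_per_group)),
                 group = g, subject_mean = p$subject_mean,
                 subject_sd = p$subject_sd, stringsAsFactors = FALSE)
    })
    subjects <- do.call(rbind, subj_tabs)

    n_trials_subj <- config$n_blocks * config$trials_per_block
    n_total <- nrow(subjects) * n_trials_subj
    streams <- if (signals) vector("list", n_total) else NULL
    keys <- character(n_total)
    col_subject <- character(n_total); col_group <- character(n_total)
    col_block <- integer(n_total); col_trial <- integer(n_total)
    col_side <- character(n_total); col_gesture <- integer(n_total)
    col_shift <- integer(n_total); col_delay <- integer(n_total)
    col_pathway <- character(n_total); col_excl <- character(n_total)
    col_latency <- integer(n_total)
    col_smean <- numeric(n_total); col_ssd <- numeric(n_total)
    k <- 0L

    p_excl <- c(config$exclusion_rates, none = 1 - sum(config$exclusion_rates))

    for (si in seq_len(nrow(subjects))) {
      subj <- subjects$subject[si]
      for (b in seq_len(config$n_blocks)) {
        half <- config$trials_per_block %/% 2
        sides <- sample(c(rep("left", half),
                          rep("right", config$trials_per_block - half)))
        for (tr in seq_len(config$trials_per_block)) {
          k <- k + 1L
          label <- if (tr == 1L) "first_trial" else
            sample(names(p_excl), 1L, prob = p_excl)
          pathway <- sample(names(config$pathway_probs), 1L,
                            prob = config$pathway_probs)
          latency <- if (label == "latency_lt_75")
            sample(40:70, 1L) else
            sample(config$saccade_latency_range[1]:config$saccade_latency_range[2], 1L)
          delay <- draw_delay(subjects$subject_mean[si], subjects$subject_sd[si])
          benign <- label %in% c("none", "first_trial") &&
            stats::runif(1) < config$blink_benign_rate
          trial <- simulate_trial(label, pathway, sides[tr], latency, delay,
                                  config, geometry, map,
                                  benign_blink = benign, signals = signals)
          keys[k] <- trial_key(subj, b, tr)
          if (signals) streams[[k]] <- trial$stream
          col_subject[k] <- subj; col_group[k] <- subjects$group[si]
          col_block[k] <- b; col_trial[k] <- tr; col_side[k] <- sides[tr]
          col_gesture[k] <- trial$gesture_onset
          col_shift[k] <- trial$true_shift_onset
          col_delay[k] <- trial$true_delay
          col_pathway[k] <- trial$pathway %||% NA_character_
          col_excl[k] <- label; col_latency[k] <- trial$latency
          col_smean[k] <- subjects$subject_mean[si]
          col_ssd[k] <- subjects$subject_sd[si]
        }
      }
    }
    truth <- data.frame(
      subject = col_subject, group = col_group, block = col_block,
      trial = col_trial, side = col_side,
      stim_onset_ms = config$stim_onset_ms, gesture_onset_ms = col_gesture,
      true_shift_onset = col_shift, true_delay = col_delay,
      pathway = col_pathway, exclusion = col_excl, latency = col_latency,
      subject_mean = col_smean, subject_sd = col_ssd,
      stringsAsFactors = FALSE)
    if (signals) names(streams) <- keys
    trials <- truth[, c("subject", "group", "block", "trial", "side",
                        "stim_onset_ms", "gesture_onset_ms")]
    annotations <- data.frame(
      subject = truth$subject, group = truth$group, block = truth$block,
      trial = truth$trial,
      verbal = stats::rbinom(nrow(truth), 1, config$verbal_p),
      gesture = stats::rbinom(nrow(truth), 1, config$gesture_p),
      stringsAsFactors = FALSE)
    structure(list(trials = trials, truth = truth, streams = streams,
                   annotations = annotations, subjects = subjects,
                   config = config, geometry = geometry, map = map),
              class = "iaps_cohort")
  })
}

#' @export
print.iaps_cohort <- function(x, ...) {
  cat(sprintf("Synthetic IaPS cohort: %d subjects (%d/group), %d trials%s\n",
              nrow(x$subjects), x$config$n_per_group, nrow(x$truth),
              if (is.null(x$streams)) " (truth tables only)" else ""))
  tab <- table(factor(x$truth$exclusion, levels = exclusion_levels()))
  cat("Exclusion labels:\n")
  print(tab)
  invisible(x)
}

trial_key <- function(subject, block, trial)
  sprintf("%s_B%d_T%02d", subject, block, trial)

# Per-trial delay: Gaussian around the subject mean, truncated at 0 by
# resampling (rule 6 guarantees non-negativity), rounded to the ms grid.
draw_delay <- function(mean, sd) {
  for (i in 1:50) {
    d <- stats::rnorm(1, mean, sd)
    if (d >= 0) return(as.integer(round(d)))
  }
  0L
}

#' Construct a single trial violating one exclusion rule
#'
#' Builds a gaze stream, gesture onset and ground-truth record for a trial
#' that violates exactly the requested selection rule and no rule of higher
#' precedence. Useful for targeted tests of the selection algorithm.
#'
#' @param rule_id One of `first_trial`, `gaze_not_social_at_onset`,
#'   `no_comm_shift`, `blink_pre_onset`, `latency_lt_75`,
#'   `gesture_precedes_gaze`, or `none` (a clean trial).
#' @param base_trial Optional named list overriding `side`, `latency`,
#'   `delay`, or `pathway`.
#' @param config,geometry,map Generator configuration and geometry.
#' @param seed RNG seed for the trial's stochastic details.
#' @return List with `stream` (gaze samples), `gesture_onset`, and `truth`
#'   (a one-row data frame with the programmed shift onset, delay, pathway
#'   and exclusion label).
#' @export
make_exclusion_case <- function(rule_id, base_trial = list(),
                                config = cohort_config(),
                                geometry = screen_geometry(), map = roi_map(),
                                seed = 1L) {
  if (!rule_id %in% exclusion_levels())
    stop(sprintf("unknown rule_id '%s'", rule_id), call. = FALSE)
  with_local_seed(seed, {
    side <- base_trial$side %||% sample(c("left", "right"), 1)
    latency <- base_trial$latency %||% (
      if (rule_id == "latency_lt_75") sample(40:70, 1) else
        sample(config$saccade_latency_range[1]:config$saccade_latency_range[2], 1))
    delay <- base_trial$delay %||%
      draw_delay(config$td_mean_delay, config$within_subject_sd_td)
    pathway <- base_trial$pathway %||% "direct"
    trial <- simulate_trial(rule_id, pathway, side, latency, delay,
                            config, geometry, map, signals = TRUE)
    truth <- data.frame(side = side, stim_onset_ms = config$stim_onset_ms,
                        gesture_onset_ms = trial$gesture_onset,
                        true_shift_onset = trial$true_shift_onset,
                        true_delay = trial$true_delay,
                        pathway = trial$pathway, exclusion = rule_id,
                        latency = trial$latency, stringsAsFactors = FALSE)
    list(stream = trial$stream, gesture_onset = trial$gesture_onset,
         truth = truth)
  })
}

# ---- single-trial stream construction -------------------------------------

# Uniform point in the inner `frac` portion of rectangle c(xmin,ymin,xmax,ymax)
point_in_rect <- function(rect, frac = 0.6) {
  mx <- (rect[1] + rect[3]) / 2; my <- (rect[2] + rect[4]) / 2
  hw <- (rect[3] - rect[1]) / 2 * frac; hh <- (rect[4] - rect[2]) / 2 * frac
  c(stats::runif(1, mx - hw, mx + hw), stats::runif(1, my - hh, my + hh))
}

# Saccade sample offsets along the straight line start->end, defined in
# angular space: a raised-sine velocity pulse with constant-slope edges so
# that the first sample with 5-point/boxcar speed >= 30 deg/s is exactly the
# programmed onset sample. Returns the px positions for sample offsets
# 0..duration (position 0 = start, position duration = end).
# Main-sequence saccade duration (ms) for the angular distance start -> end.
saccade_duration <- function(start_px, end_px, geometry) {
  sdeg <- px_to_deg(start_px, geometry)
  edeg <- px_to_deg(end_px, geometry)
  amp <- sqrt(sum((edeg - sdeg)^2))
  max(16L, as.integer(round(2.2 * amp + 21)))
}

saccade_profile <- function(start_px, end_px, geometry) {
  sdeg <- px_to_deg(start_px, geometry)
  edeg <- px_to_deg(end_px, geometry)
  amp <- sqrt(sum((edeg - sdeg)^2))
  d <- max(16L, as.integer(round(2.2 * amp + 21)))  # main-sequence duration
  edge <- min(0.08, 0.7 * amp / d)                  # deg/ms at the edges
  sins <- sin(pi * (seq_len(d) - 0.5) / d)
  b <- (amp - edge * d) / sum(sins)
  w <- edge + b * sins
  frac <- c(0, cumsum(w)) / amp
  frac[length(frac)] <- 1
  degs <- cbind(sdeg[1] + frac * (edeg[1] - sdeg[1]),
                sdeg[2] + frac * (edeg[2] - sdeg[2]))
  deg_to_px(degs, geometry)
}

# Build one trial: gaze stream (if signals), gesture onset and truth fields.
# `label` is the exclusion label the trial must carry; the construction
# violates exactly that rule and none of higher precedence.
simulate_trial <- function(label, pathway, side, latency, delay,
                           config, geometry, map, benign_blink = FALSE,
                           signals = TRUE) {
  stim <- config$stim_onset_ms
  n <- stim + config$post_onset_ms
  target_roi <- if (side == "left") map$left_stim else map$right_stim

  p_social <- point_in_rect(map$social)
  p_target <- point_in_rect(target_roi)
  p_random <- c(stats::runif(1, 700, 1220), stats::runif(1, 550, 900))
  p_center <- c(stats::runif(1, 860, 1060), stats::runif(1, 550, 750))

  t1 <- stim + latency
  segs <- NULL          # list of (onset, from, to) saccade plans
  anchor <- p_social    # fixation position covering stimulus onset
  true_shift <- NA_integer_
  first_sacc <- NA_integer_
  path_out <- pathway

  if (label == "no_comm_shift") {
    path_out <- NA_character_
  } else if (label == "gaze_not_social_at_onset") {
    anchor <- p_center
    segs <- list(list(onset = t1, from = p_center, to = p_target))
    first_sacc <- t1
    path_out <- NA_character_
  } else {
    if (pathway == "direct") {
      segs <- list(list(onset = t1, from = p_social, to = p_target))
      true_shift <- t1
    } else {
      p_mid <- p_random
      if (pathway == "social_refix") {
        # refixation point far enough from the anchor that the intermediate
        # saccade clears the parser's velocity threshold
        repeat {
          p_mid <- point_in_rect(map$social, frac = 0.9)
          if (sqrt(sum((p_mid - p_social)^2)) >= 60) break
        }
      }
      d1 <- saccade_duration(p_social, p_mid, geometry)
      mid_dur <- sample(100:250, 1)
      t2 <- t1 + d1 + mid_dur
      segs <- list(list(onset = t1, from = p_social, to = p_mid),
                   list(onset = t2, from = p_mid, to = p_target))
      true_shift <- if (pathway == "social_refix") t2 else t1
    }
    first_sacc <- t1
  }

  gesture <- switch(label,
    gesture_precedes_gaze = true_shift - sample(10:60, 1),
    no_comm_shift = ,
    gaze_not_social_at_onset = stim + 450 + sample(0:300, 1),
    true_shift + delay)
  true_delay <- if (is.na(true_shift)) NA_integer_ else
    as.integer(gesture - true_shift)

  # blink window draws happen in both modes so the RNG stream (and hence the
  # truth tables) are identical with and without signal rendering
  blink <- NULL
  if (label == "blink_pre_onset") {
    gap <- sample(5:95, 1); bdur <- sample(60:150, 1)
    blink <- c(max(5L, stim - gap - bdur), stim - gap)
  } else if (benign_blink) {
    g <- sample(130:250, 1); bdur <- sample(60:120, 1)
    blink <- c(max(5L, stim - g - bdur), stim - g)
  }

  stream <- NULL
  if (signals) {
    x <- numeric(n); y <- numeric(n); valid <- rep(1L, n)
    x[] <- anchor[1]; y[] <- anchor[2]
    for (sg in segs) {
      pos <- saccade_profile(sg$from, sg$to, geometry)
      idx <- sg$onset + seq_len(nrow(pos)) - 1L  # sample times onset..onset+d
      if (max(idx) + 1L > n)
        stop("programmed saccade exceeds the stream; increase post_onset_ms",
             call. = FALSE)
      x[idx + 1L] <- pos[, 1]; y[idx + 1L] <- pos[, 2]
      if (max(idx) + 2L <= n) {           # hold the landing position
        hold <- (max(idx) + 1L):(n - 1L)
        x[hold + 1L] <- pos[nrow(pos), 1]; y[hold + 1L] <- pos[nrow(pos), 2]
      }
    }
    if (!is.null(blink) && blink[1] < blink[2])
      valid[(blink[1] + 1L):blink[2]] <- 0L
    if (config$noise_px > 0) {
      x <- x + stats::rnorm(n, 0, config$noise_px)
      y <- y + stats::rnorm(n, 0, config$noise_px)
    }
    stream <- data.frame(time_ms = 0:(n - 1L), x_px = x, y_px = y,
                         valid = valid)
  }

  list(stream = stream, gesture_onset = as.integer(gesture),
       true_shift_onset = as.integer(true_shift), true_delay = true_delay,
       pathway = path_out, latency = as.integer(latency))
}
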