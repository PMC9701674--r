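#' Classify candidate communicative gaze pathways
#'
#' Scans parsed gaze events after stimulus onset for saccade chains anchored
#' in a social-RoI fixation and ending on the target stimulus. Three pathways
#' qualify: a direct saccade social -> target (candidate = that saccade); a
#' chain social -> social -> target (candidate = the second saccade); and a
#' chain social -> random -> target (candidate = the first saccade). Chains
#' are limited to one intermediate fixation, and a fixation on the non-target
#' stimulus bar is not a valid intermediate. Fixation RoI labels are assigned
#' by fixation centroid.
#'
#' @param events Event table from [detect_gaze_events()].
#' @param map A [roi_map()].
#' @param stim_onset Stimulus onset, ms on the trial clock.
#' @param target_side `"left"` or `"right"`.
#' @return Data frame of candidates ordered by candidate onset: `pathway`,
#'   `cand_onset`, `cand_offset`, `latency` (onset of the pathway's first
#'   saccade minus `stim_onset`). Zero rows when no pathway qualifies.
#' @export
classify_pathways <- function(events, map, stim_onset, target_side) {
  target <- paste0(target_side, "_stim")
  fix <- events$kind == "fixation"
  roi <- rep(NA_character_, nrow(events))
  if (any(fix))
    roi[fix] <- assign_roi(cbind(events$cx[fix], events$cy[fix]), map)

  sacc_idx <- which(events$kind == "saccade" & events$onset >= stim_onset)
  out <- list()
  for (i in sacc_idx) {
    prev <- rev(which(fix[seq_len(i - 1L)]))
    if (!length(prev) || roi[prev[1]] != "social") next
    if (prev[1] != i - 1L) next  # blink separates anchor from saccade
    nxt <- which(fix[-seq_len(i)]) + i
    if (!length(nxt) || nxt[1] != i + 1L) next
    land1 <- roi[nxt[1]]
    lat <- events$onset[i] - stim_onset
    if (land1 == target) {
      out[[length(out) + 1L]] <- data.frame(
        pathway = "direct", cand_onset = events$onset[i],
        cand_offset = events$offset[i], latency = lat)
    } else if (land1 %in% c("social", "random")) {
      # one intermediate fixation, then a saccade to the target
      j <- nxt[1] + 1L
      if (j > nrow(events) || events$kind[j] != "saccade") next
      if (j + 1L > nrow(events) || events$kind[j + 1L] != "fixation") next
      if (roi[j + 1L] != target) next
      if (land1 == "social") {
        out[[length(out) + 1L]] <- data.frame(
          pathway = "social_refix", cand_onset = events$onset[j],
          cand_offset = events$offset[j], latency = lat)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          pathway = "random_refix", cand_onset = events$onset[i],
          cand_offset = events$offset[i], latency = lat)
      }
    }
  }
  if (!length(out))
    return(data.frame(pathway = character(), cand_onset = integer(),
                      cand_offset = integer(), latency = integer()))
  res <- do.call(rbind, out)
  res[order(res$cand_onset), , drop = FALSE]
}

#' Select the communicative gaze shift for one trial
#'
#' Applies the selection rules in listing order and returns either the first
#' qualifying candidate saccade or the lowest-numbered violated exclusion
#' rule:
#' 1. first trial of a block;
#' 2. gaze not in the social RoI at the stimulus-onset sample;
#' 3. no candidate pathway;
#' 4. a blink ending within 100 ms before stimulus onset (or spanning it);
#' 5. pathway first-saccade latency below 75 ms;
#' 6. gesture onset preceding the candidate saccade onset.
#'
#' @param stream Gaze sample data frame (`time_ms`, `x_px`, `y_px`, `valid`).
#' @param stim_onset Stimulus onset, ms.
#' @param target_side `"left"` or `"right"`.
#' @param gesture_onset Gesture (space-bar release) onset, ms; `NA` when the
#'   gesture was not captured.
#' @param first_trial Logical: is this the first trial of its block?
#' @param map A [roi_map()].
#' @param geometry A [screen_geometry()].
#' @param blink_window_ms Pre-onset blink exclusion window (default 100 ms).
#' @param min_latency_ms Minimum externally-triggered saccade latency
#'   (default 75 ms).
#' @param parser Optional named list of arguments passed to
#'   [detect_gaze_events()].
#' @param events Optional pre-computed event table (skips parsing).
#' @return One-row data frame (`SelectionResult`): `status` (selected /
#'   excluded), `exclusion` (rule code, or "none"), `shift_onset`,
#'   `shift_offset`, `pathway`, `latency`.
#' @export
select_gaze_shift <- function(stream, stim_onset, target_side, gesture_onset,
                              first_trial = FALSE, map = roi_map(),
                              geometry = screen_geometry(),
                              blink_window_ms = 100, min_latency_ms = 75,
                              parser = list(), events = NULL) {
  excl <- function(code) data.frame(
    status = "excluded", exclusion = code, shift_onset = NA_integer_,
    shift_offset = NA_integer_, pathway = NA_character_,
    latency = NA_integer_, stringsAsFactors = FALSE)

  if (isTRUE(first_trial)) return(excl("first_trial"))

  i_on <- match(stim_onset, stream$time_ms)
  if (is.na(i_on)) stop("stimulus onset not covered by the gaze stream", call. = FALSE)
  at_onset <- c(stream$x_px[i_on], stream$y_px[i_on])
  if (!as.logical(stream$valid[i_on]) ||
      assign_roi(at_onset, map) != "social")
    return(excl("gaze_not_social_at_onset"))

  if (is.null(events))
    events <- do.call(detect_gaze_events,
                      c(list(samples = stream, geometry = geometry), parser))

  cands <- classify_pathways(events, map, stim_onset, target_side)
  if (!nrow(cands)) return(excl("no_comm_shift"))

  blinks <- events[events$kind == "blink", , drop = FALSE]
  if (nrow(blinks)) {
    # offset is half-open: last invalid sample is offset - 1
    recent <- (blinks$offset - 1L) >= (stim_onset - blink_window_ms) &
      blinks$onset <= stim_onset
    if (any(recent)) return(excl("blink_pre_onset"))
  }

  cand <- cands[1L, ]
  if (cand$latency < min_latency_ms) return(excl("latency_lt_75"))

  if (is.na(gesture_onset)) {
    res <- excl("no_comm_shift")
    res$exclusion <- "indeterminate_gesture"
    return(res)
  }
  if (gesture_onset < cand$cand_onset) return(excl("gesture_precedes_gaze"))

  data.frame(status = "selected", exclusion = "none",
             shift_onset = cand$cand_onset, shift_offset = cand$cand_offset,
             pathway = cand$pathway, latency = cand$latency,
             stringsAsFactors = FALSE)
}

#' Run the selection algorithm over a whole cohort
#'
#' Parses every gaze stream and applies [select_gaze_shift()] per trial.
#'
#' @param cohort An `iaps_cohort` from [simulate_cohort()] (with
#'   `signals = TRUE`), or a list with `trials`, `streams`, `map`,
#'   `geometry`.
#' @param ... Passed to [select_gaze_shift()].
#' @return Data frame: trial keys (subject, group, block, trial, side)
#'   followed by the `SelectionResult` columns.
#' @export
select_cohort <- function(cohort, ...) {
  if (is.null(cohort$streams))
    stop("cohort has no gaze streams (simulate with signals = TRUE)", call. = FALSE)
  trials <- cohort$trials
  n <- nrow(trials)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    key <- trial_key(trials$subject[i], trials$block[i], trials$trial[i])
    res[[i]] <- select_gaze_shift(
      cohort$streams[[key]], trials$stim_onset_ms[i], trials$side[i],
      trials$gesture_onset_ms[i], first_trial = trials$trial[i] == 1L,
      map = cohort$map, geometry = cohort$geometry, ...)
  }
  out <- cbind(trials[, c("subject", "group", "block", "trial", "side")],
               do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Compare selection results against generator ground truth
#'
#' Builds the confusion matrix of generated exclusion labels versus the
#' labels assigned by the selection algorithm (selected trials count as
#' "none") and its diagonal accuracy.
#'
#' @param selections Output of [select_cohort()].
#' @param truth Truth table of the same cohort (`$truth`).
#' @return List with `confusion` (truth in rows, predicted in columns),
#'   `accuracy`, and `n`.
#' @export
validate_selection <- function(selections, truth) {
  key_s <- trial_key(selections$subject, selections$block, selections$trial)
  key_t <- trial_key(truth$subject, truth$block, truth$trial)
  if (length(key_s) != length(key_t) || !all(sort(key_s) == sort(key_t)))
    stop("selection and truth trial keys do not match", call. = FALSE)
  truth <- truth[match(key_s, key_t), ]
  lev <- exclusion_levels()
  cm <- table(truth = factor(truth$exclusion, levels = lev),
              predicted = factor(selections$exclusion, levels = lev))
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm), n = sum(cm))
}
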