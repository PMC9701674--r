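#' Per-trial gaze-gesture delays
#'
#' Subtracts the selected communicative gaze-shift onset from the pointing
#' gesture onset for every selected trial, in integer ms. Trials with a
#' missing gesture onset are dropped with a message.
#'
#' @param selections Output of [select_cohort()] (or a data frame with the
#'   same columns plus trial keys).
#' @param trials Trial table providing `gesture_onset_ms` (defaults to the
#'   columns already present in `selections` when merged upstream).
#' @return Data frame of `DelayRecord`s: subject, group, block, trial, side,
#'   `delay` (ms).
#' @examples
#' # shift onset 500, gesture onset 750 -> 250 ms
#' @export
compute_delays <- function(selections, trials = NULL) {
  df <- selections
  if (!is.null(trials)) {
    key_s <- trial_key(df$subject, df$block, df$trial)
    key_t <- trial_key(trials$subject, trials$block, trials$trial)
    df$gesture_onset_ms <- trials$gesture_onset_ms[match(key_s, key_t)]
  }
  if (!"gesture_onset_ms" %in% names(df))
    stop("gesture onsets not found; supply `trials`", call. = FALSE)
  df <- df[df$status == "selected", , drop = FALSE]
  miss <- is.na(df$gesture_onset_ms)
  if (any(miss)) {
    message(sprintf("dropping %d selected trial(s) with missing gesture onset",
                    sum(miss)))
    df <- df[!miss, , drop = FALSE]
  }
  out <- df[, c("subject", "group", "block", "trial", "side")]
  out$delay <- as.integer(df$gesture_onset_ms - df$shift_onset)
  rownames(out) <- NULL
  out
}

#' Aggregate delay records
#'
#' `level = "subject"` returns the mean delay per subject (the subject-level
#' IaPS index); `level = "sd"` returns the sample SD (n-1 denominator) of
#' delays per subject x block x target side, omitting cells with fewer than
#' two observations (no SD can be computed there).
#'
#' @param records Output of [compute_delays()].
#' @param level `"subject"` or `"sd"`.
#' @return Data frame of aggregates with an `n_obs` count column.
#' @export
aggregate_delays <- function(records, level = c("subject", "sd")) {
  level <- match.arg(level)
  if (!nrow(records)) stop("no delay records to aggregate", call. = FALSE)
  if (level == "subject") {
    sp <- split(records$delay, list(records$subject, records$group), drop = TRUE)
    keys <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
    out <- data.frame(subject = keys[, 1], group = keys[, 2],
                      mean_delay = vapply(sp, mean, 0),
                      n_obs = vapply(sp, length, 0L),
                      stringsAsFactors = FALSE)
  } else {
    f <- interaction(records$subject, records$group, records$block,
                     records$side, drop = TRUE, sep = "\r")
    sp <- split(records$delay, f)
    keys <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
    out <- data.frame(subject = keys[, 1], group = keys[, 2],
                      block = as.integer(keys[, 3]), side = keys[, 4],
                      sd_delay = vapply(sp, stats::sd, 0),
                      n_obs = vapply(sp, length, 0L),
                      stringsAsFactors = FALSE)
    dropped <- out$n_obs < 2L
    if (any(dropped))
      message(sprintf("%d cell(s) with a single observation yield no SD", sum(dropped)))
    out <- out[!dropped, , drop = FALSE]
  }
  out <- out[order(out$group, out$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag extreme values by the 3 x IQR rule, per group
#'
#' Marks values above `Q3 + 3 * IQR` or below `Q1 - 3 * IQR`, with quartiles
#' computed per group by linear interpolation between order statistics
#' (`stats::quantile()` type 7). Groups with fewer than 4 values are not
#' flagged (warning).
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @param k Fence multiplier (default 3).
#' @return Logical mask, `TRUE` = extreme.
#' @export
flag_extremes <- function(values, groups, k = 3) {
  stopifnot(length(values) == length(groups))
  mask <- logical(length(values))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    v <- values[idx]
    if (sum(is.finite(v)) < 4) {
      warning(sprintf("group '%s' has fewer than 4 values; not flagged", g))
      next
    }
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    mask[idx] <- v > q[2] + k * iqr | v < q[1] - k * iqr
  }
  mask
}

#' Code spontaneous channel use in free-task trials
#'
#' Combines rater annotations (verbal, gesture) with the gaze selection
#' outcome (gaze = 1 iff a communicative gaze shift was selected; dismissed
#' trials are coded 0) into the six mutually exclusive combination flags
#' (gaze-only, verbal-only, gesture-only, gaze-and-gesture, gaze-and-verbal,
#' verbal-and-gesture) and the modality-count flags (unimodal, bimodal,
#' trimodal). First trials of each block are excluded from the output, as
#' they are by the gaze selection algorithm. Trials without an annotation are
#' dropped with a message.
#'
#' @param annotations Data frame with subject, block, trial, `verbal`,
#'   `gesture` (0/1).
#' @param selections Output of [select_cohort()] for the same trials.
#' @return Data frame of `ChannelCode`s: keys, the three channel binaries,
#'   six combination flags, three count flags.
#' @export
code_channels <- function(annotations, selections) {
  key_a <- trial_key(annotations$subject, annotations$block, annotations$trial)
  key_s <- trial_key(selections$subject, selections$block, selections$trial)
  m <- match(key_s, key_a)
  miss <- is.na(m)
  if (any(miss))
    message(sprintf("dropping %d trial(s) without annotation", sum(miss)))
  sel <- selections[!miss, , drop = FALSE]
  ann <- annotations[m[!miss], , drop = FALSE]
  keep <- sel$trial != 1L
  sel <- sel[keep, , drop = FALSE]; ann <- ann[keep, , drop = FALSE]

  gaze <- as.integer(sel$status == "selected")
  verbal <- as.integer(ann$verbal)
  gesture <- as.integer(ann$gesture)
  n_chan <- gaze + verbal + gesture
  out <- data.frame(
    subject = sel$subject, group = sel$group, block = sel$block,
    trial = sel$trial,
    gaze = gaze, verbal = verbal, gesture = gesture,
    gaze_only = as.integer(gaze == 1 & n_chan == 1),
    verbal_only = as.integer(verbal == 1 & n_chan == 1),
    gesture_only = as.integer(gesture == 1 & n_chan == 1),
    gaze_and_gesture = as.integer(gaze == 1 & gesture == 1 & n_chan == 2),
    gaze_and_verbal = as.integer(gaze == 1 & verbal == 1 & n_chan == 2),
    verbal_and_gesture = as.integer(verbal == 1 & gesture == 1 & n_chan == 2),
    unimodal = as.integer(n_chan == 1),
    bimodal = as.integer(n_chan == 2),
    trimodal = as.integer(n_chan == 3),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Channel-use frequencies
#'
#' Per-group sums and rates of each channel-use flag.
#'
#' @param codes Output of [code_channels()].
#' @return Data frame with one row per flag per group.
#' @export
channel_frequencies <- function(codes) {
  flags <- c("gaze", "verbal", "gesture", "gaze_only", "verbal_only",
             "gesture_only", "gaze_and_gesture", "gaze_and_verbal",
             "verbal_and_gesture", "unimodal", "bimodal", "trimodal")
  out <- do.call(rbind, lapply(split(codes, codes$group), function(d) {
    data.frame(group = d$group[1], flag = flags,
               n = vapply(flags, function(f) sum(d[[f]]), 0),
               rate = vapply(flags, function(f) mean(d[[f]]), 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Descriptive statistics of IaPS measures per group
#'
#' Mean, SD, median, min and max of subject-wise aggregated values per group
#' (the layout of a descriptives table for gaze-gesture delays and SD of
#' delays).
#'
#' @param x Data frame with a `group` column and the value column `var`.
#' @param var Name of the value column (e.g. `"mean_delay"` or `"sd_delay"`).
#' @return Data frame: group, M, SD, Mdn, min, max, n.
#' @export
delay_descriptives <- function(x, var = "mean_delay") {
  stopifnot(var %in% names(x))
  out <- do.call(rbind, lapply(split(x[[var]], x$group), function(v) {
    data.frame(M = mean(v), SD = stats::sd(v), Mdn = stats::median(v),
               min = min(v), max = max(v), n = length(v))
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}
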