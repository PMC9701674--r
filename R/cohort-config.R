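#' Configuration for a synthetic two-group cohort
#'
#' Collects the parameters of the synthetic-data generator that emulates a
#' two-group (ASD vs typically-developed comparison) gaze-and-gesture cohort:
#' group delay means and dispersions, within-subject variability coupled to
#' the subject mean, saccade latencies, trial/block design, exclusion-rule
#' violation rates, and the event geometry of the simulated gaze streams.
#'
#' Delay parameters are in ms. Per subject, a (mean delay, within-subject SD)
#' pair is drawn from a bivariate lognormal whose log-scale correlation is
#' `mean_sd_coupling`; per-trial delays are then Gaussian around the subject
#' mean with the subject SD, truncated at zero by resampling.
#'
#' @param n_per_group Subjects per group (default 24).
#' @param n_blocks Blocks per subject (default 4).
#' @param trials_per_block Trials per block (default 30), target side
#'   counterbalanced within block.
#' @param group_delay_shift Added to the TD mean delay for the ASD group, ms
#'   (default 55).
#' @param td_mean_delay TD group mean delay, ms (default 206).
#' @param td_between_subject_sd,asd_between_subject_sd Between-subject SD of
#'   subject mean delays per group, ms (defaults 59 and 103).
#' @param within_subject_sd_td,within_subject_sd_asd Expected within-subject
#'   delay SD per group, ms (defaults 81 and 95).
#' @param sd_dispersion Log-scale SD of the subject-level within-subject SD
#'   draw (default 0.45).
#' @param mean_sd_coupling Log-scale correlation between subject mean delay
#'   and subject SD, in [-1, 1] (default +0.6).
#' @param saccade_latency_range Uniform range of stimulus-to-saccade latency,
#'   ms (default c(120, 300)).
#' @param sample_rate Gaze sampling rate, fixed at 1000 Hz.
#' @param stim_onset_ms Stimulus onset within each simulated stream (default
#'   400 ms of pre-onset social fixation).
#' @param post_onset_ms Stream duration after stimulus onset (default 1100).
#' @param noise_px SD of additive Gaussian position noise on gaze samples
#'   (default 0: clean piecewise event geometry; see the vignette).
#' @param pathway_probs Probabilities of the three gaze pathways
#'   (direct, social_refix, random_refix); must sum to 1.
#' @param exclusion_rates Named violation probabilities for the five
#'   non-first-trial exclusion rules (first trials are always labelled).
#' @param blink_benign_rate Probability of an innocuous early blink on an
#'   otherwise clean trial (default 0.1).
#' @param verbal_p,gesture_p Free-task per-trial probabilities of spontaneous
#'   verbal and gesture channel use.
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @return Object of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_per_group = 24, n_blocks = 4, trials_per_block = 30,
                          group_delay_shift = 55, td_mean_delay = 206,
                          td_between_subject_sd = 59,
                          asd_between_subject_sd = 103,
                          within_subject_sd_td = 81, within_subject_sd_asd = 95,
                          sd_dispersion = 0.45, mean_sd_coupling = 0.6,
                          saccade_latency_range = c(120, 300),
                          sample_rate = 1000,
                          stim_onset_ms = 400, post_onset_ms = 1100,
                          noise_px = 0,
                          pathway_probs = c(direct = 0.8, social_refix = 0.1,
                                            random_refix = 0.1),
                          exclusion_rates = c(gaze_not_social_at_onset = 0.08,
                                              no_comm_shift = 0.04,
                                              blink_pre_onset = 0.03,
                                              latency_lt_75 = 0.02,
                                              gesture_precedes_gaze = 0.01),
                          blink_benign_rate = 0.1,
                          verbal_p = 0.35, gesture_p = 0.85,
                          seed = 1L) {
  stop_if_not_scalar_count(n_per_group, "n_per_group")
  stop_if_not_scalar_count(n_blocks, "n_blocks")
  stop_if_not_scalar_count(trials_per_block, "trials_per_block")
  if (sample_rate != 1000)
    stop("sample_rate is fixed at 1000 Hz", call. = FALSE)
  sds <- c(td_between_subject_sd, asd_between_subject_sd,
           within_subject_sd_td, within_subject_sd_asd, sd_dispersion)
  if (any(sds <= 0)) stop("all SD parameters must be > 0", call. = FALSE)
  if (td_mean_delay <= 0) stop("td_mean_delay must be > 0", call. = FALSE)
  if (abs(mean_sd_coupling) > 1)
    stop("mean_sd_coupling must lie in [-1, 1]", call. = FALSE)
  if (length(saccade_latency_range) != 2 ||
      saccade_latency_range[1] >= saccade_latency_range[2] ||
      saccade_latency_range[1] < 75)
    stop("saccade_latency_range must be an increasing pair with lower bound >= 75 ms",
         call. = FALSE)
  if (abs(sum(pathway_probs) - 1) > 1e-8 || any(pathway_probs < 0))
    stop("pathway_probs must be non-negative and sum to 1", call. = FALSE)
  need <- c("gaze_not_social_at_onset", "no_comm_shift", "blink_pre_onset",
            "latency_lt_75", "gesture_precedes_gaze")
  if (!all(need %in% names(exclusion_rates)) || any(exclusion_rates < 0) ||
      sum(exclusion_rates) >= 1)
    stop("exclusion_rates must name the five rules, be non-negative and sum to < 1",
         call. = FALSE)
  if (noise_px < 0) stop("noise_px must be >= 0", call. = FALSE)
  if (stim_onset_ms < 300 || post_onset_ms < 900)
    stop("stream too short to host the programmed events (stim_onset_ms >= 300, post_onset_ms >= 900)",
         call. = FALSE)
  structure(list(
    n_per_group = as.integer(n_per_group), n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    group_delay_shift = group_delay_shift, td_mean_delay = td_mean_delay,
    td_between_subject_sd = td_between_subject_sd,
    asd_between_subject_sd = asd_between_subject_sd,
    within_subject_sd_td = within_subject_sd_td,
    within_subject_sd_asd = within_subject_sd_asd,
    sd_dispersion = sd_dispersion, mean_sd_coupling = mean_sd_coupling,
    saccade_latency_range = saccade_latency_range,
    sample_rate = 1000L,
    stim_onset_ms = as.integer(stim_onset_ms),
    post_onset_ms = as.integer(post_onset_ms),
    noise_px = noise_px, pathway_probs = pathway_probs,
    exclusion_rates = exclusion_rates[need],
    blink_benign_rate = blink_benign_rate,
    verbal_p = verbal_p, gesture_p = gesture_p,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d subjects/group, %d blocks x %d trials, seed %d\n",
              x$n_per_group, x$n_blocks, x$trials_per_block, x$seed))
  cat(sprintf("  TD mean delay %.0f ms (between-subject SD %.0f), ASD shift +%.0f ms (SD %.0f)\n",
              x$td_mean_delay, x$td_between_subject_sd,
              x$group_delay_shift, x$asd_between_subject_sd))
  cat(sprintf("  within-subject SD: TD %.0f, ASD %.0f ms; mean-SD coupling %.2f\n",
              x$within_subject_sd_td, x$within_subject_sd_asd,
              x$mean_sd_coupling))
  cat(sprintf("  saccade latency U[%d, %d] ms; exclusion rates sum %.2f\n",
              x$saccade_latency_range[1], x$saccade_latency_range[2],
              sum(x$exclusion_rates)))
  invisible(x)
}

# Exclusion labels in precedence (listing) order. "none" sorts last.
exclusion_levels <- function() {
  c("first_trial", "gaze_not_social_at_onset", "no_comm_shift",
    "blink_pre_onset", "latency_lt_75", "gesture_precedes_gaze", "none")
}

# Subject-level (mean delay, within-subject SD) pairs from a bivariate
# lognormal. Moment-matched so E[mean] and SD[mean] hit the configured group
# values and E[sd] hits the configured within-subject SD.
draw_subject_params <- function(config, group, n = config$n_per_group) {
  m_target <- config$td_mean_delay +
    if (group == "ASD") config$group_delay_shift else 0
  s_between <- if (group == "ASD") config$asd_between_subject_sd else
    config$td_between_subject_sd
  sd_target <- if (group == "ASD") config$within_subject_sd_asd else
    config$within_subject_sd_td
  sig_m <- sqrt(log(1 + (s_between / m_target)^2))
  mu_m <- log(m_target) - sig_m^2 / 2
  sig_s <- config$sd_dispersion
  mu_s <- log(sd_target) - sig_s^2 / 2
  rho <- config$mean_sd_coupling
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  data.frame(subject_mean = exp(mu_m + sig_m * z1),
             subject_sd = exp(mu_s + sig_s * z2))
}
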