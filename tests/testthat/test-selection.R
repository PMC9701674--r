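test_that("pathway classification selects the right candidate saccade", {
  stim <- cohort_config()$stim_onset_ms
  map <- roi_map(); geom <- screen_geometry()

  # direct: one saccade social -> target, candidate is that saccade
  case <- make_exclusion_case("none", base_trial = list(pathway = "direct",
                                                        latency = 180), seed = 21)
  ev <- detect_gaze_events(case$stream, geom)
  cands <- classify_pathways(ev, map, stim, case$truth$side)
  expect_equal(cands$pathway[1], "direct")
  expect_equal(cands$latency[1], 180)
  expect_equal(cands$cand_onset[1], stim + 180)

  # random-refix: candidate is the FIRST saccade of the chain
  case <- make_exclusion_case("none", base_trial = list(pathway = "random_refix",
                                                        latency = 200), seed = 22)
  ev <- detect_gaze_events(case$stream, geom)
  cands <- classify_pathways(ev, map, stim, case$truth$side)
  expect_equal(cands$pathway[1], "random_refix")
  expect_equal(cands$cand_onset[1], stim + 200)
  expect_equal(cands$cand_onset[1], case$truth$true_shift_onset)

  # social-refix: candidate is the SECOND saccade
  case <- make_exclusion_case("none", base_trial = list(pathway = "social_refix",
                                                        latency = 150), seed = 23)
  ev <- detect_gaze_events(case$stream, geom)
  cands <- classify_pathways(ev, map, stim, case$truth$side)
  expect_equal(cands$pathway[1], "social_refix")
  # small intermediate saccades may be detected a sample or two late
  expect_lte(abs(cands$latency[1] - 150), 2)
  expect_gt(cands$cand_onset[1], stim + 150)
  expect_equal(cands$cand_onset[1], case$truth$true_shift_onset)
})

test_that("each exclusion rule is recovered on purpose-built violating trials", {
  stim <- cohort_config()$stim_onset_ms
  rules <- setdiff(iapsync:::exclusion_levels(), "none")
  for (rule in rules) {
    for (seed in 1:5) {
      case <- make_exclusion_case(rule, seed = 30 + seed)
      sel <- select_gaze_shift(case$stream, stim, case$truth$side,
                               case$gesture_onset,
                               first_trial = rule == "first_trial")
      expect_equal(sel$exclusion, rule,
                   label = sprintf("rule %s seed %d gave %s", rule, seed,
                                   sel$exclusion))
      expect_equal(sel$status, "excluded")
    }
  }
})

test_that("first trials are excluded regardless of gaze content", {
  case <- make_exclusion_case("none", seed = 44)
  sel <- select_gaze_shift(case$stream, 400, case$truth$side,
                           case$gesture_onset, first_trial = TRUE)
  expect_equal(sel$exclusion, "first_trial")
})

test_that("rule precedence picks the lowest-numbered violated rule", {
  # a trial with both a pre-onset blink (rule 4) and an early gesture (rule 6)
  case <- make_exclusion_case("blink_pre_onset", seed = 45)
  early_gesture <- case$truth$true_shift_onset - 50
  sel <- select_gaze_shift(case$stream, 400, case$truth$side, early_gesture,
                           first_trial = FALSE)
  expect_equal(sel$exclusion, "blink_pre_onset")
  # and with first_trial set, rule 1 wins over everything
  sel <- select_gaze_shift(case$stream, 400, case$truth$side, early_gesture,
                           first_trial = TRUE)
  expect_equal(sel$exclusion, "first_trial")
})

test_that("a missing gesture onset is flagged as indeterminate", {
  case <- make_exclusion_case("none", seed = 46)
  sel <- select_gaze_shift(case$stream, 400, case$truth$side, NA,
                           first_trial = FALSE)
  expect_equal(sel$status, "excluded")
  expect_equal(sel$exclusion, "indeterminate_gesture")
})

test_that("selection on the synthetic cohort reproduces every exclusion label", {
  v <- validate_selection(shared$selection, shared$cohort$truth)
  expect_equal(v$accuracy, 1)
  expect_equal(v$n, nrow(shared$cohort$truth))
  # selected trials carry pathway and latency consistent with the invariants
  sel <- shared$selection[shared$selection$status == "selected", ]
  expect_true(all(sel$latency >= 75))
  expect_true(all(!is.na(sel$shift_onset)))
  expect_true(all(shared$selection$exclusion[shared$selection$status ==
                                               "excluded"] != "none"))
})

test_that("selection is deterministic", {
  key <- names(shared$cohort$streams)[3]
  tr <- shared$cohort$trials[3, ]
  s1 <- select_gaze_shift(shared$cohort$streams[[key]], tr$stim_onset_ms,
                          tr$side, tr$gesture_onset_ms, tr$trial == 1)
  s2 <- select_gaze_shift(shared$cohort$streams[[key]], tr$stim_onset_ms,
                          tr$side, tr$gesture_onset_ms, tr$trial == 1)
  expect_identical(s1, s2)
})

test_that("widening the blink window only moves trials from selected to excluded", {
  idx <- which(shared$cohort$truth$exclusion %in% c("none", "blink_pre_onset"))[1:30]
  tr <- shared$cohort$trials
  status <- function(i, win) {
    key <- trial_keys(tr[i, ])
    select_gaze_shift(shared$cohort$streams[[key]], tr$stim_onset_ms[i],
                      tr$side[i], tr$gesture_onset_ms[i], tr$trial[i] == 1,
                      blink_window_ms = win)$status
  }
  for (i in idx) {
    narrow <- status(i, 100); wide <- status(i, 350)
    expect_false(narrow == "excluded" && wide == "selected")
  }
})
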