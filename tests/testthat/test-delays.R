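make_selection_row <- function(shift, gesture, subject = "T01", block = 2,
                               trial = 3, side = "left") {
  data.frame(subject = subject, group = "TD", block = block, trial = trial,
             side = side, status = "selected", exclusion = "none",
             shift_onset = shift, shift_offset = shift + 40,
             pathway = "direct", latency = 150, gesture_onset_ms = gesture,
             stringsAsFactors = FALSE)
}

test_that("delays are gesture onset minus shift onset in integer ms", {
  expect_equal(compute_delays(make_selection_row(500, 750))$delay, 250L)
  expect_equal(compute_delays(make_selection_row(500, 500))$delay, 0L)
  sel <- rbind(make_selection_row(500, 750),
               make_selection_row(400, NA, trial = 4))
  expect_message(d <- compute_delays(sel), "missing gesture")
  expect_equal(nrow(d), 1L)
})

test_that("cohort delays equal the generated ground truth exactly", {
  d <- compute_delays(shared$selection, shared$cohort$trials)
  tr <- aligned_truth(d)
  expect_true(all(d$delay == tr$true_delay))
  expect_equal(nrow(d), sum(shared$cohort$truth$exclusion == "none"))
})

test_that("aggregation matches closed forms and is order-invariant", {
  rec <- data.frame(subject = "A01", group = "ASD", block = 1,
                    trial = 1:2, side = "left", delay = c(200, 220))
  sdtab <- aggregate_delays(rec, "sd")
  expect_equal(sdtab$sd_delay, sd(c(200, 220)))
  expect_equal(round(sdtab$sd_delay, 3), 14.142)

  d <- compute_delays(shared$selection, shared$cohort$trials)
  perm <- d[sample(nrow(d)), ]
  a1 <- aggregate_delays(d, "subject"); a2 <- aggregate_delays(perm, "subject")
  expect_equal(a1, a2)
})

test_that("aggregates equal a brute-force group-by recomputation", {
  set.seed(77)
  rec <- data.frame(subject = sample(sprintf("S%02d", 1:8), 1000, TRUE),
                    group = "TD", block = sample(1:4, 1000, TRUE),
                    trial = 1, side = sample(c("left", "right"), 1000, TRUE),
                    delay = round(rnorm(1000, 200, 60)))
  subj <- aggregate_delays(rec, "subject")
  for (i in seq_len(nrow(subj)))
    expect_equal(subj$mean_delay[i],
                 mean(rec$delay[rec$subject == subj$subject[i]]))
  cells <- suppressMessages(aggregate_delays(rec, "sd"))
  for (i in seq_len(min(nrow(cells), 50))) {
    v <- rec$delay[rec$subject == cells$subject[i] &
                   rec$block == cells$block[i] & rec$side == cells$side[i]]
    expect_equal(cells$sd_delay[i], sd(v))
    expect_equal(cells$n_obs[i], length(v))
  }
})

test_that("cells with one observation yield no SD", {
  rec <- data.frame(subject = c("A01", "A01", "A01"), group = "ASD",
                    block = c(1, 1, 2), trial = 1:3, side = "left",
                    delay = c(200, 240, 300))
  expect_message(cells <- aggregate_delays(rec, "sd"), "single observation")
  expect_equal(nrow(cells), 1L)
  expect_true(all(cells$n_obs >= 2))
})

test_that("3 x IQR fences flag exactly the hand-computed extremes", {
  v <- c(1:8, 1000)
  g <- rep("a", 9)
  # oracle by direct fence arithmetic (type-7 quartiles of 1..8 and 1000)
  q <- quantile(v, c(.25, .75), names = FALSE)
  upper <- q[2] + 3 * (q[2] - q[1])
  expect_equal(flag_extremes(v, g), v > upper)
  expect_equal(sum(flag_extremes(v, g)), 1L)
  expect_true(flag_extremes(v, g)[9])
})

test_that("fences collapse on constant data and are translation-equivariant", {
  expect_false(any(flag_extremes(rep(5, 10), rep("a", 10))))
  set.seed(5)
  v <- c(rnorm(30), 25)
  g <- rep("a", 31)
  expect_equal(flag_extremes(v, g), flag_extremes(v + 1000, g))
  expect_warning(flag_extremes(1:3, rep("a", 3)), "fewer than 4")
})

test_that("fences are computed per group", {
  v <- c(rep(1:5, 4), 50, rep(100 * (1:5), 4), 5000)
  g <- rep(c("a", "b"), each = 21)
  m <- flag_extremes(v, g)
  expect_true(m[21]); expect_true(m[42])
  expect_equal(sum(m), 2L)
})

test_that("channel coding produces exclusive combination flags", {
  ann <- data.frame(subject = "T01", block = 1, trial = 2:4,
                    verbal = c(0, 1, 1), gesture = c(1, 0, 1))
  sel <- rbind(make_selection_row(500, 750, block = 1, trial = 2),
               make_selection_row(500, 750, block = 1, trial = 3),
               make_selection_row(500, 750, block = 1, trial = 4))
  codes <- code_channels(ann, sel)
  expect_equal(codes$gaze_and_gesture, c(1, 0, 0))
  expect_equal(codes$gaze_and_verbal, c(0, 1, 0))
  expect_equal(codes$bimodal, c(1, 1, 0))
  expect_equal(codes$trimodal, c(0, 0, 1))
  comb <- c("gaze_only", "verbal_only", "gesture_only", "gaze_and_gesture",
            "gaze_and_verbal", "verbal_and_gesture")
  expect_true(all(rowSums(codes[, comb]) <= 1))
})

test_that("dismissed trials are coded gaze = 0 and first trials dropped", {
  codes <- code_channels(shared$cohort$annotations, shared$selection)
  expect_true(all(codes$trial != 1))
  tr <- aligned_truth(codes)
  expect_equal(codes$gaze, as.integer(tr$exclusion == "none"))
  # count flags partition trials with at least one channel
  n_chan <- codes$gaze + codes$verbal + codes$gesture
  expect_equal(codes$unimodal + codes$bimodal + codes$trimodal,
               as.integer(n_chan >= 1))
})

test_that("flag sums equal brute-force recounts", {
  codes <- code_channels(shared$cohort$annotations, shared$selection)
  g <- codes$gaze; v <- codes$verbal; ge <- codes$gesture
  expect_equal(sum(codes$gaze_only), sum(g == 1 & v == 0 & ge == 0))
  expect_equal(sum(codes$verbal_and_gesture), sum(g == 0 & v == 1 & ge == 1))
  expect_equal(sum(codes$trimodal), sum(g + v + ge == 3))
  freq <- channel_frequencies(codes)
  asd_gaze <- freq$n[freq$group == "ASD" & freq$flag == "gaze"]
  expect_equal(asd_gaze, sum(codes$gaze[codes$group == "ASD"]))
})

test_that("descriptives summarise subject-wise aggregates per group", {
  d <- compute_delays(shared$selection, shared$cohort$trials)
  subj <- aggregate_delays(d, "subject")
  tab <- delay_descriptives(subj, "mean_delay")
  for (g in tab$group) {
    v <- subj$mean_delay[subj$group == g]
    i <- tab$group == g
    expect_equal(tab$M[i], mean(v))
    expect_true(tab$M[i] >= tab$min[i] && tab$M[i] <= tab$max[i])
    expect_equal(tab$Mdn[i], median(v))
  }
})
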