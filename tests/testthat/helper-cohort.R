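# Shared small fixtures, built once per test run.

tiny_config <- function(seed = 101, ...) {
  cohort_config(n_per_group = 3, n_blocks = 2, trials_per_block = 12,
                seed = seed, ...)
}

# A small cohort with signals plus its selection results, reused across files.
shared <- local({
  cohort <- simulate_cohort(tiny_config())
  selection <- select_cohort(cohort)
  list(cohort = cohort, selection = selection)
})

trial_keys <- function(df) sprintf("%s_B%d_T%02d", df$subject, df$block, df$trial)

# Truth rows aligned to a selection/delay table.
aligned_truth <- function(df, cohort = shared$cohort) {
  cohort$truth[match(trial_keys(df), trial_keys(cohort$truth)), ]
}
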