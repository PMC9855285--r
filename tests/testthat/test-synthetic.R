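test_that("cohorts respect group sizes, inclusion bounds and determinism", {
  ch <- make_cohort(18, seed = 1)
  p <- ch$participants
  expect_equal(nrow(p), 36)
  expect_equal(unname(table(p$group)["depressed"]), 18L)
  expect_false(anyDuplicated(p$id) > 0)
  expect_true(all(p$bdi[p$group == "depressed"] >= 14))
  expect_true(all(p$bdi[p$group == "control"] <= 9))
  expect_true(all(p$true_k >= 0 & p$true_k <= 6))
  expect_identical(make_cohort(18, seed = 1), ch)

  # degenerate SD pins the score at the group mean
  gp <- default_group_params()
  gp$depressed$bdi_sd <- 0
  one <- make_cohort(1, gp, seed = 5)
  expect_equal(one$participants$bdi[1], 26.83)

  # overlapping inclusion ranges are rejected
  gp2 <- default_group_params()
  gp2$control$bdi_range <- c(0, 20)
  expect_error(make_cohort(2, gp2), "overlap")
})

test_that("trial tables are exactly counterbalanced per condition", {
  tt <- simulate_trial_table(task_config(), seed = 3)
  expect_equal(nrow(tt), 600)
  expect_equal(as.vector(table(tt$condition)), rep(200L, 3))
  expect_equal(sum(tt$change_present), 300)
  for (cond in cda_conditions) {
    sel <- tt[tt$condition == cond, ]
    expect_lte(abs(sum(sel$cue_side == "left") - sum(sel$cue_side == "right")), 1)
    expect_lte(abs(sum(sel$change_present) - sum(!sel$change_present)), 1)
  }
  expect_equal(length(unique(tt$block)), 12)
  expect_identical(simulate_trial_table(task_config(), seed = 3), tt)

  tiny <- simulate_trial_table(task_config(n_trials_per_condition = 2,
                                           n_blocks = 1), seed = 1)
  expect_equal(nrow(tiny), 6)
  expect_equal(as.vector(tapply(tiny$change_present, tiny$condition, sum)),
               rep(1L, 3))

  expect_error(
    simulate_trial_table(task_config(n_trials_per_condition = 3,
                                     n_blocks = 1)),
    "counterbalanced")
})

test_that("slots-model behavior hits the analytic ceiling and identity", {
  full <- simulate_behavior(6, 6, lapse = 0, trials = 100, seed = 1)
  hf <- hit_false_alarm(full)
  expect_equal(unname(hf), c(1, 0))
  expect_equal(cowan_k(hf["H"], hf["F"], 6), c(H = 6))

  # E[H] = 0.75, E[F] = 0.25 at k = 3, N = 6, g = 0.5 -> K-hat unbiased
  reps <- vapply(1:400, function(s) {
    hf <- hit_false_alarm(simulate_behavior(3, 6, 0.5, 0, 100, seed = s))
    cowan_k(hf["H"], hf["F"], 6)
  }, 0)
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 3), 3 * se)
})

test_that("noise-free injection reproduces the ground truth exactly", {
  tt <- simulate_trial_table(task_config(n_trials_per_condition = 4,
                                         n_blocks = 1), seed = 2)
  amps <- c(non_dis = 0, fearful_dis = -1, sad_dis = -0.85)
  ep <- simulate_epochs(tt, amps, small_eeg(noise_sd = 0, seed = 9))
  m <- measure_lateralized(ep, tt)
  expect_equal(m$cda[m$condition == "non_dis"], 0, tolerance = 1e-12)
  expect_equal(m$cda[m$condition == "fearful_dis"], -1, tolerance = 1e-12)
  expect_equal(m$cda[m$condition == "sad_dis"], -0.85, tolerance = 1e-12)
  # null lateralization: the whole difference wave vanishes
  w <- contra_ipsi_waves(ep, tt, montage(), "non_dis")
  expect_true(all(abs(w$diff) < 1e-12))
  # determinism
  ep2 <- simulate_epochs(tt, amps, small_eeg(noise_sd = 0, seed = 9))
  expect_identical(ep$data, ep2$data)
})

test_that("artifact injection flags match the realized draws and rates", {
  tt <- simulate_trial_table(task_config(n_trials_per_condition = 20,
                                         n_blocks = 1), seed = 4)
  eeg <- small_eeg(noise_sd = 0, saccade_rate = 0, blast_rate = 0)
  ep <- simulate_epochs(tt, c(non_dis = 0, fearful_dis = 0, sad_dis = 0), eeg)
  none <- inject_artifacts(ep, eeg, seed = 1)
  expect_equal(sum(none$flags$saccade), 0)
  expect_equal(sum(none$flags$blast), 0)

  eeg2 <- small_eeg(noise_sd = 0, saccade_rate = 0.1, blast_rate = 0.05)
  a1 <- inject_artifacts(ep, eeg2, seed = 11, trial_table = tt)
  a2 <- inject_artifacts(ep, eeg2, seed = 11, trial_table = tt)
  expect_identical(a1$flags, a2$flags)
  expect_identical(a1$epochs$data, a2$epochs$data)
  # flagged saccade trials really exceed the HEOG threshold
  hi <- which(a1$flags$saccade)
  for (tr in hi)
    expect_gt(max(abs(a1$epochs$data[tr, 7, ])), 60)
})
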