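test_that("contra/ipsi assignment follows the cue and montage construction", {
  tt <- data.frame(trial_id = 1:4,
                   condition = "non_dis",
                   cue_side = c("left", "right", "left", "right"),
                   change_present = TRUE, block = 1L,
                   response_change = NA, correct = NA,
                   rejected_heog = FALSE, rejected_amp = FALSE)
  ep <- make_flat_epochs(4)
  left_i <- match(c("P7", "P9", "PO7"), ep$channel_names)
  right_i <- match(c("P8", "P10", "PO8"), ep$channel_names)
  # put -1 on the contralateral hemisphere of every trial
  for (i in 1:4) {
    contra <- if (tt$cue_side[i] == "left") right_i else left_i
    ep$data[i, contra, ] <- -1
  }
  w <- contra_ipsi_waves(ep, tt, montage(), "non_dis")
  expect_equal(w$contra, rep(-1, length(w$times)))
  expect_equal(w$ipsi, rep(0, length(w$times)))
  expect_equal(w$diff, w$contra - w$ipsi)
  expect_equal(w$n_trials_used, 4)

  # swapping cue labels exchanges contra and ipsi
  tt2 <- tt
  tt2$cue_side <- ifelse(tt$cue_side == "left", "right", "left")
  w2 <- contra_ipsi_waves(ep, tt2, montage(), "non_dis")
  expect_equal(w2$contra, w$ipsi)
  expect_equal(w2$ipsi, w$contra)

  # zero usable trials on one side errors with the side named
  tt3 <- tt
  tt3$rejected_amp[tt3$cue_side == "left"] <- TRUE
  expect_error(contra_ipsi_waves(ep, tt3, montage(), "non_dis"),
               "cue side left")
})

test_that("contra/ipsi averaging matches a brute-force per-trial oracle", {
  set.seed(77)
  tt <- simulate_trial_table(task_config(n_trials_per_condition = 12,
                                         n_blocks = 1), seed = 3)
  ep <- make_flat_epochs(nrow(tt))
  ep$data[] <- rnorm(length(ep$data))
  tt$rejected_heog[c(2, 9)] <- TRUE
  mtg <- montage()
  w <- contra_ipsi_waves(ep, tt, mtg, "fearful_dis")

  # oracle: loop trials, reassign sites by cue, average sides equally
  usable <- which(tt$condition == "fearful_dis" & !tt$rejected_heog &
                    !tt$rejected_amp)
  li <- match(mtg$left, ep$channel_names)
  ri <- match(mtg$right, ep$channel_names)
  acc <- function(trials, chans) {
    s <- 0
    for (tr in trials) for (ch in chans) s <- s + ep$data[tr, ch, ]
    s / (length(trials) * length(chans))
  }
  cl <- usable[tt$cue_side[usable] == "left"]
  cr <- usable[tt$cue_side[usable] == "right"]
  contra <- (acc(cl, ri) + acc(cr, li)) / 2
  ipsi <- (acc(cl, li) + acc(cr, ri)) / 2
  expect_lt(max(abs(w$contra - contra)), 1e-10)
  expect_lt(max(abs(w$ipsi - ipsi)), 1e-10)

  # shuffling the pair order leaves the output unchanged
  mtg2 <- montage(list(c("PO7", "PO8"), c("P7", "P8"), c("P9", "P10")))
  w2 <- contra_ipsi_waves(ep, tt, mtg2, "fearful_dis")
  expect_equal(w2$contra, w$contra, tolerance = 1e-12)
})

test_that("window means are inclusive-endpoint arithmetic means", {
  times <- seq(-200, 1100, by = 1)
  const <- rep(-0.42, length(times))
  expect_equal(window_mean(const, c(500, 1000), times), -0.42)

  # linear ramp 0 -> -1 across exactly the window averages to its midpoint
  ramp <- numeric(length(times))
  idx <- which(times >= 500 & times <= 1000)
  ramp[idx] <- seq(0, -1, length.out = length(idx))
  expect_equal(window_mean(ramp, c(500, 1000), times), -0.5)

  expect_error(window_mean(const, c(2000, 3000), times), "no samples")
})

test_that("difference scores subtract the non-distractor baseline", {
  expect_equal(cda_difference_score(-0.85, -0.42), -0.43)
  expect_equal(cda_difference_score(-0.71, -0.68), -0.03, tolerance = 1e-12)
  expect_equal(cda_difference_score(-0.5, -0.5), 0)
})

test_that("grand averages are linear in participants", {
  make_w <- function(amp) {
    times <- seq(-200, 1100, by = 1)
    structure(list(condition = "non_dis", times = times,
                   contra = rep(amp, length(times)),
                   ipsi = rep(0, length(times)),
                   diff = rep(amp, length(times)), n_trials_used = 10L),
              class = "lat_waves")
  }
  g1 <- grand_average(list(make_w(-0.2)))
  expect_equal(g1$diff, make_w(-0.2)$diff)
  g2 <- grand_average(list(make_w(-0.2), make_w(-0.6)))
  expect_equal(window_mean(g2, c(500, 1000)), -0.4)

  # window mean of the grand average equals the mean of window means
  set.seed(12)
  ws <- lapply(1:5, function(i) {
    w <- make_w(0)
    w$diff <- rnorm(length(w$times))
    w
  })
  ga <- grand_average(ws)
  expect_equal(window_mean(ga, c(500, 1000)),
               mean(vapply(ws, window_mean, 0, window = c(500, 1000))),
               tolerance = 1e-10)
})

test_that("null lateralization stays within sampling error", {
  # ground truth 0, amplitude-level noise: |estimate| < 3 * sd/sqrt(n)
  tt <- simulate_trial_table(task_config(n_trials_per_condition = 50,
                                         n_blocks = 1,
                                         conditions = "non_dis"), seed = 5)
  hits <- vapply(1:60, function(s) {
    eeg <- small_eeg(noise_sd = 0, amp_noise_sd = 2, seed = s)
    ep <- simulate_epochs(tt, c(non_dis = 0), eeg)
    w <- contra_ipsi_waves(ep, tt, montage(), "non_dis")
    abs(window_mean(w, c(500, 1000))) < 3 * 2 / sqrt(50)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
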