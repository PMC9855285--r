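# Small programmatic fixtures shared across test files.

analysis_channels <- c("P7", "P8", "P9", "P10", "PO7", "PO8", "HEOG")

# epoch_set filled with a constant (or supplied array), default geometry
make_flat_epochs <- function(n_trials = 2, channels = analysis_channels,
                             value = 0, epoch_window = c(-200, 1100),
                             sampling_rate = 1000) {
  n_sp <- diff(epoch_window) * sampling_rate / 1000 + 1
  epoch_set(array(value, c(n_trials, length(channels), n_sp)),
            channels, sampling_rate, epoch_window)
}

# compact EEG-sim config for fast tests
small_eeg <- function(...) {
  eeg_sim_config(channels = analysis_channels, ...)
}

# a tiny but complete study config (few trials, small cohort)
small_study <- function(master_seed = 7, ...) {
  study_config(
    n_per_group = 3,
    task = task_config(n_trials_per_condition = 8, n_blocks = 2,
                       vwm_task_trials = 40),
    eeg = small_eeg(noise_sd = 5),
    master_seed = master_seed, ...)
}

# explicit split-plot sums-of-squares decomposition: the independent oracle
# for the mixed ANOVA on balanced two-group designs
ss_oracle <- function(Y, group) {
  Y <- as.matrix(Y)
  n <- nrow(Y); cc <- ncol(Y)
  g <- factor(group)
  m <- n / nlevels(g)
  grand <- mean(Y)
  subj <- rowMeans(Y)
  cond <- colMeans(Y)
  grp <- tapply(subj, g, mean)
  cell <- apply(Y, 2, function(col) tapply(col, g, mean))
  ss_group <- cc * m * sum((grp - grand)^2)
  ss_subj <- cc * sum((subj - grp[g])^2)
  ss_cond <- n * sum((cond - grand)^2)
  ss_int <- m * sum(sweep(sweep(cell, 1, grp - grand), 2, cond)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_cond - ss_int
  list(
    F_group = (ss_group / (nlevels(g) - 1)) / (ss_subj / (n - nlevels(g))),
    F_cond = (ss_cond / (cc - 1)) / (ss_err / ((n - nlevels(g)) * (cc - 1))),
    F_int = (ss_int / ((cc - 1) * (nlevels(g) - 1))) /
      (ss_err / ((n - nlevels(g)) * (cc - 1))))
}
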