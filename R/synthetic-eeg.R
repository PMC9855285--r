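#' EEG simulation configuration
#'
#' Defaults reproduce the recording and epoching of the study: 1000 Hz
#' sampling, epochs from -200 to 1100 ms around memory-array onset, six
#' posterior analysis sites (P7/P8, P9/P10, PO7/PO8) plus a bipolar HEOG
#' channel and a few midline filler channels, and a sustained lateralized
#' component spanning 500-1000 ms.
#'
#' The lateralized component is a plateau covering the component window
#' plus `plateau_pad_ms` on each side, with raised-cosine onset/offset
#' ramps of `ramp_ms` outside the padded plateau. Because the plateau
#' covers the whole analysis window, the noise-free contra-minus-ipsi
#' window mean equals the injected amplitude exactly, and the padding keeps
#' the window mean essentially unchanged after low-pass filtering.
#'
#' @param sampling_rate Hz (default 1000).
#' @param epoch_window ms relative to stimulus onset (default -200..1100).
#' @param channels channel names; must contain all lateral sites and the
#'   HEOG channel.
#' @param lateral_sites list with `left` and `right` site name vectors,
#'   pairing by position.
#' @param heog_channel name of the bipolar HEOG channel.
#' @param noise_sd per-sample noise SD in uV (default 15).
#' @param noise_model `"white"` Gaussian per sample, or `"ar1"` with
#'   autoregression `ar_phi` (innovations scaled so the stationary SD is
#'   `noise_sd`).
#' @param ar_phi AR(1) coefficient (default 0.97).
#' @param heog_noise_sd per-sample SD of the HEOG channel (default 0; the
#'   simulated HEOG is flat except for injected saccades).
#' @param component_window ms window of the sustained component (default
#'   500..1000, the CDA measurement window).
#' @param plateau_pad_ms plateau extension beyond the component window on
#'   each side (default 50 ms).
#' @param ramp_ms raised-cosine ramp duration (default 50 ms).
#' @param amp_noise_sd SD (uV) of zero-mean trial-to-trial jitter of the
#'   lateralized component amplitude (default 0). Because the plateau
#'   covers the analysis window, this is noise at the window-mean level:
#'   the single-trial contra-minus-ipsi window mean is the ground-truth
#'   amplitude plus `N(0, amp_noise_sd)`.
#' @param bilateral_amp uV amplitude of a non-lateralized component with
#'   the same time course, added to all lateral sites (default 0).
#' @param saccade_rate per-trial probability of an injected HEOG saccade.
#' @param saccade_amp saccade step amplitude in uV (default 100).
#' @param blast_rate per-trial probability of a high-amplitude scalp
#'   artifact.
#' @param blast_amp artifact amplitude in uV (default 120).
#' @param seed integer seed for epoch synthesis.
#' @return An `eeg_sim_config` list.
#' @export
eeg_sim_config <- function(sampling_rate = 1000,
                           epoch_window = c(-200, 1100),
                           channels = c("P7", "P8", "P9", "P10", "PO7", "PO8",
                                        "Fz", "Cz", "Pz", "Oz", "HEOG"),
                           lateral_sites = list(left = c("P7", "P9", "PO7"),
                                                right = c("P8", "P10", "PO8")),
                           heog_channel = "HEOG",
                           noise_sd = 15, noise_model = c("white", "ar1"),
                           ar_phi = 0.97, heog_noise_sd = 0,
                           component_window = c(500, 1000),
                           plateau_pad_ms = 50, ramp_ms = 50,
                           amp_noise_sd = 0, bilateral_amp = 0,
                           saccade_rate = 0.05, saccade_amp = 100,
                           blast_rate = 0.02, blast_amp = 120,
                           seed = 1) {
  noise_model <- match.arg(noise_model)
  need <- c(lateral_sites$left, lateral_sites$right, heog_channel)
  missing <- setdiff(need, channels)
  if (length(missing) > 0L)
    stop("required channels missing from `channels`: ",
         paste(missing, collapse = ", "))
  if (length(lateral_sites$left) != length(lateral_sites$right))
    stop("left and right lateral site lists must pair by position")
  stopifnot(sampling_rate > 0, noise_sd >= 0,
            saccade_rate >= 0, saccade_rate <= 1,
            blast_rate >= 0, blast_rate <= 1)
  if (component_window[1L] < epoch_window[1L] ||
      component_window[2L] > epoch_window[2L])
    stop("component_window must lie inside epoch_window")
  structure(list(sampling_rate = sampling_rate, epoch_window = epoch_window,
                 channels = channels, lateral_sites = lateral_sites,
                 heog_channel = heog_channel, noise_sd = noise_sd,
                 noise_model = noise_model, ar_phi = ar_phi,
                 heog_noise_sd = heog_noise_sd,
                 component_window = component_window,
                 plateau_pad_ms = plateau_pad_ms, ramp_ms = ramp_ms,
                 amp_noise_sd = amp_noise_sd, bilateral_amp = bilateral_amp,
                 saccade_rate = saccade_rate, saccade_amp = saccade_amp,
                 blast_rate = blast_rate, blast_amp = blast_amp,
                 seed = seed),
            class = "eeg_sim_config")
}

#' Per-sample noise SD that yields a target window-mean noise SD
#'
#' With white per-sample noise of SD `sigma` on each of `n_pairs` site
#' pairs, the single-trial contra-minus-ipsi window mean over `n_samples`
#' samples has SD `sigma * sqrt(2 / (n_pairs * n_samples))`. This helper
#' inverts that relation, so simulations can be specified by the noise SD
#' at the level the component is actually measured.
#'
#' @param window_sd target SD of the single-trial difference window mean, uV.
#' @param n_pairs number of electrode pairs averaged (default 3).
#' @param window ms window (default 500..1000).
#' @param sampling_rate Hz (default 1000).
#' @return Per-sample noise SD in uV.
#' @export
per_sample_noise_sd <- function(window_sd, n_pairs = 3,
                                window = c(500, 1000), sampling_rate = 1000) {
  n_samples <- diff(window) * sampling_rate / 1000 + 1
  window_sd * sqrt(n_pairs * n_samples / 2)
}

## raised-cosine-edged plateau, 1 on [w1 - pad, w2 + pad]
component_shape <- function(times, window, pad, ramp) {
  lo <- window[1L] - pad
  hi <- window[2L] + pad
  s <- numeric(length(times))
  s[times >= lo & times <= hi] <- 1
  if (ramp > 0) {
    up <- times > lo - ramp & times < lo
    s[up] <- 0.5 * (1 - cos(pi * (times[up] - (lo - ramp)) / ramp))
    dn <- times > hi & times < hi + ramp
    s[dn] <- 0.5 * (1 + cos(pi * (times[dn] - hi) / ramp))
  }
  s
}

make_noise <- function(n, sd, model, phi) {
  if (sd == 0) return(numeric(n))
  eps <- stats::rnorm(n, 0, sd)
  if (model == "ar1") {
    # innovations scaled so the stationary SD equals `sd`
    innov <- eps * sqrt(1 - phi^2)
    eps <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  }
  eps
}

#' Synthesize epoched EEG with a known lateralized component
#'
#' For every trial, baseline noise receives a sustained deflection of the
#' participant's ground-truth amplitude for that trial's condition on the
#' lateral sites of the hemisphere contralateral to the cue; ipsilateral
#' sites carry only the shared (non-lateralized) activity. The noise-free
#' contra-minus-ipsi window mean therefore equals the ground-truth
#' amplitude exactly. The HEOG channel is flat (up to `heog_noise_sd`)
#' until saccades are injected by [inject_artifacts()].
#'
#' @param trial_table a trial table from [simulate_trial_table()].
#' @param participant one row of a cohort's `participants` data.frame, or a
#'   named numeric vector of per-condition amplitudes (uV).
#' @param eeg an [eeg_sim_config()]; its `seed` drives the noise.
#' @return An [epoch_set()] with one epoch per trial, in table order.
#' @export
simulate_epochs <- function(trial_table, participant, eeg = eeg_sim_config()) {
  stopifnot(inherits(eeg, "eeg_sim_config"))
  amps <- if (is.numeric(participant)) participant else participant_cda(participant)
  conds <- unique(trial_table$condition)
  if (!all(conds %in% names(amps)))
    stop("no ground-truth amplitude for condition(s): ",
         paste(setdiff(conds, names(amps)), collapse = ", "))
  n_tr <- nrow(trial_table)
  n_ch <- length(eeg$channels)
  step <- 1000 / eeg$sampling_rate
  times <- seq(eeg$epoch_window[1L], eeg$epoch_window[2L], by = step)
  n_sp <- length(times)

  set.seed(eeg$seed)
  x <- array(make_noise(n_tr * n_ch * n_sp, eeg$noise_sd,
                        eeg$noise_model, eeg$ar_phi),
             dim = c(n_tr, n_ch, n_sp))
  heog_i <- match(eeg$heog_channel, eeg$channels)
  x[, heog_i, ] <- if (eeg$heog_noise_sd > 0)
    matrix(stats::rnorm(n_tr * n_sp, 0, eeg$heog_noise_sd), n_tr, n_sp)
  else 0

  shape <- component_shape(times, eeg$component_window,
                           eeg$plateau_pad_ms, eeg$ramp_ms)
  amp_tr <- as.numeric(amps[trial_table$condition])
  if (eeg$amp_noise_sd > 0)
    amp_tr <- amp_tr + stats::rnorm(n_tr, 0, eeg$amp_noise_sd)
  contrib <- outer(amp_tr, shape)                    # trials x samples
  left_i <- match(eeg$lateral_sites$left, eeg$channels)
  right_i <- match(eeg$lateral_sites$right, eeg$channels)
  cue_left <- trial_table$cue_side == "left"
  for (ch in right_i)   # contralateral to a left cue
    x[cue_left, ch, ] <- x[cue_left, ch, ] + contrib[cue_left, , drop = FALSE]
  for (ch in left_i)    # contralateral to a right cue
    x[!cue_left, ch, ] <- x[!cue_left, ch, ] + contrib[!cue_left, , drop = FALSE]
  if (eeg$bilateral_amp != 0) {
    bi <- matrix(eeg$bilateral_amp * shape, n_tr, n_sp, byrow = TRUE)
    for (ch in c(left_i, right_i))
      x[, ch, ] <- x[, ch, ] + bi
  }
  epoch_set(x, eeg$channels, eeg$sampling_rate, eeg$epoch_window)
}

#' Inject HEOG saccades and high-amplitude artifacts
#'
#' Randomly selected trials receive a step excursion on the HEOG channel
#' (saccade, amplitude `saccade_amp`, signed toward the cued side) and/or a
#' 100-ms square pulse of `blast_amp` uV on one random scalp channel. The
#' ground-truth flags are returned alongside the data so rejection
#' operators can be tested against a known answer.
#'
#' @param epochs an [epoch_set()].
#' @param eeg the [eeg_sim_config()] used to build the epochs (rates and
#'   amplitudes are taken from it).
#' @param seed integer seed for artifact placement.
#' @param trial_table optional trial table supplying cue sides for saccade
#'   polarity; without it polarity is random.
#' @return List with `epochs` (modified copy) and `flags`, a data.frame
#'   with columns `trial`, `saccade`, `blast`.
#' @export
inject_artifacts <- function(epochs, eeg, seed = 1, trial_table = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(eeg, "eeg_sim_config"))
  n_tr <- n_trials(epochs)
  n_sp <- length(epochs$times)
  set.seed(seed)
  saccade <- stats::runif(n_tr) < eeg$saccade_rate
  blast <- stats::runif(n_tr) < eeg$blast_rate
  heog_i <- channel_index(epochs, eeg$heog_channel)
  scalp <- setdiff(epochs$channel_names, eeg$heog_channel)
  onset0 <- epochs$time_zero_index
  for (tr in which(saccade)) {
    at <- sample(onset0:(n_sp - 50L), 1L)
    sign <- if (!is.null(trial_table))
      ifelse(trial_table$cue_side[tr] == "left", -1, 1)
    else sample(c(-1, 1), 1L)
    epochs$data[tr, heog_i, at:n_sp] <-
      epochs$data[tr, heog_i, at:n_sp] + sign * eeg$saccade_amp
  }
  pulse_len <- max(1L, as.integer(round(100 * epochs$sampling_rate / 1000)))
  for (tr in which(blast)) {
    ch <- channel_index(epochs, sample(scalp, 1L))
    at <- sample(seq_len(n_sp - pulse_len), 1L)
    sgn <- sample(c(-1, 1), 1L)
    idx <- at:(at + pulse_len - 1L)
    epochs$data[tr, ch, idx] <- epochs$data[tr, ch, idx] + sgn * eeg$blast_amp
  }
  list(epochs = epochs,
       flags = data.frame(trial = seq_len(n_tr), saccade = saccade,
                          blast = blast))
}
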