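#' Preprocessing configuration
#'
#' @param bad_channels channels to interpolate from neighbors.
#' @param lowpass_hz low-pass cutoff in Hz (default 17, the passband edge).
#' @param transition_hz transition-band width (default 8, i.e. 17 -> 25 Hz).
#' @param epoch_window epoch limits in ms (default -200..1100).
#' @param baseline_window baseline interval in ms (default -200..0).
#' @param eog_channels channels excluded from the average reference and the
#'   low-pass filter (default `"HEOG"`).
#' @return A `preproc_config` list.
#' @export
preproc_config <- function(bad_channels = character(), lowpass_hz = 17,
                           transition_hz = 8,
                           epoch_window = c(-200, 1100),
                           baseline_window = c(-200, 0),
                           eog_channels = "HEOG") {
  if (baseline_window[1L] < epoch_window[1L] ||
      baseline_window[2L] > epoch_window[2L])
    stop("baseline_window must lie inside epoch_window")
  structure(list(bad_channels = bad_channels, lowpass_hz = lowpass_hz,
                 transition_hz = transition_hz, epoch_window = epoch_window,
                 baseline_window = baseline_window,
                 eog_channels = eog_channels),
            class = "preproc_config")
}

#' Interpolate bad channels from their neighbors
#'
#' Each bad channel is replaced, at every trial and sample, by the
#' unweighted mean of its good neighbors as given by the adjacency map.
#' All other channels are untouched.
#'
#' @param epochs an [epoch_set()].
#' @param bad character vector of bad channel names.
#' @param neighbor_map named list: channel name -> character vector of
#'   neighboring channel names.
#' @return The interpolated `epoch_set`.
#' @export
interpolate_bad_channels <- function(epochs, bad, neighbor_map) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(bad) == 0L) return(epochs)
  channel_index(epochs, bad)  # errors on unknown names
  for (ch in bad) {
    nb <- neighbor_map[[ch]]
    if (is.null(nb)) stop("no neighbor entry for bad channel ", ch)
    good <- setdiff(nb, bad)
    if (length(good) == 0L)
      stop("all neighbors of channel ", ch, " are bad; cannot interpolate")
    gi <- channel_index(epochs, good)
    acc <- 0
    for (g in gi) acc <- acc + epochs$data[, g, ]
    epochs$data[, channel_index(epochs, ch), ] <- acc / length(gi)
  }
  epochs
}

#' Re-reference to the average of the scalp channels
#'
#' At every trial and sample, the mean over the included channels is
#' subtracted from each included channel, so the included-channel mean is
#' zero afterwards. Excluded channels (e.g. the bipolar HEOG) are left
#' untouched and do not enter the average.
#'
#' @param epochs an [epoch_set()].
#' @param exclude channel names kept out of the average (default `"HEOG"`).
#' @return The re-referenced `epoch_set`.
#' @export
rereference_average <- function(epochs, exclude = "HEOG") {
  stopifnot(inherits(epochs, "epoch_set"))
  inc <- setdiff(epochs$channel_names, exclude)
  if (length(inc) < 2L)
    stop("average reference needs at least 2 included channels")
  ii <- channel_index(epochs, inc)
  m <- 0
  for (ch in ii) m <- m + epochs$data[, ch, ]
  m <- m / length(ii)
  for (ch in ii) epochs$data[, ch, ] <- epochs$data[, ch, ] - m
  epochs
}

#' Design the zero-phase low-pass filter
#'
#' Linear-phase FIR (Hamming window) with passband edge `cutoff` and a
#' transition band of `transition` Hz; applied non-causally (group delay
#' compensated) the response is zero-phase with DC gain exactly 1. The
#' order follows the Hamming-window rule of thumb (about 3.3 / normalized
#' transition width).
#'
#' @param cutoff passband edge, Hz.
#' @param sampling_rate Hz.
#' @param transition transition-band width, Hz (default 8).
#' @return Numeric vector of filter coefficients (odd length).
#' @keywords internal
design_lowpass_fir <- function(cutoff, sampling_rate, transition = 8) {
  if (cutoff >= sampling_rate / 2)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 cutoff, sampling_rate / 2))
  order <- ceiling(3.3 * sampling_rate / transition)
  if (order %% 2L == 1L) order <- order + 1L   # even order -> odd length
  wc <- (cutoff + transition / 2) / (sampling_rate / 2)
  h <- as.numeric(signal::fir1(order, wc, type = "low"))
  h / sum(h)   # DC gain exactly 1
}

## zero-phase FIR along the rows of x, FFT convolution, mirror padding
filter_rows <- function(x, h) {
  n <- ncol(x)
  taps <- length(h)
  pad <- min(n - 1L, taps)
  delay <- (taps - 1L) %/% 2L
  left <- x[, pad:1L, drop = FALSE]
  right <- x[, n:(n - pad + 1L), drop = FALSE]
  xp <- cbind(left, x, right)
  m <- ncol(xp) + taps - 1L
  nfft <- stats::nextn(m, c(2, 3, 5))
  H <- stats::fft(c(h, numeric(nfft - taps)))
  X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(x), nfft - ncol(xp)))))
  Y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  t(Y)[, (pad + delay + 1L):(pad + delay + n), drop = FALSE]
}

#' Zero-phase low-pass filter
#'
#' Filters every trial and channel along time with the symmetric FIR from
#' [design_lowpass_fir()], compensating the group delay so the response is
#' zero-phase. Edges are mirror-padded. A constant signal passes unchanged
#' (DC gain 1); at twice the cutoff the attenuation exceeds 20 dB.
#'
#' @param epochs an [epoch_set()], or a channels x samples matrix.
#' @param cutoff passband edge, Hz (default 17).
#' @param transition transition-band width, Hz (default 8).
#' @param exclude channel names left unfiltered (e.g. HEOG).
#' @param sampling_rate required when `epochs` is a bare matrix.
#' @return Object of the same shape as the input.
#' @export
lowpass_filter <- function(epochs, cutoff = 17, transition = 8,
                           exclude = character(), sampling_rate = NULL) {
  if (inherits(epochs, "epoch_set")) {
    h <- design_lowpass_fir(cutoff, epochs$sampling_rate, transition)
    d <- dim(epochs$data)
    keep <- setdiff(epochs$channel_names, exclude)
    ki <- channel_index(epochs, keep)
    flat <- matrix(aperm(epochs$data[, ki, , drop = FALSE], c(3L, 1L, 2L)),
                   nrow = d[3L])          # samples x (trials*channels)
    out <- t(filter_rows(t(flat), h))
    epochs$data[, ki, ] <- aperm(array(out, c(d[3L], d[1L], length(ki))),
                                 c(2L, 3L, 1L))
    epochs
  } else {
    if (is.null(sampling_rate))
      stop("sampling_rate is required when filtering a bare matrix")
    h <- design_lowpass_fir(cutoff, sampling_rate, transition)
    keep_mat <- filter_rows(as.matrix(epochs), h)
    dimnames(keep_mat) <- dimnames(epochs)
    keep_mat
  }
}

#' Subtract the pre-stimulus baseline
#'
#' Shifts every trial and channel so its mean over the baseline window is
#' exactly zero. Idempotent.
#'
#' @param epochs an [epoch_set()].
#' @param baseline_window ms interval (default -200..0).
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline_window = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- time_window_indices(epochs, baseline_window)
  b <- rowSums(epochs$data[, , idx, drop = FALSE], dims = 2L) / length(idx)
  epochs$data <- epochs$data - as.numeric(b)   # recycles trials x channels
  epochs
}

#' Cut epochs from a continuous recording and baseline-correct them
#'
#' Markers whose full epoch window does not fit inside the recording are
#' dropped with a warning stating the count.
#'
#' @param data channels x samples matrix, uV (e.g. from
#'   [read_brainvision()]).
#' @param markers marker positions in samples (1-based, time zero of each
#'   epoch), or a marker data.frame with a `position` column.
#' @param sampling_rate Hz.
#' @param epoch_window ms (default -200..1100).
#' @param baseline_window ms (default -200..0).
#' @param channel_names defaults to `rownames(data)`.
#' @return An [epoch_set()], baseline corrected.
#' @export
epoch_and_baseline <- function(data, markers, sampling_rate,
                               epoch_window = c(-200, 1100),
                               baseline_window = c(-200, 0),
                               channel_names = rownames(data)) {
  if (is.data.frame(markers)) markers <- markers$position
  data <- as.matrix(data)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  step <- 1000 / sampling_rate
  rel <- round(seq(epoch_window[1L], epoch_window[2L], by = step) / step)
  ok <- markers + rel[1L] >= 1L & markers + rel[length(rel)] <= ncol(data)
  if (any(!ok))
    warning(sum(!ok), " marker(s) too close to the recording edge; ",
            "their epochs were dropped")
  markers <- markers[ok]
  x <- array(0, dim = c(length(markers), nrow(data), length(rel)))
  for (i in seq_along(markers))
    x[i, , ] <- data[, markers[i] + rel, drop = FALSE]
  epochs <- epoch_set(x, channel_names, sampling_rate, epoch_window)
  baseline_correct(epochs, baseline_window)
}

#' Run the full preprocessing chain on epoched data
#'
#' Applies, in order: bad-channel interpolation, average reference
#' (EOG excluded), zero-phase low-pass filtering (EOG excluded), and
#' baseline correction.
#'
#' @param epochs an [epoch_set()].
#' @param config a [preproc_config()].
#' @param neighbor_map adjacency map for interpolation (required if
#'   `config$bad_channels` is non-empty).
#' @return The preprocessed `epoch_set`.
#' @export
preprocess_epochs <- function(epochs, config = preproc_config(),
                              neighbor_map = NULL) {
  stopifnot(inherits(config, "preproc_config"))
  epochs <- interpolate_bad_channels(epochs, config$bad_channels, neighbor_map)
  epochs <- rereference_average(epochs, exclude = config$eog_channels)
  epochs <- lowpass_filter(epochs, config$lowpass_hz, config$transition_hz,
                           exclude = config$eog_channels)
  baseline_correct(epochs, config$baseline_window)
}

#' Run the full preprocessing chain on a continuous recording
#'
#' Same stage order as the epoched path, with epoching between filtering
#' and baseline correction: interpolation -> average reference -> low-pass
#' -> epoching -> baseline.
#'
#' @param data channels x samples matrix, uV.
#' @param markers marker positions (see [epoch_and_baseline()]).
#' @param sampling_rate Hz.
#' @param config a [preproc_config()].
#' @param neighbor_map adjacency map for interpolation.
#' @return A preprocessed [epoch_set()].
#' @export
preprocess_continuous <- function(data, markers, sampling_rate,
                                  config = preproc_config(),
                                  neighbor_map = NULL) {
  stopifnot(inherits(config, "preproc_config"))
  data <- as.matrix(data)
  cn <- rownames(data)
  if (is.null(cn)) cn <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- cn
  # interpolation on the continuous record
  if (length(config$bad_channels) > 0L) {
    tmp <- epoch_set(array(data, c(1L, nrow(data), ncol(data))), cn,
                     sampling_rate, c(0, (ncol(data) - 1L) * 1000 / sampling_rate))
    tmp <- interpolate_bad_channels(tmp, config$bad_channels, neighbor_map)
    data <- tmp$data[1L, , ]
    rownames(data) <- cn
  }
  inc <- setdiff(cn, config$eog_channels)
  if (length(inc) < 2L) stop("average reference needs at least 2 channels")
  avg <- colMeans(data[inc, , drop = FALSE])
  data[inc, ] <- sweep(data[inc, , drop = FALSE], 2L, avg)
  data[inc, ] <- lowpass_filter(data[inc, , drop = FALSE],
                                config$lowpass_hz, config$transition_hz,
                                sampling_rate = sampling_rate)
  epoch_and_baseline(data, markers, sampling_rate, config$epoch_window,
                     config$baseline_window, cn)
}
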