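#' Conditions of the face-filtering change-detection task
#'
#' The task presents bilateral colored-square targets with, depending on
#' condition, no face distractors (`non_dis`), fearful face distractors
#' (`fearful_dis`), or sad face distractors (`sad_dis`).
#'
#' @format Character vector of the three condition labels.
#' @export
cda_conditions <- c("non_dis", "fearful_dis", "sad_dis")

#' Construct an epoched EEG container
#'
#' An `epoch_set` holds single-participant epoched EEG as a 3-d array of
#' trials x channels x samples, in microvolts, together with the channel
#' names, sampling rate and epoch window. The time axis is inclusive on both
#' ends: a window of -200..1100 ms at 1000 Hz has 1301 samples, with time
#' zero (memory-array onset) on the grid.
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`, in uV.
#' @param channel_names character vector, one unique name per channel.
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_window length-2 numeric, epoch start and end in ms relative
#'   to stimulus onset (both endpoints on the sampling grid).
#' @return An object of class `epoch_set` with elements `data`,
#'   `channel_names`, `sampling_rate`, `epoch_window`, `times` (ms, one per
#'   sample) and `time_zero_index`.
#' @export
epoch_set <- function(data, channel_names, sampling_rate, epoch_window) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trials, channels, samples]")
  if (length(channel_names) != dim(data)[2L])
    stop("length(channel_names) must match dim(data)[2]")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (length(epoch_window) != 2L || epoch_window[1L] >= epoch_window[2L])
    stop("epoch_window must be c(start_ms, end_ms) with start < end")
  step <- 1000 / sampling_rate
  times <- seq(epoch_window[1L], epoch_window[2L], by = step)
  if (length(times) != dim(data)[3L])
    stop(sprintf(
      "epoch_window %g..%g ms at %g Hz implies %d samples, data has %d",
      epoch_window[1L], epoch_window[2L], sampling_rate,
      length(times), dim(data)[3L]))
  structure(
    list(data = data,
         channel_names = as.character(channel_names),
         sampling_rate = sampling_rate,
         epoch_window = as.numeric(epoch_window),
         times = times,
         time_zero_index = which.min(abs(times))),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz, %g..%g ms\n",
    d[1L], d[2L], d[3L], x$sampling_rate,
    x$epoch_window[1L], x$epoch_window[2L]))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials <- function(epochs) dim(epochs$data)[1L]

#' Indices of the samples falling inside a time window
#'
#' Both window endpoints are inclusive on the sampling grid.
#'
#' @param epochs an `epoch_set` (or a numeric time axis in ms).
#' @param window length-2 numeric window in ms, `start <= end`.
#' @return Integer vector of sample indices.
#' @export
time_window_indices <- function(epochs, window) {
  times <- if (inherits(epochs, "epoch_set")) epochs$times else epochs
  if (length(window) != 2L || window[1L] > window[2L])
    stop("window must be c(start_ms, end_ms) with start <= end")
  idx <- which(times >= window[1L] - 1e-9 & times <= window[2L] + 1e-9)
  if (length(idx) == 0L)
    stop(sprintf("window %g..%g ms contains no samples of the time axis",
                 window[1L], window[2L]))
  idx
}

channel_index <- function(epochs, names) {
  idx <- match(names, epochs$channel_names)
  if (anyNA(idx))
    stop("channel(s) not present: ",
         paste(names[is.na(idx)], collapse = ", "))
  idx
}

#' Select a subset of trials from an epoch_set
#'
#' @param epochs an `epoch_set`.
#' @param which integer or logical index over trials.
#' @return An `epoch_set` with the selected trials.
#' @export
subset_trials <- function(epochs, which) {
  stopifnot(inherits(epochs, "epoch_set"))
  epoch_set(epochs$data[which, , , drop = FALSE], epochs$channel_names,
            epochs$sampling_rate, epochs$epoch_window)
}
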