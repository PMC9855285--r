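#' Electrode-pair montage for lateralized analyses
#'
#' Defaults to the three posterior parietal pairs used for the CDA:
#' P7/P8, P9/P10 and PO7/PO8.
#'
#' @param pairs list of `c(left_site, right_site)` character pairs.
#' @return A `montage` object.
#' @export
montage <- function(pairs = list(c("P7", "P8"), c("P9", "P10"),
                                 c("PO7", "PO8"))) {
  sites <- unlist(pairs)
  if (anyDuplicated(sites)) stop("montage pairs must be disjoint")
  structure(list(pairs = pairs,
                 left = vapply(pairs, `[`, "", 1L),
                 right = vapply(pairs, `[`, "", 2L)),
            class = "montage")
}

#' Component measurement windows
#'
#' The CDA is measured as the mean difference-wave amplitude over
#' 500-1000 ms after memory-array onset. Earlier lateralized components can
#' be added as named extra windows; the N2pc (200-300 ms) and Ppc
#' (100-200 ms) defaults here are generic conventions, not authoritative
#' values, and should be configured for any serious use.
#'
#' @param cda ms interval of the CDA window.
#' @param ... further named ms intervals (e.g. `n2pc = c(200, 300)`).
#' @return Named list of windows; class `analysis_windows`.
#' @export
analysis_windows <- function(cda = c(500, 1000), ...) {
  w <- c(list(cda = cda), list(...))
  for (nm in names(w))
    if (length(w[[nm]]) != 2L || w[[nm]][1L] >= w[[nm]][2L])
      stop("window `", nm, "` must be c(start, end) with start < end")
  structure(w, class = "analysis_windows")
}

#' Contralateral and ipsilateral waveforms for one condition
#'
#' The contralateral waveform averages left-hemisphere sites on cue-right
#' trials with right-hemisphere sites on cue-left trials; the ipsilateral
#' waveform uses the complementary assignment. Averaging proceeds trials
#' within each cue side first, then sites, then the two cue sides with
#' equal weight, so unequal surviving-trial counts across cue sides cannot
#' bias the contra/ipsi comparison asymmetrically. Trials flagged
#' `rejected_heog` or `rejected_amp` are excluded.
#'
#' @param epochs an [epoch_set()], trials in table order.
#' @param trial_table the matching trial table.
#' @param mtg a [montage()].
#' @param condition condition label to analyze.
#' @return A `lat_waves` list: `condition`, `times`, `contra`, `ipsi`,
#'   `diff` (uV series), and `n_trials_used`.
#' @export
contra_ipsi_waves <- function(epochs, trial_table, mtg = montage(),
                              condition) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(mtg, "montage"),
            nrow(trial_table) == n_trials(epochs))
  li <- channel_index(epochs, mtg$left)
  ri <- channel_index(epochs, mtg$right)
  usable <- trial_table$condition == condition &
    !trial_table$rejected_heog & !trial_table$rejected_amp
  side_mean <- function(trials, chans) {
    # mean over trials, then over sites
    acc <- 0
    for (ch in chans) {
      x <- epochs$data[trials, ch, , drop = FALSE]
      acc <- acc + colMeans(matrix(x, nrow = sum(trials)))
    }
    acc / length(chans)
  }
  for (side in c("left", "right")) {
    if (!any(usable & trial_table$cue_side == side))
      stop(sprintf("no usable trials for condition %s, cue side %s",
                   condition, side))
  }
  cue_l <- usable & trial_table$cue_side == "left"
  cue_r <- usable & trial_table$cue_side == "right"
  contra <- (side_mean(cue_l, ri) + side_mean(cue_r, li)) / 2
  ipsi <- (side_mean(cue_l, li) + side_mean(cue_r, ri)) / 2
  structure(list(condition = condition, times = epochs$times,
                 contra = contra, ipsi = ipsi, diff = contra - ipsi,
                 n_trials_used = sum(usable)),
            class = "lat_waves")
}

#' Mean amplitude over a measurement window
#'
#' Arithmetic mean of the samples with time in `[start, end]`, both
#' endpoints inclusive on the sampling grid.
#'
#' @param wave numeric uV series (e.g. a difference wave), or a
#'   `lat_waves` object (its `diff` series is used).
#' @param window length-2 ms interval.
#' @param times time axis in ms; taken from a `lat_waves` input.
#' @return Mean amplitude in uV.
#' @export
window_mean <- function(wave, window, times = NULL) {
  if (inherits(wave, "lat_waves")) {
    times <- wave$times
    wave <- wave$diff
  }
  if (is.null(times)) stop("`times` is required for a bare numeric wave")
  mean(wave[time_window_indices(times, window)])
}

#' CDA difference score
#'
#' Distractor-condition amplitude minus non-distractor (baseline)
#' amplitude. A negative score indicates a larger (more negative) CDA under
#' distractors, i.e. unnecessary storage of the distractors (filtering
#' difficulty).
#'
#' @param distractor_amp uV amplitude in the distractor condition.
#' @param baseline_amp uV amplitude in the non-distractor condition.
#' @return Difference score in uV.
#' @export
cda_difference_score <- function(distractor_amp, baseline_amp) {
  distractor_amp - baseline_amp
}

#' Window-mean amplitudes for every condition
#'
#' @param epochs an [epoch_set()].
#' @param trial_table the matching trial table (flags applied).
#' @param mtg a [montage()].
#' @param windows an [analysis_windows()].
#' @param conditions conditions to measure (default: all in the table).
#' @return Data.frame with one row per condition: the window-mean amplitude
#'   per component window and `n_trials_used`. The waveforms are attached
#'   as attribute `"waves"` (a named list of `lat_waves`).
#' @export
measure_lateralized <- function(epochs, trial_table, mtg = montage(),
                                windows = analysis_windows(),
                                conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(trial_table$condition)
  waves <- lapply(conditions, function(cond)
    contra_ipsi_waves(epochs, trial_table, mtg, cond))
  names(waves) <- conditions
  out <- data.frame(condition = conditions, stringsAsFactors = FALSE)
  for (nm in names(windows))
    out[[nm]] <- vapply(waves, window_mean, 0, window = windows[[nm]])
  out$n_trials_used <- vapply(waves, function(w) w$n_trials_used, 0L)
  attr(out, "waves") <- waves
  out
}

#' Grand average of per-participant lateralized measures
#'
#' Unweighted mean across participants of the contra/ipsi/difference
#' waveforms; because averaging is linear, the window mean of the grand
#' average equals the mean of the per-participant window means.
#'
#' @param waves_list list of `lat_waves`, one per participant, same
#'   condition and time axis.
#' @return A `lat_waves` object with the grand-average waveforms.
#' @export
grand_average <- function(waves_list) {
  stopifnot(length(waves_list) >= 1L)
  first <- waves_list[[1L]]
  avg <- function(field)
    Reduce(`+`, lapply(waves_list, `[[`, field)) / length(waves_list)
  structure(list(condition = first$condition, times = first$times,
                 contra = avg("contra"), ipsi = avg("ipsi"),
                 diff = avg("diff"),
                 n_trials_used = sum(vapply(waves_list,
                                            function(w) w$n_trials_used, 0L))),
            class = "lat_waves")
}

#' Export waveforms as a TSV for plotting
#'
#' @param waves a `lat_waves` object.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_waveforms <- function(waves, path) {
  utils::write.table(
    data.frame(time_ms = waves$times, contra = waves$contra,
               ipsi = waves$ipsi, diff = waves$diff),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
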