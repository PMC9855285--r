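#' Trial-rejection and participant-exclusion policy
#'
#' Defaults follow the study thresholds: trials with HEOG excursions beyond
#' +/-60 uV (lateral eye movements) or any scalp sample beyond +/-80 uV are
#' rejected; participants with more than 30% of trials rejected are
#' excluded. Thresholds are read as strict inequalities on the epoch
#' extremum (`mode = "peak"`); a peak-to-peak criterion is available as an
#' option.
#'
#' @param heog_threshold uV (default 60).
#' @param amp_threshold uV (default 80).
#' @param participant_max_rejection proportion above which a participant is
#'   excluded (default 0.30, strict).
#' @param heog_channel HEOG channel name.
#' @param scalp_channels scalp channels checked by the amplitude rule;
#'   `NULL` means every channel except `heog_channel`.
#' @param mode `"peak"` (|x| > threshold at any sample) or `"peak_to_peak"`
#'   (max - min > 2 * threshold).
#' @return A `rejection_policy` list.
#' @export
rejection_policy <- function(heog_threshold = 60, amp_threshold = 80,
                             participant_max_rejection = 0.30,
                             heog_channel = "HEOG", scalp_channels = NULL,
                             mode = c("peak", "peak_to_peak")) {
  mode <- match.arg(mode)
  stopifnot(heog_threshold > 0, amp_threshold > 0,
            participant_max_rejection > 0, participant_max_rejection <= 1)
  structure(list(heog_threshold = heog_threshold,
                 amp_threshold = amp_threshold,
                 participant_max_rejection = participant_max_rejection,
                 heog_channel = heog_channel,
                 scalp_channels = scalp_channels, mode = mode),
            class = "rejection_policy")
}

trial_extremum <- function(x, mode) {
  # x: trials x channels x samples; returns per-trial max statistic
  d <- dim(x)
  flat <- matrix(x, nrow = d[1L])
  if (mode == "peak") {
    apply(abs(flat), 1L, max)
  } else {
    apply(flat, 1L, max) - apply(flat, 1L, min)
  }
}

#' Flag trials with horizontal eye movements
#'
#' A trial is flagged iff the absolute HEOG amplitude exceeds the threshold
#' (strictly) at any sample of the epoch, baseline included.
#'
#' @param epochs an [epoch_set()].
#' @param policy a [rejection_policy()].
#' @return Logical vector, one flag per trial.
#' @export
flag_heog <- function(epochs, policy = rejection_policy()) {
  stopifnot(inherits(epochs, "epoch_set"))
  hi <- channel_index(epochs, policy$heog_channel)
  stat <- trial_extremum(epochs$data[, hi, , drop = FALSE], policy$mode)
  thr <- if (policy$mode == "peak") policy$heog_threshold else
    2 * policy$heog_threshold
  stat > thr
}

#' Flag trials with high-amplitude scalp artifacts
#'
#' A trial is flagged iff any scalp channel exceeds the amplitude threshold
#' (strictly) at any sample. Flags are computed for all trials,
#' independently of the HEOG rule.
#'
#' @param epochs an [epoch_set()].
#' @param policy a [rejection_policy()].
#' @return Logical vector, one flag per trial.
#' @export
flag_amplitude <- function(epochs, policy = rejection_policy()) {
  stopifnot(inherits(epochs, "epoch_set"))
  scalp <- policy$scalp_channels
  if (is.null(scalp))
    scalp <- setdiff(epochs$channel_names, policy$heog_channel)
  if (length(scalp) == 0L) stop("no scalp channels to check")
  si <- channel_index(epochs, scalp)
  stat <- trial_extremum(epochs$data[, si, , drop = FALSE], policy$mode)
  thr <- if (policy$mode == "peak") policy$amp_threshold else
    2 * policy$amp_threshold
  stat > thr
}

#' Apply both rejection rules to a trial table
#'
#' Populates `rejected_heog` and `rejected_amp`; a trial rejected by either
#' rule is removed from ERP averaging downstream.
#'
#' @param epochs an [epoch_set()], trials in table order.
#' @param trial_table the matching trial table.
#' @param policy a [rejection_policy()].
#' @return The trial table with both flag columns set.
#' @export
apply_rejection <- function(epochs, trial_table,
                            policy = rejection_policy()) {
  stopifnot(nrow(trial_table) == n_trials(epochs))
  trial_table$rejected_heog <- flag_heog(epochs, policy)
  trial_table$rejected_amp <- flag_amplitude(epochs, policy)
  trial_table
}

#' Exclude participants by trial rejection rate
#'
#' A participant is excluded iff their rejection rate is strictly higher
#' than the policy maximum (default 30%); a rate of exactly 30% is
#' retained.
#'
#' @param rejection_rates named numeric vector of per-participant
#'   proportions in `[0, 1]`.
#' @param policy a [rejection_policy()].
#' @return List with `included` and `excluded` name vectors.
#' @export
exclude_participants <- function(rejection_rates,
                                 policy = rejection_policy()) {
  stopifnot(all(rejection_rates >= 0), all(rejection_rates <= 1))
  ids <- names(rejection_rates)
  if (is.null(ids)) ids <- as.character(seq_along(rejection_rates))
  out <- rejection_rates > policy$participant_max_rejection
  list(included = ids[!out], excluded = ids[out])
}

#' Rejection rates by condition and cue side
#'
#' HEOG-rule rejection rates per condition x cue-side cell, the quantity
#' analyzed by the rejection-rate ANOVA.
#'
#' @param trial_table trial table with populated `rejected_heog` flags.
#' @param rule which flag column to tabulate (default `"rejected_heog"`).
#' @return Data.frame with `condition`, `cue_side`, `n_trials`,
#'   `n_rejected`, `rate` (NA for empty cells).
#' @export
rejection_rate_table <- function(trial_table, rule = "rejected_heog") {
  stopifnot(rule %in% names(trial_table))
  cells <- expand.grid(condition = unique(trial_table$condition),
                       cue_side = c("left", "right"),
                       stringsAsFactors = FALSE)
  cells$n_trials <- NA_integer_
  cells$n_rejected <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    sel <- trial_table$condition == cells$condition[i] &
      trial_table$cue_side == cells$cue_side[i]
    cells$n_trials[i] <- sum(sel)
    cells$n_rejected[i] <- sum(trial_table[[rule]][sel])
  }
  cells$rate <- ifelse(cells$n_trials > 0, cells$n_rejected / cells$n_trials,
                       NA_real_)
  cells
}
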