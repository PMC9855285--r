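#' Accuracy by condition
#'
#' Proportion of correct responses per condition over all responded trials
#' (behavioral analyses do not exclude EEG-rejected trials).
#'
#' @param trial_table trial table with `correct` filled in.
#' @return Named numeric vector, one proportion per condition, in the order
#'   the conditions first appear.
#' @export
accuracy_by_condition <- function(trial_table) {
  resp <- trial_table[!is.na(trial_table$correct), , drop = FALSE]
  if (nrow(resp) == 0L) stop("no responded trials")
  conds <- unique(trial_table$condition)
  vapply(conds, function(cond)
    mean(resp$correct[resp$condition == cond]), 0)
}

#' Hit and false-alarm rates of a change-detection run
#'
#' @param trial_table trial table of the VWM measurement with
#'   `change_present` and `response_change`.
#' @return Named numeric vector `c(H = ..., F = ...)`: hit rate (proportion
#'   "change" responses on change trials) and false-alarm rate (proportion
#'   "change" responses on no-change trials).
#' @export
hit_false_alarm <- function(trial_table) {
  resp <- trial_table[!is.na(trial_table$response_change), , drop = FALSE]
  ch <- resp$change_present
  if (!any(ch) || all(ch))
    stop("both change and no-change trials are required")
  c(H = mean(resp$response_change[ch]),
    F = mean(resp$response_change[!ch]))
}

#' Cowan's K capacity estimate
#'
#' `K = N * (H - F)` for whole-display change detection at set size `N`.
#' No clamping is applied: a negative estimate is preserved.
#'
#' @param H hit rate in `[0, 1]`.
#' @param F false-alarm rate in `[0, 1]`.
#' @param N set size (default 6, the set size of the VWM measurement).
#' @return Capacity estimate in items.
#' @export
cowan_k <- function(H, F, N = 6) {
  stopifnot(H >= 0, H <= 1, F >= 0, F <= 1, N >= 1)
  N * (H - F)
}

#' Signal-detection sensitivity d-prime
#'
#' `d' = Z(H) - Z(F)` with `Z` the standard-normal quantile function.
#' Extreme rates (0 or 1) are undefined under `correction = "none"`; the
#' default correction replaces 0 by `1/(2n)` and 1 by `1 - 1/(2n)`, with
#' `n` the number of trials of that class.
#'
#' @param H hit rate.
#' @param F false-alarm rate.
#' @param correction `"adjust"` (default) or `"none"`.
#' @param n_change,n_nochange trial counts per class, required by the
#'   correction when a rate is extreme.
#' @return d-prime (unitless).
#' @export
dprime <- function(H, F, correction = c("adjust", "none"),
                   n_change = NULL, n_nochange = NULL) {
  correction <- match.arg(correction)
  stopifnot(H >= 0, H <= 1, F >= 0, F <= 1)
  fix <- function(p, n, what) {
    if (p > 0 && p < 1) return(p)
    if (correction == "none")
      stop("rate ", what, " = ", p, " gives an infinite d-prime; ",
           "use correction = \"adjust\"")
    if (is.null(n)) stop("trial count needed to correct an extreme ", what)
    min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  }
  H <- fix(H, n_change, "H")
  F <- fix(F, n_nochange, "F")
  stats::qnorm(H) - stats::qnorm(F)
}

#' Behavioral summary of one participant's VWM measurement
#'
#' @param trial_table VWM-measurement trial table with responses.
#' @param N set size (default 6).
#' @return One-row data.frame with `H`, `F`, `K`, `d_prime`, `accuracy`,
#'   `N`.
#' @export
behavioral_summary <- function(trial_table, N = 6) {
  hf <- hit_false_alarm(trial_table)
  resp <- trial_table[!is.na(trial_table$response_change), , drop = FALSE]
  data.frame(
    H = unname(hf["H"]), F = unname(hf["F"]),
    K = cowan_k(hf["H"], hf["F"], N),
    d_prime = dprime(hf["H"], hf["F"],
                     n_change = sum(resp$change_present),
                     n_nochange = sum(!resp$change_present)),
    accuracy = mean(resp$correct), N = N)
}
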