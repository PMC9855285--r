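#' Deterministic child seeds from a master seed
#'
#' Fans a master seed out to per-participant / per-stage child seeds so any
#' subset of a study can be regenerated in isolation. The scheme is a fixed
#' integer hash: starting from the master seed, each index folds in as
#' `h <- (h * 69069 + index + 1) mod (2^31 - 1)`; all arithmetic is exact in
#' doubles, and the result always fits a 32-bit integer.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer indices (participant number,
#'   stage number, ...), folded in order.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  h <- as.double(master) %% 2147483647
  for (x in c(...)) h <- (h * 69069 + as.double(x) + 1) %% 2147483647
  as.integer(h)
}

## truncated-normal sampling by rejection; exact under a fixed RNG state
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate distribution outside truncation range")
    return(rep(mean, n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Default per-group score and CDA distributions
#'
#' Questionnaire scores default to the group means and standard deviations
#' of the study sample (BDI-II 26.83 +/- 6.76 in the depressed group versus
#' 2.56 +/- 1.79 in controls; DASS-A 8 +/- 4.17 versus 1.83 +/- 2.77),
#' truncated to the group inclusion ranges (BDI-II >= 14 for the depressed
#' group, <= 9 for controls). Ground-truth CDA amplitudes default to the
#' group x condition mean amplitudes (uV), with a 0.5-uV between-participant
#' SD; true VWM capacity defaults to the group K means/SDs, truncated to
#' [0, 6].
#'
#' @return Named list with one parameter list per group (`depressed`,
#'   `control`).
#' @export
default_group_params <- function() {
  list(
    depressed = list(
      bdi_mean = 26.83, bdi_sd = 6.76, bdi_range = c(14, 63),
      dass_mean = 8, dass_sd = 4.17, dass_range = c(0, 42),
      k_mean = 2.42, k_sd = 0.688,
      cda_mean = c(non_dis = -0.68, fearful_dis = -0.71, sad_dis = -0.80),
      cda_sd = 0.5),
    control = list(
      bdi_mean = 2.56, bdi_sd = 1.79, bdi_range = c(0, 9),
      dass_mean = 1.83, dass_sd = 2.77, dass_range = c(0, 42),
      k_mean = 2.66, k_sd = 1.005,
      cda_mean = c(non_dis = -0.42, fearful_dis = -0.85, sad_dis = -0.67),
      cda_sd = 0.5)
  )
}

#' Generate a synthetic two-group cohort
#'
#' Samples per-participant questionnaire scores (BDI-II, DASS-A), true VWM
#' capacity, and ground-truth CDA amplitudes per condition from the
#' group-level distributions, truncating scores to each group's inclusion
#' range.
#'
#' @param n_per_group participants per group (default 18).
#' @param group_params per-group distributions, see [default_group_params()].
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @return A `cohort` object: list with `participants` (a data.frame with
#'   columns `id`, `group`, `bdi`, `dass_a`, `true_k`, and one
#'   `cda_<condition>` column per condition) and `seed`.
#' @export
make_cohort <- function(n_per_group = 18, group_params = default_group_params(),
                        seed = 1) {
  stopifnot(n_per_group >= 1)
  groups <- names(group_params)
  if (length(groups) != 2L) stop("group_params must describe two groups")
  r1 <- group_params[[1L]]$bdi_range
  r2 <- group_params[[2L]]$bdi_range
  if (max(r1[1L], r2[1L]) <= min(r1[2L], r2[2L]))
    stop("BDI inclusion ranges of the two groups overlap; ",
         "groups would not be separable")
  set.seed(seed)
  rows <- lapply(groups, function(g) {
    p <- group_params[[g]]
    if (is.null(names(p$cda_mean))) names(p$cda_mean) <- cda_conditions
    cda <- vapply(names(p$cda_mean), function(cond)
      stats::rnorm(n_per_group, p$cda_mean[[cond]], p$cda_sd),
      numeric(n_per_group))
    if (n_per_group == 1L) cda <- matrix(cda, nrow = 1L,
                                         dimnames = list(NULL, names(p$cda_mean)))
    df <- data.frame(
      id = sprintf("%s_%02d", g, seq_len(n_per_group)),
      group = g,
      bdi = rtruncnorm(n_per_group, p$bdi_mean, p$bdi_sd,
                       p$bdi_range[1L], p$bdi_range[2L]),
      dass_a = rtruncnorm(n_per_group, p$dass_mean, p$dass_sd,
                          max(0, p$dass_range[1L]), p$dass_range[2L]),
      true_k = rtruncnorm(n_per_group, p$k_mean, p$k_sd, 0, 6),
      stringsAsFactors = FALSE)
    cdadf <- as.data.frame(cda)
    names(cdadf) <- paste0("cda_", colnames(cda))
    cbind(df, cdadf)
  })
  participants <- do.call(rbind, rows)
  rownames(participants) <- NULL
  structure(list(participants = participants, seed = seed), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$participants$group)
  cat(sprintf("<cohort> %d participants (%s), seed %d\n",
              nrow(x$participants),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Ground-truth CDA amplitudes of one participant
#'
#' @param participant one row of a cohort's `participants` data.frame.
#' @return Named numeric vector, one uV amplitude per condition.
#' @export
participant_cda <- function(participant) {
  cols <- grep("^cda_", names(participant), value = TRUE)
  amps <- as.numeric(participant[1, cols])
  names(amps) <- sub("^cda_", "", cols)
  amps
}

#' Task configuration for the face-filtering change-detection task
#'
#' Defaults reproduce the study design: 3 conditions x 200 trials, 50%
#' change trials, cue side balanced left/right, 12 randomized blocks; the
#' separate VWM performance measurement uses set size 6 and 100 trials.
#'
#' @param n_trials_per_condition trials per condition (default 200).
#' @param conditions condition labels.
#' @param change_rate proportion of change trials (default 0.5).
#' @param cue_balance proportion of cue-left trials (default 0.5).
#' @param n_blocks number of blocks (default 12).
#' @param set_size_targets targets per hemifield in the filtering task.
#' @param vwm_task_set_size set size of the VWM measurement (default 6).
#' @param vwm_task_trials trials of the VWM measurement (default 100).
#' @return A `task_config` list.
#' @export
task_config <- function(n_trials_per_condition = 200,
                        conditions = cda_conditions,
                        change_rate = 0.5, cue_balance = 0.5,
                        n_blocks = 12, set_size_targets = 2,
                        vwm_task_set_size = 6, vwm_task_trials = 100) {
  stopifnot(n_trials_per_condition >= 1, n_blocks >= 1,
            change_rate >= 0, change_rate <= 1,
            cue_balance >= 0, cue_balance <= 1)
  structure(list(n_trials_per_condition = n_trials_per_condition,
                 conditions = conditions, change_rate = change_rate,
                 cue_balance = cue_balance, n_blocks = n_blocks,
                 set_size_targets = set_size_targets,
                 vwm_task_set_size = vwm_task_set_size,
                 vwm_task_trials = vwm_task_trials),
            class = "task_config")
}

exact_count <- function(n, rate, what) {
  k <- n * rate
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf(
      "%d trials cannot be exactly counterbalanced at rate %g for %s; %s",
      n, rate, what, "choose counts divisible by the rate denominator"))
  as.integer(round(k))
}

#' Simulate a counterbalanced trial table
#'
#' Builds the per-trial task metadata for one participant. Within each
#' condition, change/no-change and cue left/right are exactly
#' counterbalanced (stratified assignment, not Bernoulli draws), and the
#' change x cue cross is kept as even as the margins allow. Trial order is
#' then randomized and trials are assigned to blocks by position.
#'
#' @param task a [task_config()].
#' @param seed integer seed.
#' @return A data.frame with columns `trial_id`, `condition`, `cue_side`,
#'   `change_present`, `block`, `response_change`, `correct`,
#'   `rejected_heog`, `rejected_amp` (responses `NA` until
#'   [simulate_behavior()]; rejection flags `FALSE` until the artifact
#'   stage).
#' @export
simulate_trial_table <- function(task = task_config(), seed = 1) {
  stopifnot(inherits(task, "task_config"))
  n <- task$n_trials_per_condition
  per_cond <- lapply(task$conditions, function(cond) {
    n_change <- exact_count(n, task$change_rate, "change/no-change")
    n_left <- exact_count(n, task$cue_balance, "cue left/right")
    # cross-balance: split cue-left trials across change strata as evenly
    # as the margins permit
    n_cl <- min(n_change, max(0L, as.integer(round(n_change * task$cue_balance))))
    n_nl <- n_left - n_cl
    if (n_nl < 0L) { n_cl <- n_cl + n_nl; n_nl <- 0L }
    if (n_nl > n - n_change) { n_cl <- n_cl + (n_nl - (n - n_change)); n_nl <- n - n_change }
    data.frame(
      condition = cond,
      change_present = rep(c(TRUE, FALSE), c(n_change, n - n_change)),
      cue_side = c(rep(c("left", "right"), c(n_cl, n_change - n_cl)),
                   rep(c("left", "right"), c(n_nl, n - n_change - n_nl))),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_cond)
  set.seed(seed)
  tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
  tab$trial_id <- seq_len(nrow(tab))
  tab$block <- as.integer(ceiling(tab$trial_id / (nrow(tab) / task$n_blocks)))
  tab$response_change <- NA
  tab$correct <- NA
  tab$rejected_heog <- FALSE
  tab$rejected_amp <- FALSE
  rownames(tab) <- NULL
  tab[, c("trial_id", "condition", "cue_side", "change_present", "block",
          "response_change", "correct", "rejected_heog", "rejected_amp")]
}

#' Simulate change-detection responses under the slots model
#'
#' Generative model: on a change trial the probed change is detected with
#' probability `min(true_k / set_size, 1)`; an undetected change, like an
#' unstored item on a no-change trial, elicits a "change" guess with
#' probability `guess_rate`. With probability `lapse` the response is
#' replaced by a coin flip. Under this model the expected hit and
#' false-alarm rates are `H = k/N + (1 - k/N) g` and `F = (1 - k/N) g`, so
#' Cowan's `K = N (H - F)` recovers `true_k` without bias when `lapse = 0`.
#'
#' @param true_k true capacity in items (a capacity above `set_size` makes
#'   storage certain).
#' @param set_size number of items in the memory array.
#' @param guess_rate probability of guessing "change" when uninformed.
#' @param lapse probability a response is replaced by a random one.
#' @param trials either a trial table with a `change_present` column or a
#'   single integer number of trials (change/no-change then exactly
#'   counterbalanced).
#' @param seed integer seed.
#' @return The trial table with `response_change` and `correct` filled in.
#' @export
simulate_behavior <- function(true_k, set_size, guess_rate = 0.5, lapse = 0,
                              trials = 100, seed = 1) {
  stopifnot(true_k >= 0, set_size >= 1,
            guess_rate >= 0, guess_rate <= 1, lapse >= 0, lapse <= 1)
  if (is.numeric(trials) && length(trials) == 1L) {
    n <- as.integer(trials)
    n_change <- n %/% 2L
    trials <- data.frame(
      trial_id = seq_len(n),
      change_present = rep(c(TRUE, FALSE), c(n_change, n - n_change)))
  }
  stopifnot(is.data.frame(trials), "change_present" %in% names(trials))
  n <- nrow(trials)
  set.seed(seed)
  p_store <- min(true_k / set_size, 1)
  stored <- stats::runif(n) < p_store
  guess <- stats::runif(n) < guess_rate
  resp <- ifelse(trials$change_present,
                 stored | guess,   # detected change, or uninformed guess
                 !stored & guess)  # false alarm only if probe not stored
  lapsed <- stats::runif(n) < lapse
  coin <- stats::runif(n) < 0.5
  resp[lapsed] <- coin[lapsed]
  trials$response_change <- resp
  trials$correct <- trials$response_change == trials$change_present
  trials
}
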