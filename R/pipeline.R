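#' Study configuration
#'
#' Bundles every stage's configuration with a master seed. Defaults
#' reproduce the study conditions: 18 participants per group, 3 conditions
#' x 200 trials, 1000-Hz epochs from -200 to 1100 ms, 17-Hz zero-phase
#' low-pass, +/-60 uV HEOG and +/-80 uV rejection with 30% participant
#' exclusion, the P7/P8, P9/P10, PO7/PO8 montage and the 500-1000 ms CDA
#' window. Every stage's seed is derived deterministically from
#' `master_seed` via [derive_seed()], so any participant or stage can be
#' regenerated in isolation.
#'
#' @param n_per_group participants per group.
#' @param group_params see [default_group_params()].
#' @param task a [task_config()].
#' @param eeg an [eeg_sim_config()].
#' @param preproc a [preproc_config()].
#' @param policy a [rejection_policy()].
#' @param mtg a [montage()].
#' @param windows an [analysis_windows()].
#' @param guess_rate guessing probability of the slots model.
#' @param filter_task_lapse lapse rate in the filtering task (default 0.1,
#'   giving the ~95% accuracies typical of this task; the VWM measurement
#'   uses no lapse).
#' @param master_seed integer master seed.
#' @param output_dir optional directory for persisted intermediates.
#' @return A `study_config` list.
#' @export
study_config <- function(n_per_group = 18,
                         group_params = default_group_params(),
                         task = task_config(), eeg = eeg_sim_config(),
                         preproc = preproc_config(),
                         policy = rejection_policy(), mtg = montage(),
                         windows = analysis_windows(),
                         guess_rate = 0.5, filter_task_lapse = 0.1,
                         master_seed = 1, output_dir = NULL) {
  structure(list(n_per_group = n_per_group, group_params = group_params,
                 task = task, eeg = eeg, preproc = preproc, policy = policy,
                 mtg = mtg, windows = windows, guess_rate = guess_rate,
                 filter_task_lapse = filter_task_lapse,
                 master_seed = master_seed, output_dir = output_dir),
            class = "study_config")
}

stage_try <- function(stage, id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage `%s` failed for participant %s: %s",
                 stage, id, conditionMessage(e)), call. = FALSE))
}

#' Simulate and measure a single participant
#'
#' Runs the per-participant chain: trial table, filtering-task responses,
#' epoch synthesis, artifact injection, preprocessing, trial rejection,
#' lateralized measures, and the separate VWM measurement.
#'
#' @param participant one row of a cohort's `participants` data.frame.
#' @param index participant index (seeds the stages).
#' @param config a [study_config()].
#' @return One-row data.frame of per-participant measures (accuracy and
#'   component amplitude per condition, difference scores, K, d-prime,
#'   rejection rates).
#' @export
simulate_participant_measures <- function(participant, index, config) {
  id <- participant$id
  ms <- config$master_seed
  tt <- stage_try("trial_table", id,
                  simulate_trial_table(config$task, derive_seed(ms, index, 1)))
  tt <- stage_try("behavior", id, simulate_behavior(
    participant$true_k, config$task$set_size_targets,
    config$guess_rate, config$filter_task_lapse, tt,
    derive_seed(ms, index, 2)))
  eeg <- config$eeg
  eeg$seed <- derive_seed(ms, index, 3)
  epochs <- stage_try("epochs", id, simulate_epochs(tt, participant, eeg))
  art <- stage_try("artifacts", id,
                   inject_artifacts(epochs, eeg, derive_seed(ms, index, 4), tt))
  epochs <- stage_try("preprocess", id,
                      preprocess_epochs(art$epochs, config$preproc))
  tt <- stage_try("rejection", id, apply_rejection(epochs, tt, config$policy))
  meas <- stage_try("lateralized", id,
                    measure_lateralized(epochs, tt, config$mtg,
                                        config$windows))
  acc <- stage_try("accuracy", id, accuracy_by_condition(tt))
  vwm <- stage_try("vwm_task", id, simulate_behavior(
    participant$true_k, config$task$vwm_task_set_size, config$guess_rate,
    0, config$task$vwm_task_trials, derive_seed(ms, index, 5)))
  beh <- stage_try("vwm_summary", id,
                   behavioral_summary(vwm, config$task$vwm_task_set_size))

  rec <- data.frame(id = id, group = participant$group,
                    bdi = participant$bdi, dass_a = participant$dass_a,
                    true_k = participant$true_k,
                    k_hat = beh$K, d_prime = beh$d_prime,
                    n_trials = nrow(tt),
                    n_rejected = sum(tt$rejected_heog | tt$rejected_amp),
                    stringsAsFactors = FALSE)
  rec$rejection_rate <- rec$n_rejected / rec$n_trials
  for (cond in meas$condition) {
    rec[[paste0("acc_", cond)]] <- unname(acc[cond])
    rec[[paste0("cda_", cond)]] <- meas$cda[meas$condition == cond]
    rec[[paste0("n_used_", cond)]] <-
      meas$n_trials_used[meas$condition == cond]
  }
  if (all(c("cda_fearful_dis", "cda_non_dis") %in% names(rec))) {
    rec$diff_fearful <- cda_difference_score(rec$cda_fearful_dis,
                                             rec$cda_non_dis)
    rec$diff_sad <- cda_difference_score(rec$cda_sad_dis, rec$cda_non_dis)
  }
  rec
}

#' Run a full synthetic study
#'
#' Generates a cohort, runs every participant through the per-participant
#' chain, excludes participants whose trial rejection rate exceeds the
#' policy maximum, and assembles the group-level report. Deterministic
#' given `master_seed`. Per-participant records are persisted (CSV) before
#' aggregation when `output_dir` is set.
#'
#' @param config a [study_config()].
#' @param verbose print per-stage counts.
#' @return A `study_report`, see [make_report()]; per-participant records
#'   are in `$records`, exclusions in `$excluded`.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cohort <- make_cohort(config$n_per_group, config$group_params,
                        derive_seed(config$master_seed, 0, 0))
  recs <- lapply(seq_len(nrow(cohort$participants)), function(i) {
    rec <- simulate_participant_measures(cohort$participants[i, ], i, config)
    if (verbose)
      message(sprintf("%s: %d/%d trials rejected (%.1f%%)", rec$id,
                      rec$n_rejected, rec$n_trials,
                      100 * rec$rejection_rate))
    rec
  })
  records <- do.call(rbind, recs)
  rates <- stats::setNames(records$rejection_rate, records$id)
  keep <- exclude_participants(rates, config$policy)
  if (verbose)
    message(sprintf("%d participants included, %d excluded (>%.0f%% rejected)",
                    length(keep$included), length(keep$excluded),
                    100 * config$policy$participant_max_rejection))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records,
                     file.path(config$output_dir, "participant_records.csv"),
                     row.names = FALSE)
    write_cohort_json(cohort, file.path(config$output_dir, "cohort.json"))
  }
  report <- make_report(records[records$id %in% keep$included, , drop = FALSE])
  report$excluded <- keep$excluded
  report$config_seed <- config$master_seed
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

group_cond_cell <- function(records, group, col) {
  x <- records[[col]][records$group == group]
  c(mean = mean(x), sd = stats::sd(x))
}

#' Assemble the group-level study report
#'
#' Builds the summary tables and the inferential layer from per-participant
#' records: group x condition means/SDs of accuracy, CDA amplitude and CDA
#' difference score; mixed rm-ANOVAs for accuracy and CDA; the ANCOVA with
#' VWM capacity as covariate; planned paired comparisons per group with
#' JZS Bayes factors; group comparisons of K and d-prime; and the
#' exploratory correlations. Difference scores are distractor minus
#' non-distractor: negative values mean a larger CDA under distractors.
#'
#' @param records per-participant data.frame as produced by
#'   [simulate_participant_measures()] (or read back from the persisted
#'   CSV).
#' @return A `study_report` list with `table1`, `table2`, `omnibus`,
#'   `behavioral`, `correlations`, `records`.
#' @export
make_report <- function(records) {
  groups <- unique(records$group)
  if (any(table(records$group) < 2L))
    stop("need at least 2 participants per group")
  conds <- sub("^cda_", "", grep("^cda_", names(records), value = TRUE))
  need <- c(paste0("acc_", conds), paste0("cda_", conds))
  for (col in need)
    if (anyNA(records[[col]]))
      stop("missing condition measure for participant ",
           paste(records$id[is.na(records[[col]])], collapse = ", "))

  rows <- list()
  for (g in groups) for (cond in conds) {
    a <- group_cond_cell(records, g, paste0("acc_", cond))
    cda <- group_cond_cell(records, g, paste0("cda_", cond))
    ds <- if (cond == "non_dis") c(mean = NA_real_, sd = NA_real_) else
      group_cond_cell(records, g,
                      if (cond == "fearful_dis") "diff_fearful" else "diff_sad")
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, condition = cond,
      accuracy_mean = a["mean"], accuracy_sd = a["sd"],
      cda_mean = cda["mean"], cda_sd = cda["sd"],
      diff_score_mean = ds["mean"], diff_score_sd = ds["sd"],
      row.names = NULL)
  }
  table1 <- do.call(rbind, rows)

  cda_mat <- as.matrix(records[, paste0("cda_", conds)])
  colnames(cda_mat) <- conds
  acc_mat <- as.matrix(records[, paste0("acc_", conds)])
  colnames(acc_mat) <- conds
  omnibus <- rbind(
    cbind(measure = "accuracy", rm_anova_mixed(acc_mat, records$group)),
    cbind(measure = "cda", rm_anova_mixed(cda_mat, records$group)),
    cbind(measure = "cda_ancova_k",
          ancova_mixed(cda_mat, records$group, records$k_hat)))

  pairs <- utils::combn(conds, 2, simplify = FALSE)
  t2 <- list()
  for (g in groups) for (pr in pairs) {
    sel <- records$group == g
    res <- paired_t(records[[paste0("cda_", pr[1L])]][sel],
                    records[[paste0("cda_", pr[2L])]][sel], bf = TRUE)
    t2[[length(t2) + 1L]] <- cbind(group = g,
                                   comparison = paste(pr, collapse = " vs "),
                                   res)
  }
  table2 <- do.call(rbind, t2)

  g1 <- records$group == groups[1L]
  behavioral <- rbind(
    cbind(measure = "K",
          independent_t(records$k_hat[g1], records$k_hat[!g1], bf = TRUE)),
    cbind(measure = "d_prime",
          independent_t(records$d_prime[g1], records$d_prime[!g1], bf = TRUE)),
    cbind(measure = "bdi",
          independent_t(records$bdi[g1], records$bdi[!g1], bf = TRUE)),
    cbind(measure = "dass_a",
          independent_t(records$dass_a[g1], records$dass_a[!g1], bf = TRUE)))

  cor_pairs <- list(c("bdi", "dass_a"), c("bdi", "k_hat"),
                    c("bdi", "diff_fearful"), c("bdi", "diff_sad"),
                    c("dass_a", "diff_fearful"), c("dass_a", "diff_sad"),
                    c("k_hat", "diff_fearful"), c("k_hat", "diff_sad"))
  correlations <- do.call(rbind, lapply(cor_pairs, function(pr) {
    if (!all(pr %in% names(records))) return(NULL)
    cbind(pair = paste(pr, collapse = " ~ "),
          pearson_r(records[[pr[1L]]], records[[pr[2L]]]))
  }))

  structure(list(table1 = table1, table2 = table2, omnibus = omnibus,
                 behavioral = behavioral, correlations = correlations,
                 records = records),
            class = "study_report")
}

#' Write report tables as CSV files
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("table1", "table2", "omnibus", "behavioral", "correlations"))
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", nrow(x$records), "participants included\n\n")
  cat("Group x condition means (SD):\n")
  t1 <- x$table1
  for (i in seq_len(nrow(t1)))
    cat(sprintf("  %-10s %-12s acc %.3f (%.3f)  CDA %6.2f (%.2f) uV%s\n",
                t1$group[i], t1$condition[i], t1$accuracy_mean[i],
                t1$accuracy_sd[i], t1$cda_mean[i], t1$cda_sd[i],
                if (is.na(t1$diff_score_mean[i])) "" else
                  sprintf("  diff %6.2f (%.2f) uV", t1$diff_score_mean[i],
                          t1$diff_score_sd[i])))
  cat("\nOmnibus tests:\n")
  for (i in seq_len(nrow(x$omnibus)))
    cat(sprintf("  %-14s %-20s %s\n", x$omnibus$measure[i],
                x$omnibus$effect[i], format_stat(x$omnibus[i, -1L])))
  cat("\nBehavioral group comparisons:\n")
  for (i in seq_len(nrow(x$behavioral)))
    cat(sprintf("  %-8s %s\n", x$behavioral$measure[i],
                format_stat(x$behavioral[i, -1L])))
  invisible(x)
}
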