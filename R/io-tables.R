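trial_table_columns <- c("trial_id", "condition", "cue_side",
                         "change_present", "block", "response_change",
                         "correct", "rejected_heog", "rejected_amp")

#' Validate a per-trial task table
#'
#' Checks required columns, condition and cue-side labels, and the
#' invariant `correct == (response_change == change_present)` wherever
#' responses are present.
#'
#' @param table a trial table data.frame.
#' @param conditions allowed condition labels.
#' @return The table, invisibly; errors name the offending column/label.
#' @export
validate_trial_table <- function(table, conditions = cda_conditions) {
  missing <- setdiff(trial_table_columns, names(table))
  if (length(missing) > 0L)
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(table$condition), conditions)
  if (length(bad) > 0L)
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(conditions, collapse = ", "), ")")
  bad_side <- setdiff(unique(table$cue_side), c("left", "right"))
  if (length(bad_side) > 0L)
    stop("unknown cue_side label(s): ", paste(bad_side, collapse = ", "))
  resp <- !is.na(table$response_change)
  if (any(resp)) {
    expect <- table$response_change[resp] == table$change_present[resp]
    if (!identical(as.logical(table$correct[resp]), expect))
      stop("column `correct` is inconsistent with response_change/change_present")
  }
  invisible(table)
}

#' Write / read a trial table as TSV
#'
#' Tab-separated with a header row; logical columns are stored as
#' TRUE/FALSE and the round trip is exact.
#'
#' @param table a trial table.
#' @param path file path.
#' @return `read_trial_table()` returns the validated data.frame.
#' @export
write_trial_table <- function(table, path) {
  validate_trial_table(table)
  utils::write.table(table[, trial_table_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @param conditions allowed condition labels, checked on read.
#' @export
read_trial_table <- function(path, conditions = cda_conditions) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.info(path)$size == 0) stop("empty trial table file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("trial table has a header but no rows: ", path)
  tab$response_change <- as.logical(tab$response_change)
  tab$correct <- as.logical(tab$correct)
  validate_trial_table(tab, conditions)
  tab
}

#' Write / read a cohort as JSON
#'
#' @param cohort a [make_cohort()] result.
#' @param path file path.
#' @return `read_cohort_json()` returns the `cohort` object.
#' @export
write_cohort_json <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  jsonlite::write_json(list(seed = cohort$seed,
                            participants = cohort$participants),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_json
#' @export
read_cohort_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(participants = as.data.frame(x$participants),
                 seed = as.integer(x$seed)),
            class = "cohort")
}
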