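#' Read and validate a trial table
#'
#' Trial tables are comma-separated text with a header row and one row per
#' choice. Required columns: `participant_id`, `group`, `condition`,
#' `amount_ll` (euros), `delay_days`, `choice_ll` (1 = chose the delayed
#' larger-later option, 0 = chose the immediate 20 euros). An optional `tag`
#' column carries the episodic event label.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of trials.
#' @seealso [validate_trials()], [write_trials()]
#' @export
read_trials <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_trials(x)
}

#' @rdname read_trials
#' @param trials A trial table.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Validate a trial table against the package's input contract
#'
#' Checks the column set, value domains (positive amounts, non-negative
#' delays, binary choices) and condition labels. Rows with missing values in
#' required columns are dropped with a warning, never imputed. Larger-later
#' amounts at or below the smaller-sooner amount are allowed only with
#' `allow_dominated = TRUE`.
#'
#' @param trials A data frame of trials.
#' @param require_choice If `TRUE` (default) a binary `choice_ll` column must
#'   be present; design-stage tables may omit it.
#' @param ss_amount The fixed smaller-sooner amount, euros.
#' @param allow_dominated Permit `amount_ll <= ss_amount`.
#' @return The trials as a tibble, invisibly validated.
#' @export
validate_trials <- function(trials, require_choice = TRUE, ss_amount = 20,
                            allow_dominated = FALSE) {
  trials <- tibble::as_tibble(trials)
  required <- c("participant_id", "group", "condition", "amount_ll", "delay_days")
  if (require_choice) required <- c(required, "choice_ll")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "discountr_validation_error")
  }
  ok <- complete.cases(trials[required])
  if (!all(ok)) {
    warn(sprintf("Dropped %d trial(s) with missing values.", sum(!ok)))
    trials <- trials[ok, , drop = FALSE]
  }
  if (!nrow(trials)) {
    abort("Trial table has no complete rows.",
          class = "discountr_validation_error")
  }
  if (any(trials$amount_ll <= 0) || any(trials$delay_days < 0)) {
    abort("Amounts must be > 0 and delays >= 0.",
          class = "discountr_validation_error")
  }
  if (!all(trials$condition %in% c("control", "episodic"))) {
    abort("`condition` must be 'control' or 'episodic'.",
          class = "discountr_validation_error")
  }
  if (require_choice && !all(trials$choice_ll %in% c(0, 1))) {
    abort("`choice_ll` must be 0 or 1.", class = "discountr_validation_error")
  }
  if (!allow_dominated && any(trials$amount_ll <= ss_amount)) {
    abort(sprintf("All larger-later amounts must exceed the %s-euro immediate amount (set `allow_dominated = TRUE` to override).",
                  format(ss_amount)),
          class = "discountr_validation_error")
  }
  trials
}

#' Read or write a participant's episodic event list
#'
#' Events files are JSON arrays of objects with fields `label` (the episodic
#' tag text shown with the delayed reward) and `delay_days` (days until the
#' event, >= 1).
#'
#' @param path Path to a JSON file.
#' @return `read_events()` returns a tibble with columns `label`,
#'   `delay_days`.
#' @export
read_events <- function(path) {
  x <- jsonlite::fromJSON(path)
  validate_events(tibble::as_tibble(x))
}

#' @rdname read_events
#' @param events A tibble of events.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  jsonlite::write_json(events, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

validate_events <- function(events) {
  events <- tibble::as_tibble(events)
  if (!all(c("label", "delay_days") %in% names(events)) || !nrow(events)) {
    abort("Events must be a non-empty table with columns `label` and `delay_days`.",
          class = "discountr_validation_error")
  }
  if (any(!nzchar(events$label)) || any(events$delay_days < 1)) {
    abort("Event labels must be non-empty and delays >= 1 day.",
          class = "discountr_validation_error")
  }
  events
}
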