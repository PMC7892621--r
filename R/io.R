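#' Read and write the long-format artifact files
#'
#' All files are plain UTF-8 comma-separated values with a header row and
#' no index column. `write_trial_log()` / `read_trial_log()` round-trip
#' the trial log exactly; the same holds for the event log and the survey
#' table. Reports are serialized as JSON with stable key order.
#'
#' @param trials Trial-log tibble with the canonical columns (see
#'   [run_session()]).
#' @param path Output file path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name artifact_io
NULL

write_csv_plain <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

read_csv_plain <- function(path, required, coltypes) {
  if (!file.exists(path)) {
    stop_casino(paste0("file not found: ", path), "casinosim_parse_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_casino(paste0("missing column(s): ",
                       paste(missing, collapse = ", ")),
                "casinosim_parse_error")
  }
  for (col in names(coltypes)) {
    if (col %in% names(df)) {
      df[[col]] <- switch(coltypes[[col]],
        integer = as.integer(df[[col]]),
        numeric = as.numeric(df[[col]]),
        character = as.character(df[[col]])
      )
    }
  }
  tibble::as_tibble(df)
}

#' @rdname artifact_io
#' @export
write_trial_log <- function(trials, path) {
  stopifnot(all(trial_log_columns %in% names(trials)))
  write_csv_plain(trials[trial_log_columns], path)
}

#' @rdname artifact_io
#' @export
read_trial_log <- function(path) {
  read_csv_plain(
    path,
    required = trial_log_columns,
    coltypes = c(
      study_id = "character", timestamp_ms = "numeric",
      arm_id = "character", game_type = "character",
      block_index = "integer", trial_number = "integer",
      balance_in = "numeric", theme_id = "character",
      response = "character", outcome = "character",
      outcome_credit = "numeric", balance_out = "numeric"
    )
  )
}

#' @rdname artifact_io
#' @param events Event-log tibble.
#' @export
write_event_log <- function(events, path) {
  stopifnot(all(event_log_columns %in% names(events)))
  write_csv_plain(events[event_log_columns], path)
}

#' @rdname artifact_io
#' @export
read_event_log <- function(path) {
  read_csv_plain(
    path,
    required = event_log_columns,
    coltypes = c(study_id = "character", timestamp_ms = "numeric",
                 event_type = "character", payload = "character")
  )
}

#' @rdname artifact_io
#' @param survey Survey tibble.
#' @export
write_survey <- function(survey, path) {
  write_csv_plain(survey, path)
}

#' @rdname artifact_io
#' @export
read_survey <- function(path) {
  df <- read_csv_plain(
    path,
    required = c("study_id", "age", "sex", "gambling_frequency",
                 paste0("pgsi_item_", 1:9), "pgsi_total"),
    coltypes = c(study_id = "character", sex = "character")
  )
  int_cols <- c("gambling_frequency", paste0("pgsi_item_", 1:9),
                "pgsi_total", intersect(gambling_type_labels(), names(df)),
                intersect("none", names(df)))
  for (col in int_cols) df[[col]] <- as.integer(df[[col]])
  df
}

# Serialize any report object to JSON with metadata. Keys are emitted in
# a fixed order so reports diff cleanly.
report_to_list <- function(x) {
  if (inherits(x, "mechanics_report")) {
    list(
      report_type = "mechanics",
      arm_id = x$arm_id,
      n_trials = x$n_trials,
      blocks = purrr::map(x$blocks, function(b) {
        list(
          block_index = b$block_index,
          game_type = b$game_type,
          strata = b$strata,
          independence = b$independence,
          display = b$display,
          balance = if (is.null(b$balance)) NULL else list(
            by_trial = b$balance$by_trial,
            change = b$balance$change,
            discrepancy = b$balance$discrepancy,
            implied_rtp = b$balance$implied_rtp,
            marginal_p = b$balance$marginal_p
          )
        )
      })
    )
  } else if (inherits(x, "quality_report")) {
    list(
      report_type = "quality",
      reference_option = x$reference_option,
      summary = x$summary,
      participants = x$participants
    )
  } else if (inherits(x, "psychometrics_report")) {
    list(
      report_type = "psychometrics",
      n = x$n,
      n_nonzero = x$n_nonzero,
      alpha_full = x$alpha_full,
      alpha_nonzero = x$alpha_nonzero,
      parallel = list(
        n_components = x$parallel$n_components,
        percentile = x$parallel$percentile,
        n_resamples = x$parallel$n_resamples,
        series = x$parallel$series
      ),
      associations = x$associations$estimates
    )
  } else {
    stop_casino("unknown report type", "casinosim_contract_error")
  }
}

#' Write an analysis report as JSON
#'
#' Serializes a `mechanics_report`, `quality_report` or
#' `psychometrics_report`, wrapped in a metadata envelope carrying the
#' package version and, when given, the seed and input-file hashes, so a
#' report is traceable to the run that produced it.
#'
#' @param report A report object.
#' @param path Output `.json` path.
#' @param seed Seed recorded in the metadata.
#' @param inputs Character vector of input file paths to hash (md5).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, seed = NULL, inputs = NULL) {
  envelope <- list(
    artifact = "casinosim",
    version = as.character(packageVersion("casinosim")),
    seed = seed,
    input_md5 = if (!is.null(inputs)) {
      as.list(setNames(as.character(tools::md5sum(inputs)),
                       basename(inputs)))
    },
    report = report_to_list(report)
  )
  jsonlite::write_json(envelope, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "rows")
  invisible(path)
}
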