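#' Response-variation score of choice-game trials
#'
#' The percentage of choice trials on which the designated reference option
#' (by default the first option label encountered, in a stable sort) was
#' chosen. A fair alternating chooser scores near 50%; an indiscriminate
#' responder who repeats one option scores 0 or 100. The score ignores
#' trial order entirely.
#'
#' @param trials Trial-log tibble (rows of one participant's binary-choice
#'   block(s); slot rows are rejected).
#' @param reference_option Option label treated as the reference; default
#'   the alphabetically first response observed in the block spec order.
#' @return Percentage in `[0, 100]`.
#' @export
response_variation_score <- function(trials, reference_option = NULL) {
  trials <- dplyr::filter(trials, .data$game_type != "slot")
  if (nrow(trials) == 0L) {
    stop_casino("no choice trials: variation score undefined",
                "casinosim_contract_error")
  }
  if (is.null(reference_option)) {
    reference_option <- sort(unique(trials$response))[1L]
  }
  100 * mean(trials$response == reference_option)
}

#' Flag a variation score outside the acceptable range
#'
#' Scores strictly outside `[lower, upper]` (defaults 10 and 90, the
#' screening rule used for crowdsourced behavioral data) are flagged as
#' indicative of indiscriminate, repetitive responding. Bounds are
#' inclusive: exactly 10 or 90 is not flagged.
#'
#' @param score Variation score(s) in percent.
#' @param lower,upper Acceptance bounds in percent.
#' @return Logical vector.
#' @examples
#' flag_low_variation(c(100, 52.5, 10)) # TRUE FALSE FALSE
#' @export
flag_low_variation <- function(score, lower = 10, upper = 90) {
  stopifnot(lower <= upper)
  score < lower | score > upper
}

#' Completion-time summary of a cohort
#'
#' Durations summarize the session clock (first to last logged event or
#' trial). Durations are reported, never used for exclusion: a long
#' duration need not indicate poor data since participants may pause
#' between phases.
#'
#' @param durations_min Numeric vector of session durations in minutes, or
#'   a `casino_cohort` (durations derived from each session's trial
#'   timestamps).
#' @param thresholds_min Thresholds (minutes) for the "count above" fields.
#' @return One-row tibble: `n`, `mean_min`, `sd_min`, `min_min`, `max_min`
#'   and one `n_above_<t>` column per threshold.
#' @export
completion_time_summary <- function(durations_min,
                                    thresholds_min = c(15, 20)) {
  if (inherits(durations_min, "casino_cohort")) {
    durations_min <- purrr::map_dbl(
      durations_min$sessions,
      function(s) max(s$trials$timestamp_ms) / 60000
    )
  }
  if (length(durations_min) == 0L) {
    stop_casino("no sessions: duration summary undefined",
                "casinosim_contract_error")
  }
  out <- tibble::tibble(
    n = length(durations_min),
    mean_min = mean(durations_min),
    sd_min = if (length(durations_min) > 1L) sd(durations_min) else NA_real_,
    min_min = min(durations_min),
    max_min = max(durations_min)
  )
  for (t in thresholds_min) {
    out[[paste0("n_above_", t)]] <- sum(durations_min > t)
  }
  out
}

#' Cohort data-quality report
#'
#' Screens every participant's binary-choice trials with the
#' response-variation rule and summarizes completion times. The flag rule
#' and thresholds are configurable; the defaults are the 10-90% range.
#'
#' @param cohort A `casino_cohort`, or a trial-log tibble covering several
#'   participants.
#' @param lower,upper Variation-score bounds in percent.
#' @param block_index Which block to screen; default the first choice block
#'   present per participant.
#' @return A `quality_report` object with `participants` (per-participant
#'   tibble: `study_id`, `variation_score`, `flagged`, `duration_min`) and
#'   `summary` (one-row tibble with `n`, `n_flagged`, `pct_flagged`,
#'   `mean_variation`, `sd_variation` and duration fields).
#' @examples
#' co <- generate_cohort(replication_design(), cohort_spec(n_participants = 10),
#'                       seed = 1)
#' cohort_quality_report(co)
#' @export
cohort_quality_report <- function(cohort, lower = 10, upper = 90,
                                  block_index = NULL) {
  trials <- if (inherits(cohort, "casino_cohort")) cohort$trials else cohort
  if (nrow(trials) == 0L) {
    stop_casino("empty trial log", "casinosim_contract_error")
  }
  choice <- dplyr::filter(trials, .data$game_type != "slot")
  if (is.null(block_index)) {
    block_index <- min(choice$block_index)
  }
  choice <- dplyr::filter(choice, .data$block_index == !!block_index)
  if (nrow(choice) == 0L) {
    stop_casino("no choice trials in the requested block",
                "casinosim_contract_error")
  }
  reference_option <- sort(unique(choice$response))[1L]

  per <- choice |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(
      variation_score = 100 * mean(.data$response == reference_option),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = flag_low_variation(.data$variation_score,
                                               lower, upper))
  durations <- trials |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(duration_min = max(.data$timestamp_ms) / 60000,
                     .groups = "drop")
  per <- dplyr::left_join(per, durations, by = "study_id")

  dur <- completion_time_summary(per$duration_min)
  summary <- tibble::tibble(
    n = nrow(per),
    n_flagged = sum(per$flagged),
    pct_flagged = 100 * mean(per$flagged),
    mean_variation = mean(per$variation_score),
    sd_variation = sd(per$variation_score),
    lower = lower, upper = upper
  )
  summary <- dplyr::bind_cols(summary, dur[-1])
  structure(
    list(participants = per, summary = summary,
         reference_option = reference_option),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<quality_report> n = %d; flagged %d (%.1f%%); variation %.1f%% (SD %.1f)\n",
    s$n, s$n_flagged, s$pct_flagged, s$mean_variation, s$sd_variation
  ))
  invisible(x)
}

#' @export
tidy.quality_report <- function(x, ...) x$participants

#' @export
glance.quality_report <- function(x, ...) x$summary
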