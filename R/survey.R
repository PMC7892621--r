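#' Gambling-type labels used by the intake survey
#'
#' Twelve last-year gambling forms (including forms prevalent outside
#' Western countries) plus a `"none"` option; respondents may select any
#' subset of the twelve, and `"none"` excludes all others.
#'
#' @return Character vector of the twelve type labels (without `"none"`).
#' @export
gambling_type_labels <- function() {
  c(
    "lottery", "sports_betting", "race_betting", "cards", "casino_slots",
    "festival", "dice", "online_lottery", "online_betting", "online_cards",
    "online_slots", "other"
  )
}

#' Score the nine-item problem-gambling screener
#'
#' Items are ordinal 0-3 ("never" to "almost always"); the total is their
#' sum, ranging 0-27. Higher totals indicate more gambling problems.
#'
#' @param items Numeric vector of 9 item scores, or a data frame / matrix
#'   with 9 columns (one row per respondent).
#' @return Numeric total(s) in `[0, 27]`.
#' @examples
#' score_pgsi(c(1, 0, 2, 0, 0, 1, 0, 0, 3)) # 7
#' @export
score_pgsi <- function(items) {
  if (is.data.frame(items) || is.matrix(items)) {
    m <- as.matrix(items)
    if (ncol(m) != 9L) {
      stop_casino(sprintf("expected 9 items, got %d columns", ncol(m)),
                  "casinosim_contract_error")
    }
    bad <- which(!(m %in% 0:3), arr.ind = TRUE)
    if (length(bad)) {
      stop_casino(
        sprintf("item %d of row %d out of range 0-3", bad[1, 2], bad[1, 1]),
        "casinosim_contract_error"
      )
    }
    return(rowSums(m))
  }
  if (length(items) != 9L) {
    stop_casino(sprintf("expected 9 items, got %d", length(items)),
                "casinosim_contract_error")
  }
  bad <- which(!items %in% 0:3)
  if (length(bad)) {
    stop_casino(sprintf("item %d out of range 0-3 (value %s)",
                        bad[1], items[bad[1]]),
                "casinosim_contract_error")
  }
  sum(items)
}

#' Count selected gambling types
#'
#' @param response A one-row data frame (or list) with logical/0-1 columns
#'   named after [gambling_type_labels()], or a character vector of selected
#'   labels. `"none"` yields 0.
#' @return Integer count 0-12.
#' @examples
#' count_gambling_types(c("lottery", "casino_slots")) # 2
#' count_gambling_types("none") # 0
#' @export
count_gambling_types <- function(response) {
  labels <- gambling_type_labels()
  if (is.character(response)) {
    sel <- setdiff(response, "none")
    unknown <- setdiff(sel, labels)
    if (length(unknown)) {
      stop_casino(paste0("unknown gambling type(s): ",
                         paste(unknown, collapse = ", ")),
                  "casinosim_contract_error")
    }
    if ("none" %in% response && length(sel) > 0L) {
      stop_casino("'none' excludes other gambling types",
                  "casinosim_contract_error")
    }
    return(length(unique(sel)))
  }
  cols <- intersect(labels, names(response))
  if (length(cols) == 0L) {
    stop_casino("no gambling-type columns found", "casinosim_contract_error")
  }
  sum(as.integer(unlist(response[cols])) > 0L)
}

#' Classify a screener total into standard risk bands
#'
#' Standard cut-offs for the nine-item screener: 0 non-problem, 1-2 low
#' risk, 3-7 moderate risk, 8+ problem gambling.
#'
#' @param total Numeric vector of totals in `[0, 27]`.
#' @return Ordered factor with levels `non-problem < low-risk <
#'   moderate-risk < problem`.
#' @examples
#' classify_pgsi(c(0, 2, 7, 8))
#' @export
classify_pgsi <- function(total) {
  if (any(total < 0 | total > 27 | total != floor(total))) {
    stop_casino("totals must be integers in [0, 27]",
                "casinosim_contract_error")
  }
  cut(
    total,
    breaks = c(-0.5, 0.5, 2.5, 7.5, 27.5),
    labels = c("non-problem", "low-risk", "moderate-risk", "problem"),
    ordered_result = TRUE
  )
}
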