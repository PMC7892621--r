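#' Observed win rates, stratified by theme or option
#'
#' Exact counts and proportions of win outcomes per stratum, with Wilson
#' confidence intervals, plus a trial-indexed win-rate series for plotting
#' observed rates against the programmed probabilities.
#'
#' @param trials Trial-log tibble.
#' @param stratify_by `"theme"` (slot trials, the default when themes are
#'   present) or `"option"` (choice trials, stratified by response).
#' @param level Confidence level for the Wilson intervals.
#' @return A list with `strata` (tibble: `stratum`, `n`, `wins`,
#'   `observed_p`, `conf.low`, `conf.high`) and `by_trial` (tibble:
#'   `stratum`, `trial_number`, `n`, `win_rate`).
#' @export
observed_win_rates <- function(trials,
                               stratify_by = c("theme", "option"),
                               level = 0.95) {
  stratify_by <- match.arg(stratify_by)
  if (stratify_by == "theme") {
    trials <- dplyr::filter(trials, !is.na(.data$theme_id))
    if (nrow(trials) == 0L) {
      stop_casino("no themed (slot) trials to stratify",
                  "casinosim_contract_error")
    }
    trials$stratum <- trials$theme_id
  } else {
    trials <- dplyr::filter(trials, .data$game_type != "slot")
    if (nrow(trials) == 0L) {
      stop_casino("no choice trials to stratify",
                  "casinosim_contract_error")
    }
    trials$stratum <- trials$response
  }
  strata <- trials |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      wins = sum(.data$outcome == "win"),
      .groups = "drop"
    )
  strata <- dplyr::bind_cols(
    strata, wilson_ci(strata$wins, strata$n, level)
  ) |>
    dplyr::rename(observed_p = "estimate")
  by_trial <- trials |>
    dplyr::group_by(.data$stratum, .data$trial_number) |>
    dplyr::summarise(
      n = dplyr::n(),
      win_rate = mean(.data$outcome == "win"),
      .groups = "drop"
    )
  list(strata = strata, by_trial = by_trial)
}

#' Audit sampling-with-replacement independence
#'
#' If outcomes are drawn with replacement, the win rate cannot depend on
#' the preceding trial's outcome. The audit forms consecutive within-
#' participant, within-block trial pairs (session boundaries never chain;
#' each block's first trial only conditions, it is never conditioned on),
#' and compares the win rate after a win with the win rate after a loss
#' using a two-proportion z test.
#'
#' @param trials Trial-log tibble of a constant-probability block (across
#'   one or many participants).
#' @param level Confidence level of the difference interval.
#' @return A one-row tibble: `n_after_win`, `wins_after_win`,
#'   `p_after_win`, `n_after_loss`, `wins_after_loss`, `p_after_loss`,
#'   `difference`, `conf.low`, `conf.high`, `z`, `p.value`.
#' @export
replacement_independence_check <- function(trials, level = 0.95) {
  paired <- trials |>
    dplyr::arrange(.data$study_id, .data$block_index,
                   .data$trial_number) |>
    dplyr::group_by(.data$study_id, .data$block_index) |>
    dplyr::mutate(prev_outcome = dplyr::lag(.data$outcome)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_outcome))
  if (nrow(paired) == 0L) {
    stop_casino("no consecutive trial pairs to audit",
                "casinosim_contract_error")
  }
  tab <- paired |>
    dplyr::group_by(.data$prev_outcome) |>
    dplyr::summarise(
      n = dplyr::n(),
      wins = sum(.data$outcome == "win"),
      .groups = "drop"
    )
  get <- function(prev, col) {
    v <- tab[[col]][tab$prev_outcome == prev]
    if (length(v) == 0L) 0L else v
  }
  n1 <- get("win", "n"); x1 <- get("win", "wins")
  n0 <- get("loss", "n"); x0 <- get("loss", "wins")
  p1 <- if (n1 > 0) x1 / n1 else NA_real_
  p0 <- if (n0 > 0) x0 / n0 else NA_real_
  diff <- p1 - p0
  se <- sqrt(p1 * (1 - p1) / max(n1, 1) + p0 * (1 - p0) / max(n0, 1))
  z <- qnorm(1 - (1 - level) / 2)
  zstat <- if (is.finite(se) && se > 0) diff / se else NA_real_
  tibble::tibble(
    n_after_win = n1, wins_after_win = x1, p_after_win = p1,
    n_after_loss = n0, wins_after_loss = x0, p_after_loss = p0,
    difference = diff,
    conf.low = diff - z * se,
    conf.high = diff + z * se,
    z = zstat,
    p.value = if (is.na(zstat)) NA_real_ else 2 * pnorm(-abs(zstat))
  )
}

#' Marginal win probability of a stimulus mixture
#'
#' The overall win probability when the per-trial win probability depends
#' on which stimulus (theme) is displayed: the display-frequency-weighted
#' mean of the per-theme probabilities.
#'
#' @param theme_freqs Display frequencies (must sum to 1).
#' @param theme_ps Per-theme win probabilities, same length.
#' @return A single probability.
#' @examples
#' marginal_win_probability(c(0.5, 0.5), c(0.5, 0.2))     # 0.35
#' marginal_win_probability(c(0.515, 0.485), c(0.5, 0.2)) # 0.3545
#' @export
marginal_win_probability <- function(theme_freqs, theme_ps) {
  stopifnot(length(theme_freqs) == length(theme_ps))
  if (abs(sum(theme_freqs) - 1) > 1e-9) {
    stop_casino("theme frequencies must sum to 1",
                "casinosim_contract_error")
  }
  sum(theme_freqs * theme_ps)
}

#' Expected-versus-observed balance trajectory analysis
#'
#' Compares the cohort's mean balance after each trial of a block with the
#' closed-form expectation from the programmed probabilities, and
#' summarizes the distribution of per-trial balance changes. Because
#' balance is accumulated, a random early fluctuation propagates to all
#' later momentary discrepancies; the per-trial change is the
#' non-accumulated diagnostic and is the one that must match the
#' programmed return-to-player rate.
#'
#' @param trials Trial-log tibble restricted to the audited block (one
#'   block across many participants).
#' @param block The [game_block()] the records came from.
#' @param starting_balance Balance at the block's first trial.
#' @param level Confidence level for the mean-change interval.
#' @return A list with `by_trial` (tibble: `trial_number`, `n`,
#'   `observed_mean_balance`, `expected_balance`, `discrepancy`),
#'   `change` (one-row tibble: `mean_change`, `sd_change`, `conf.low`,
#'   `conf.high`, `expected_change`), and `discrepancy` (one-row tibble:
#'   mean and CI of the momentary observed-expected discrepancy).
#' @export
balance_trajectory_analysis <- function(trials, block, starting_balance,
                                        level = 0.95) {
  if (!all(trials$game_type == block$game_type)) {
    stop_casino("records and block disagree on game_type",
                "casinosim_contract_error")
  }
  if (max(trials$trial_number) > block$n_trials) {
    stop_casino("records contain trial numbers beyond the block length",
                "casinosim_contract_error")
  }
  expected <- expected_balance_trajectory(block, starting_balance)
  by_trial <- trials |>
    dplyr::group_by(.data$trial_number) |>
    dplyr::summarise(
      n = dplyr::n(),
      observed_mean_balance = mean(.data$balance_out),
      .groups = "drop"
    ) |>
    dplyr::left_join(expected, by = c(trial_number = "trial")) |>
    dplyr::mutate(discrepancy = .data$observed_mean_balance -
                    .data$expected_balance)

  z <- qnorm(1 - (1 - level) / 2)
  delta <- trials$balance_out - trials$balance_in
  m <- block_marginals(block)
  mean_change <- mean(delta)
  sd_change <- sd(delta)
  se <- sd_change / sqrt(length(delta))

  # momentary discrepancy: observed - expected balance, per participant
  # and trial. Balances are cumulative, hence serially correlated within a
  # session, so the CI clusters on participants: one mean discrepancy per
  # participant, normal-theory interval across participants.
  disc <- trials$balance_out -
    expected$expected_balance[trials$trial_number]
  per_part <- tapply(disc, trials$study_id, mean)
  disc_se <- if (length(per_part) > 1L) {
    sd(per_part) / sqrt(length(per_part))
  } else {
    sd(disc) / sqrt(length(disc))
  }

  list(
    by_trial = by_trial,
    change = tibble::tibble(
      mean_change = mean_change,
      sd_change = sd_change,
      conf.low = mean_change - z * se,
      conf.high = mean_change + z * se,
      expected_change = -(block$bet_size - m$expected_payout)
    ),
    discrepancy = tibble::tibble(
      mean_discrepancy = mean(disc),
      conf.low = mean(disc) - z * disc_se,
      conf.high = mean(disc) + z * disc_se,
      skewness = {
        d <- disc - mean(disc)
        mean(d^3) / (mean(d^2)^1.5)
      }
    )
  )
}

#' Full game-mechanics audit of a trial log
#'
#' Bundles the individual audits into one report against a design: per-
#' theme and per-option observed win rates with Wilson intervals and the
#' programmed probabilities they should match, the sampling-with-
#' replacement independence check on the first constant-probability choice
#' block, realized theme display frequencies, the implied marginal win
#' probability and return-to-player rate, and the balance-trajectory
#' comparison for the slot block.
#'
#' @param trials Trial-log tibble (a whole cohort).
#' @param design The [casino_design()] the log was generated under.
#' @param arm_id Arm to audit (default the first arm present in the log).
#' @return A `mechanics_report` object.
#' @examples
#' co <- generate_cohort(replication_design(), cohort_spec(n_participants = 20),
#'                       seed = 1)
#' rep <- mechanics_report(co$trials, replication_design())
#' tidy(rep)
#' @export
mechanics_report <- function(trials, design, arm_id = NULL) {
  assert_valid_design(design)
  if (is.null(arm_id)) arm_id <- trials$arm_id[1]
  arm_ids <- purrr::map_chr(design$arms, "arm_id")
  if (!arm_id %in% arm_ids) {
    stop_casino(sprintf("arm '%s' not present in the design", arm_id),
                "casinosim_contract_error")
  }
  arm <- design$arms[[match(arm_id, arm_ids)]]
  trials <- dplyr::filter(trials, .data$arm_id == !!arm_id)
  if (nrow(trials) == 0L) {
    stop_casino(sprintf("no trials for arm '%s'", arm_id),
                "casinosim_contract_error")
  }
  spec_tbl <- tidy(design) |> dplyr::filter(.data$arm_id == !!arm_id)
  present <- unique(trials$block_index)
  missing_blocks <- setdiff(seq_along(arm$blocks) - 1L, present)
  if (length(missing_blocks)) {
    warn(paste0("no records for block index ",
                paste(missing_blocks, collapse = ", ")))
  }
  unknown <- setdiff(present, seq_along(arm$blocks) - 1L)
  if (length(unknown)) {
    stop_casino(
      sprintf("log contains block index %s not in the design",
              paste(unknown, collapse = ", ")),
      "casinosim_contract_error"
    )
  }

  per_block <- purrr::map(intersect(seq_along(arm$blocks) - 1L, present),
    function(bi) {
      blk <- arm$blocks[[bi + 1L]]
      btr <- dplyr::filter(trials, .data$block_index == bi)
      rates <- observed_win_rates(
        btr,
        stratify_by = if (blk$game_type == "slot") "theme" else "option"
      )
      set <- spec_tbl |>
        dplyr::filter(.data$block_index == bi) |>
        dplyr::select("stratum", set_p = "win_probability",
                      "display_probability")
      strata <- dplyr::left_join(rates$strata, set, by = "stratum")
      indep <- NULL
      if (blk$game_type != "slot") {
        ps <- purrr::map_dbl(blk$options, "win_probability")
        if (length(unique(ps)) == 1L && nrow(btr) > 0L) {
          indep <- replacement_independence_check(btr)
          indep$set_p <- ps[1]
        }
      }
      display <- NULL
      balance <- NULL
      if (blk$game_type == "slot") {
        display <- btr |>
          dplyr::count(.data$theme_id, name = "n") |>
          dplyr::mutate(observed_freq = .data$n / sum(.data$n)) |>
          dplyr::left_join(
            dplyr::select(set, "stratum", "display_probability"),
            by = c(theme_id = "stratum")
          )
        start <- btr |>
          dplyr::filter(.data$trial_number == 1L) |>
          dplyr::pull(.data$balance_in) |>
          mean()
        balance <- balance_trajectory_analysis(btr, blk, start)
        balance$implied_rtp <- return_to_player(blk)
        balance$marginal_p <- block_marginals(blk)$p_bar
      }
      list(block_index = bi, game_type = blk$game_type, strata = strata,
           independence = indep, display = display, balance = balance)
    })

  structure(
    list(arm_id = arm_id, blocks = per_block,
         n_trials = nrow(trials)),
    class = "mechanics_report"
  )
}

#' @export
print.mechanics_report <- function(x, ...) {
  cat(sprintf("<mechanics_report> arm %s, %d trials\n", x$arm_id,
              x$n_trials))
  for (b in x$blocks) {
    cat(sprintf("  block %d (%s):\n", b$block_index, b$game_type))
    s <- b$strata
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %s: observed %.1f%% (n=%d), set %.0f%%\n",
                  s$stratum[i], 100 * s$observed_p[i], s$n[i],
                  100 * s$set_p[i]))
    }
    if (!is.null(b$independence)) {
      cat(sprintf(
        "    after-win %.1f%% vs after-loss %.1f%% (diff CI %.3f..%.3f)\n",
        100 * b$independence$p_after_win, 100 * b$independence$p_after_loss,
        b$independence$conf.low, b$independence$conf.high
      ))
    }
    if (!is.null(b$balance)) {
      ch <- b$balance$change
      cat(sprintf(
        "    per-trial change %.3f (CI %.2f..%.2f; expected %.2f); RTP %.2f\n",
        ch$mean_change, ch$conf.low, ch$conf.high, ch$expected_change,
        b$balance$implied_rtp
      ))
    }
  }
  invisible(x)
}

#' @export
tidy.mechanics_report <- function(x, ...) {
  purrr::map_dfr(x$blocks, function(b) {
    dplyr::mutate(b$strata, block_index = b$block_index,
                  game_type = b$game_type, .before = 1)
  })
}

#' @export
glance.mechanics_report <- function(x, ...) {
  slot <- purrr::detect(x$blocks, ~ .x$game_type == "slot")
  indep <- purrr::detect(x$blocks, ~ !is.null(.x$independence))
  tibble::tibble(
    arm_id = x$arm_id,
    n_trials = x$n_trials,
    p_after_win = if (!is.null(indep)) indep$independence$p_after_win
                  else NA_real_,
    p_after_loss = if (!is.null(indep)) indep$independence$p_after_loss
                   else NA_real_,
    mean_balance_change = if (!is.null(slot)) slot$balance$change$mean_change
                          else NA_real_,
    implied_rtp = if (!is.null(slot)) slot$balance$implied_rtp else NA_real_
  )
}
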