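#' Trial-log and event-log column layouts
#'
#' Every gamble produces one long-format row with columns `study_id`,
#' `timestamp_ms`, `arm_id`, `game_type`, `block_index`, `trial_number`,
#' `balance_in`, `theme_id`, `response`, `outcome`, `outcome_credit`,
#' `balance_out`. Messages shown between games are logged separately as
#' typed events (`study_id`, `timestamp_ms`, `event_type`, `payload`), not
#' as trials.
#'
#' @name trial_log
#' @keywords internal
NULL

trial_log_columns <- c(
  "study_id", "timestamp_ms", "arm_id", "game_type", "block_index",
  "trial_number", "balance_in", "theme_id", "response", "outcome",
  "outcome_credit", "balance_out"
)

event_log_columns <- c("study_id", "timestamp_ms", "event_type", "payload")

empty_trial_log <- function() {
  tibble::tibble(
    study_id = character(), timestamp_ms = numeric(), arm_id = character(),
    game_type = character(), block_index = integer(),
    trial_number = integer(), balance_in = numeric(),
    theme_id = character(), response = character(), outcome = character(),
    outcome_credit = numeric(), balance_out = numeric()
  )
}

legal_responses <- function(block) {
  if (block$game_type == "slot") "spin"
  else purrr::map_chr(block$options, "option_id")
}

#' Draw the displayed theme for one slot trial
#'
#' Themes are sampled independently on every trial (with replacement)
#' according to their display probabilities, so the realized stimulus
#' stream carries no sequential structure.
#'
#' @param block A slot [game_block()].
#' @return A single `theme_id`.
#' @export
sample_theme <- function(block) {
  if (block$game_type != "slot") {
    stop_casino("sample_theme() requires a slot block",
                "casinosim_contract_error")
  }
  ids <- purrr::map_chr(block$themes, "theme_id")
  probs <- purrr::map_dbl(block$themes, "display_probability")
  if (length(ids) == 1L) return(ids)
  sample(ids, 1L, prob = probs)
}

#' Resolve a single gamble
#'
#' The outcome is a fresh Bernoulli draw at the win probability of the
#' chosen option (choice games) or of the displayed theme (slot), so draws
#' are made with replacement exactly as in live casino play. Balance
#' accounting follows `balance_out = balance_in - bet_size + outcome_credit`
#' with `outcome_credit = 0` on a loss and `win_amount` (plus the bet when
#' `bet_returned_on_win`) on a win.
#'
#' @param state A session-state list with at least `study_id`, `arm_id`,
#'   `balance` and `clock_ms` (see [run_session()]).
#' @param response The chosen `option_id`, or `"spin"` for slot blocks.
#' @param block The [game_block()] being played.
#' @param block_index 0-based index of the block within the session.
#' @param trial_number 1-based trial index within the block.
#' @return A one-row trial-log tibble.
#' @export
resolve_trial <- function(state, response, block, block_index = 0L,
                          trial_number = 1L) {
  legal <- legal_responses(block)
  if (!response %in% legal) {
    stop_casino(
      sprintf("illegal response '%s'; legal responses: %s",
              response, paste(legal, collapse = ", ")),
      "casinosim_contract_error"
    )
  }
  theme_id <- NA_character_
  if (block$game_type == "slot") {
    theme_id <- sample_theme(block)
    th <- block$themes[[match(theme_id, purrr::map_chr(block$themes,
                                                       "theme_id"))]]
    p <- th$win_probability
    amount <- th$win_amount
  } else {
    op <- block$options[[match(response, legal)]]
    p <- op$win_probability
    amount <- op$win_amount
  }
  win <- runif(1L) < p
  credit <- if (win) amount + if (block$bet_returned_on_win) block$bet_size
            else 0 else 0
  tibble::tibble(
    study_id = state$study_id,
    timestamp_ms = state$clock_ms,
    arm_id = state$arm_id,
    game_type = block$game_type,
    block_index = as.integer(block_index),
    trial_number = as.integer(trial_number),
    balance_in = state$balance,
    theme_id = theme_id,
    response = response,
    outcome = if (win) "win" else "loss",
    outcome_credit = credit,
    balance_out = state$balance - block$bet_size + credit
  )
}

# Fast internal block runner: pre-allocated vectors, one tibble per block.
run_block_impl <- function(state, block, policy, block_index) {
  n <- block$n_trials
  legal <- legal_responses(block)
  is_slot <- block$game_type == "slot"
  theme_ids <- if (is_slot) purrr::map_chr(block$themes, "theme_id")
  theme_p <- if (is_slot) purrr::map_dbl(block$themes, "display_probability")
  theme_win <- if (is_slot) purrr::map_dbl(block$themes, "win_probability")
  theme_amt <- if (is_slot) purrr::map_dbl(block$themes, "win_amount")
  opt_win <- if (!is_slot) purrr::map_dbl(block$options, "win_probability")
  opt_amt <- if (!is_slot) purrr::map_dbl(block$options, "win_amount")

  timestamp <- balance_in <- credit <- balance_out <- numeric(n)
  theme <- response <- outcome <- character(n)

  balance <- state$balance
  clock <- state$clock_ms
  prev_response <- state$prev_response
  prev_outcome <- state$prev_outcome
  bet <- block$bet_size
  returned <- block$bet_returned_on_win

  for (t in seq_len(n)) {
    obs <- list(
      game_type = block$game_type,
      block_index = block_index,
      trial_number = t,
      options = legal,
      balance = if (block$show_balance) balance else NA_real_,
      prev_response = prev_response,
      prev_outcome = prev_outcome
    )
    act <- policy$respond(obs)
    resp <- act$response
    if (!resp %in% legal) {
      stop_casino(
        sprintf("policy '%s' returned illegal response '%s'; legal: %s",
                policy$policy_id, resp, paste(legal, collapse = ", ")),
        "casinosim_contract_error"
      )
    }
    if (is_slot) {
      j <- if (length(theme_ids) == 1L) 1L
           else sample.int(length(theme_ids), 1L, prob = theme_p)
      theme[t] <- theme_ids[j]
      p <- theme_win[j]
      amount <- theme_amt[j]
    } else {
      j <- match(resp, legal)
      theme[t] <- NA_character_
      p <- opt_win[j]
      amount <- opt_amt[j]
    }
    win <- runif(1L) < p
    cr <- if (win) amount + (if (returned) bet else 0) else 0
    clock <- clock + act$latency_ms
    timestamp[t] <- clock
    balance_in[t] <- balance
    response[t] <- resp
    outcome[t] <- if (win) "win" else "loss"
    credit[t] <- cr
    balance_out[t] <- balance - bet + cr
    balance <- balance_out[t]
    prev_response <- resp
    prev_outcome <- outcome[t]
  }

  records <- tibble::tibble(
    study_id = state$study_id,
    timestamp_ms = timestamp,
    arm_id = state$arm_id,
    game_type = block$game_type,
    block_index = as.integer(block_index),
    trial_number = seq_len(n),
    balance_in = balance_in,
    theme_id = theme,
    response = response,
    outcome = outcome,
    outcome_credit = credit,
    balance_out = balance_out
  )
  state$balance <- balance
  state$clock_ms <- clock
  state$prev_response <- prev_response
  state$prev_outcome <- prev_outcome
  list(records = records, state = state)
}

#' Run one game block under an agent policy
#'
#' @param state Session-state list (see [run_session()]); a fresh state can
#'   be built with `new_session_state()`.
#' @param block A [game_block()].
#' @param policy An [agent_policy()] supplying a response and latency per
#'   trial.
#' @param block_index 0-based block index recorded in the log.
#' @return A list with `records` (trial-log tibble, one row per trial) and
#'   the advanced `state`.
#' @export
run_block <- function(state, block, policy, block_index = 0L) {
  run_block_impl(state, block, policy, as.integer(block_index))
}

#' @rdname run_block
#' @param study_id Anonymous participant identifier.
#' @param arm_id Arm label recorded in the log.
#' @param starting_balance Credits at session start.
#' @export
new_session_state <- function(study_id, arm_id, starting_balance) {
  list(
    study_id = study_id, arm_id = arm_id, balance = starting_balance,
    clock_ms = 0, prev_response = NA_character_,
    prev_outcome = NA_character_
  )
}

#' Run a complete participant session
#'
#' Allocates an arm, then plays the arm's blocks in order under the given
#' policy, logging every gamble in long format and every message as a typed
#' event. The whole session is a pure function of `(design, policy, seed)`:
#' the same triple reproduces the identical record stream.
#'
#' @param design A valid [casino_design()].
#' @param policy An [agent_policy()].
#' @param survey Optional one-row survey tibble attached to the session.
#' @param seed Integer seed for the session's private RNG stream.
#' @param study_id Anonymous identifier; defaults to `"P1"`.
#' @return A `participant_session` object: a list with `study_id`,
#'   `arm_id`, `seed`, `survey`, `trials` (trial-log tibble) and `events`
#'   (event-log tibble).
#' @examples
#' s <- run_session(replication_design(), random_responder(), seed = 1)
#' nrow(s$trials) # 96
#' @export
run_session <- function(design, policy, survey = NULL, seed = 1L,
                        study_id = "P1") {
  assert_valid_design(design)
  withr::with_seed(as.integer(seed), {
    arm_id <- allocate_arm(design)
    arm <- design$arms[[match(arm_id, purrr::map_chr(design$arms, "arm_id"))]]
    state <- new_session_state(study_id, arm_id, arm$starting_balance)
    events <- list(
      tibble::tibble(study_id = study_id, timestamp_ms = state$clock_ms,
                     event_type = "session_start", payload = arm_id)
    )
    trials <- vector("list", length(arm$blocks))
    for (i in seq_along(arm$blocks)) {
      blk <- arm$blocks[[i]]
      if (!is.null(blk$pre_block_message)) {
        events[[length(events) + 1L]] <- tibble::tibble(
          study_id = study_id, timestamp_ms = state$clock_ms,
          event_type = "message_pre_block", payload = blk$pre_block_message
        )
      }
      res <- run_block_impl(state, blk, policy, i - 1L)
      trials[[i]] <- res$records
      state <- res$state
    }
    if (!is.null(arm$end_message)) {
      events[[length(events) + 1L]] <- tibble::tibble(
        study_id = study_id, timestamp_ms = state$clock_ms,
        event_type = "message_end", payload = arm$end_message
      )
    }
    structure(
      list(
        study_id = study_id, arm_id = arm_id, seed = as.integer(seed),
        survey = survey, trials = dplyr::bind_rows(trials),
        events = dplyr::bind_rows(events)
      ),
      class = "participant_session"
    )
  })
}

#' @export
print.participant_session <- function(x, ...) {
  cat(sprintf(
    "<participant_session> %s (arm %s, seed %d): %d trials, final balance %g\n",
    x$study_id, x$arm_id, x$seed, nrow(x$trials),
    if (nrow(x$trials)) x$trials$balance_out[nrow(x$trials)] else NA_real_
  ))
  invisible(x)
}

#' @export
tidy.participant_session <- function(x, ...) x$trials

# Marginal per-trial win probability and expected payout for a block.
# Choice blocks require a common win probability and amount across options
# (otherwise the marginal depends on the agent's choices).
block_marginals <- function(block) {
  if (block$game_type == "slot") {
    freq <- purrr::map_dbl(block$themes, "display_probability")
    p <- purrr::map_dbl(block$themes, "win_probability")
    amt <- purrr::map_dbl(block$themes, "win_amount")
  } else {
    p <- purrr::map_dbl(block$options, "win_probability")
    amt <- purrr::map_dbl(block$options, "win_amount")
    if (length(unique(p)) > 1L || length(unique(amt)) > 1L) {
      stop_casino(
        "marginal win probability undefined: options differ in probability or amount",
        "casinosim_contract_error"
      )
    }
    freq <- c(1, rep(0, length(p) - 1L))
  }
  payout <- amt + if (block$bet_returned_on_win) block$bet_size else 0
  list(
    p_bar = sum(freq * p),
    expected_payout = sum(freq * p * payout),
    payout = payout
  )
}

#' Closed-form expected balance trajectory
#'
#' For a block with marginal win probability `p` (theme-weighted for slot
#' blocks) and per-win payout `w` (win amount plus the bet when it is
#' returned), the expected balance after trial `t` is
#' `B_0 - t * (bet - p * w)`: a straight line whose slope is the negative
#' expected per-trial loss.
#'
#' @param block A [game_block()].
#' @param starting_balance Balance before the first trial of the block.
#' @return A tibble with `trial` (1..n_trials) and `expected_balance`.
#' @examples
#' # bet 10, win 20, marginal p 0.35: expected decline 3 credits per trial
#' b <- replication_design()$arms[[1]]$blocks[[2]]
#' expected_balance_trajectory(b, 1000)
#' @export
expected_balance_trajectory <- function(block, starting_balance) {
  m <- block_marginals(block)
  t <- seq_len(block$n_trials)
  tibble::tibble(
    trial = t,
    expected_balance = starting_balance - t * (block$bet_size -
                                                 m$expected_payout)
  )
}

#' Return-to-player rate of a block
#'
#' RTP is the expected credits returned per credit wagered:
#' `p * payout / bet`, with the payout including the returned bet when
#' `bet_returned_on_win` is set. An RTP below 1 means the house wins on
#' average.
#'
#' @inheritParams expected_balance_trajectory
#' @return A single number.
#' @examples
#' b <- replication_design()$arms[[1]]$blocks[[2]]
#' return_to_player(b) # 0.7
#' @export
return_to_player <- function(block) {
  if (block$bet_size <= 0) {
    stop_casino("return_to_player undefined for bet_size <= 0",
                "casinosim_contract_error")
  }
  block_marginals(block)$expected_payout / block$bet_size
}
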