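# Shared fixtures, all built in code.

# Two-option card block, equal probabilities (replacement-audit setting).
card_block <- function(p = 0.45, n_trials = 40, bet = 10, win = 20,
                       returned = FALSE) {
  game_block(
    "card", n_trials = n_trials, bet_size = bet,
    options = list(option_spec("deck_left", p, win),
                   option_spec("deck_right", p, win)),
    bet_returned_on_win = returned
  )
}

slot_block <- function(p1 = 0.5, p2 = 0.2, f1 = 0.5, n_trials = 40,
                       bet = 10, win = 20) {
  game_block(
    "slot", n_trials = n_trials, bet_size = bet,
    themes = list(theme_spec("S1", f1, p1, win),
                  theme_spec("S2", 1 - f1, p2, win))
  )
}

one_block_design <- function(block, starting_balance = 1000,
                             design_id = "test") {
  casino_design(design_id, list(
    arm_spec("A", 100, starting_balance, list(block))
  ))
}

# A hand-buildable trial log with chosen outcome sequences, one row per
# trial, enough columns for the audit functions.
manual_log <- function(outcomes, study_id = "P001", game_type = "card",
                       theme_id = NA_character_, response = "deck_left",
                       bet = 10, win_amount = 20, start = 1000) {
  n <- length(outcomes)
  credit <- ifelse(outcomes == "win", win_amount, 0)
  delta <- -bet + credit
  balance_out <- start + cumsum(delta)
  tibble::tibble(
    study_id = study_id,
    timestamp_ms = seq_len(n) * 1000,
    arm_id = "A",
    game_type = game_type,
    block_index = 0L,
    trial_number = seq_len(n),
    balance_in = balance_out - delta,
    theme_id = theme_id,
    response = response,
    outcome = outcomes,
    outcome_credit = credit,
    balance_out = balance_out
  )
}

# A deterministic policy cycling through given responses (for choice games).
scripted_policy <- function(responses) {
  i <- 0L
  agent_policy("scripted", function(state) {
    if (state$game_type == "slot") {
      return(list(response = "spin", latency_ms = 1000))
    }
    i <<- i + 1L
    list(response = responses[(i - 1L) %% length(responses) + 1L],
         latency_ms = 1000)
  })
}
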