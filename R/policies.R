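#' Agent policies: synthetic participant behavior
#'
#' An agent policy maps the game state visible to a participant (game type,
#' legal options, trial number, previous response and outcome, balance if
#' shown) to a response and a response latency in milliseconds. Policies are
#' the behavioral half of the synthetic-participant generator; the bundled
#' ones span the quality spectrum the screening tools are designed to
#' separate.
#'
#' @param policy_id Label recorded in reports.
#' @param respond Function taking the observable state list and returning
#'   `list(response = <chr>, latency_ms = <positive numeric>)`.
#' @return A list of class `agent_policy`.
#' @export
agent_policy <- function(policy_id, respond) {
  structure(list(policy_id = policy_id, respond = respond),
            class = "agent_policy")
}

#' @export
print.agent_policy <- function(x, ...) {
  cat("<agent_policy>", x$policy_id, "\n")
  invisible(x)
}

# Per-trial response latencies are log-normal. The default median of 5.5 s
# per trial puts a 96-trial session near a 10-minute completion time, the
# scale typical of crowdsourced sessions of this length.
latency_sampler <- function(median_ms = 5500, sdlog = 0.5) {
  meanlog <- log(median_ms)
  function() rlnorm(1L, meanlog = meanlog, sdlog = sdlog)
}

#' Random responder: independent choices every trial
#'
#' Chooses the first listed option with probability `p_first` and otherwise
#' one of the remaining options uniformly; slot blocks always receive
#' `"spin"`. This is the well-behaved participant model: response variation
#' concentrates near `p_first` and is essentially never flagged by the
#' 10-90% screening rule at 40 trials.
#'
#' @param p_first Probability of choosing the first option (default 0.5).
#' @param median_latency_ms Median per-trial response latency.
#' @param latency_sdlog Log-scale SD of the latency distribution.
#' @return An [agent_policy()].
#' @export
random_responder <- function(p_first = 0.5, median_latency_ms = 5500,
                             latency_sdlog = 0.5) {
  stopifnot(p_first >= 0, p_first <= 1)
  lat <- latency_sampler(median_latency_ms, latency_sdlog)
  agent_policy(
    sprintf("random_responder(p_first=%g)", p_first),
    function(state) {
      resp <- if (state$game_type == "slot") "spin"
      else if (length(state$options) == 1L || runif(1L) < p_first)
        state$options[[1L]]
      else sample(state$options[-1L], 1L)
      list(response = resp, latency_ms = lat())
    }
  )
}

#' Repetitive responder: indiscriminate single-option play
#'
#' Always returns the same option (the block's first, unless `fixed_option`
#' is given), emulating the poor-quality worker who clicks through the task
#' as fast as possible. Such sessions have zero response entropy and a
#' variation score of 100%, so they are always flagged by the 10-90% rule.
#'
#' @param fixed_option Option label to repeat; defaults to the first legal
#'   option of each block.
#' @param median_latency_ms Median per-trial latency (defaults faster than
#'   [random_responder()], as indiscriminate responders rush).
#' @param latency_sdlog Log-scale SD of the latency distribution.
#' @return An [agent_policy()].
#' @export
repetitive_responder <- function(fixed_option = NULL,
                                 median_latency_ms = 2500,
                                 latency_sdlog = 0.4) {
  lat <- latency_sampler(median_latency_ms, latency_sdlog)
  agent_policy(
    "repetitive_responder",
    function(state) {
      resp <- if (state$game_type == "slot") "spin"
      else if (!is.null(fixed_option) && fixed_option %in% state$options)
        fixed_option
      else state$options[[1L]]
      list(response = resp, latency_ms = lat())
    }
  )
}

#' Win-stay / lose-shift responder
#'
#' After a win, repeats the previous response with probability `stay_prob`;
#' after a loss, switches to the other option with probability `shift_prob`.
#' The first choice of each block is uniform. With
#' `stay_prob = shift_prob = 0.5` this reduces to a fair random responder.
#' The policy exists to give the mechanics audits a behaviorally dependent
#' response stream: outcome draws must remain independent even when
#' responses are sequentially structured.
#'
#' @param stay_prob Probability of repeating the previous response after a
#'   win.
#' @param shift_prob Probability of switching after a loss.
#' @inheritParams random_responder
#' @return An [agent_policy()].
#' @export
win_stay_lose_shift <- function(stay_prob = 0.8, shift_prob = 0.8,
                                median_latency_ms = 5500,
                                latency_sdlog = 0.5) {
  stopifnot(stay_prob >= 0, stay_prob <= 1, shift_prob >= 0, shift_prob <= 1)
  lat <- latency_sampler(median_latency_ms, latency_sdlog)
  agent_policy(
    sprintf("win_stay_lose_shift(stay=%g, shift=%g)", stay_prob, shift_prob),
    function(state) {
      resp <- if (state$game_type == "slot") {
        "spin"
      } else if (is.na(state$prev_response) ||
                 !state$prev_response %in% state$options) {
        sample(state$options, 1L)
      } else {
        other <- setdiff(state$options, state$prev_response)
        if (length(other) == 0L) {
          state$prev_response
        } else if (identical(state$prev_outcome, "win")) {
          if (runif(1L) < stay_prob) state$prev_response
          else sample(other, 1L)
        } else {
          if (runif(1L) < shift_prob) sample(other, 1L)
          else state$prev_response
        }
      }
      list(response = resp, latency_ms = lat())
    }
  )
}
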