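#' Cohort specification for synthetic participants
#'
#' Pairs a policy mixture (which behavioral policies occur, in what
#' proportions) with a survey-generation model. The default mixture is 94%
#' fair random responders and 6% repetitive responders, the split observed
#' in crowdsourced validation data of this task length.
#'
#' @param n_participants Number of participants.
#' @param policies List of policy factories: functions of no arguments
#'   returning a fresh [agent_policy()] per participant.
#' @param proportions Mixture proportions (must sum to 1).
#' @param survey_model A [survey_gen_model()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 101,
                        policies = list(
                          function() random_responder(),
                          function() repetitive_responder()
                        ),
                        proportions = c(0.94, 0.06),
                        survey_model = survey_gen_model()) {
  if (length(policies) != length(proportions)) {
    stop_casino("policies and proportions must have equal length",
                "casinosim_contract_error")
  }
  if (abs(sum(proportions) - 1) > 1e-9 || any(proportions < 0)) {
    stop_casino("mixture proportions must be nonnegative and sum to 1",
                "casinosim_contract_error")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      policies = policies,
      proportions = proportions,
      survey_model = survey_model
    ),
    class = "cohort_spec"
  )
}

#' Generate a full synthetic cohort
#'
#' Draws one survey row and runs one complete session per participant.
#' Policies are assigned by the mixture, each participant gets a private
#' RNG sub-seed derived from `seed`, and the result is a pure function of
#' `(design, spec, seed)`.
#'
#' @param design A valid [casino_design()].
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @return A `casino_cohort` object: list with `sessions` (list of
#'   `participant_session`), `survey` (tibble), `trials` (combined
#'   trial-log tibble), `events` (combined event log) and `policy_ids`
#'   (character vector of assigned policy labels).
#' @examples
#' co <- generate_cohort(replication_design(), cohort_spec(n_participants = 5),
#'                       seed = 1)
#' nrow(co$trials) # 5 * 96
#' @export
generate_cohort <- function(design, spec = cohort_spec(), seed = 1L) {
  assert_valid_design(design)
  n <- spec$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  survey <- generate_survey_cohort(spec$survey_model, n,
                                   seed = derive_seeds(seed, 1L),
                                   study_ids = ids)
  seeds <- derive_seeds(seed + 1L, n)
  assignment <- withr::with_seed(
    as.integer(seed) + 2L,
    sample.int(length(spec$policies), n, replace = TRUE,
               prob = spec$proportions)
  )
  sessions <- vector("list", n)
  policy_ids <- character(n)
  for (i in seq_len(n)) {
    policy <- withr::with_seed(seeds[i], spec$policies[[assignment[i]]]())
    policy_ids[i] <- policy$policy_id
    sessions[[i]] <- run_session(
      design, policy, survey = survey[i, ], seed = seeds[i],
      study_id = ids[i]
    )
  }
  structure(
    list(
      sessions = sessions,
      survey = survey,
      trials = dplyr::bind_rows(purrr::map(sessions, "trials")),
      events = dplyr::bind_rows(purrr::map(sessions, "events")),
      policy_ids = policy_ids,
      seed = as.integer(seed)
    ),
    class = "casino_cohort"
  )
}

#' @export
print.casino_cohort <- function(x, ...) {
  cat(sprintf(
    "<casino_cohort> %d participants, %d trials, seed %d\n",
    length(x$sessions), nrow(x$trials), x$seed
  ))
  invisible(x)
}

#' @export
tidy.casino_cohort <- function(x, ...) x$trials

#' @export
glance.casino_cohort <- function(x, ...) {
  tibble::tibble(
    n_participants = length(x$sessions),
    n_trials = nrow(x$trials),
    n_survey_rows = nrow(x$survey),
    seed = x$seed
  )
}
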