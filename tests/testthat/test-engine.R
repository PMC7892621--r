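test_that("single-trial accounting follows the payout convention", {
  st <- new_session_state("P1", "A", 1000)
  blk_never <- card_block(p = 0)
  blk_always <- card_block(p = 1)
  blk_ret <- card_block(p = 1, returned = TRUE)

  withr::with_seed(1, {
    r <- resolve_trial(st, "deck_left", blk_never)
    expect_equal(r$outcome, "loss")
    expect_equal(r$outcome_credit, 0)
    expect_equal(r$balance_out, 1000 - 10)

    r2 <- resolve_trial(st, "deck_left", blk_always)
    expect_equal(r2$outcome, "win")
    expect_equal(r2$outcome_credit, 20)
    expect_equal(r2$balance_out - r2$balance_in, 10) # net +10, bet kept

    r3 <- resolve_trial(st, "deck_right", blk_ret)
    expect_equal(r3$outcome_credit, 30)
    expect_equal(r3$balance_out - r3$balance_in, 20) # net +20, bet returned
  })

  expect_error(resolve_trial(st, "deck_middle", blk_never),
               "deck_left, deck_right",
               class = "casinosim_contract_error")
  expect_error(sample_theme(blk_never), class = "casinosim_contract_error")
})

test_that("run_block produces n chained records and extinction never pays", {
  st <- new_session_state("P1", "A", 1000)
  res <- withr::with_seed(2, run_block(st, card_block(p = 0, n_trials = 40),
                                       random_responder()))
  expect_equal(nrow(res$records), 40L)
  expect_equal(res$records$trial_number, 1:40)
  expect_true(all(res$records$outcome == "loss"))
  # chaining: balance_out of t equals balance_in of t+1
  expect_equal(res$records$balance_in[-1],
               res$records$balance_out[-40])
  expect_equal(res$state$balance, 1000 - 400)
  # balance conservation at every trial
  expect_equal(res$records$balance_out - res$records$balance_in,
               -10 + res$records$outcome_credit)
  # clock strictly increases by positive latencies
  expect_true(all(diff(res$records$timestamp_ms) > 0))
})

test_that("a session replays the design and is seed-deterministic", {
  d <- replication_design()
  s <- run_session(d, random_responder(), seed = 5)
  expect_equal(nrow(s$trials), 96L)
  expect_equal(as.integer(table(s$trials$block_index)[c("0", "1", "2")]),
               c(40L, 40L, 16L))
  expect_true(all(s$trials$response[s$trials$game_type == "slot"] == "spin"))
  expect_true(all(s$trials$outcome[s$trials$block_index == 2] == "loss"))
  expect_identical(run_session(d, random_responder(), seed = 5)$trials,
                   s$trials)
  # messages logged as events, not trials
  expect_setequal(
    unique(s$events$event_type),
    c("session_start", "message_pre_block", "message_end")
  )
  expect_equal(sum(s$events$event_type == "message_pre_block"), 2L)

  co <- generate_cohort(d, cohort_spec(n_participants = 101), seed = 3)
  expect_equal(nrow(co$trials), 9696L)
  co2 <- generate_cohort(d, cohort_spec(n_participants = 101), seed = 3)
  expect_identical(co$trials, co2$trials)
  expect_identical(co$survey, co2$survey)
})

test_that("theme sampling matches display probabilities and is lag-independent", {
  blk1 <- game_block("slot", 5, 10,
                     themes = list(theme_spec("only", 1, 0.3, 20)))
  expect_equal(sample_theme(blk1), "only")

  blk <- slot_block()
  draws <- withr::with_seed(21, replicate(4040, sample_theme(blk)))
  expect_lt(abs(mean(draws == "S1") - 0.5), 3 * sqrt(0.25 / 4040))

  big <- withr::with_seed(22, replicate(100000, sample_theme(blk)))
  prev <- big[-length(big)]
  curr <- big[-1]
  p_cond <- mean(curr[prev == "S1"] == "S1")
  p_marg <- mean(curr == "S1")
  n1 <- sum(prev == "S1")
  expect_lt(abs(p_cond - p_marg), 3 * sqrt(0.25 / n1))
})

test_that("outcome draws are made with replacement in long engine runs", {
  d <- one_block_design(card_block(p = 0.45, n_trials = 100000))
  s <- run_session(d, random_responder(), seed = 31)
  chk <- replacement_independence_check(s$trials)
  pooled_se <- sqrt(0.45 * 0.55 * (1 / chk$n_after_win +
                                     1 / chk$n_after_loss))
  expect_lt(abs(chk$difference), 3 * pooled_se)
})

test_that("closed-form expectations match the programmed schedule", {
  blk <- slot_block() # bet 10, win 20, marginal p 0.35
  traj <- expected_balance_trajectory(blk, 1000)
  expect_equal(diff(traj$expected_balance), rep(-3, 39))
  expect_equal(return_to_player(blk), 0.7)

  fair <- card_block(p = 0.5, n_trials = 10) # p * payout = bet
  expect_equal(
    unique(round(expected_balance_trajectory(fair, 500)$expected_balance, 9)),
    500
  )
  expect_equal(return_to_player(card_block(p = 0)), 0)
  expect_equal(return_to_player(card_block(p = 0.35, returned = TRUE)),
               0.35 * 30 / 10)

  # marginal undefined when options differ
  mixed <- game_block("card", 5, 10,
                      options = list(option_spec("a", 0.5, 20),
                                     option_spec("b", 0.1, 20)))
  expect_error(return_to_player(mixed), class = "casinosim_contract_error")
})
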