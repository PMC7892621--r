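# brute-force oracle: count win rates conditional on the previous outcome
# within each (participant, block), by direct enumeration
brute_conditional <- function(trials) {
  after_win <- c(0L, 0L)  # wins, n
  after_loss <- c(0L, 0L)
  for (id in unique(trials$study_id)) {
    for (bi in unique(trials$block_index[trials$study_id == id])) {
      o <- trials$outcome[trials$study_id == id &
                            trials$block_index == bi]
      o <- o[order(trials$trial_number[trials$study_id == id &
                                         trials$block_index == bi])]
      for (t in seq_along(o)[-1]) {
        if (o[t - 1] == "win") {
          after_win <- after_win + c(o[t] == "win", 1L)
        } else {
          after_loss <- after_loss + c(o[t] == "win", 1L)
        }
      }
    }
  }
  list(p_after_win = after_win[1] / after_win[2], n_after_win = after_win[2],
       p_after_loss = after_loss[1] / after_loss[2],
       n_after_loss = after_loss[2])
}

test_that("stratified win rates are exact counts with Wilson intervals", {
  log <- dplyr::bind_rows(
    manual_log(c(rep("win", 3), rep("loss", 7)), game_type = "slot",
               theme_id = "A", response = "spin"),
    manual_log(rep("loss", 5), game_type = "slot", theme_id = "B",
               response = "spin", study_id = "P002")
  )
  r <- observed_win_rates(log, stratify_by = "theme")
  expect_equal(r$strata$observed_p[r$strata$stratum == "A"], 0.3)
  expect_equal(r$strata$observed_p[r$strata$stratum == "B"], 0)
  expect_equal(sum(r$strata$n), nrow(log))

  # Wilson CI against the prop.test score interval (no continuity corr.)
  ci <- wilson_ci(30, 100)
  ref <- prop.test(30, 100, correct = FALSE)$conf.int
  expect_equal(c(ci$conf.low, ci$conf.high), as.numeric(ref),
               tolerance = 1e-10)

  # option stratification uses the response column
  clog <- manual_log(rep(c("win", "loss"), 5))
  clog$response <- rep(c("deck_left", "deck_right"), each = 5)
  ro <- observed_win_rates(clog, stratify_by = "option")
  expect_setequal(ro$strata$stratum, c("deck_left", "deck_right"))
})

test_that("replacement audit matches brute-force enumeration on fixtures", {
  o <- c("win", "loss", "win", "win", "loss", "loss", "loss", "win",
         "loss", "win")
  log <- manual_log(o)
  chk <- replacement_independence_check(log)
  oracle <- brute_conditional(log)
  expect_equal(chk$p_after_win, oracle$p_after_win)   # 1/4
  expect_equal(chk$p_after_loss, oracle$p_after_loss) # 3/5
  expect_equal(chk$p_after_win, 0.25)
  expect_equal(chk$p_after_loss, 0.6)
  expect_equal(chk$n_after_win, 4L)
  expect_equal(chk$n_after_loss, 5L)

  # deterministic alternation is detected as maximal dependence
  alt <- manual_log(rep(c("win", "loss"), 10))
  chk_alt <- replacement_independence_check(alt)
  expect_equal(chk_alt$p_after_win, 0)
  expect_equal(chk_alt$p_after_loss, 1)
  expect_equal(chk_alt$difference, -1)

  # session boundaries never chain: same totals as per-participant oracle
  two <- dplyr::bind_rows(
    manual_log(c("loss", "win", "win")),
    manual_log(c("win", "loss", "loss"), study_id = "P002")
  )
  chk2 <- replacement_independence_check(two)
  oracle2 <- brute_conditional(two)
  expect_equal(chk2$n_after_win + chk2$n_after_loss, 4L)
  expect_equal(chk2$p_after_win, oracle2$p_after_win)
  expect_equal(chk2$p_after_loss, oracle2$p_after_loss)
})

test_that("marginal win probability is the display-weighted mixture", {
  expect_equal(marginal_win_probability(c(0.5, 0.5), c(0.5, 0.2)), 0.35)
  expect_equal(marginal_win_probability(c(0.515, 0.485), c(0.5, 0.2)),
               0.3545)
  expect_equal(marginal_win_probability(1, 0.3), 0.3)
  expect_error(marginal_win_probability(c(0.6, 0.5), c(0.5, 0.2)),
               class = "casinosim_contract_error")
})

test_that("audits flag injected violations of the programmed mechanics", {
  # Markov outcomes with a 20-point conditional gap must be caught
  markov_log <- function(n, p_after_win, p_after_loss, seed) {
    withr::with_seed(seed, {
      o <- character(n)
      o[1] <- if (runif(1) < 0.45) "win" else "loss"
      for (t in 2:n) {
        p <- if (o[t - 1] == "win") p_after_win else p_after_loss
        o[t] <- if (runif(1) < p) "win" else "loss"
      }
      manual_log(o)
    })
  }
  bad <- replacement_independence_check(markov_log(4000, 0.55, 0.35, 8))
  expect_gt(bad$conf.low, 0)   # dependence detected
  expect_lt(bad$p.value, 0.01)

  # wrong win probability must fall outside the Wilson interval
  wrong_p <- withr::with_seed(
    9, manual_log(ifelse(runif(4000) < 0.30, "win", "loss"),
                  game_type = "slot", theme_id = "S1", response = "spin")
  )
  ci <- observed_win_rates(wrong_p, "theme")$strata
  expect_lt(ci$conf.high, 0.45)
})

test_that("balance trajectories match the closed form on engine data", {
  # fair game: discrepancy interval covers zero
  fair <- one_block_design(card_block(p = 0.5, n_trials = 40))
  tr <- dplyr::bind_rows(lapply(1:40, function(i) {
    run_session(fair, random_responder(), seed = 600 + i,
                study_id = sprintf("P%03d", i))$trials
  }))
  an <- balance_trajectory_analysis(tr, card_block(p = 0.5, n_trials = 40),
                                    1000)
  expect_lt(an$discrepancy$conf.low, 0)
  expect_gt(an$discrepancy$conf.high, 0)
  expect_equal(an$change$expected_change, 0)

  # replication slot block at cohort scale: mean per-trial change within
  # 3 analytic SE of -3 (SD of a single change is 20 * sqrt(.35 * .65))
  d <- replication_design()
  co <- generate_cohort(d, cohort_spec(n_participants = 101), seed = 1)
  slot_trials <- dplyr::filter(co$trials, block_index == 1)
  blk <- d$arms[[1]]$blocks[[2]]
  start <- mean(slot_trials$balance_in[slot_trials$trial_number == 1])
  an2 <- balance_trajectory_analysis(slot_trials, blk, start)
  se <- 20 * sqrt(0.35 * 0.65) / sqrt(nrow(slot_trials))
  expect_lt(abs(an2$change$mean_change - (-3)), 3 * se)
  expect_true(an2$change$conf.low < an2$change$mean_change &&
                an2$change$mean_change < an2$change$conf.high)

  # early-win excess skews accumulated discrepancy but not per-trial change
  inject <- withr::with_seed(10, {
    dplyr::bind_rows(lapply(1:50, function(i) {
      o <- ifelse(runif(40) < 0.35, "win", "loss")
      o[3:8] <- "win" # planted early lucky streak
      manual_log(o, study_id = sprintf("P%03d", i), game_type = "slot",
                 theme_id = "S1", response = "spin")
    }))
  })
  blk35 <- game_block("slot", 40, 10,
                      themes = list(theme_spec("S1", 1, 0.35, 20)))
  an3 <- balance_trajectory_analysis(inject, blk35, 1000)
  expect_gt(an3$discrepancy$mean_discrepancy, 0)

  expect_error(
    balance_trajectory_analysis(inject, card_block(), 1000),
    class = "casinosim_contract_error"
  )
})

test_that("the bundled report ties the audits together", {
  d <- replication_design()
  co <- generate_cohort(d, cohort_spec(n_participants = 30), seed = 2)
  rep <- mechanics_report(co$trials, d)
  td <- tidy(rep)
  expect_true(all(c("stratum", "observed_p", "set_p") %in% names(td)))
  expect_equal(sum(td$n), nrow(co$trials))
  g <- glance(rep)
  expect_equal(g$implied_rtp, 0.7)
  expect_false(is.na(g$p_after_loss))

  # wrong-design pairing is rejected
  short <- one_block_design(card_block())
  expect_error(mechanics_report(co$trials, short),
               class = "casinosim_contract_error")
})
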