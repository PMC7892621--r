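test_that("a well-formed design validates cleanly and bad fields are named", {
  expect_equal(nrow(validate_design(replication_design())), 0L)

  d <- casino_design("bad", list(
    arm_spec("A", 60, 1000, list(card_block())),
    arm_spec("B", 50, 1000, list(card_block()))
  ))
  v <- validate_design(d)
  expect_true(any(grepl("sum to 110", v$message)))
  expect_true(any(v$field == "allocation_percent"))

  d2 <- one_block_design(game_block(
    "slot", n_trials = 10, bet_size = 10,
    themes = list(theme_spec("S1", 0.5, 0.5, 20),
                  theme_spec("S2", 0.4, 0.2, 20))
  ))
  v2 <- validate_design(d2)
  expect_true(any(grepl("sum to 0.9", v2$message)))

  # invariant violations on option fields are reported, not raised
  d3 <- one_block_design(game_block(
    "card", n_trials = 5, bet_size = 10,
    options = list(option_spec("a", 1.2, 20), option_spec("b", 0.5, -1))
  ))
  v3 <- validate_design(d3)
  expect_true(any(grepl("win_probability outside", v3$message)))
  expect_true(any(grepl("win_amount must be", v3$message)))
})

test_that("arm allocation follows the design percentages", {
  d1 <- one_block_design(card_block())
  expect_true(all(allocate_arm(d1, 50) == "A"))

  d2 <- casino_design("two", list(
    arm_spec("A", 50, 1000, list(card_block())),
    arm_spec("B", 50, 1000, list(card_block()))
  ))
  draws <- withr::with_seed(11, allocate_arm(d2, 10000))
  expect_lt(abs(mean(draws == "A") - 0.5), 3 * sqrt(0.25 / 10000))

  d3 <- casino_design("skew", list(
    arm_spec("A", 80, 1000, list(card_block())),
    arm_spec("B", 20, 1000, list(card_block()))
  ))
  draws3 <- withr::with_seed(12, allocate_arm(d3, 10000))
  gof <- chisq.test(table(factor(draws3, c("A", "B"))), p = c(0.8, 0.2))
  expect_gt(gof$p.value, 0.001)

  bad <- casino_design("bad", list(arm_spec("A", 70, 1000,
                                            list(card_block()))))
  expect_error(allocate_arm(bad), class = "casinosim_invalid_design")
})

test_that("design serialization round-trips and parse errors name the key", {
  path <- system.file("extdata", "designs", "validation_replication.yaml",
                      package = "casinosim")
  d <- load_design(path)
  expect_equal(nrow(validate_design(d)), 0L)
  expect_equal(d$design_id, "validation_replication")
  expect_equal(sum(purrr::map_int(d$arms[[1]]$blocks, "n_trials")), 96L)

  # property: save -> load is the identity, YAML and JSON alike
  random_design <- function(seed) {
    withr::with_seed(seed, {
      n_arms <- sample(1:3, 1)
      alloc <- as.numeric(rmultinom(1, 100, rep(1, n_arms)))
      if (any(alloc == 0)) alloc <- rep(100 / n_arms, n_arms)
      casino_design(paste0("rand", seed), purrr::map(seq_len(n_arms),
        function(i) {
          blocks <- purrr::map(seq_len(sample(1:3, 1)), function(j) {
            if (runif(1) < 0.5) {
              card_block(p = round(runif(1), 3),
                         n_trials = sample(1:50, 1),
                         returned = runif(1) < 0.5)
            } else {
              f <- round(runif(1, 0.1, 0.9), 3)
              game_block("slot", n_trials = sample(1:50, 1), bet_size = 5,
                         themes = list(theme_spec("T1", f, 0.4, 10),
                                       theme_spec("T2", 1 - f, 0.1, 10)))
            }
          })
          arm_spec(LETTERS[i], alloc[i], sample(100:2000, 1), blocks)
        }))
    })
  }
  for (seed in 1:5) {
    d0 <- random_design(seed)
    for (ext in c(".yaml", ".json")) {
      f <- withr::local_tempfile(fileext = ext)
      save_design(d0, f)
      expect_equal(load_design(f), d0, ignore_attr = FALSE)
    }
  }

  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(design_id = "x", arms = list(list(
    arm_id = "A", allocation_percent = 100, starting_balance = 10,
    blocks = list(list(game_type = "poker", n_trials = 1, bet_size = 1))
  ))), f)
  expect_error(load_design(f), "game_type",
               class = "casinosim_parse_error")

  yaml::write_yaml(list(design_id = "x", arms = list(list(
    arm_id = "A", allocation_percent = 100,
    blocks = list()
  ))), f)
  expect_error(load_design(f), "starting_balance",
               class = "casinosim_parse_error")

  expect_error(load_design("no/such/file.yaml"), "not found",
               class = "casinosim_parse_error")
})
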