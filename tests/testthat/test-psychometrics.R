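test_that("alpha matches direct formula evaluation and its invariances", {
  # 4 x 3 fixture evaluated by hand: item variances sum to 17/6,
  # total-score variance 7, alpha = (3/2) * (1 - (17/6)/7) = 0.8928571
  m <- matrix(c(1, 2, 3,
                2, 3, 3,
                0, 1, 2,
                3, 3, 3), nrow = 4, byrow = TRUE)
  expect_equal(cronbach_alpha(m), 0.8928571, tolerance = 1e-6)

  # perfectly consistent items
  x <- cbind(1:6, 1:6, 1:6)
  expect_equal(cronbach_alpha(x), 1)

  # invariant to adding a constant to an item, and to item order
  m2 <- m
  m2[, 2] <- m2[, 2] + 100
  expect_equal(cronbach_alpha(m2), cronbach_alpha(m))
  expect_equal(cronbach_alpha(m[, c(3, 1, 2)]), cronbach_alpha(m))

  expect_error(cronbach_alpha(m[, 1, drop = FALSE]),
               class = "casinosim_contract_error")
  expect_error(cronbach_alpha(matrix(1, 5, 3)),
               class = "casinosim_contract_error")

  # tau-equivalent closed form at large n
  lam <- 0.8
  pop <- 9 * lam^2 / (1 + 8 * lam^2)
  x5 <- simulate_factor_items(5000, rep(lam, 9), seed = 42)
  expect_lt(abs(cronbach_alpha(x5) - pop), 0.01)
})

test_that("alpha intervals are sane across methods and degenerate n", {
  x <- simulate_factor_items(200, rep(0.8, 9), seed = 7)
  feldt <- alpha_confidence_interval(x)
  boot <- alpha_confidence_interval(x, method = "bootstrap", n_boot = 400,
                                    seed = 3)
  expect_true(feldt$conf.low < feldt$alpha && feldt$alpha < feldt$conf.high)
  expect_true(boot$conf.low < boot$alpha && boot$alpha < boot$conf.high)
  # the two intervals overlap
  expect_lt(max(feldt$conf.low, boot$conf.low),
            min(feldt$conf.high, boot$conf.high))

  tiny <- alpha_confidence_interval(simulate_factor_items(3, rep(0.7, 5),
                                                          seed = 1))
  expect_true(all(is.finite(c(tiny$conf.low, tiny$conf.high))))
  expect_gt(tiny$conf.high - tiny$conf.low, 0)
})

test_that("parallel analysis recovers planted dimensionality", {
  one <- simulate_factor_items(500, rep(0.8, 9), seed = 11)
  pa1 <- parallel_analysis(one, n_resamples = 300, seed = 12)
  expect_equal(pa1$n_components, 1L)

  noise <- withr::with_seed(13, matrix(rnorm(500 * 9), 500, 9))
  pa0 <- parallel_analysis(noise, n_resamples = 300, seed = 14)
  expect_equal(pa0$n_components, 0L)

  two <- simulate_factor_items(
    1000,
    cbind(c(rep(0.8, 4), rep(0, 5)), c(rep(0, 4), rep(0.8, 5))),
    seed = 15
  )
  pa2 <- parallel_analysis(two, n_resamples = 300, seed = 16)
  expect_equal(pa2$n_components, 2L)

  # retained count is non-increasing in the percentile
  counts <- vapply(c(50, 95, 99), function(p) {
    parallel_analysis(one, n_resamples = 300, percentile = p,
                      seed = 17)$n_components
  }, integer(1))
  expect_true(all(diff(counts) <= 0))

  # permutation null works on ordinal data
  svy <- generate_survey_cohort(survey_gen_model(), 500, seed = 18)
  pa_perm <- parallel_analysis(as.matrix(svy[paste0("pgsi_item_", 1:9)]),
                               n_resamples = 300, seed = 19,
                               method = "permute")
  expect_equal(pa_perm$n_components, 1L)

  expect_warning(parallel_analysis(matrix(rnorm(5 * 9), 5, 9),
                                   n_resamples = 50, seed = 1),
                 "more items")
})

test_that("Poisson IRLS agrees with a brute-force likelihood grid search", {
  svy <- generate_survey_cohort(survey_gen_model(), n = 50, seed = 21)
  svy$type_count <- rowSums(svy[gambling_type_labels()])
  fit <- glm(type_count ~ gambling_frequency, family = poisson(),
             data = svy)

  nll <- function(a, b) {
    mu <- exp(a + b * svy$gambling_frequency)
    -sum(dpois(svy$type_count, mu, log = TRUE))
  }
  # coarse-to-fine grid search, independent of glm
  a_grid <- seq(-2, 2, length.out = 81)
  b_grid <- seq(-1, 1, length.out = 81)
  for (step in 1:6) {
    vals <- outer(a_grid, b_grid, Vectorize(nll))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    a0 <- a_grid[ix[1]]; b0 <- b_grid[ix[2]]
    da <- diff(a_grid[1:2]); db <- diff(b_grid[1:2])
    a_grid <- seq(a0 - 2 * da, a0 + 2 * da, length.out = 41)
    b_grid <- seq(b0 - 2 * db, b0 + 2 * db, length.out = 41)
  }
  expect_lt(abs(coef(fit)[1] - a0), 1e-4)
  expect_lt(abs(coef(fit)[2] - b0), 1e-4)
})

test_that("association models recover planted and null effects", {
  # perfect linear fixture: slope exact, SE ~ 0
  perfect <- tibble::tibble(
    pgsi_total = 2 * rep(0:4, each = 10) + 1,
    gambling_frequency = rep(0:4, each = 10),
    type_count = rep(c(0, 1, 2, 3, 4), each = 10)
  )
  # lm warns about the essentially perfect fit; that is the point here
  est <- suppressWarnings(tidy(fit_severity_associations(perfect)))
  slope <- est[est$model == "pgsi_on_frequency" &
                 est$term == "gambling_frequency", ]
  expect_equal(slope$estimate, 2, tolerance = 1e-12)
  expect_lt(slope$std.error, 1e-10)

  # null generator: no spurious detections across seeded runs
  null_model <- survey_gen_model(pgsi_freq_slope = 1e-9,
                                 pgsi_intercept = 4.26,
                                 types_freq_slope = 0)
  n_bad <- sum(vapply(1:20, function(s) {
    svy <- generate_survey_cohort(null_model, n = 1000, seed = 1000 + s)
    est <- tidy(fit_severity_associations(svy))
    sl <- est[est$term %in% c("gambling_frequency", "type_count",
                              "no_gambling"), ]
    any(abs(sl$statistic) >= 3)
  }, logical(1)))
  expect_lte(n_bad, 1L)

  # constant predictor is named
  const <- tibble::tibble(pgsi_total = c(1, 2, 3),
                          gambling_frequency = c(1, 1, 1),
                          type_count = c(0, 1, 2))
  expect_error(fit_severity_associations(const), "gambling_frequency",
               class = "casinosim_contract_error")
})

test_that("the psychometrics report reproduces its own subsample recomputation", {
  svy <- generate_survey_cohort(survey_gen_model(), n = 800, seed = 31)
  rep <- psychometrics_report(svy, n_resamples = 200, seed = 32)
  items <- as.matrix(svy[paste0("pgsi_item_", 1:9)])
  expect_equal(rep$alpha_full$alpha, cronbach_alpha(items))
  nz <- svy$pgsi_total > 0
  expect_equal(rep$alpha_nonzero$alpha,
               cronbach_alpha(items[nz, , drop = FALSE]))
  # floor group removed: alpha drops (shared variance shrinks)
  expect_lt(rep$alpha_nonzero$alpha, rep$alpha_full$alpha)
  expect_equal(rep$parallel$n_components, 1L)
  g <- glance(rep)
  expect_equal(g$n, 800L)
  expect_equal(g$n_nonzero, sum(nz))
})
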