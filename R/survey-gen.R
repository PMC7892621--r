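#' Synthetic survey-generation model
#'
#' Defines the joint distribution from which synthetic intake surveys are
#' drawn. The construction is chosen so that the quantities the analysis
#' tools estimate are planted exactly:
#'
#' * `gambling_frequency` is categorical on 0-4 with probabilities
#'   `freq_probs`.
#' * `type_count` given frequency is Poisson with log-link
#'   `log(mu) = types_intercept + types_freq_slope * frequency`, truncated
#'   to 0-12 by inverse-CDF sampling, so a Poisson regression of type count
#'   on frequency recovers `types_freq_slope`.
#' * The screener total is a hurdle: positive with probability
#'   `pi(f) = 1 - exp(-r * (pgsi_intercept + pgsi_freq_slope * f))`, where
#'   `r` is solved so that the marginal positive rate equals
#'   `p_pgsi_positive`; conditional on positive, the total is `1 +` a
#'   negative-binomial count (dispersion `pgsi_size`) truncated to 0-26,
#'   with its mean solved per frequency level so that
#'   `E[total | f] = pgsi_intercept + pgsi_freq_slope * f` holds exactly.
#'   A linear regression of the total on frequency therefore estimates
#'   `pgsi_freq_slope` without bias, while the marginal distribution keeps
#'   excess zeros and a long right tail.
#' * The nine items are a sum-preserving decomposition of the total:
#'   near-equal split plus `item_noise` random one-point transfers between
#'   items. All shared item variance flows through the single severity
#'   total, so parallel analysis sees one component, and `item_noise`
#'   tunes the internal consistency (defaults target alpha near 0.95).
#'
#' @param age_mean,age_sd Age distribution (normal, rounded, clamped to
#'   18-80).
#' @param male_prop Proportion coded `"male"`.
#' @param freq_probs Probabilities of the five last-year gambling-frequency
#'   categories coded 0-4 (not at all ... once per day or more).
#' @param p_pgsi_positive Marginal probability of a nonzero screener total.
#' @param pgsi_intercept,pgsi_freq_slope Planted linear model of the
#'   expected screener total on frequency. The intercept must be positive:
#'   conditional means of a nonnegative score cannot be negative.
#' @param pgsi_size Negative-binomial dispersion of the positive part
#'   (smaller = heavier tail).
#' @param types_intercept,types_freq_slope Planted Poisson log-link model
#'   of gambling-type count on frequency.
#' @param type_weights Relative selection weights of the twelve gambling
#'   types used to distribute a respondent's type count over named types.
#' @param item_noise Expected number of sum-preserving one-point transfers
#'   applied to each respondent's item decomposition (the realized number
#'   is Poisson); larger values lower the internal consistency.
#' @return A list of class `survey_gen_model`.
#' @seealso [generate_survey_cohort()], [survey_model_moments()]
#' @export
survey_gen_model <- function(age_mean = 34.89,
                             age_sd = 10.32,
                             male_prop = 0.65,
                             freq_probs = c(10, 43, 23, 22, 3) / 101,
                             p_pgsi_positive = 63 / 101,
                             pgsi_intercept = 0.25,
                             pgsi_freq_slope = 2.60,
                             pgsi_size = 1.9,
                             types_intercept = 0.15,
                             types_freq_slope = 0.34,
                             type_weights = c(
                               lottery = 63, sports_betting = 22,
                               race_betting = 6, cards = 1,
                               casino_slots = 41, festival = 3, dice = 13,
                               online_lottery = 19, online_betting = 15,
                               online_cards = 23, online_slots = 12,
                               other = 2
                             ),
                             item_noise = 0.5) {
  if (abs(sum(freq_probs) - 1) > 1e-9 || any(freq_probs < 0)) {
    stop_casino("freq_probs must be nonnegative and sum to 1",
                "casinosim_contract_error")
  }
  if (p_pgsi_positive < 0 || p_pgsi_positive > 1) {
    stop_casino("p_pgsi_positive must be in [0, 1]",
                "casinosim_contract_error")
  }
  if (male_prop < 0 || male_prop > 1) {
    stop_casino("male_prop must be in [0, 1]", "casinosim_contract_error")
  }
  if (pgsi_intercept <= 0 && p_pgsi_positive > 0) {
    stop_casino("pgsi_intercept must be positive",
                "casinosim_contract_error")
  }
  model <- structure(
    list(
      age_mean = age_mean, age_sd = age_sd, male_prop = male_prop,
      freq_probs = freq_probs, p_pgsi_positive = p_pgsi_positive,
      pgsi_intercept = pgsi_intercept, pgsi_freq_slope = pgsi_freq_slope,
      pgsi_size = pgsi_size, types_intercept = types_intercept,
      types_freq_slope = types_freq_slope, type_weights = type_weights,
      item_noise = as.numeric(item_noise)
    ),
    class = "survey_gen_model"
  )
  model$solved <- solve_survey_model(model)
  model
}

# Targets of the planted linear model, one per frequency level 0..4.
pgsi_targets <- function(model) {
  model$pgsi_intercept + model$pgsi_freq_slope * 0:4
}

# Mean of a size-theta NB truncated to 0..26 at untruncated mean mu.
trunc_nb_mean <- function(mu, size) {
  x <- 0:26
  w <- stats::dnbinom(x, size = size, mu = mu)
  sum(x * w) / sum(w)
}

trunc_nb_var <- function(mu, size) {
  x <- 0:26
  w <- stats::dnbinom(x, size = size, mu = mu)
  w <- w / sum(w)
  m <- sum(x * w)
  sum((x - m)^2 * w)
}

# Solve the hurdle rate r and the per-frequency positive-part means so the
# planted linear model and the marginal positive rate hold exactly.
solve_survey_model <- function(model) {
  targets <- pgsi_targets(model)
  if (model$p_pgsi_positive == 0) {
    return(list(r = 0, pi_f = rep(0, 5), mu_pos = rep(0, 5),
                m_pos = rep(0, 5)))
  }
  marg_pos <- function(r) {
    sum(model$freq_probs * (1 - exp(-r * targets)))
  }
  upper <- 1
  while (marg_pos(upper) < model$p_pgsi_positive && upper < 1e4) {
    upper <- upper * 2
  }
  if (marg_pos(upper) < model$p_pgsi_positive) {
    stop_casino(
      "p_pgsi_positive unattainable under the planted frequency model",
      "casinosim_contract_error"
    )
  }
  r <- uniroot(function(x) marg_pos(x) - model$p_pgsi_positive,
               c(1e-9, upper), tol = 1e-12)$root
  pi_f <- 1 - exp(-r * targets)
  m_pos <- targets / pi_f           # E[total | positive, f], must be >= 1
  if (any(m_pos < 1 - 1e-9)) {
    stop_casino(
      "planted model infeasible: conditional positive mean below 1",
      "casinosim_contract_error"
    )
  }
  mu_pos <- vapply(m_pos, function(m) {
    if (m <= 1 + 1e-9) return(0)
    uniroot(function(mu) trunc_nb_mean(mu, model$pgsi_size) - (m - 1),
            c(1e-9, 500), tol = 1e-10)$root
  }, numeric(1))
  list(r = r, pi_f = pi_f, mu_pos = mu_pos, m_pos = m_pos)
}

# Truncated-Poisson pmf of type count given frequency (support 0..12).
type_count_pmf <- function(model, f) {
  mu <- exp(model$types_intercept + model$types_freq_slope * f)
  w <- dpois(0:12, mu)
  w / sum(w)
}

#' Analytic moments of the survey-generation model
#'
#' Exact moments implied by the model parameters, for checking the sampler
#' against its own distribution (the generator's sample moments at large
#' `n` must match these within sampling error).
#'
#' @param model A [survey_gen_model()].
#' @return A one-row tibble with `mean_pgsi`, `sd_pgsi`, `p_pgsi_positive`,
#'   `mean_types` and `mean_frequency`.
#' @export
survey_model_moments <- function(model) {
  stopifnot(inherits(model, "survey_gen_model"))
  s <- model$solved
  targets <- pgsi_targets(model)
  w <- model$freq_probs
  mean_pgsi <- sum(w * targets)
  # second moment: mixture over f of hurdle second moments
  second <- vapply(0:4, function(f) {
    i <- f + 1L
    if (s$pi_f[i] == 0) return(0)
    v_pos <- if (s$mu_pos[i] == 0) 0
             else trunc_nb_var(s$mu_pos[i], model$pgsi_size)
    m_pos <- s$m_pos[i]
    s$pi_f[i] * (v_pos + m_pos^2)
  }, numeric(1))
  var_pgsi <- sum(w * second) - mean_pgsi^2
  mean_types <- sum(vapply(0:4, function(f) {
    w[f + 1L] * sum((0:12) * type_count_pmf(model, f))
  }, numeric(1)))
  tibble::tibble(
    mean_pgsi = mean_pgsi,
    sd_pgsi = sqrt(var_pgsi),
    p_pgsi_positive = sum(w * s$pi_f),
    mean_types = mean_types,
    mean_frequency = sum(w * 0:4)
  )
}

# Decompose totals into 9 items in 0..3 summing exactly to the total:
# near-equal base split, then `noise` random one-point transfers.
decompose_pgsi_items <- function(totals, noise = 0.5) {
  n <- length(totals)
  items <- matrix(0L, nrow = n, ncol = 9L)
  q <- totals %/% 9L
  r <- totals %% 9L
  for (i in seq_len(n)) {
    row <- rep.int(q[i], 9L)
    if (r[i] > 0L) {
      bump <- sample.int(9L, r[i])
      row[bump] <- row[bump] + 1L
    }
    n_tr <- if (noise > 0) stats::rpois(1L, noise) else 0L
    if (n_tr > 0L && totals[i] > 0L && totals[i] < 27L) {
      for (s in seq_len(n_tr)) {
        donors <- which(row > 0L)
        receivers <- which(row < 3L)
        if (length(donors) == 0L || length(receivers) == 0L) break
        d <- donors[sample.int(length(donors), 1L)]
        rcv <- receivers[sample.int(length(receivers), 1L)]
        if (d != rcv) {
          row[d] <- row[d] - 1L
          row[rcv] <- row[rcv] + 1L
        }
      }
    }
    items[i, ] <- row
  }
  colnames(items) <- paste0("pgsi_item_", 1:9)
  items
}

#' Generate a cohort of synthetic intake surveys
#'
#' Draws `n` survey rows from a [survey_gen_model()]. Defaults are
#' calibrated to the margins of a crowdsourced validation sample of 101
#' online workers (age 34.89 +/- 10.32, 65% male, frequency counts
#' 10/43/23/22/3, 62% nonzero screener totals with a long right tail) with
#' planted severity-frequency and types-frequency associations.
#'
#' @param model A [survey_gen_model()].
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @param study_ids Optional character vector of ids (length `n`).
#' @return A tibble with columns `study_id`, `age`, `sex`,
#'   `gambling_frequency`, one 0/1 column per gambling type, `none`,
#'   `pgsi_item_1` ... `pgsi_item_9`, `pgsi_total`.
#' @examples
#' svy <- generate_survey_cohort(survey_gen_model(), n = 101, seed = 1)
#' mean(svy$pgsi_total)
#' @export
generate_survey_cohort <- function(model = survey_gen_model(), n,
                                   seed = 1L, study_ids = NULL) {
  stopifnot(inherits(model, "survey_gen_model"), n >= 1)
  if (is.null(study_ids)) study_ids <- sprintf("P%03d", seq_len(n))
  stopifnot(length(study_ids) == n)
  withr::with_seed(as.integer(seed), {
    s <- model$solved
    age <- pmin(80, pmax(18, round(rnorm(n, model$age_mean, model$age_sd))))
    sex <- ifelse(runif(n) < model$male_prop, "male", "female")
    freq <- sample(0:4, n, replace = TRUE, prob = model$freq_probs)

    # type counts: exact truncated-Poisson by inverse CDF
    mu_types <- exp(model$types_intercept + model$types_freq_slope * freq)
    cap <- stats::ppois(12, mu_types)
    type_count <- stats::qpois(runif(n) * cap, mu_types)

    # hurdle screener total
    positive <- runif(n) < s$pi_f[freq + 1L]
    total <- integer(n)
    for (f in 0:4) {
      idx <- which(positive & freq == f)
      if (length(idx) == 0L) next
      mu <- s$mu_pos[f + 1L]
      if (mu == 0) {
        total[idx] <- 1L
      } else {
        capnb <- stats::pnbinom(26, size = model$pgsi_size, mu = mu)
        x <- stats::qnbinom(runif(length(idx)) * capnb,
                            size = model$pgsi_size, mu = mu)
        total[idx] <- 1L + as.integer(x)
      }
    }
    items <- decompose_pgsi_items(total, model$item_noise)

    # distribute counts over named types by weighted sampling
    labels <- gambling_type_labels()
    wts <- model$type_weights[labels]
    type_mat <- matrix(0L, nrow = n, ncol = 12L,
                       dimnames = list(NULL, labels))
    for (i in seq_len(n)) {
      k <- min(type_count[i], 12L)
      if (k > 0L) {
        sel <- sample.int(12L, k, prob = wts)
        type_mat[i, sel] <- 1L
      }
    }

    out <- tibble::tibble(
      study_id = study_ids,
      age = as.numeric(age),
      sex = sex,
      gambling_frequency = as.integer(freq)
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(type_mat))
    out$none <- as.integer(rowSums(type_mat) == 0L)
    out <- dplyr::bind_cols(out, tibble::as_tibble(items))
    out$pgsi_total <- as.integer(total)
    out
  })
}
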