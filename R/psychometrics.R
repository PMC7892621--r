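#' Cronbach's alpha
#'
#' Internal consistency of a set of items:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#' Alpha is invariant to adding constants to items and to item order.
#'
#' @param items Matrix or data frame, one row per respondent, one column
#'   per item (`k >= 2`, no missing values).
#' @return A single number `<= 1`.
#' @examples
#' x <- simulate_factor_items(500, rep(0.8, 9), seed = 1)
#' cronbach_alpha(x)
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  k <- ncol(m)
  if (k < 2L) {
    stop_casino("alpha needs at least 2 items", "casinosim_contract_error")
  }
  if (anyNA(m)) {
    stop_casino("missing values in item matrix", "casinosim_contract_error")
  }
  total_var <- var(rowSums(m))
  if (total_var == 0) {
    stop_casino("total-score variance is zero: alpha undefined",
                "casinosim_contract_error")
  }
  (k / (k - 1)) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Confidence interval for Cronbach's alpha
#'
#' Feldt's F-based interval (default) treats
#' `(1 - alpha) / (1 - alpha_hat)` as F-distributed with `n - 1` and
#' `(n - 1)(k - 1)` degrees of freedom. The nonparametric bootstrap
#' resamples respondents and takes percentile bounds.
#'
#' @param items Item matrix as in [cronbach_alpha()].
#' @param level Confidence level.
#' @param method `"feldt"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (bootstrap method only).
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `alpha`, `conf.low`, `conf.high`, `method`.
#' @export
alpha_confidence_interval <- function(items, level = 0.95,
                                      method = c("feldt", "bootstrap"),
                                      n_boot = 1000, seed = 1L) {
  method <- match.arg(method)
  m <- as.matrix(items)
  a <- cronbach_alpha(m)
  n <- nrow(m)
  k <- ncol(m)
  if (method == "feldt") {
    lo_q <- qf(1 - (1 - level) / 2, n - 1, (n - 1) * (k - 1))
    hi_q <- qf((1 - level) / 2, n - 1, (n - 1) * (k - 1))
    out <- tibble::tibble(
      alpha = a,
      conf.low = 1 - (1 - a) * lo_q,
      conf.high = 1 - (1 - a) * hi_q,
      method = "feldt"
    )
  } else {
    boots <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        b <- m[idx, , drop = FALSE]
        tv <- var(rowSums(b))
        if (tv == 0) NA_real_
        else (k / (k - 1)) * (1 - sum(apply(b, 2, var)) / tv)
      }, numeric(1))
    })
    qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                   na.rm = TRUE, names = FALSE)
    out <- tibble::tibble(alpha = a, conf.low = qs[1], conf.high = qs[2],
                          method = "bootstrap")
  }
  out
}

#' Horn's parallel analysis
#'
#' Compares the eigenvalues of the observed item correlation matrix with
#' the percentile of eigenvalues from resampled null data of the same
#' shape. The number of components retained is the length of the leading
#' run of observed eigenvalues exceeding their null percentile.
#'
#' @param items Item matrix (n x k).
#' @param n_resamples Number of null datasets.
#' @param percentile Null percentile compared against (default 95).
#' @param seed Seed for the resampling.
#' @param method `"normal"` resamples independent standard normal data;
#'   `"permute"` permutes each observed column independently, preserving
#'   marginal item distributions.
#' @return A `parallel_analysis` object with `n_components`, and a
#'   `series` tibble (`component`, `observed`, `null_percentile`) for
#'   scree plotting.
#' @examples
#' x <- simulate_factor_items(300, rep(0.8, 9), seed = 1)
#' parallel_analysis(x, n_resamples = 200, seed = 2)
#' @export
parallel_analysis <- function(items, n_resamples = 1000, percentile = 95,
                              seed = 1L, method = c("normal", "permute")) {
  method <- match.arg(method)
  m <- as.matrix(items)
  n <- nrow(m)
  k <- ncol(m)
  if (k > n) warn("more items than observations; eigenvalues unstable")
  obs <- eigen(cor(m), symmetric = TRUE, only.values = TRUE)$values
  null_eigs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_resamples), function(i) {
      x <- if (method == "normal") {
        matrix(rnorm(n * k), n, k)
      } else {
        apply(m, 2, sample)
      }
      eigen(cor(x), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(k))
  })
  thresh <- apply(null_eigs, 1, quantile, probs = percentile / 100)
  above <- obs > thresh
  n_comp <- if (above[1]) {
    which.min(c(above, FALSE)) - 1L
  } else 0L
  structure(
    list(
      n_components = n_comp,
      series = tibble::tibble(
        component = seq_len(k),
        observed = obs,
        null_percentile = thresh
      ),
      percentile = percentile,
      n_resamples = n_resamples,
      method = method
    ),
    class = "parallel_analysis"
  )
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat(sprintf(
    "<parallel_analysis> %d component(s) retained (%s null, %dth percentile, %d resamples)\n",
    x$n_components, x$method, x$percentile, x$n_resamples
  ))
  invisible(x)
}

#' @export
tidy.parallel_analysis <- function(x, ...) x$series

#' @export
glance.parallel_analysis <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    percentile = x$percentile,
    n_resamples = x$n_resamples,
    method = x$method
  )
}

#' Simulate continuous items from a common-factor model
#'
#' `x_j = sum_m lambda_jm * F_m + sqrt(1 - sum_m lambda_jm^2) * e_j` with
#' independent standard-normal factors and uniquenesses. Used as the
#' ground-truth generator for the psychometric machinery: under a single
#' factor with equal loadings `l`, the population alpha has the
#' tau-equivalent closed form `k l^2 / (1 + (k - 1) l^2)`.
#'
#' @param n Number of respondents.
#' @param loadings Either a vector of length `k` (one factor) or a `k x m`
#'   matrix (m orthogonal factors).
#' @param seed Integer seed.
#' @return An `n x k` numeric matrix.
#' @export
simulate_factor_items <- function(n, loadings, seed = 1L) {
  L <- if (is.matrix(loadings)) loadings else matrix(loadings, ncol = 1)
  k <- nrow(L)
  comm <- rowSums(L^2)
  if (any(comm > 1)) {
    stop_casino("item communalities exceed 1", "casinosim_contract_error")
  }
  withr::with_seed(as.integer(seed), {
    f <- matrix(rnorm(n * ncol(L)), n, ncol(L))
    e <- matrix(rnorm(n * k), n, k)
    f %*% t(L) + e * matrix(sqrt(1 - comm), n, k, byrow = TRUE)
  })
}

#' Severity-association regressions
#'
#' The four association models used to check convergent validity of the
#' intake survey: linear models of the screener total on (i) a
#' no-gambling indicator, (ii) the gambling-type count and (iii) the
#' gambling-frequency code, and a Poisson log-link regression (fitted by
#' IRLS maximum likelihood via `glm`) of the type count on frequency.
#'
#' @param survey Survey tibble with columns `pgsi_total`,
#'   `gambling_frequency`, and either a `type_count` column or the named
#'   gambling-type 0/1 columns from which it is computed. The no-gambling
#'   indicator is `type_count == 0`.
#' @return A `severity_associations` object; `tidy()` gives one row per
#'   model with `model`, `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
fit_severity_associations <- function(survey) {
  if (!"type_count" %in% names(survey)) {
    cols <- intersect(gambling_type_labels(), names(survey))
    if (length(cols) == 0L) {
      stop_casino("survey has neither type_count nor gambling-type columns",
                  "casinosim_contract_error")
    }
    survey$type_count <- rowSums(survey[cols])
  }
  survey$no_gambling <- as.integer(survey$type_count == 0)
  for (col in c("pgsi_total", "gambling_frequency", "type_count",
                "no_gambling")) {
    if (!col %in% names(survey)) {
      stop_casino(paste0("missing column: ", col),
                  "casinosim_contract_error")
    }
    if (col != "pgsi_total" && var(survey[[col]]) == 0) {
      stop_casino(paste0("constant predictor: ", col),
                  "casinosim_contract_error")
    }
  }
  fits <- list(
    pgsi_on_no_gambling = lm(pgsi_total ~ no_gambling, data = survey),
    pgsi_on_type_count = lm(pgsi_total ~ type_count, data = survey),
    pgsi_on_frequency = lm(pgsi_total ~ gambling_frequency, data = survey),
    types_on_frequency = glm(type_count ~ gambling_frequency,
                             family = poisson(), data = survey)
  )
  rows <- purrr::imap_dfr(fits, function(fit, name) {
    sm <- summary(fit)$coefficients
    tibble::tibble(
      model = name,
      term = rownames(sm),
      estimate = unname(sm[, 1]),
      std.error = unname(sm[, 2]),
      statistic = unname(sm[, 3]),
      # two-sided Wald p on the normal reference for lm and glm alike
      p.value = 2 * pnorm(-abs(sm[, 3]))
    )
  })
  structure(list(estimates = rows, fits = fits),
            class = "severity_associations")
}

#' @export
print.severity_associations <- function(x, ...) {
  slopes <- dplyr::filter(x$estimates, .data$term != "(Intercept)")
  for (i in seq_len(nrow(slopes))) {
    cat(sprintf("  %s: B = %.3f (SE %.3f), p = %.4g\n",
                slopes$model[i], slopes$estimate[i], slopes$std.error[i],
                slopes$p.value[i]))
  }
  invisible(x)
}

#' @export
tidy.severity_associations <- function(x, ...) x$estimates

#' @export
glance.severity_associations <- function(x, ...) {
  slopes <- dplyr::filter(x$estimates, .data$term != "(Intercept)")
  tibble::tibble(
    n_models = length(x$fits),
    n_significant = sum(slopes$p.value < 0.05)
  )
}

#' Full psychometrics report for a survey table
#'
#' Internal consistency of the nine screener items (full sample and the
#' nonzero-total subsample, since an all-zero floor group inflates alpha),
#' dimensionality by parallel analysis, and the severity-association
#' regressions.
#'
#' @param survey Survey tibble with `pgsi_item_1`..`pgsi_item_9`,
#'   `pgsi_total`, `gambling_frequency` and gambling-type columns.
#' @param n_resamples,percentile Passed to [parallel_analysis()].
#' @param seed Seed for the parallel-analysis resampling.
#' @param ci_method Passed to [alpha_confidence_interval()].
#' @return A `psychometrics_report` object.
#' @export
psychometrics_report <- function(survey, n_resamples = 1000,
                                 percentile = 95, seed = 1L,
                                 ci_method = "feldt") {
  item_cols <- paste0("pgsi_item_", 1:9)
  if (!all(item_cols %in% names(survey))) {
    stop_casino("survey lacks pgsi_item_1..pgsi_item_9 columns",
                "casinosim_contract_error")
  }
  items <- as.matrix(survey[item_cols])
  alpha_full <- alpha_confidence_interval(items, method = ci_method)
  nz <- survey$pgsi_total > 0
  alpha_nonzero <- if (sum(nz) >= 3L &&
                       var(rowSums(items[nz, , drop = FALSE])) > 0) {
    alpha_confidence_interval(items[nz, , drop = FALSE], method = ci_method)
  } else {
    tibble::tibble(alpha = NA_real_, conf.low = NA_real_,
                   conf.high = NA_real_, method = ci_method)
  }
  pa <- parallel_analysis(items, n_resamples = n_resamples,
                          percentile = percentile, seed = seed)
  assoc <- fit_severity_associations(survey)
  structure(
    list(
      alpha_full = alpha_full,
      alpha_nonzero = alpha_nonzero,
      parallel = pa,
      associations = assoc,
      n = nrow(survey),
      n_nonzero = sum(nz)
    ),
    class = "psychometrics_report"
  )
}

#' @export
print.psychometrics_report <- function(x, ...) {
  cat(sprintf(
    "<psychometrics_report> n = %d (nonzero totals %d)\n", x$n, x$n_nonzero
  ))
  cat(sprintf("  alpha = %.3f (%.2f..%.2f, %s); nonzero-only %.3f\n",
              x$alpha_full$alpha, x$alpha_full$conf.low,
              x$alpha_full$conf.high, x$alpha_full$method,
              x$alpha_nonzero$alpha))
  cat(sprintf("  parallel analysis: %d component(s)\n",
              x$parallel$n_components))
  print(x$associations)
  invisible(x)
}

#' @export
glance.psychometrics_report <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_nonzero = x$n_nonzero,
    alpha = x$alpha_full$alpha,
    alpha_conf.low = x$alpha_full$conf.low,
    alpha_conf.high = x$alpha_full$conf.high,
    alpha_nonzero = x$alpha_nonzero$alpha,
    n_components = x$parallel$n_components
  )
}

#' @export
tidy.psychometrics_report <- function(x, ...) tidy(x$associations)
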