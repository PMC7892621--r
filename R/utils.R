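#' Wilson score interval for a binomial proportion
#'
#' The Wilson interval inverts the score test and behaves well for
#' proportions near 0 or 1, which makes it the standard choice for audit
#' summaries of observed win rates.
#'
#' @param x Number of successes.
#' @param n Number of trials (`n >= 1`).
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `estimate`, `conf.low`, `conf.high`.
#' @examples
#' wilson_ci(30, 100)
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(length(x) == length(n), all(n >= 1), all(x >= 0), all(x <= n))
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(
    estimate = p,
    conf.low = pmax(0, centre - half),
    conf.high = pmin(1, centre + half)
  )
}

# Derive a vector of independent sub-seeds from one master seed without
# touching the caller's RNG state. Values stay below .Machine$integer.max.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Internal: stop with a classed condition so callers can test error types.
stop_casino <- function(msg, class) {
  abort(msg, class = c(class, "casinosim_error"))
}

near <- function(x, y, tol = 1e-9) abs(x - y) <= tol
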