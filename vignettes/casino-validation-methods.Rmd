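---
title: "Simulated-casino experiments: engine mechanics, synthetic cohorts, and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated-casino experiments: engine mechanics, synthetic cohorts, and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casinosim)
```

## The problem this package addresses

Behavioral research on gambling sits between two poles: tightly controlled
laboratory reinforcement-learning tasks with limited external validity, and
account-tracking data from live gambling operators where nothing can be
randomized. A simulated online casino occupies the middle ground — real-
looking games whose reinforcement schedules, payouts and stimuli are under
full experimental control, played by crowdsourced participants. Before such
a platform can carry substantive experiments (for example on responsible-
gambling messaging), three things must be demonstrated about it:

1. **Mechanics**: outcomes really are independent Bernoulli draws at the
   programmed win probabilities ("sampling with replacement", as in live
   casino games), and credit balances evolve according to the programmed
   return-to-player rate.
2. **Behavioral data quality**: indiscriminate responders (workers who
   click one option throughout) can be identified from the logs.
3. **Survey validity**: the intake questionnaire (gambling frequency,
   gambling types, and the nine-item problem-gambling screener scored 0-27)
   behaves psychometrically as the instrument should.

`casinosim` implements the platform as a headless, fully seeded engine plus
the complete validation toolchain, and adds a synthetic-participant
generator so that every analysis stage can be exercised end-to-end with
data of known ground truth.

## The engine and its expectations

An experiment is a *design matrix*: between-subject arms with allocation
percentages, each an ordered list of game blocks. A block fixes a game type
(binary-choice card draw or roulette, or a no-choice slot machine), a trial
count, a bet, and either per-option win probabilities and amounts or, for
slot blocks, a set of visual-theme labels with display probabilities and
per-theme win probabilities. Every gamble appends one long-format record
(`study_id, timestamp_ms, arm_id, game_type, block_index, trial_number,
balance_in, theme_id, response, outcome, outcome_credit, balance_out`), and
between-game messages are logged as typed events rather than trials.

Accounting follows a single invariant:
`balance_out = balance_in - bet + outcome_credit`, with
`outcome_credit = 0` on a loss and `win_amount` (plus the bet when
`bet_returned_on_win` is set) on a win. For a block with marginal win
probability $\bar p$ (display-weighted over themes for the slot) and
per-win payout $w$,

$$\mathrm{E}[B_t] = B_0 - t\,(b - \bar p\, w), \qquad
\mathrm{RTP} = \frac{\bar p\, w}{b},$$

so the bundled validation schedule (bet 10, win 20 not returned, themes
50/50 at win probabilities 0.5 and 0.2) has $\bar p = 0.35$, RTP 0.7 and an
expected decline of 3 credits per trial. These closed forms are what the
audit functions compare cohorts against; they are themselves validated in
the test suite against a vectorized Monte-Carlo rerun of $10^5$ sessions.

Randomness is one RNG stream per session, seeded from the cohort master
seed, which makes every cohort a pure function of
`(design, cohort spec, seed)` and exported logs byte-reproducible. Clock
time is simulated in milliseconds by accumulating policy-drawn response
latencies. The record's `balance_in` is the pre-bet balance; the live
convention was not documented, and this choice makes the accounting
invariant self-evident from the log.

## Agent policies and what the synthetic cohort emulates

Three bundled policies span the quality spectrum the screening tools must
separate: a *random responder* (independent choices, probability
`p_first = 0.5` of the first option), a *repetitive responder* (one option
throughout — the indiscriminate worker the 10–90% response-variation rule
is designed to catch), and a *win-stay/lose-shift* responder, included so
the mechanics audits can be shown to hold under sequentially dependent
behavior (outcome draws must stay independent even when responses are
not). Per-trial latencies are log-normal with a median of 5.5 s (2.5 s
for repetitive responders, who rush), putting a 96-trial session near a
10-minute completion time — the scale typical of crowdsourced sessions of
this length. Latencies are calibration, not an audited quantity.

The default cohort mixes 94% random and 6% repetitive responders,
matching the fraction of poor-quality sessions observed in crowdsourced
validation data for this task length.

What the synthetic cohort deliberately does *not* emulate: learning or
extinction dynamics (no policy adapts its rate over trials), drop-out,
pauses between phases (latencies are i.i.d., so simulated durations are
narrower than real ones), and any dependence of behavior on the survey.
Passing audits on synthetic data therefore demonstrates that the
*machinery* is correct and calibrated — not that real participants behave
like the agents.

## The survey generator: planted truths

The survey model is built so that the quantities the analysis stage
estimates exist in the generator as exact parameters:

* **Frequency** is categorical on 0–4 with probabilities 10/43/23/22/3
  (out of 101), the margins of the reference cohort.
* **Type count** given frequency is Poisson, $\log \mu = 0.15 + 0.34 f$,
  truncated to 0–12 by inverse-CDF sampling. A Poisson regression of
  count on frequency therefore recovers 0.34. The count is distributed
  over named types by weighted sampling (weights from the reference
  cohort's per-type counts; the never-endorsed "cards" type gets weight 1
  rather than 0 so that all twelve types remain reachable).
* **Screener total** is a hurdle: positive with probability
  $\pi(f) = 1 - e^{-r\,(0.25 + 2.6 f)}$, with $r$ solved so the marginal
  positive rate is exactly 63/101; conditional on positive, the total is
  one plus a negative-binomial count (dispersion 1.9) truncated to 0–26,
  whose mean is solved per frequency level so that
  $\mathrm{E}[\text{total}\mid f] = 0.25 + 2.6 f$ holds *exactly*. A
  linear regression of total on frequency is therefore unbiased for 2.60,
  while the marginal distribution keeps the excess zeros and long right
  tail characteristic of general-population screener data.
* **Items**: the nine items are a sum-preserving decomposition of the
  total — near-equal split plus a Poisson(0.5) number of random one-point
  transfers. All shared item variance flows through the single severity
  total, so parallel analysis sees one component; the transfer rate is
  the free parameter and its default targets an internal consistency of
  about 0.95 on cohort-sized samples.

Two calibration compromises are worth stating plainly. First, a mean
total of 4.26 (the reference margin) is arithmetically incompatible with
a planted linear slope of 2.60 and nonnegative conditional means
($4.26 - 2.60 \times 1.653 < 0$); the slope is the estimable, graded
quantity, so it is kept exact and the intercept is set to 0.25, giving an
analytic mean of 4.55. Second, the generator allows respondents with
frequency 0 to endorse gambling types (the Poisson link applies at every
frequency level); collapsing them to zero would bias the planted slope.
The "none" indicator is defined as a zero type count.

An alternative construction — items thresholded from a latent factor with
a loading parameter — was considered and set aside: it makes both the
planted linear slope and the moment calibration only approximate, which
would turn exact parameter-recovery checks into loose ones. The
decomposition approach trades a conventional item-response mechanism for
exactly plantable targets; since no item-level margins exist to calibrate
against anyway, the trade is cheap.

## Audit methodology and numerical choices

* **Win rates** are exact counts per stratum with Wilson score intervals
  (well-behaved near 0 and 1; checked in the tests against
  `prop.test(correct = FALSE)`).
* **Replacement check**: win rates conditional on the previous trial's
  outcome, paired strictly within participant and block — session
  boundaries never chain, and each block's first trial only conditions.
  The difference gets a two-proportion z interval.
* **Balance trajectory**: per-trial observed mean balance against the
  closed form. Two summaries are kept apart deliberately: the per-trial
  *change* (i.i.d. across trials; naive normal CI) is the statistic that
  must match $-(b - \bar p w)$, while the *momentary discrepancy*
  (observed minus expected balance) accumulates, so early luck skews it
  for the rest of the block. Because accumulated balances are serially
  correlated within a session, the discrepancy CI clusters on
  participants (one mean per participant); a pooled-trials CI would be
  spuriously narrow and fail even a fair-game martingale check.
* **Screening**: the variation score is the percentage of choice trials
  on which a designated reference option (first label in stable sort
  order) was chosen. The 10–90% bounds are inclusive — exactly 10% or 90%
  is not flagged — and configurable, since the threshold deserves
  reconsideration per experiment. The score is direction-symmetric at
  those bounds, so the designated-option and majority-option conventions
  flag identically. Durations are summarized (with counts above 15 and
  20 minutes) but never used for exclusion.
* **Alpha CI**: Feldt's F interval by default
  ($({1-\alpha})/({1-\hat\alpha}) \sim F_{n-1,(n-1)(k-1)}$), bootstrap as
  the alternative; the two are required to overlap in the tests, and
  Feldt coverage is verified by simulation (500 one-factor replicates).
* **Parallel analysis** uses correlation-matrix eigenvalues against the
  95th percentile of resampled independent standard-normal data of the
  same shape (a column-permutation null is available for ordinal data);
  retention is the leading run of observed eigenvalues above their null
  percentile. Correlation rather than covariance is standard for ordinal
  screening items; polychoric machinery was judged not worth the cost at
  nine items.
* **Association models** are OLS (screener total on no-gambling
  indicator, type count, frequency) and Poisson IRLS via `glm` (type
  count on frequency), with two-sided Wald p-values on the normal
  reference. OLS is assumed since nothing indicates robust variants were
  used; under the hurdle generator the errors are heteroskedastic across
  frequency levels, which in simulation costs the nominal 95% interval
  about one point of coverage at n = 101 — inside the tolerance the
  acceptance checks use.

## Problem sizes

The validation suite runs at the reference scale where that is cheap —
101 participants × 96 trials per cohort, 20 seeds for the cohort-level
audit bands, 200 replicates for association-coverage studies, 500 for
Feldt coverage, $10^5$ sessions for the Monte-Carlo trajectory oracle —
and at 300 resamples for parallel-analysis calibration runs (the
user-facing default stays 1000). These sizes were chosen so each
statistical check has the power claimed for it while the whole suite
stays comfortably interactive.

## Known limitations

* One win probability and one amount per option/theme per block; jackpot
  tables and losses-disguised-as-wins accounting are out of scope.
* No graphics, sound or web front end: themes are categorical labels, and
  the platform's original crowdsourcing integration is not modeled.
* The synthetic cohort validates machinery, not human behavior; effect
  sizes estimated from it say nothing about real populations.
* Item-level screener margins are unanchored (no reference data exists),
  so item-level calibration beyond total-score moments is arbitrary.
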