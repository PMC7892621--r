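Package: casinosim
Title: Seeded Simulated-Casino Experiment Engine with Mechanics and
    Survey Validation Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, fully seeded engine for behavioral experiments in a
    simulated online casino. Experiments are specified in a design matrix
    (arms, allocation percentages, ordered game blocks with trial counts,
    bets, win amounts and win probabilities, visual-theme labels, messages);
    the engine runs card-draw, roulette and slot-machine blocks trial by
    trial with independent Bernoulli outcome draws and long-format event
    logging. A synthetic-participant module generates cohorts of agent
    policies and intake-survey responses (gambling frequency, gambling
    types, nine-item problem-gambling screener) with plantable association
    structure. Companion analysis tools audit game mechanics (stratified
    win rates with Wilson intervals, sampling-with-replacement independence
    checks, expected-versus-observed balance trajectories, return-to-player
    rates), screen behavioral logs for indiscriminate responding, and
    assess survey psychometrics (Cronbach's alpha with Feldt or bootstrap
    intervals, Horn's parallel analysis, severity-association regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
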