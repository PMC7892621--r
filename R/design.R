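#' Specify a choice option for a card-draw or roulette block
#'
#' @param option_id Label shown in the log (e.g. `"red"`, `"deck_left"`).
#' @param win_probability Probability of a win when this option is chosen,
#'   in `[0, 1]`. A probability of 0 is legal and encodes extinction
#'   (non-reinforced) trials.
#' @param win_amount Credits paid on a win (bet handling is controlled at the
#'   block level by `bet_returned_on_win`).
#' @return A list of class `option_spec`.
#' @export
option_spec <- function(option_id, win_probability, win_amount) {
  structure(
    list(
      option_id = as.character(option_id),
      win_probability = as.numeric(win_probability),
      win_amount = as.numeric(win_amount)
    ),
    class = "option_spec"
  )
}

#' Specify a visual theme for a slot-machine block
#'
#' Themes are categorical stimulus labels drawn independently per trial; the
#' win probability of a slot trial is the probability attached to the theme
#' that was displayed, which is how a no-choice game can still carry a
#' manipulated reinforcement schedule.
#'
#' @param theme_id Label logged as the presented stimulus.
#' @param display_probability Probability that this theme is shown on a
#'   given trial. Display probabilities over a block's themes must sum to 1.
#' @param win_probability Win probability conditional on this theme.
#' @param win_amount Credits paid on a win under this theme.
#' @return A list of class `theme_spec`.
#' @export
theme_spec <- function(theme_id, display_probability, win_probability,
                       win_amount) {
  structure(
    list(
      theme_id = as.character(theme_id),
      display_probability = as.numeric(display_probability),
      win_probability = as.numeric(win_probability),
      win_amount = as.numeric(win_amount)
    ),
    class = "theme_spec"
  )
}

#' Specify one game block (an ordered sequence of trials of one game)
#'
#' @param game_type One of `"card"`, `"roulette"` (binary-choice games) or
#'   `"slot"` (no-choice game; the only response is `"spin"`).
#' @param n_trials Number of trials in the block (`>= 1`).
#' @param bet_size Credits deducted at every trial (`> 0`).
#' @param options For choice games, a list of [option_spec()] objects
#'   (at least two).
#' @param themes For slot blocks, a list of [theme_spec()] objects
#'   (at least one).
#' @param bet_returned_on_win If `TRUE` a win pays `win_amount` plus the
#'   returned bet; if `FALSE` (the convention used when collecting the
#'   bundled validation setup) only `win_amount` is paid.
#' @param show_balance Whether the running balance is visible to the agent
#'   policy. Logging is unaffected.
#' @param pre_block_message Optional message displayed (logged as an event)
#'   before the block starts.
#' @return A list of class `game_block`.
#' @export
game_block <- function(game_type, n_trials, bet_size,
                       options = NULL, themes = NULL,
                       bet_returned_on_win = FALSE, show_balance = TRUE,
                       pre_block_message = NULL) {
  structure(
    list(
      game_type = as.character(game_type),
      n_trials = as.integer(n_trials),
      bet_size = as.numeric(bet_size),
      options = options,
      themes = themes,
      bet_returned_on_win = isTRUE(bet_returned_on_win),
      show_balance = isTRUE(show_balance),
      pre_block_message = pre_block_message
    ),
    class = "game_block"
  )
}

#' Specify an experimental arm
#'
#' @param arm_id Unique label for the arm.
#' @param allocation_percent Percentage of participants randomly allocated to
#'   this arm; allocations across arms must sum to 100.
#' @param starting_balance Credits at session start.
#' @param blocks Ordered list of [game_block()] objects.
#' @param end_message Optional message displayed after the last block.
#' @return A list of class `arm_spec`.
#' @export
arm_spec <- function(arm_id, allocation_percent, starting_balance, blocks,
                     end_message = NULL) {
  structure(
    list(
      arm_id = as.character(arm_id),
      allocation_percent = as.numeric(allocation_percent),
      starting_balance = as.numeric(starting_balance),
      blocks = blocks,
      end_message = end_message
    ),
    class = "arm_spec"
  )
}

#' Assemble an experiment design matrix
#'
#' The design matrix is the complete specification of an experiment:
#' between-subject arms with their allocation percentages, and within each
#' arm an ordered sequence of game blocks with trial counts, bets, payouts,
#' win probabilities, themes and messages. Multiple arms can collect data at
#' the same time; each participant is randomly allocated once at session
#' start.
#'
#' @param design_id Label for the design.
#' @param arms List of [arm_spec()] objects.
#' @param rng_seed Optional default seed recorded with the design.
#' @return A list of class `casino_design`.
#' @seealso [validate_design()], [load_design()], [run_session()]
#' @export
casino_design <- function(design_id, arms, rng_seed = NULL) {
  structure(
    list(
      design_id = as.character(design_id),
      arms = arms,
      rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
    ),
    class = "casino_design"
  )
}

#' @export
print.casino_design <- function(x, ...) {
  cat("<casino_design> ", x$design_id, "\n", sep = "")
  for (arm in x$arms) {
    cat(
      sprintf(
        "  arm %s (%g%%), start %g credits, %d block(s)\n",
        arm$arm_id, arm$allocation_percent, arm$starting_balance,
        length(arm$blocks)
      )
    )
    for (b in arm$blocks) {
      cat(sprintf(
        "    %s x%d, bet %g%s\n", b$game_type, b$n_trials, b$bet_size,
        if (b$bet_returned_on_win) ", bet returned on win" else ""
      ))
    }
  }
  invisible(x)
}

#' Check a design against its structural invariants
#'
#' Violations are collected and returned (never raised), so a design can be
#' inspected wholesale. A design is valid if and only if the returned tibble
#' has zero rows.
#'
#' @param design A [casino_design()].
#' @return A tibble with columns `field` and `message`, one row per
#'   violation.
#' @examples
#' d <- replication_design()
#' validate_design(d) # zero rows
#' @export
validate_design <- function(design) {
  v <- list()
  bad <- function(field, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(field = field, message = message)
  }

  if (!inherits(design, "casino_design")) {
    bad("design", "not a casino_design object")
    return(dplyr::bind_rows(v))
  }
  if (length(design$arms) == 0L) bad("arms", "design has no arms")

  ids <- purrr::map_chr(design$arms, "arm_id")
  if (anyDuplicated(ids)) {
    bad("arm_id", paste0(
      "arm_ids not unique: ", paste(ids[duplicated(ids)], collapse = ", ")
    ))
  }
  alloc <- sum(purrr::map_dbl(design$arms, "allocation_percent"))
  if (length(design$arms) > 0L && !near(alloc, 100)) {
    bad("allocation_percent", sprintf("allocations sum to %g, not 100", alloc))
  }

  for (arm in design$arms) {
    at <- function(field) paste0("arms[", arm$arm_id, "]$", field)
    if (arm$allocation_percent <= 0 || arm$allocation_percent > 100) {
      bad(at("allocation_percent"), sprintf(
        "allocation_percent %g outside (0, 100]", arm$allocation_percent
      ))
    }
    if (is.na(arm$starting_balance) || arm$starting_balance < 0) {
      bad(at("starting_balance"), "starting_balance must be >= 0")
    }
    for (i in seq_along(arm$blocks)) {
      blk <- arm$blocks[[i]]
      bt <- function(field) paste0(at("blocks"), "[", i, "]$", field)
      if (!blk$game_type %in% c("card", "roulette", "slot")) {
        bad(bt("game_type"), sprintf(
          "unknown game_type '%s' (must be card, roulette or slot)",
          blk$game_type
        ))
        next
      }
      if (is.na(blk$n_trials) || blk$n_trials < 1L) {
        bad(bt("n_trials"), "n_trials must be >= 1")
      }
      if (is.na(blk$bet_size) || blk$bet_size <= 0) {
        bad(bt("bet_size"), "bet_size must be > 0")
      }
      if (blk$game_type == "slot") {
        if (length(blk$themes) < 1L) {
          bad(bt("themes"), "slot block needs at least one theme")
        } else {
          disp <- sum(purrr::map_dbl(blk$themes, "display_probability"))
          if (!near(disp, 1)) {
            bad(bt("themes"), sprintf(
              "theme display probabilities sum to %g, not 1", disp
            ))
          }
          for (th in blk$themes) {
            if (th$win_probability < 0 || th$win_probability > 1) {
              bad(bt(paste0("themes[", th$theme_id, "]$win_probability")),
                  "win_probability outside [0, 1]")
            }
            if (th$win_amount < 0) {
              bad(bt(paste0("themes[", th$theme_id, "]$win_amount")),
                  "win_amount must be >= 0")
            }
          }
        }
        if (length(blk$options) > 0L) {
          bad(bt("options"), "slot block must not declare choice options")
        }
      } else {
        if (length(blk$options) < 2L) {
          bad(bt("options"), sprintf(
            "%s block needs at least two options", blk$game_type
          ))
        }
        for (op in blk$options) {
          if (op$win_probability < 0 || op$win_probability > 1) {
            bad(bt(paste0("options[", op$option_id, "]$win_probability")),
                "win_probability outside [0, 1]")
          }
          if (op$win_amount < 0) {
            bad(bt(paste0("options[", op$option_id, "]$win_amount")),
                "win_amount must be >= 0")
          }
        }
        opt_ids <- purrr::map_chr(blk$options, "option_id")
        if (anyDuplicated(opt_ids)) {
          bad(bt("options"), "option_ids not unique within block")
        }
      }
    }
  }
  out <- dplyr::bind_rows(v)
  if (nrow(out) == 0L) {
    tibble::tibble(field = character(), message = character())
  } else {
    out
  }
}

assert_valid_design <- function(design) {
  viol <- validate_design(design)
  if (nrow(viol) > 0L) {
    stop_casino(
      c("invalid design:",
        stats::setNames(paste0(viol$field, ": ", viol$message),
                        rep("x", nrow(viol)))),
      "casinosim_invalid_design"
    )
  }
  invisible(design)
}

#' Randomly allocate participants to arms
#'
#' Each draw is independent, with arm probabilities equal to
#' `allocation_percent / 100`, mirroring randomized between-subject
#' allocation at session start.
#'
#' @param design A valid [casino_design()].
#' @param n Number of independent allocations to draw.
#' @return Character vector of `n` arm ids.
#' @export
allocate_arm <- function(design, n = 1) {
  assert_valid_design(design)
  ids <- purrr::map_chr(design$arms, "arm_id")
  probs <- purrr::map_dbl(design$arms, "allocation_percent") / 100
  sample(ids, size = n, replace = TRUE, prob = probs)
}

# ---- serialization ----------------------------------------------------------

design_to_list <- function(design) {
  list(
    design_id = design$design_id,
    rng_seed = design$rng_seed,
    arms = purrr::map(design$arms, function(arm) {
      list(
        arm_id = arm$arm_id,
        allocation_percent = arm$allocation_percent,
        starting_balance = arm$starting_balance,
        end_message = arm$end_message,
        blocks = purrr::map(arm$blocks, function(blk) {
          out <- list(
            game_type = blk$game_type,
            n_trials = blk$n_trials,
            bet_size = blk$bet_size,
            bet_returned_on_win = blk$bet_returned_on_win,
            show_balance = blk$show_balance,
            pre_block_message = blk$pre_block_message
          )
          if (blk$game_type == "slot") {
            out$themes <- purrr::map(blk$themes, unclass)
          } else {
            out$options <- purrr::map(blk$options, unclass)
          }
          out
        })
      )
    })
  )
}

require_key <- function(x, key, where) {
  if (is.null(x[[key]])) {
    stop_casino(
      sprintf("missing required key '%s' in %s", key, where),
      "casinosim_parse_error"
    )
  }
  x[[key]]
}

design_from_list <- function(lst) {
  require_key(lst, "design_id", "design")
  arms_raw <- require_key(lst, "arms", "design")
  arms <- purrr::map(arms_raw, function(a) {
    arm_id <- require_key(a, "arm_id", "arm")
    blocks_raw <- require_key(a, "blocks", paste0("arm '", arm_id, "'"))
    blocks <- purrr::map(blocks_raw, function(b) {
      gt <- require_key(b, "game_type", paste0("arm '", arm_id, "' block"))
      if (!gt %in% c("card", "roulette", "slot")) {
        stop_casino(
          sprintf("game_type: unknown value '%s' in arm '%s'", gt, arm_id),
          "casinosim_parse_error"
        )
      }
      where <- paste0("arm '", arm_id, "' ", gt, " block")
      opts <- themes <- NULL
      if (gt == "slot") {
        themes <- purrr::map(require_key(b, "themes", where), function(th) {
          theme_spec(
            require_key(th, "theme_id", where),
            require_key(th, "display_probability", where),
            require_key(th, "win_probability", where),
            require_key(th, "win_amount", where)
          )
        })
      } else {
        opts <- purrr::map(require_key(b, "options", where), function(op) {
          option_spec(
            require_key(op, "option_id", where),
            require_key(op, "win_probability", where),
            require_key(op, "win_amount", where)
          )
        })
      }
      game_block(
        game_type = gt,
        n_trials = require_key(b, "n_trials", where),
        bet_size = require_key(b, "bet_size", where),
        options = opts,
        themes = themes,
        bet_returned_on_win = b$bet_returned_on_win %||% FALSE,
        show_balance = b$show_balance %||% TRUE,
        pre_block_message = b$pre_block_message
      )
    })
    arm_spec(
      arm_id = arm_id,
      allocation_percent = require_key(a, "allocation_percent",
                                       paste0("arm '", arm_id, "'")),
      starting_balance = require_key(a, "starting_balance",
                                     paste0("arm '", arm_id, "'")),
      blocks = blocks,
      end_message = a$end_message
    )
  })
  casino_design(lst$design_id, arms, rng_seed = lst$rng_seed)
}

#' Read or write a design matrix file
#'
#' Designs are stored as structured text configuration files; YAML (`.yaml`,
#' `.yml`) and JSON (`.json`) are both accepted and the format is inferred
#' from the file extension. `save_design()` followed by `load_design()` is
#' the identity on the design data model.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param design A [casino_design()].
#' @return `load_design()` returns a `casino_design`; `save_design()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' save_design(replication_design(), f)
#' d <- load_design(f)
#' @export
load_design <- function(path) {
  if (!file.exists(path)) {
    stop_casino(paste0("design file not found: ", path),
                "casinosim_parse_error")
  }
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    stop_casino(paste0("unsupported design format: .", ext),
                "casinosim_parse_error")
  )
  design_from_list(lst)
}

#' @rdname load_design
#' @export
save_design <- function(design, path) {
  lst <- design_to_list(design)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(lst, path),
    json = jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
    stop_casino(paste0("unsupported design format: .", ext),
                "casinosim_parse_error")
  )
  invisible(path)
}

#' The bundled validation-replication design
#'
#' A single-arm design used throughout the package's own validation suite:
#' 40 card-draw trials with two decks at win probability 0.45 each (bet 10,
#' win 20, bet not returned), then 40 slot-machine trials with two themes
#' displayed 50/50 at win probabilities 0.50 (`S1`) and 0.20 (`S2`), and
#' finally 16 non-reinforced (extinction) card-draw trials at win
#' probability 0. One session produces 96 trial records.
#'
#' The same design ships as a YAML file under
#' `system.file("extdata", "designs", "validation_replication.yaml",
#' package = "casinosim")`.
#'
#' @param starting_balance Credits at session start (default 1000).
#' @return A [casino_design()].
#' @export
replication_design <- function(starting_balance = 1000) {
  casino_design(
    design_id = "validation_replication",
    arms = list(
      arm_spec(
        arm_id = "A",
        allocation_percent = 100,
        starting_balance = starting_balance,
        blocks = list(
          game_block(
            "card", n_trials = 40, bet_size = 10,
            options = list(
              option_spec("deck_left", 0.45, 20),
              option_spec("deck_right", 0.45, 20)
            ),
            pre_block_message = "Card game: pick a deck on every trial."
          ),
          game_block(
            "slot", n_trials = 40, bet_size = 10,
            themes = list(
              theme_spec("S1", 0.5, 0.5, 20),
              theme_spec("S2", 0.5, 0.2, 20)
            ),
            pre_block_message = "Slot machine: press spin on every trial."
          ),
          game_block(
            "card", n_trials = 16, bet_size = 10,
            options = list(
              option_spec("deck_left", 0, 20),
              option_spec("deck_right", 0, 20)
            )
          )
        ),
        end_message = "Thanks for playing; the house always wins."
      )
    )
  )
}

#' @export
tidy.casino_design <- function(x, ...) {
  purrr::map_dfr(x$arms, function(arm) {
    purrr::imap_dfr(arm$blocks, function(blk, i) {
      strata <- if (blk$game_type == "slot") {
        purrr::map_dfr(blk$themes, function(th) {
          tibble::tibble(
            stratum = th$theme_id, stratum_type = "theme",
            display_probability = th$display_probability,
            win_probability = th$win_probability,
            win_amount = th$win_amount
          )
        })
      } else {
        purrr::map_dfr(blk$options, function(op) {
          tibble::tibble(
            stratum = op$option_id, stratum_type = "option",
            display_probability = NA_real_,
            win_probability = op$win_probability,
            win_amount = op$win_amount
          )
        })
      }
      dplyr::mutate(
        strata,
        arm_id = arm$arm_id, block_index = i - 1L,
        game_type = blk$game_type, n_trials = blk$n_trials,
        bet_size = blk$bet_size,
        bet_returned_on_win = blk$bet_returned_on_win,
        .before = 1
      )
    })
  })
}
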