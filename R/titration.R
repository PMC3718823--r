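#' Create an adjusting-amount titration state
#'
#' The adjusting-amount staircase offers a variable amount for the easy (or
#' immediate) option against a fixed base amount for the hard (or delayed)
#' option. After each choice the variable amount moves by the current step —
#' up after a HARD choice, down after an EASY choice — and the step halves.
#' All amounts live on a dyadic grid (start plus/minus subset sums of the
#' halving steps), which binary doubles represent exactly.
#'
#' @param base_amount Fixed dollar amount of the harder/delayed option.
#' @param start_amount Initial variable amount (default `base_amount / 2`).
#' @param initial_step First adjustment size (default `base_amount / 4`).
#' @param max_choices Number of choices in the staircase (default 6).
#' @param condition Condition label (load level N or delay in days).
#' @param clamp_amounts If `TRUE`, clamp the variable amount into
#'   `[0.01, base_amount - 0.01]` after each update (off by default; the
#'   default parameters never leave `[0, base_amount]`).
#' @return A list of class `coged_titration_state`.
#' @export
titration_state <- function(base_amount, start_amount = base_amount / 2,
                            initial_step = base_amount / 4, max_choices = 6L,
                            condition = NA, clamp_amounts = FALSE) {
  stopifnot(base_amount > 0, start_amount > 0, initial_step > 0, max_choices >= 1L)
  structure(
    list(
      condition = condition,
      base_amount = base_amount,
      variable_amount = start_amount,
      start_amount = start_amount,
      initial_step = initial_step,
      step = initial_step,
      choices_made = 0L,
      max_choices = as.integer(max_choices),
      history = character(0),
      clamp_amounts = isTRUE(clamp_amounts)
    ),
    class = "coged_titration_state"
  )
}

#' Apply one choice to a titration state
#'
#' A `"HARD"` choice (the larger offer for the harder/later option was
#' preferred) increases the easy offer by the current step; an `"EASY"`
#' choice decreases it. The step then halves and the choice is appended to
#' the history.
#'
#' @param state A `coged_titration_state`.
#' @param choice `"HARD"` or `"EASY"`.
#' @return The updated state.
#' @examples
#' st <- titration_state(base_amount = 2)          # v = $1.00, step = $0.50
#' st <- apply_choice(st, "HARD")                  # v = $1.50, step = $0.25
#' st$variable_amount
#' @export
apply_choice <- function(state, choice) {
  stopifnot(inherits(state, "coged_titration_state"))
  if (state$choices_made >= state$max_choices) {
    stop(sprintf(
      "titration exhausted: %d of %d choices already made",
      state$choices_made, state$max_choices
    ), call. = FALSE)
  }
  if (!is.character(choice) || length(choice) != 1L ||
      !choice %in% c("HARD", "EASY")) {
    stop("choice must be \"HARD\" or \"EASY\"", call. = FALSE)
  }
  delta <- if (choice == "HARD") state$step else -state$step
  state$variable_amount <- state$variable_amount + delta
  if (state$clamp_amounts) {
    state$variable_amount <- clamp(state$variable_amount, 0.01,
                                   state$base_amount - 0.01)
  }
  state$step <- state$step / 2
  state$choices_made <- state$choices_made + 1L
  state$history <- c(state$history, choice)
  state
}

#' Run a full titration to an indifference point
#'
#' Iterates [apply_choice()] for `n_choices` choices, querying `agent` for
#' each decision, and returns the resulting indifference record. With the
#' defaults for a $2.00 base (start $1.00, first step $0.50, six choices) the
#' adjustment applied on the sixth choice is $0.015625 — $0.015 at millicent
#' truncation — and the post-final amount is the indifference point.
#'
#' @param agent A function `(easy_offer, condition, base_amount) -> "HARD"|"EASY"`.
#' @param condition Condition label (load level or delay in days).
#' @param base_amount Fixed dollar amount for the hard option.
#' @param start_amount Initial easy offer (default `base_amount / 2`).
#' @param initial_step First adjustment (default `base_amount / 4`).
#' @param n_choices Number of choices (default 6).
#' @param clamp_amounts Passed to [titration_state()].
#' @return A one-row tibble (class also `coged_indifference_record`) with
#'   columns `condition`, `base_amount`, `indifference_amount`, `n_choices`,
#'   `history` (choice string such as `"HEHHEH"`).
#' @examples
#' always_hard <- function(offer, condition, base) "HARD"
#' run_titration(always_hard, condition = 4, base_amount = 2)
#' @export
run_titration <- function(agent, condition, base_amount,
                          start_amount = base_amount / 2,
                          initial_step = base_amount / 4,
                          n_choices = 6L, clamp_amounts = FALSE) {
  stopifnot(is.function(agent), n_choices >= 1L, start_amount > 0)
  st <- titration_state(
    base_amount = base_amount, start_amount = start_amount,
    initial_step = initial_step, max_choices = n_choices,
    condition = condition, clamp_amounts = clamp_amounts
  )
  for (k in seq_len(n_choices)) {
    ch <- agent(st$variable_amount, condition, base_amount)
    if (!is.character(ch) || length(ch) != 1L || !ch %in% c("HARD", "EASY")) {
      stop("agent returned an invalid choice token (expected \"HARD\" or \"EASY\")",
           call. = FALSE)
    }
    st <- apply_choice(st, ch)
  }
  rec <- tibble::tibble(
    condition = condition,
    base_amount = base_amount,
    indifference_amount = st$variable_amount,
    n_choices = as.integer(n_choices),
    history = paste(substr(st$history, 1, 1), collapse = "")
  )
  class(rec) <- c("coged_indifference_record", class(rec))
  rec
}

#' Build a randomized, non-nested trial schedule
#'
#' Discounting offers are presented interleaved rather than nested: for each
#' choice round k = 1..`n_choices`, every (condition, base amount) pair
#' appears once, in an independently shuffled order, so successive choices
#' for the same condition are separated by other conditions.
#'
#' @param conditions Vector of condition labels (load levels or delays).
#' @param base_amounts Vector of base amounts (dollars).
#' @param n_choices Choices per (condition, amount) staircase (default 6).
#' @param seed Optional integer seed for the shuffles.
#' @return A tibble with columns `trial`, `condition`, `base_amount`,
#'   `choice_index`; `nrow` equals
#'   `length(conditions) * length(base_amounts) * n_choices`.
#' @examples
#' nrow(build_schedule(2:6, 2, 6))   # 30 choices
#' @export
build_schedule <- function(conditions, base_amounts, n_choices = 6L,
                           seed = NULL) {
  stopifnot(length(conditions) >= 1L, length(base_amounts) >= 1L,
            n_choices >= 1L)
  pairs <- tidyr::expand_grid(condition = conditions,
                              base_amount = base_amounts)
  with_optional_seed(seed, {
    rounds <- lapply(seq_len(n_choices), function(k) {
      shuffled <- pairs[sample.int(nrow(pairs)), ]
      shuffled$choice_index <- k
      shuffled
    })
    out <- dplyr::bind_rows(rounds)
    out$trial <- seq_len(nrow(out))
    out[, c("trial", "condition", "base_amount", "choice_index")]
  })
}
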