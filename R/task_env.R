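#' Define a dynamic binary-choice condition
#'
#' A condition describes one cell of the experimental design: the direction in
#' which the dynamic ("risky") option's high-outcome probability changes, the
#' feedback regime, the payoff structure, and the composition of the option
#' pair. The dynamic option pays `risky_high` with probability
#' [p_high()]`(condition, trial)` and `risky_low` otherwise. The reference
#' option is either a sure `safe_payoff` (`composition = "safe_risky"`) or a
#' static 50/50 gamble over the same two risky payoffs
#' (`composition = "risky_risky"`).
#'
#' @param direction Direction of change of the dynamic option's high-outcome
#'   probability: `"static"` (constant .50), `"increasing"` (.01 on trial 1 up
#'   to 1.00 on the last trial) or `"decreasing"` (the mirror schedule).
#' @param feedback `"partial"` (outcome of the chosen option only) or `"full"`
#'   (foregone outcome shown as well).
#' @param n_trials Number of trials (default 100).
#' @param safe_payoff Sure payoff of the reference option, in points.
#' @param risky_high,risky_low The two payoffs of the dynamic option, in
#'   points; `risky_high` must exceed `risky_low`.
#' @param composition `"safe_risky"` (sure reference option) or
#'   `"risky_risky"` (reference is a static p = .50 gamble over
#'   `risky_low`/`risky_high`).
#'
#' @return An object of class `choice_condition`.
#' @examples
#' cond <- condition("increasing", "partial")
#' p_high(cond, c(1, 50, 100))
#' @export
condition <- function(direction = c("static", "increasing", "decreasing"),
                      feedback = c("partial", "full"),
                      n_trials = 100L,
                      safe_payoff = 250,
                      risky_high = 500,
                      risky_low = 0,
                      composition = c("safe_risky", "risky_risky")) {
  direction <- match.arg(direction)
  feedback <- match.arg(feedback)
  composition <- match.arg(composition)
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 2L) {
    stop("`n_trials` must be an integer >= 2.", call. = FALSE)
  }
  if (!is.numeric(risky_high) || !is.numeric(risky_low) ||
      risky_high <= risky_low) {
    stop("`risky_high` must be strictly greater than `risky_low`.",
         call. = FALSE)
  }
  structure(
    list(direction = direction, feedback = feedback, n_trials = n_trials,
         safe_payoff = safe_payoff, risky_high = risky_high,
         risky_low = risky_low, composition = composition),
    class = "choice_condition"
  )
}

#' @export
print.choice_condition <- function(x, ...) {
  ref <- if (x$composition == "safe_risky") {
    sprintf("sure %g", x$safe_payoff)
  } else {
    sprintf("static %g/%g at p = .50", x$risky_low, x$risky_high)
  }
  cat(sprintf(
    "<choice_condition> %s probabilities, %s feedback, %d trials\n  dynamic: %g/%g, reference: %s\n",
    x$direction, x$feedback, x$n_trials, x$risky_low, x$risky_high, ref
  ))
  invisible(x)
}

is_condition <- function(x) inherits(x, "choice_condition")

check_trial <- function(condition, trial) {
  if (any(trial < 1L) || any(trial > condition$n_trials) ||
      any(trial != floor(trial))) {
    stop(sprintf("`trial` must be an integer in 1..%d.", condition$n_trials),
         call. = FALSE)
  }
}

#' Probability of the high outcome on a given trial
#'
#' The dynamic option's probability of paying `risky_high`. The increasing
#' schedule runs linearly from .01 on trial 1 to 1.00 on the last trial; the
#' decreasing schedule is its mirror (1.00 down to .01); the static schedule
#' is .50 throughout. For the default 100 trials this is a .01 step per trial.
#'
#' @param condition A [condition()].
#' @param trial Trial index (1-based); vectorized.
#' @return Probability in `[0, 1]`, same length as `trial`.
#' @export
p_high <- function(condition, trial) {
  stopifnot(is_condition(condition))
  check_trial(condition, trial)
  n <- condition$n_trials
  switch(condition$direction,
    static = rep(0.5, length(trial)),
    increasing = 0.01 + (trial - 1) * (0.99 / (n - 1)),
    decreasing = 1 - (trial - 1) * (0.99 / (n - 1))
  )
}

ev_dynamic <- function(condition, trial) {
  p <- p_high(condition, trial)
  p * condition$risky_high + (1 - p) * condition$risky_low
}

ev_reference <- function(condition) {
  if (condition$composition == "safe_risky") {
    condition$safe_payoff
  } else {
    0.5 * (condition$risky_high + condition$risky_low)
  }
}

#' Expected-value maximizing option on a trial
#'
#' Compares the per-trial expected values of the two options. Returns
#' `"dynamic"` or `"reference"`, or `NA` when the expected values tie (the
#' static condition throughout; the exact turning point of a dynamic
#' schedule).
#'
#' @inheritParams p_high
#' @return Character vector: `"dynamic"`, `"reference"` or `NA`.
#' @export
maximizing_option <- function(condition, trial) {
  evd <- ev_dynamic(condition, trial)
  evr <- ev_reference(condition)
  out <- rep(NA_character_, length(trial))
  tol <- 1e-9
  out[evd > evr + tol] <- "dynamic"
  out[evd < evr - tol] <- "reference"
  out
}

draw_option_outcome <- function(condition, trial, option, u) {
  if (option == "dynamic") {
    ifelse(u < p_high(condition, trial), condition$risky_high,
           condition$risky_low)
  } else if (condition$composition == "safe_risky") {
    rep(condition$safe_payoff, length(u))
  } else {
    ifelse(u < 0.5, condition$risky_high, condition$risky_low)
  }
}

#' Sample one trial's outcomes
#'
#' Draws the obtained outcome for the chosen option and, under full feedback,
#' an independent foregone outcome for the unchosen option.
#'
#' @inheritParams p_high
#' @param trial Single trial index.
#' @param choice `"dynamic"` or `"reference"`.
#' @return One-row tibble with columns `trial`, `choice`, `outcome_obtained`,
#'   `outcome_foregone` (`NA` under partial feedback) and `p_high`.
#' @export
sample_trial <- function(condition, trial, choice = c("dynamic", "reference")) {
  choice <- match.arg(choice)
  check_trial(condition, trial)
  stopifnot(length(trial) == 1L)
  obtained <- draw_option_outcome(condition, trial, choice, stats::runif(1))
  foregone <- if (condition$feedback == "full") {
    other <- if (choice == "dynamic") "reference" else "dynamic"
    draw_option_outcome(condition, trial, other, stats::runif(1))
  } else {
    NA_real_
  }
  tibble::tibble(trial = as.integer(trial), choice = choice,
                 outcome_obtained = obtained, outcome_foregone = foregone,
                 p_high = p_high(condition, trial))
}

payoff_support <- function(condition, option) {
  if (option == "dynamic" || condition$composition == "risky_risky") {
    c(condition$risky_low, condition$risky_high)
  } else {
    condition$safe_payoff
  }
}

condition_cols <- function(condition) {
  tibble::tibble(direction = condition$direction,
                 feedback = condition$feedback,
                 composition = condition$composition)
}

#' Reconstruct a condition from trial-table columns
#'
#' Inverse of the condition columns written by [write_trial_csv()]: builds a
#' [condition()] from one participant's rows of a long trial table.
#'
#' @param df Data frame with columns `direction`, `feedback`, `composition`
#'   and `trial` (a single participant's rows).
#' @param safe_payoff,risky_high,risky_low Payoffs (the trial table stores
#'   probabilities and outcomes, not the payoff menu; defaults match the
#'   standard design).
#' @return A `choice_condition`.
#' @export
as_condition <- function(df, safe_payoff = 250, risky_high = 500,
                         risky_low = 0) {
  stopifnot(all(c("direction", "feedback", "trial") %in% names(df)))
  comp <- if ("composition" %in% names(df)) df$composition[1] else "safe_risky"
  condition(direction = df$direction[1], feedback = df$feedback[1],
            n_trials = max(df$trial), safe_payoff = safe_payoff,
            risky_high = risky_high, risky_low = risky_low,
            composition = comp)
}
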