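#' Reinforcement-learning model parameters
#'
#' Two expectancy-updating rules are supported. The delta rule moves the
#' chosen option's expectancy toward the obtained reward by a fraction
#' `phi`; the decay rule multiplies every expectancy by `d_rl` and adds the
#' reward to the updated option(s). Choice follows a softmax with inverse
#' temperature `theta`. Payoffs are divided by `outcome_scale` before
#' updating so `theta` is of order one.
#'
#' @param rule `"delta"` or `"decay"`.
#' @param phi Delta-rule learning rate in `[0, 1]` (delta only). Values near
#'   0 mean little updating (weak recency).
#' @param d_rl Decay parameter in `[0, 1]` (decay only). Values near 1 mean
#'   little forgetting (weak recency).
#' @param theta Softmax inverse temperature, >= 0, on scaled outcomes.
#' @param outcome_scale Divisor applied to payoffs before updating
#'   (default 500, the high risky payoff).
#' @param e0 Initial expectancy of every option, on the scaled-outcome scale.
#' @return An object of class `rl_params`.
#' @export
rl_params <- function(rule = c("delta", "decay"), phi = NULL, d_rl = NULL,
                      theta, outcome_scale = 500, e0 = 0) {
  rule <- match.arg(rule)
  if (rule == "delta") {
    if (is.null(phi) || !is.null(d_rl)) {
      stop("the delta rule takes `phi` (and no `d_rl`).", call. = FALSE)
    }
    if (phi < 0 || phi > 1) stop("`phi` must lie in [0, 1].", call. = FALSE)
  } else {
    if (is.null(d_rl) || !is.null(phi)) {
      stop("the decay rule takes `d_rl` (and no `phi`).", call. = FALSE)
    }
    if (d_rl < 0 || d_rl > 1) stop("`d_rl` must lie in [0, 1].", call. = FALSE)
  }
  if (theta < 0) stop("`theta` must be non-negative.", call. = FALSE)
  structure(list(rule = rule, phi = phi, d_rl = d_rl, theta = theta,
                 outcome_scale = outcome_scale, e0 = e0),
            class = "rl_params")
}

#' Delta-rule expectancy update
#'
#' `E_j <- E_j + delta_j * phi * (r_j - E_j)`: options with indicator
#' `delta_j = 1` move toward their reward by fraction `phi`; others are
#' untouched.
#'
#' @param E Named expectancy vector.
#' @param rewards Scaled rewards, aligned with `E` (may be `NA` where
#'   `delta = 0`).
#' @param phi Learning rate in `[0, 1]`.
#' @param delta 0/1 update indicator per option (1 = chosen, or both under
#'   full feedback).
#' @return Updated expectancy vector.
#' @export
delta_update <- function(E, rewards, phi, delta) {
  stopifnot(phi >= 0, phi <= 1, length(delta) == length(E))
  upd <- delta == 1
  if (any(upd & is.na(rewards))) {
    stop("reward missing for an option with delta = 1.", call. = FALSE)
  }
  E[upd] <- E[upd] + phi * (rewards[upd] - E[upd])
  E
}

#' Decay-rule expectancy update
#'
#' `E_j <- d_rl * E_j + delta_j * r_j`: every option's expectancy decays
#' multiplicatively; updated options additionally gain their reward.
#'
#' @inheritParams delta_update
#' @param d_rl Decay parameter in `[0, 1]`.
#' @return Updated expectancy vector.
#' @export
decay_update <- function(E, rewards, d_rl, delta) {
  stopifnot(d_rl >= 0, d_rl <= 1, length(delta) == length(E))
  upd <- delta == 1
  if (any(upd & is.na(rewards))) {
    stop("reward missing for an option with delta = 1.", call. = FALSE)
  }
  E <- d_rl * E
  E[upd] <- E[upd] + rewards[upd]
  E
}

#' Softmax choice probabilities
#'
#' `P(j) = exp(theta * E_j) / sum_k exp(theta * E_k)`, computed with
#' max-subtraction.
#'
#' @param E Expectancy vector.
#' @param theta Inverse temperature, >= 0.
#' @return Probability simplex over the options.
#' @export
softmax_prob <- function(E, theta) {
  stopifnot(theta >= 0)
  z <- theta * E
  e <- exp(z - max(z))
  e / sum(e)
}

# Deterministic replay of a choice/outcome sequence through an RL rule.
# Returns per-trial P(choose dynamic), emitted before each trial's update.
# choices: integer, 1 = dynamic, 2 = reference.
rl_replay <- function(choices, obtained, foregone, feedback, rule, par1,
                      theta, scale, e0) {
  n <- length(choices)
  E <- c(e0, e0)
  p <- numeric(n)
  full <- feedback == "full"
  for (t in seq_len(n)) {
    z1 <- theta * E[1]
    z2 <- theta * E[2]
    m <- max(z1, z2)
    e1 <- exp(z1 - m)
    p[t] <- e1 / (e1 + exp(z2 - m))
    ch <- choices[t]
    r_ch <- obtained[t] / scale
    if (full) {
      r <- c(0, 0)
      r[ch] <- r_ch
      r[3L - ch] <- foregone[t] / scale
      if (rule == "delta") E <- E + par1 * (r - E) else E <- par1 * E + r
    } else if (rule == "delta") {
      E[ch] <- E[ch] + par1 * (r_ch - E[ch])
    } else {
      E <- par1 * E
      E[ch] <- E[ch] + r_ch
    }
  }
  p
}

choices_to_index <- function(choice) {
  ifelse(choice == "dynamic", 1L, 2L)
}

#' One-step-ahead choice probabilities of an RL model
#'
#' Replays the participant's choices and outcomes through the update rule and
#' returns the softmax probability of choosing the dynamic option before each
#' trial's update. Deterministic: no Monte-Carlo is involved.
#'
#' @param params An [rl_params()].
#' @param trials One participant's trial tibble.
#' @param condition The participant's [condition()]; taken from
#'   `attr(trials, "condition")` when omitted.
#' @return Numeric vector of per-trial probabilities of choosing the dynamic
#'   option.
#' @export
predict_rl <- function(params, trials, condition = NULL) {
  if (is.null(condition)) condition <- attr(trials, "condition")
  stopifnot(inherits(params, "rl_params"), is_condition(condition))
  if (condition$feedback == "full" && anyNA(trials$outcome_foregone)) {
    stop("full-feedback data must carry foregone outcomes on every trial.",
         call. = FALSE)
  }
  par1 <- if (params$rule == "delta") params$phi else params$d_rl
  rl_replay(choices_to_index(trials$choice), trials$outcome_obtained,
            trials$outcome_foregone, condition$feedback, params$rule, par1,
            params$theta, params$outcome_scale, params$e0)
}

#' Simulate a reinforcement learner in a condition
#'
#' On each trial the agent chooses by a softmax draw over current
#' expectancies, outcomes are sampled from the condition's payoff schedule,
#' and expectancies are updated under the rule and feedback regime (both
#' options carry an update indicator of 1 under full feedback).
#'
#' @param params An [rl_params()].
#' @param condition A [condition()].
#' @param seed Optional integer seed.
#' @return A trial tibble like [simulate_ibl()]'s, with attribute
#'   `ground_truth` recording the generating rule and parameters.
#' @export
simulate_rl <- function(params, condition, seed = NULL) {
  stopifnot(inherits(params, "rl_params"), is_condition(condition))
  with_optional_seed(seed, {
    n <- condition$n_trials
    E <- c(params$e0, params$e0)
    par1 <- if (params$rule == "delta") params$phi else params$d_rl
    choice <- character(n)
    obtained <- numeric(n)
    foregone <- rep(NA_real_, n)
    full <- condition$feedback == "full"
    for (t in seq_len(n)) {
      pd <- softmax_prob(E, params$theta)[1]
      ch <- if (stats::runif(1) < pd) 1L else 2L
      choice[t] <- c("dynamic", "reference")[ch]
      obtained[t] <- draw_option_outcome(condition, t, choice[t],
                                         stats::runif(1))
      r_ch <- obtained[t] / params$outcome_scale
      if (full) {
        other <- c("reference", "dynamic")[ch]
        foregone[t] <- draw_option_outcome(condition, t, other,
                                           stats::runif(1))
        r <- c(0, 0)
        r[ch] <- r_ch
        r[3L - ch] <- foregone[t] / params$outcome_scale
        if (params$rule == "delta") {
          E <- E + par1 * (r - E)
        } else {
          E <- par1 * E + r
        }
      } else if (params$rule == "delta") {
        E[ch] <- E[ch] + par1 * (r_ch - E[ch])
      } else {
        E <- par1 * E
        E[ch] <- E[ch] + r_ch
      }
    }
    out <- tibble::tibble(trial = seq_len(n), choice = choice,
                          outcome_obtained = obtained,
                          outcome_foregone = foregone,
                          p_high = p_high(condition, seq_len(n)))
    attr(out, "condition") <- condition
    attr(out, "ground_truth") <- list(model = params$rule, phi = params$phi,
                                      d_rl = params$d_rl,
                                      theta = params$theta)
    out
  })
}
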