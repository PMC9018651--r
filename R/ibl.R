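#' Instance-based learning model parameters
#'
#' @param d Memory decay exponent (>= 0). Higher values discount older
#'   outcome instances more steeply, i.e. stronger recency.
#' @param sigma Activation noise scale (>= 0). The retrieval temperature is
#'   always derived as `tau = sigma * sqrt(2)` and never stored separately.
#' @param default_outcome Outcome value used to prepopulate each option with a
#'   single pseudo-instance at trial 0, so the first choice is defined before
#'   any outcome has been experienced. The optimistic default (the high risky
#'   payoff) induces early exploration of both options; the pseudo-instance is
#'   removed permanently once the option has a real instance.
#' @return An object of class `ibl_params`.
#' @export
ibl_params <- function(d, sigma, default_outcome = 500) {
  if (!is.numeric(d) || length(d) != 1L || d < 0) {
    stop("`d` must be a single non-negative number.", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("`sigma` must be a single non-negative number.", call. = FALSE)
  }
  structure(list(d = d, sigma = sigma, default_outcome = default_outcome),
            class = "ibl_params")
}

ibl_tau <- function(params) params$sigma * sqrt(2)

#' Activation of one outcome's instances
#'
#' Memory activation of outcome instances observed on trials `occurrences`,
#' evaluated at trial `t`: the log power-law sum over lags plus logistic
#' retrieval noise,
#' `sigma * log((1 - gamma) / gamma) + log(sum((t - occurrences)^-d))`.
#'
#' @param occurrences Integer vector of past trials on which the outcome was
#'   observed; all strictly before `t`, non-empty.
#' @param t Current trial.
#' @param d,sigma Decay and noise parameters (see [ibl_params()]).
#' @param gamma A fresh Uniform(0,1) draw in the open interval.
#' @return A finite activation value.
#' @export
activation <- function(occurrences, t, d, sigma, gamma) {
  if (length(occurrences) == 0L) {
    stop("`occurrences` must be non-empty; prepopulate options instead.",
         call. = FALSE)
  }
  if (any(occurrences >= t)) {
    stop("all `occurrences` must lie strictly before trial `t`.",
         call. = FALSE)
  }
  if (gamma <= 0 || gamma >= 1) {
    stop("`gamma` must lie strictly inside (0, 1).", call. = FALSE)
  }
  sigma * log((1 - gamma) / gamma) + log(sum((t - occurrences)^(-d)))
}

#' Retrieval probabilities over one option's outcomes
#'
#' Softmax of the activations at temperature `tau`, normalized over the
#' outcomes observed from the option under consideration. Computed with
#' max-subtraction; `tau = 0` is the hard-argmax limit with exact ties split
#' uniformly.
#'
#' @param activations Named or unnamed numeric vector, one activation per
#'   distinct outcome of the option.
#' @param tau Retrieval noise scale, `sigma * sqrt(2)`.
#' @return Probabilities of the same length, summing to 1.
#' @export
retrieval_probabilities <- function(activations, tau) {
  if (length(activations) == 0L) {
    stop("`activations` must be non-empty.", call. = FALSE)
  }
  if (tau == 0) {
    best <- activations == max(activations)
    return(best / sum(best))
  }
  z <- activations / tau
  e <- exp(z - max(z))
  e / sum(e)
}

#' Blended value of an option
#'
#' Retrieval-probability-weighted mean of the option's distinct outcome
#' values; always lies inside the range of the outcomes.
#'
#' @param probs Retrieval probability simplex (see
#'   [retrieval_probabilities()]).
#' @param outcomes Outcome values aligned with `probs`.
#' @return A value in points.
#' @export
blended_value <- function(probs, outcomes) {
  if (length(probs) != length(outcomes)) {
    stop("`probs` and `outcomes` must have the same length.", call. = FALSE)
  }
  sum(probs * outcomes)
}

#' Deterministic choice over blended values
#'
#' Picks the option with the highest blended value; exact ties are broken by
#' a fair coin.
#'
#' @param values Named numeric vector of blended values, one per option.
#' @return The name of the chosen option.
#' @export
ibl_choose <- function(values) {
  stopifnot(!is.null(names(values)))
  best <- which(values == max(values))
  if (length(best) > 1L) best <- sample(best, 1L)
  names(values)[best]
}

# Instance store: per option, parallel lists `outcomes` (distinct values) and
# `occ` (integer vectors of occurrence trials). A prepopulated option holds
# one pseudo-instance of `default_outcome` at trial 0 until its first real
# observation.
new_ibl_memory <- function(default_outcome = 500,
                           options = c("dynamic", "reference")) {
  mem <- lapply(options, function(o) {
    list(outcomes = default_outcome, occ = list(0L), prepop = TRUE)
  })
  names(mem) <- options
  mem
}

add_instance <- function(mem, option, outcome, trial) {
  m <- mem[[option]]
  if (isTRUE(m$prepop)) {
    m$outcomes <- numeric(0)
    m$occ <- list()
    m$prepop <- FALSE
  }
  i <- match(outcome, m$outcomes)
  if (is.na(i)) {
    m$outcomes <- c(m$outcomes, outcome)
    m$occ <- c(m$occ, list(as.integer(trial)))
  } else {
    m$occ[[i]] <- c(m$occ[[i]], as.integer(trial))
  }
  mem[[option]] <- m
  mem
}

#' Record a trial's outcomes in instance memory
#'
#' Under partial feedback one instance is stored (chosen option, obtained
#' outcome); under full feedback the foregone outcome of the unchosen option
#' is stored as a second instance on the same trial. An option's
#' prepopulated pseudo-instance is removed the first time it receives a real
#' instance.
#'
#' @param memory Memory as created by the simulators (see [simulate_ibl()]).
#' @param trial Trial index of the record.
#' @param choice Chosen option, `"dynamic"` or `"reference"`.
#' @param outcome_obtained Obtained outcome in points.
#' @param outcome_foregone Foregone outcome (required under full feedback).
#' @param feedback `"partial"` or `"full"`.
#' @return The updated memory.
#' @export
ibl_observe <- function(memory, trial, choice, outcome_obtained,
                        outcome_foregone = NA_real_,
                        feedback = c("partial", "full")) {
  feedback <- match.arg(feedback)
  memory <- add_instance(memory, choice, outcome_obtained, trial)
  if (feedback == "full") {
    if (is.na(outcome_foregone)) {
      stop("full feedback requires a foregone outcome.", call. = FALSE)
    }
    other <- if (choice == "dynamic") "reference" else "dynamic"
    memory <- add_instance(memory, other, outcome_foregone, trial)
  }
  memory
}

# Blended value of one option at trial t, one fresh gamma per outcome.
ibl_option_value <- function(m, t, d, sigma, tau) {
  g <- stats::runif(length(m$outcomes))
  g <- pmin(pmax(g, .Machine$double.eps), 1 - .Machine$double.eps)
  base <- vapply(m$occ, function(occ) log(sum((t - occ)^(-d))), numeric(1))
  a <- sigma * log((1 - g) / g) + base
  blended_value(retrieval_probabilities(a, tau), m$outcomes)
}

#' Simulate an instance-based learner in a condition
#'
#' Runs the model forward: on each trial a fresh noise draw per (option,
#' outcome) yields activations, retrieval probabilities and blended values;
#' the option with the higher blended value is chosen (ties by fair coin);
#' outcomes are sampled from the condition's payoff schedule and stored in
#' memory according to the feedback regime.
#'
#' @param params An [ibl_params()].
#' @param condition A [condition()].
#' @param seed Optional integer seed for exact reproducibility.
#' @return A tibble with one row per trial (`trial`, `choice`,
#'   `outcome_obtained`, `outcome_foregone`, `p_high`) carrying the condition
#'   as attribute `condition` and the generating parameters as attribute
#'   `ground_truth`.
#' @export
simulate_ibl <- function(params, condition, seed = NULL) {
  stopifnot(inherits(params, "ibl_params"), is_condition(condition))
  run <- function() {
    n <- condition$n_trials
    tau <- ibl_tau(params)
    mem <- new_ibl_memory(params$default_outcome)
    choice <- character(n)
    obtained <- numeric(n)
    foregone <- rep(NA_real_, n)
    for (t in seq_len(n)) {
      v <- c(
        dynamic = ibl_option_value(mem$dynamic, t, params$d, params$sigma, tau),
        reference = ibl_option_value(mem$reference, t, params$d, params$sigma, tau)
      )
      ch <- ibl_choose(v)
      choice[t] <- ch
      obtained[t] <- draw_option_outcome(condition, t, ch, stats::runif(1))
      if (condition$feedback == "full") {
        other <- if (ch == "dynamic") "reference" else "dynamic"
        foregone[t] <- draw_option_outcome(condition, t, other, stats::runif(1))
      }
      mem <- ibl_observe(mem, t, ch, obtained[t], foregone[t],
                         condition$feedback)
    }
    out <- tibble::tibble(trial = seq_len(n), choice = choice,
                          outcome_obtained = obtained,
                          outcome_foregone = foregone,
                          p_high = p_high(condition, seq_len(n)))
    attr(out, "condition") <- condition
    attr(out, "ground_truth") <- list(model = "ibl", d = params$d,
                                      sigma = params$sigma)
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Yoked memory snapshots: for each trial t, the distinct outcomes and lag
# vectors (t - t_p) of each option, after replaying the participant's own
# records through ibl_observe. Used by predict_ibl and fit_ibl.
ibl_history <- function(trials, condition, default_outcome = 500) {
  n <- nrow(trials)
  mem <- new_ibl_memory(default_outcome)
  snap <- vector("list", n)
  for (t in seq_len(n)) {
    snap[[t]] <- list(
      dynamic = list(x = mem$dynamic$outcomes,
                     lags = lapply(mem$dynamic$occ, function(o) t - o)),
      reference = list(x = mem$reference$outcomes,
                       lags = lapply(mem$reference$occ, function(o) t - o))
    )
    mem <- ibl_observe(mem, t, trials$choice[t], trials$outcome_obtained[t],
                       trials$outcome_foregone[t], condition$feedback)
  }
  snap
}

# Decay-dependent part of the activations: per trial and option, the
# log power-law lag sums. Depends on d only, so grid search caches it.
ibl_base_activations <- function(snap, d) {
  lapply(snap, function(s) list(
    dynamic = vapply(s$dynamic$lags, function(lg) log(sum(lg^(-d))),
                     numeric(1)),
    reference = vapply(s$reference$lags, function(lg) log(sum(lg^(-d))),
                       numeric(1))
  ))
}

# Per-trial P(choose dynamic) for one (d, sigma), given snapshots and a
# pre-drawn logistic noise stream L[[t]] = list(dynamic =, reference =)
# n_sims x n_outcomes matrices of log((1-gamma)/gamma) draws.
ibl_predict_core <- function(snap, d, sigma, noise, base = NULL) {
  if (is.null(base)) base <- ibl_base_activations(snap, d)
  n <- length(snap)
  n_sims <- nrow(noise[[1]]$dynamic)
  p <- numeric(n)
  sqrt2 <- sqrt(2)
  value_matrix <- function(side, base, L) {
    k <- length(base)
    if (sigma == 0) {
      pr <- retrieval_probabilities(base, 0)
      return(rep(sum(pr * side$x), n_sims))
    }
    # softmax((base + sigma * L) / (sigma * sqrt 2)) row-wise; k is tiny
    S <- L[, seq_len(k), drop = FALSE] / sqrt2 +
      matrix(base / (sigma * sqrt2), n_sims, k, byrow = TRUE)
    m <- do.call(pmax, lapply(seq_len(k), function(j) S[, j]))
    E <- exp(S - m)
    as.vector(E %*% side$x) / rowSums(E)
  }
  for (t in seq_len(n)) {
    vd <- value_matrix(snap[[t]]$dynamic, base[[t]]$dynamic,
                       noise[[t]]$dynamic)
    vr <- value_matrix(snap[[t]]$reference, base[[t]]$reference,
                       noise[[t]]$reference)
    p[t] <- (sum(vd > vr) + 0.5 * sum(vd == vr)) / n_sims
  }
  p
}

# Draw the shared noise stream: one logistic variate per (trial, option,
# outcome slot, simulation). Slots are padded to the maximum outcome count so
# the same stream serves every grid point (common random numbers).
ibl_noise_stream <- function(snap, n_sims, max_k = 3L) {
  lapply(snap, function(s) {
    kd <- max(length(s$dynamic$x), 1L)
    kr <- max(length(s$reference$x), 1L)
    g <- matrix(stats::runif(n_sims * max(kd, kr, max_k) * 2),
                nrow = n_sims * 2)
    L <- log((1 - g) / g)
    list(dynamic = L[seq_len(n_sims), , drop = FALSE],
         reference = L[n_sims + seq_len(n_sims), , drop = FALSE])
  })
}

#' One-step-ahead choice predictions of the instance model
#'
#' Rebuilds instance memory from the participant's experienced records (their
#' own choices and observed — and, under full feedback, foregone — outcomes)
#' and, before each trial, simulates the choice the model would make `n_sims`
#' times over fresh noise draws. The prediction is the fraction of
#' simulations choosing the dynamic option, clipped to
#' `[1/(2 n_sims), 1 - 1/(2 n_sims)]` so likelihoods stay finite. With
#' `mode = "free"` the model instead runs on its own simulated experience
#' (`n_sims` independent runs) and the prediction is the per-trial mean
#' simulated choice, unanchored to the participant's history.
#'
#' @param params An [ibl_params()].
#' @param trials One participant's trial tibble.
#' @param condition The participant's [condition()]; taken from
#'   `attr(trials, "condition")` when omitted.
#' @param n_sims Simulated predictions per trial.
#' @param seed Optional seed.
#' @param clip Clip predictions away from 0/1 (default `TRUE`).
#' @param mode `"yoked"` (default; memory driven by the participant's
#'   history) or `"free"` (free-running simulation).
#' @return Numeric vector of per-trial probabilities of choosing the dynamic
#'   option.
#' @export
predict_ibl <- function(params, trials, condition = NULL, n_sims = 1000,
                        seed = NULL, clip = TRUE,
                        mode = c("yoked", "free")) {
  mode <- match.arg(mode)
  if (is.null(condition)) condition <- attr(trials, "condition")
  stopifnot(inherits(params, "ibl_params"), is_condition(condition),
            n_sims >= 1)
  run <- function() {
    if (mode == "free") {
      sims <- replicate(n_sims,
                        simulate_ibl(params, condition)$choice == "dynamic")
      p <- rowMeans(sims)
    } else {
      snap <- ibl_history(trials, condition, params$default_outcome)
      noise <- ibl_noise_stream(snap, n_sims)
      p <- ibl_predict_core(snap, params$d, params$sigma, noise)
    }
    if (clip) clip_probs(p, n_sims) else p
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
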