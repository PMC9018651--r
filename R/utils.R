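# Clip Monte-Carlo choice probabilities away from 0/1 so log-likelihoods
# stay finite; floor 1/(2 n_sims) matches the resolution of the simulation.
clip_probs <- function(p, n_sims) {
  floor <- 1 / (2 * n_sims)
  pmin(pmax(p, floor), 1 - floor)
}

#' Negative log-likelihood of observed choices
#'
#' Bernoulli negative log-likelihood (in nats) of the observed choice
#' sequence under per-trial predicted probabilities of choosing the dynamic
#' option.
#'
#' @param predictions Per-trial probability of choosing the dynamic option,
#'   strictly inside (0, 1).
#' @param choices Observed choices, `"dynamic"`/`"reference"` (or a 0/1
#'   vector with 1 = dynamic).
#' @return Negative log-likelihood in nats.
#' @export
negative_log_likelihood <- function(predictions, choices) {
  if (is.character(choices) || is.factor(choices)) {
    choices <- as.integer(as.character(choices) == "dynamic")
  }
  if (length(predictions) != length(choices)) {
    stop("`predictions` and `choices` must have the same length.",
         call. = FALSE)
  }
  if (any(predictions <= 0 | predictions >= 1)) {
    stop("`predictions` must lie strictly inside (0, 1); clip first.",
         call. = FALSE)
  }
  -sum(choices * log(predictions) + (1 - choices) * log(1 - predictions))
}

# Run `expr` under `seed` when given, otherwise in the current RNG stream.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
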