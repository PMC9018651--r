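# Build a trial tibble from explicit choices, drawing outcomes from the
# condition's schedule under a fixed seed (used by analysis-level tests that
# need a known choice sequence).
trials_from_choices <- function(choices, cond, seed = 1) {
  withr::with_seed(seed, {
    n <- length(choices)
    obtained <- numeric(n)
    foregone <- rep(NA_real_, n)
    for (t in seq_len(n)) {
      row <- sample_trial(cond, t, choices[t])
      obtained[t] <- row$outcome_obtained
      foregone[t] <- row$outcome_foregone
    }
    out <- tibble::tibble(trial = seq_len(n), choice = choices,
                          outcome_obtained = obtained,
                          outcome_foregone = foregone,
                          p_high = p_high(cond, seq_len(n)))
    attr(out, "condition") <- cond
    out
  })
}

# Long-format cohort tibble from a list of per-participant trial tibbles.
bind_cohort <- function(sims, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("p%02d", seq_along(sims))
  dplyr::bind_rows(lapply(seq_along(sims), function(i) {
    cond <- attr(sims[[i]], "condition")
    dplyr::bind_cols(
      tibble::tibble(participant_id = ids[i]),
      tibble::tibble(direction = cond$direction, feedback = cond$feedback,
                     composition = cond$composition)[rep(1, nrow(sims[[i]])), ],
      sims[[i]]
    )
  }))
}

# Mean second-period maximization across simulated agents of one parameter set.
mean_p2_maximization <- function(d, sigma, cond, n_agents, seed) {
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_agents), function(i) {
      sim <- simulate_ibl(ibl_params(d, sigma), cond)
      maximization_rate(sim, cond, "p2")
    }, numeric(1)))
  })
}
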