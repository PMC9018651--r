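#' Grid specification for fitting the instance model
#'
#' The likelihood surface of the instance model is evaluated over a
#' rectangular grid of decay and noise values, with `n_sims`
#' Monte-Carlo-averaged predictions per trial at each grid point. The
#' `"fast"` profile (step 0.1, 200 simulations) is the default working
#' resolution; the `"exhaustive"` profile uses the full 0.01-step grid with
#' 1,000 simulations per trial and is orders of magnitude slower.
#'
#' @param d_min,d_max,d_step Decay grid: `seq(d_min, d_max, by = d_step)`,
#'   open interval (0, 5) by default.
#' @param sigma_min,sigma_max,sigma_step Noise grid over (0, 3).
#' @param n_sims Simulated predictions per trial and grid point.
#' @param profile Convenience presets: `"fast"` leaves the defaults,
#'   `"exhaustive"` sets both steps to 0.01 and `n_sims` to 1000.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(d_min = 0.01, d_max = 4.99, d_step = 0.1,
                      sigma_min = 0.01, sigma_max = 2.99, sigma_step = 0.1,
                      n_sims = 200, profile = c("fast", "exhaustive")) {
  profile <- match.arg(profile)
  if (profile == "exhaustive") {
    d_step <- 0.01
    sigma_step <- 0.01
    n_sims <- 1000
  }
  stopifnot(d_min > 0, d_max > d_min, d_step > 0,
            sigma_min > 0, sigma_max > sigma_min, sigma_step > 0,
            n_sims >= 1)
  structure(list(d = seq(d_min, d_max, by = d_step),
                 sigma = seq(sigma_min, sigma_max, by = sigma_step),
                 n_sims = as.integer(n_sims)),
            class = "grid_spec")
}

fit_result_row <- function(participant_id, model, condition, nll, n_trials,
                           n_params, d = NA_real_, sigma = NA_real_,
                           phi = NA_real_, d_rl = NA_real_,
                           theta = NA_real_, n_sims_or_starts, seed,
                           convergence = 0L, settings = NA_character_) {
  dplyr::bind_cols(
    tibble::tibble(participant_id = participant_id, model = model),
    condition_cols(condition),
    tibble::tibble(d = d, sigma = sigma, phi = phi, d_rl = d_rl,
                   theta = theta, nll = nll, n_params = n_params,
                   aic = 2 * n_params + 2 * nll,
                   bic = n_params * log(n_trials) + 2 * nll,
                   n_sims_or_starts = n_sims_or_starts,
                   seed = if (is.null(seed)) NA_integer_ else seed,
                   convergence = convergence, settings = settings)
  )
}

#' Fit the instance model to one participant by grid search
#'
#' Evaluates the negative log-likelihood of the participant's choices under
#' [predict_ibl()] at every (d, sigma) grid point and returns the minimum.
#' A single noise stream, drawn once from `seed`, is reused at every grid
#' point (common random numbers), so the surface is smooth in the parameters
#' and re-evaluation is bitwise-reproducible. Ties are broken toward smaller
#' `d`, then smaller `sigma`.
#'
#' @param trials One participant's trial tibble.
#' @param condition The participant's [condition()]; defaults to
#'   `attr(trials, "condition")`.
#' @param grid A [grid_spec()].
#' @param seed Optional seed for the shared noise stream.
#' @param participant_id Identifier copied into the result.
#' @param default_outcome Prepopulation outcome (see [ibl_params()]).
#' @return A one-row fit tibble (parameters, `nll`, AIC/BIC, metadata).
#' @export
fit_ibl <- function(trials, condition = NULL, grid = grid_spec(),
                    seed = NULL, participant_id = "p1",
                    default_outcome = 500) {
  if (is.null(condition)) condition <- attr(trials, "condition")
  stopifnot(inherits(grid, "grid_spec"), is_condition(condition))
  n <- nrow(trials)
  choices <- as.integer(trials$choice == "dynamic")
  snap <- ibl_history(trials, condition, default_outcome)
  noise <- with_optional_seed(seed, ibl_noise_stream(snap, grid$n_sims))
  nll <- matrix(NA_real_, nrow = length(grid$sigma), ncol = length(grid$d))
  for (j in seq_along(grid$d)) {
    base <- ibl_base_activations(snap, grid$d[j])
    for (i in seq_along(grid$sigma)) {
      p <- clip_probs(
        ibl_predict_core(snap, grid$d[j], grid$sigma[i], noise, base),
        grid$n_sims)
      nll[i, j] <- -sum(choices * log(p) + (1 - choices) * log(1 - p))
    }
  }
  # column-major scan of nll[sigma, d] visits sigma fastest within each d,
  # so which.min's first-index rule prefers smaller d, then smaller sigma
  best <- arrayInd(which.min(nll), dim(nll))
  fit_result_row(
    participant_id, "ibl", condition, nll = min(nll), n_trials = n,
    n_params = 2L, d = grid$d[best[2]], sigma = grid$sigma[best[1]],
    n_sims_or_starts = grid$n_sims, seed = seed,
    settings = sprintf("grid_step_d=%g;grid_step_sigma=%g;default_outcome=%g",
                       grid$d[2] - grid$d[1], grid$sigma[2] - grid$sigma[1],
                       default_outcome)
  )
}

#' Fit a reinforcement-learning model to one participant
#'
#' Multi-start Nelder-Mead maximum likelihood. Start points come from a
#' Latin-hypercube design over the bounded box (`phi` or `d_rl` in `[0, 1]`,
#' `theta` in `[0, theta_max]`); the search runs in transformed space (logit
#' for the unit-interval parameter, log for `theta`, with `theta` clamped at
#' `theta_max` inside the objective) and the best solution is mapped back to
#' natural units.
#'
#' @inheritParams fit_ibl
#' @param rule `"delta"` or `"decay"`.
#' @param n_starts Number of start points.
#' @param theta_max Upper clamp for the inverse temperature on scaled
#'   outcomes.
#' @param outcome_scale,e0 Payoff scaling and initial expectancy (see
#'   [rl_params()]).
#' @return A one-row fit tibble.
#' @export
fit_rl <- function(trials, condition = NULL, rule = c("delta", "decay"),
                   n_starts = 25, seed = NULL, participant_id = "p1",
                   theta_max = 20, outcome_scale = 500, e0 = 0) {
  rule <- match.arg(rule)
  if (is.null(condition)) condition <- attr(trials, "condition")
  stopifnot(is_condition(condition), n_starts >= 1)
  n <- nrow(trials)
  choices_idx <- choices_to_index(trials$choice)
  choices01 <- as.integer(choices_idx == 1L)
  obtained <- trials$outcome_obtained
  foregone <- trials$outcome_foregone
  feedback <- condition$feedback
  objective <- function(z) {
    par1 <- stats::plogis(z[1])
    theta <- min(exp(z[2]), theta_max)
    p <- rl_replay(choices_idx, obtained, foregone, feedback, rule, par1,
                   theta, outcome_scale, e0)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(choices01 * log(p) + (1 - choices01) * log(1 - p))
  }
  starts <- with_optional_seed(seed, lhs::randomLHS(as.integer(n_starts), 2))
  best <- NULL
  any_converged <- FALSE
  for (s in seq_len(nrow(starts))) {
    z0 <- c(stats::qlogis(0.02 + 0.96 * starts[s, 1]),
            log(0.05 + (theta_max - 0.05) * starts[s, 2]))
    opt <- stats::optim(z0, objective, method = "Nelder-Mead",
                        control = list(maxit = 500))
    if (opt$convergence == 0L) any_converged <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  par1 <- stats::plogis(best$par[1])
  theta <- min(exp(best$par[2]), theta_max)
  fit_result_row(
    participant_id, rule, condition, nll = best$value, n_trials = n,
    n_params = 2L,
    phi = if (rule == "delta") par1 else NA_real_,
    d_rl = if (rule == "decay") par1 else NA_real_,
    theta = theta, n_sims_or_starts = as.integer(n_starts), seed = seed,
    convergence = if (any_converged) 0L else 1L,
    settings = sprintf("theta_max=%g;outcome_scale=%g;e0=%g",
                       theta_max, outcome_scale, e0)
  )
}

#' Fit a cohort of participants under one or more models
#'
#' Applies [fit_ibl()] and/or [fit_rl()] to every participant in a long
#' trial table and returns a tidy fit table, one row per participant and
#' model. Per-participant failures are caught and logged, not fatal. Each
#' participant gets a deterministic sub-seed derived from `seed`.
#'
#' @param cohort Long trial tibble (multiple participants; the format
#'   produced by [generate_cohort()] or [read_trial_csv()]).
#' @param models Subset of `c("ibl", "delta", "decay")`.
#' @param grid A [grid_spec()] for the instance-model fits.
#' @param n_starts Start points for the RL fits.
#' @param seed Integer seed governing all Monte-Carlo and start-point draws.
#' @param progress Emit a message per participant.
#' @return Tidy fit tibble; attribute `failures` lists any participants that
#'   could not be fitted.
#' @export
fit_cohort <- function(cohort, models = c("ibl", "delta", "decay"),
                       grid = grid_spec(), n_starts = 25, seed = 1,
                       progress = FALSE) {
  if (length(models) == 0L) stop("`models` must be non-empty.", call. = FALSE)
  models <- match.arg(models, c("ibl", "delta", "decay"), several.ok = TRUE)
  if (nrow(cohort) == 0L) stop("`cohort` is empty.", call. = FALSE)
  ids <- unique(cohort$participant_id)
  failures <- character(0)
  rows <- vector("list", length(ids) * length(models))
  k <- 0L
  for (i in seq_along(ids)) {
    pid <- ids[i]
    trials <- dplyr::arrange(cohort[cohort$participant_id == pid, ], .data$trial)
    cond <- as_condition(trials)
    pseed <- (seed * 1009L + i * 7919L) %% .Machine$integer.max
    if (progress) message("fitting ", pid, " (", i, "/", length(ids), ")")
    for (m in models) {
      k <- k + 1L
      rows[[k]] <- tryCatch({
        if (m == "ibl") {
          fit_ibl(trials, cond, grid = grid, seed = pseed,
                  participant_id = pid)
        } else {
          fit_rl(trials, cond, rule = m, n_starts = n_starts, seed = pseed,
                 participant_id = pid)
        }
      }, error = function(e) {
        failures <<- c(failures, sprintf("%s/%s: %s", pid, m,
                                         conditionMessage(e)))
        NULL
      })
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- failures
  out
}
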