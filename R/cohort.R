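#' Default parameter priors for synthetic cohorts
#'
#' Generating distributions for the synthetic agents, centered on the
#' regimes the fitted human cohorts occupy: decay `d` log-normal truncated
#' to (0, 5); noise `sigma` uniform on (0.05, 1.5); delta-rule `phi` and
#' decay-rule `d_rl` Beta; inverse temperature `theta` log-normal, with a
#' lower center for the decay rule because decay-rule expectancies are
#' several times larger in magnitude than delta-rule ones (steady state
#' `r / (1 - d_rl)` vs a convex combination of rewards), so a shared theta
#' scale would make most decay agents deterministic perseverators —
#' behavior outside the range real cohorts show.
#'
#' @return Named list of prior settings, one entry per parameter.
#' @export
default_priors <- function() {
  list(
    d = list(meanlog = log(0.8), sdlog = 0.6, min = 0, max = 5),
    sigma = list(min = 0.05, max = 1.5),
    phi = list(shape1 = 1.5, shape2 = 4),
    d_rl = list(shape1 = 5, shape2 = 1.5),
    theta_delta = list(meanlog = log(3), sdlog = 0.5),
    theta_decay = list(meanlog = log(1), sdlog = 0.6)
  )
}

rtrunc_lnorm <- function(n, meanlog, sdlog, min, max) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    out <- c(out, x[x > min & x < max])
  }
  out[seq_len(n)]
}

#' Specify a synthetic cohort
#'
#' @param n_per_cell Participants per design cell.
#' @param directions,feedbacks,compositions Design cells to cross.
#' @param generator Generating model: `"ibl"`, `"delta"`, `"decay"`, or
#'   `"mixture"` (each participant's model drawn uniformly from the three).
#' @param priors Parameter priors, see [default_priors()].
#' @param n_trials Trials per participant.
#' @param seed Mandatory integer seed; the cohort is fully reproducible
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_cell,
                        directions = c("increasing", "decreasing"),
                        feedbacks = c("partial", "full"),
                        compositions = "safe_risky",
                        generator = c("ibl", "delta", "decay", "mixture"),
                        priors = default_priors(),
                        n_trials = 100L,
                        seed) {
  generator <- match.arg(generator)
  if (missing(seed) || !is.numeric(seed)) {
    stop("`seed` is mandatory for a cohort spec.", call. = FALSE)
  }
  stopifnot(n_per_cell >= 1)
  directions <- match.arg(directions, c("static", "increasing", "decreasing"),
                          several.ok = TRUE)
  feedbacks <- match.arg(feedbacks, c("partial", "full"), several.ok = TRUE)
  compositions <- match.arg(compositions, c("safe_risky", "risky_risky"),
                            several.ok = TRUE)
  if (priors$sigma$min < 0 || priors$sigma$max <= priors$sigma$min ||
      priors$d$min < 0 || priors$d$max <= priors$d$min) {
    stop("invalid prior bounds.", call. = FALSE)
  }
  structure(list(n_per_cell = as.integer(n_per_cell),
                 directions = directions, feedbacks = feedbacks,
                 compositions = compositions, generator = generator,
                 priors = priors, n_trials = as.integer(n_trials),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

sample_agent_params <- function(model, priors) {
  pr <- priors
  switch(model,
    ibl = list(d = rtrunc_lnorm(1, pr$d$meanlog, pr$d$sdlog, pr$d$min,
                                pr$d$max),
               sigma = stats::runif(1, pr$sigma$min, pr$sigma$max)),
    delta = list(phi = stats::rbeta(1, pr$phi$shape1, pr$phi$shape2),
                 theta = stats::rlnorm(1, pr$theta_delta$meanlog,
                                       pr$theta_delta$sdlog)),
    decay = list(d_rl = stats::rbeta(1, pr$d_rl$shape1, pr$d_rl$shape2),
                 theta = stats::rlnorm(1, pr$theta_decay$meanlog,
                                       pr$theta_decay$sdlog))
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' For each participant: a generating model and parameters are sampled from
#' the spec's priors, the matching simulator is run in the participant's
#' design cell, and the trials are collected into one long tibble. Fully
#' reproducible from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `trials` (long trial tibble: `participant_id`,
#'   condition columns, `trial`, `choice`, `choice_label`,
#'   `outcome_obtained`, `outcome_foregone`, `p_high`) and `ground_truth`
#'   (one row per participant: `participant_id`, `model`, `d`, `sigma`,
#'   `phi`, `d_rl`, `theta`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    cells <- expand.grid(direction = spec$directions,
                         feedback = spec$feedbacks,
                         composition = spec$compositions,
                         stringsAsFactors = FALSE)
    trial_rows <- list()
    gt_rows <- list()
    pnum <- 0L
    for (ci in seq_len(nrow(cells))) {
      cond <- condition(direction = cells$direction[ci],
                        feedback = cells$feedback[ci],
                        composition = cells$composition[ci],
                        n_trials = spec$n_trials)
      for (k in seq_len(spec$n_per_cell)) {
        pnum <- pnum + 1L
        pid <- sprintf("synth_%03d", pnum)
        model <- if (spec$generator == "mixture") {
          sample(c("ibl", "delta", "decay"), 1L)
        } else {
          spec$generator
        }
        pars <- sample_agent_params(model, spec$priors)
        sim <- if (model == "ibl") {
          simulate_ibl(ibl_params(pars$d, pars$sigma), cond)
        } else if (model == "delta") {
          simulate_rl(rl_params("delta", phi = pars$phi, theta = pars$theta),
                      cond)
        } else {
          simulate_rl(rl_params("decay", d_rl = pars$d_rl,
                                theta = pars$theta), cond)
        }
        trial_rows[[pnum]] <- dplyr::bind_cols(
          tibble::tibble(participant_id = pid),
          condition_cols(cond)[rep(1, nrow(sim)), ],
          tibble::tibble(
            trial = sim$trial, choice = sim$choice,
            choice_label = ifelse(sim$choice == "dynamic", "risky", "safe"),
            outcome_obtained = sim$outcome_obtained,
            outcome_foregone = sim$outcome_foregone, p_high = sim$p_high)
        )
        gt_rows[[pnum]] <- tibble::tibble(
          participant_id = pid, model = model,
          d = pars$d %||% NA_real_, sigma = pars$sigma %||% NA_real_,
          phi = pars$phi %||% NA_real_, d_rl = pars$d_rl %||% NA_real_,
          theta = pars$theta %||% NA_real_)
      }
    }
    list(trials = dplyr::bind_rows(trial_rows),
         ground_truth = dplyr::bind_rows(gt_rows))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

trial_csv_cols <- c("participant_id", "direction", "feedback", "composition",
                    "trial", "choice", "choice_label", "outcome_obtained",
                    "outcome_foregone", "p_high")

#' Write / read a long-format trial CSV
#'
#' One row per participant and trial; header required; UTF-8; a missing
#' foregone outcome (partial feedback) is an empty field, never 0. Reading
#' validates the schema — contiguous 1..n trials per participant, outcomes
#' inside the payoff support, foregone present exactly when feedback is full
#' — and reports offending rows by line number.
#'
#' @param cohort Long trial tibble (the `trials` element of
#'   [generate_cohort()]).
#' @param path File path.
#' @return `write_trial_csv()` returns `path` invisibly; `read_trial_csv()`
#'   returns the validated trial tibble.
#' @export
write_trial_csv <- function(cohort, path) {
  stopifnot(all(setdiff(trial_csv_cols, "choice_label") %in% names(cohort)))
  if (!"choice_label" %in% names(cohort)) {
    cohort$choice_label <- ifelse(cohort$choice == "dynamic", "risky", "safe")
  }
  readr::write_csv(cohort[, trial_csv_cols], path, na = "")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      participant_id = readr::col_character(),
      direction = readr::col_character(),
      feedback = readr::col_character(),
      composition = readr::col_character(),
      trial = readr::col_integer(),
      choice = readr::col_character(),
      choice_label = readr::col_character(),
      outcome_obtained = readr::col_double(),
      outcome_foregone = readr::col_double(),
      p_high = readr::col_double()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(setdiff(trial_csv_cols, "choice_label"), names(df))
  if (length(missing_cols) > 0L) {
    stop("trial CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # line numbers: header is line 1
  row_line <- function(i) i + 1L
  bad <- which(!df$direction %in% c("static", "increasing", "decreasing") |
                 !df$feedback %in% c("partial", "full") |
                 !df$choice %in% c("dynamic", "reference"))
  if (length(bad) > 0L) {
    stop("invalid factor level at line ", row_line(bad[1]), ".",
         call. = FALSE)
  }
  for (pid in unique(df$participant_id)) {
    rows <- which(df$participant_id == pid)
    sub <- df[rows, ]
    if (!identical(sort(sub$trial), seq_len(max(sub$trial)))) {
      stop("participant ", pid, " has non-contiguous or duplicated trials ",
           "(rows near line ", row_line(rows[1]), ").", call. = FALSE)
    }
  }
  # payoff-support and foregone-presence checks, vectorized (default menu:
  # safe 250, risky 0/500)
  risky_side <- df$choice == "dynamic" | df$composition == "risky_risky"
  ok_obtained <- ifelse(risky_side, df$outcome_obtained %in% c(0, 500),
                        df$outcome_obtained == 250)
  bad <- which(!ok_obtained)
  if (length(bad) > 0L) {
    stop("outcome ", df$outcome_obtained[bad[1]],
         " outside the payoff support at line ", row_line(bad[1]), ".",
         call. = FALSE)
  }
  full <- df$feedback == "full"
  bad <- which(full & is.na(df$outcome_foregone))
  if (length(bad) > 0L) {
    stop("full-feedback row missing a foregone outcome at line ",
         row_line(bad[1]), ".", call. = FALSE)
  }
  bad <- which(!full & !is.na(df$outcome_foregone))
  if (length(bad) > 0L) {
    stop("partial-feedback row carries a foregone outcome at line ",
         row_line(bad[1]), ".", call. = FALSE)
  }
  other_risky <- df$choice == "reference" | df$composition == "risky_risky"
  ok_foregone <- !full | ifelse(other_risky,
                                df$outcome_foregone %in% c(0, 500),
                                df$outcome_foregone == 250)
  bad <- which(!ok_foregone)
  if (length(bad) > 0L) {
    stop("foregone outcome outside the payoff support at line ",
         row_line(bad[1]), ".", call. = FALSE)
  }
  df
}

#' Write a ground-truth CSV
#'
#' @param ground_truth The `ground_truth` tibble of [generate_cohort()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(ground_truth, path) {
  readr::write_csv(ground_truth, path, na = "")
  invisible(path)
}
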