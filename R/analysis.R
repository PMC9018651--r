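period_trials <- function(period, n_trials) {
  half <- n_trials %/% 2
  switch(period,
    p1 = seq_len(half),
    p2 = seq(half + 1L, n_trials),
    last30 = seq(n_trials - 29L, n_trials),
    stop("unknown period: ", period, call. = FALSE)
  )
}

# Per-trial maximizing labels with the turning-point rule: the tie trial at
# the exact EV crossing (trial 50 of the standard schedules) takes Period 1's
# label for period-level rates.
maximizing_labels <- function(condition) {
  t <- seq_len(condition$n_trials)
  lab <- maximizing_option(condition, t)
  mid <- condition$n_trials %/% 2
  if (condition$direction != "static" && is.na(lab[mid]) && mid > 1L) {
    lab[mid] <- lab[mid - 1L]
  }
  lab
}

#' Maximization rate within a task period
#'
#' Fraction of the period's trials on which the choice equals the maximizing
#' (higher expected value) option. Trials with tied expected values are
#' excluded from the denominator, except the exact turning point, which takes
#' the first period's maximizing label. Undefined for the static condition
#' (every trial ties): returns `NA` with a warning.
#'
#' @param trials One participant's trial tibble.
#' @param condition The participant's [condition()]; defaults to
#'   `attr(trials, "condition")`.
#' @param period `"p1"` (first half), `"p2"` (second half) or `"last30"`
#'   (final 30 trials).
#' @return Proportion in `[0, 1]`, or `NA` for the static condition.
#' @export
maximization_rate <- function(trials, condition = NULL,
                              period = c("p1", "p2", "last30")) {
  period <- match.arg(period)
  if (is.null(condition)) condition <- attr(trials, "condition")
  stopifnot(is_condition(condition))
  if (condition$direction == "static") {
    warning("maximization is undefined in the static condition (tied EVs).",
            call. = FALSE)
    return(NA_real_)
  }
  idx <- period_trials(period, condition$n_trials)
  lab <- maximizing_labels(condition)[idx]
  ch <- trials$choice[match(idx, trials$trial)]
  ok <- !is.na(lab)
  mean(ch[ok] == lab[ok])
}

#' Period summaries for a cohort
#'
#' Per-participant maximization and risky-choice rates in the standard
#' periods (first half, second half, last 30 trials).
#'
#' @param cohort Long trial tibble.
#' @return Tidy tibble: `participant_id`, condition columns, `period`,
#'   `maximization_rate`, `risky_rate`.
#' @export
period_summary <- function(cohort) {
  ids <- unique(cohort$participant_id)
  purrr::map_dfr(ids, function(pid) {
    trials <- dplyr::arrange(cohort[cohort$participant_id == pid, ],
                             .data$trial)
    cond <- as_condition(trials)
    purrr::map_dfr(c("p1", "p2", "last30"), function(per) {
      idx <- period_trials(per, cond$n_trials)
      ch <- trials$choice[match(idx, trials$trial)]
      mr <- if (cond$direction == "static") {
        NA_real_
      } else {
        suppressWarnings(maximization_rate(trials, cond, per))
      }
      dplyr::bind_cols(
        tibble::tibble(participant_id = pid),
        condition_cols(cond),
        tibble::tibble(period = per, maximization_rate = mr,
                       risky_rate = mean(ch == "dynamic"))
      )
    })
  })
}

median_split <- function(x, labels = c("high", "low")) {
  med <- stats::median(x)
  degenerate <- length(unique(x)) == 1L
  list(group = ifelse(x >= med, labels[1], labels[2]),
       median = med, degenerate = degenerate)
}

#' Classify participants as adaptive or non-adaptive
#'
#' Median split on maximization performance in the last 30 trials, within
#' each direction-by-feedback cell. Participants at the median go to the
#' adaptive group (so with heavy ties the groups can differ in size by more
#' than one). Static-condition participants are excluded (undefined
#' maximization). Cells in which every rate is identical are flagged
#' `degenerate`.
#'
#' @param summaries Output of [period_summary()] (or any tibble with
#'   `participant_id`, `direction`, `feedback`, `period`,
#'   `maximization_rate`).
#' @return Tibble: `participant_id`, `direction`, `feedback`,
#'   `maximization_last30`, `adaptation` (`"adaptive"`/`"non_adaptive"`),
#'   `cell_median`, `degenerate`.
#' @export
classify_adaptation <- function(summaries) {
  last30 <- summaries[summaries$period == "last30" &
                        !is.na(summaries$maximization_rate), ]
  if (nrow(last30) == 0L) {
    stop("no participants with a defined last-30 maximization rate.",
         call. = FALSE)
  }
  out <- last30 |>
    dplyr::group_by(.data$direction, .data$feedback) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2L) {
        stop("a median split needs at least 2 participants per cell.",
             call. = FALSE)
      }
      sp <- median_split(df$maximization_rate,
                         labels = c("adaptive", "non_adaptive"))
      if (sp$degenerate) {
        warning(sprintf("degenerate split (all rates equal) in cell %s/%s.",
                        key$direction, key$feedback), call. = FALSE)
      }
      tibble::tibble(participant_id = df$participant_id,
                     maximization_last30 = df$maximization_rate,
                     adaptation = sp$group, cell_median = sp$median,
                     degenerate = sp$degenerate)
    }) |>
    dplyr::ungroup()
  out
}

#' Split fitted participants into high- and low-recency groups
#'
#' Median split on the best-fitting decay parameter `d` within each
#' direction-by-feedback cell; `d` at or above the cell median is high
#' recency. Also reports each cell's mean high and low `d` (the quantities
#' shown per panel in the generalization analysis).
#'
#' @param fits Instance-model fit tibble (rows with `model == "ibl"`), as
#'   produced by [fit_cohort()].
#' @return Tibble of assignments (`participant_id`, cell columns, `d`,
#'   `sigma`, `recency`), with attribute `summary`: per-cell mean high/low
#'   `d` and group sizes.
#' @export
recency_split <- function(fits) {
  fits <- fits[fits$model == "ibl", ]
  if (nrow(fits) == 0L) stop("no instance-model fits supplied.", call. = FALSE)
  assign <- fits |>
    dplyr::group_by(.data$direction, .data$feedback) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2L) {
        stop("a median split needs at least 2 participants per cell.",
             call. = FALSE)
      }
      sp <- median_split(df$d)
      if (sp$degenerate) {
        warning(sprintf("degenerate split (all d equal) in cell %s/%s.",
                        key$direction, key$feedback), call. = FALSE)
      }
      tibble::tibble(participant_id = df$participant_id, d = df$d,
                     sigma = df$sigma, recency = sp$group,
                     cell_median = sp$median, degenerate = sp$degenerate)
    }) |>
    dplyr::ungroup()
  summary <- assign |>
    dplyr::group_by(.data$direction, .data$feedback, .data$recency) |>
    dplyr::summarise(mean_d = mean(.data$d), n = dplyr::n(),
                     .groups = "drop")
  attr(assign, "summary") <- summary
  assign
}

#' Calibration-to-test generalization simulation
#'
#' Samples fitted (d, sigma) pairs — intact pairs, with replacement — from
#' each calibration group, simulates that many instance-based learners in
#' the test condition, and returns per-trial mean maximization and
#' risky-choice curves per group with Monte-Carlo standard errors.
#'
#' @param calibration Tibble of fitted parameters with columns `d`, `sigma`
#'   and optionally `recency` (or any grouping column named by `group_col`);
#'   typically the output of [recency_split()].
#' @param test_condition The [condition()] in which behavior is simulated.
#' @param n_agents Simulated agents per group.
#' @param seed Optional seed.
#' @param group_col Name of the grouping column; groups are simulated
#'   separately. When absent, all rows form one group `"all"`.
#' @return Tibble: `group`, `trial`, `p_high`, `mean_maximize`,
#'   `mean_risky`, `mc_se`, `n_agents`.
#' @export
generalize <- function(calibration, test_condition, n_agents = 1000,
                       seed = NULL, group_col = "recency") {
  stopifnot(is_condition(test_condition), n_agents >= 1)
  if (nrow(calibration) == 0L) {
    stop("`calibration` must be non-empty.", call. = FALSE)
  }
  groups <- if (group_col %in% names(calibration)) {
    split(calibration, calibration[[group_col]])
  } else {
    list(all = calibration)
  }
  lab <- maximizing_labels(test_condition)
  n_tr <- test_condition$n_trials
  with_optional_seed(seed, {
    purrr::map_dfr(names(groups), function(g) {
      pool <- groups[[g]]
      idx <- sample.int(nrow(pool), n_agents, replace = TRUE)
      risky <- matrix(0L, n_agents, n_tr)
      for (a in seq_len(n_agents)) {
        sim <- simulate_ibl(ibl_params(pool$d[idx[a]], pool$sigma[idx[a]]),
                            test_condition)
        risky[a, ] <- sim$choice == "dynamic"
      }
      # trials with tied EVs (no defined maximizing option) stay NA
      maxi <- matrix(NA_real_, n_agents, n_tr)
      dyn_t <- which(lab == "dynamic")
      ref_t <- which(lab == "reference")
      maxi[, dyn_t] <- risky[, dyn_t]
      maxi[, ref_t] <- 1 - risky[, ref_t]
      tibble::tibble(
        group = g, trial = seq_len(n_tr),
        p_high = p_high(test_condition, seq_len(n_tr)),
        mean_maximize = colMeans(maxi),
        mean_risky = colMeans(risky),
        mc_se = apply(risky, 2, stats::sd) / sqrt(n_agents),
        n_agents = n_agents
      )
    })
  })
}

#' Risky-choice proportions by block
#'
#' Mean dynamic-option choice per block of trials and design cell — the
#' descriptive backbone of learning-curve plots.
#'
#' @param cohort Long trial tibble.
#' @param block_size Trials per block (default 20). A trailing short block
#'   is kept with a warning.
#' @return Tibble: condition columns, `block`, `n_trials`, `risky_rate`.
#' @export
block_summary <- function(cohort, block_size = 20) {
  if (nrow(cohort) == 0L) stop("`cohort` is empty.", call. = FALSE)
  if (max(cohort$trial) %% block_size != 0) {
    warning("`block_size` does not divide the trial count; last block is short.",
            call. = FALSE)
  }
  cohort |>
    dplyr::mutate(block = ceiling(.data$trial / block_size)) |>
    dplyr::group_by(.data$direction, .data$feedback, .data$composition,
                    .data$block) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     risky_rate = mean(.data$choice == "dynamic"),
                     .groups = "drop")
}
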