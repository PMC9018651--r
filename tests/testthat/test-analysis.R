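test_that("maximization rates follow the schedule's turning point", {
  dec <- condition("decreasing", "partial")
  inc <- condition("increasing", "partial")
  always_risky <- trials_from_choices(rep("dynamic", 100), dec)
  expect_equal(maximization_rate(always_risky, dec, "p1"), 1.0)
  expect_equal(maximization_rate(always_risky, dec, "p2"), 0.0)
  always_safe <- trials_from_choices(rep("reference", 100), inc)
  expect_equal(maximization_rate(always_safe, inc, "p1"), 1.0)
  expect_equal(maximization_rate(always_safe, inc, "p2"), 0.0)
  # a per-trial maximizer scores 1 in both periods
  lab <- choiceadapt:::maximizing_labels(inc)
  lab[is.na(lab)] <- "reference"
  maximizer <- trials_from_choices(lab, inc)
  expect_equal(maximization_rate(maximizer, inc, "p1"), 1.0)
  expect_equal(maximization_rate(maximizer, inc, "p2"), 1.0)
  sta <- condition("static", "partial")
  expect_warning(r <- maximization_rate(trials_from_choices(
    rep("dynamic", 100), sta), sta, "last30"), "undefined")
  expect_true(is.na(r))
})

test_that("adaptive/non-adaptive median splits behave as specified", {
  mk <- function(rates) {
    tibble::tibble(participant_id = sprintf("p%d", seq_along(rates)),
                   direction = "increasing", feedback = "partial",
                   period = "last30", maximization_rate = rates)
  }
  cls <- classify_adaptation(mk(c(0.1, 0.2, 0.8, 0.9)))
  expect_equal(sum(cls$adaptation == "adaptive"), 2)
  expect_setequal(cls$participant_id[cls$adaptation == "adaptive"],
                  c("p3", "p4"))
  # participants at the median join the adaptive group
  cls2 <- classify_adaptation(mk(c(0.2, 0.5, 0.8)))
  expect_equal(cls2$adaptation[cls2$participant_id == "p2"], "adaptive")
  expect_warning(cls3 <- classify_adaptation(mk(c(0.5, 0.5, 0.5))),
                 "degenerate")
  expect_true(all(cls3$degenerate))
})

test_that("recency splits report per-cell mean decay values", {
  fits <- tibble::tibble(
    participant_id = sprintf("p%d", 1:4), model = "ibl",
    direction = "decreasing", feedback = "partial",
    d = c(0.2, 0.4, 1.0, 2.0), sigma = 0.3)
  sp <- recency_split(fits)
  expect_setequal(sp$participant_id[sp$recency == "high"], c("p3", "p4"))
  sm <- attr(sp, "summary")
  expect_equal(sm$mean_d[sm$recency == "high"], 1.5)
  expect_equal(sm$mean_d[sm$recency == "low"], 0.3)
  # invariant to participant ordering
  sp2 <- recency_split(fits[4:1, ])
  expect_equal(dplyr::arrange(sp2, participant_id)$recency,
               dplyr::arrange(sp, participant_id)$recency)
  expect_warning(recency_split(dplyr::mutate(fits, d = 1)), "degenerate")
})

test_that("a single calibration pair degenerates to plain simulation averaging", {
  cal <- tibble::tibble(d = 1.2, sigma = 0.4)
  cond <- condition("increasing", "full")
  g <- generalize(cal, cond, n_agents = 40, seed = 77, group_col = "none")
  manual <- withr::with_seed(77, {
    idx <- sample.int(1, 40, replace = TRUE)
    sims <- vapply(seq_len(40), function(i) {
      simulate_ibl(ibl_params(1.2, 0.4), cond)$choice == "dynamic"
    }, logical(100))
    rowMeans(sims)
  })
  expect_equal(g$mean_risky, manual)
  expect_identical(g, generalize(cal, cond, n_agents = 40, seed = 77,
                                 group_col = "none"))
  expect_true(all(g$mean_risky >= 0 & g$mean_risky <= 1))
  expect_true(all(g$mean_maximize >= 0 & g$mean_maximize <= 1, na.rm = TRUE))
})

test_that("block summaries aggregate risky choice by design cell", {
  cond <- condition("increasing", "partial")
  cohort <- bind_cohort(list(trials_from_choices(rep("dynamic", 100), cond)))
  bs <- block_summary(cohort, block_size = 20)
  expect_equal(nrow(bs), 5)
  expect_true(all(bs$risky_rate == 1))
  expect_equal(unique(bs$n_trials), 20)
  expect_warning(block_summary(cohort, block_size = 30), "short")
})

test_that("mirrored schedules exchange period maximization of reversed choices", {
  inc <- condition("increasing", "partial")
  dec <- condition("decreasing", "partial")
  withr::with_seed(88, {
    choices <- sample(c("dynamic", "reference"), 100, replace = TRUE)
  })
  fwd <- trials_from_choices(choices, dec)
  rev <- trials_from_choices(base::rev(choices), inc)
  # decreasing P1 (trials 1-50, no EV ties) maps onto increasing P2 of the
  # reversed sequence under the mirror p_dec(t) = p_inc(101 - t)
  expect_equal(maximization_rate(fwd, dec, "p1"),
               maximization_rate(rev, inc, "p2"))
})

test_that("period summaries cover every participant and period", {
  cond <- condition("decreasing", "full")
  cohort <- bind_cohort(list(
    simulate_ibl(ibl_params(1, 0.3), cond, seed = 91),
    simulate_ibl(ibl_params(0.3, 0.3), cond, seed = 92)))
  ps <- period_summary(cohort)
  expect_equal(nrow(ps), 6)
  expect_setequal(ps$period, c("p1", "p2", "last30"))
  expect_true(all(ps$risky_rate >= 0 & ps$risky_rate <= 1))
  expect_false(anyNA(ps$maximization_rate))
})
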