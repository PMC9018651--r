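test_that("activation matches hand-computed values", {
  # single lag-1 instance, zero noise: log(1^-d) = 0 for any d
  expect_equal(activation(4, 5, d = 2.3, sigma = 0, gamma = 0.5), 0)
  expect_equal(activation(1, 5, d = 1, sigma = 0, gamma = 0.5), log(1 / 4),
               tolerance = 1e-10)
  expect_equal(activation(c(3, 4), 5, d = 0, sigma = 0, gamma = 0.5), log(2),
               tolerance = 1e-10)
  # noise term: sigma * log((1 - gamma) / gamma)
  expect_equal(activation(4, 5, d = 1, sigma = 2, gamma = 0.25),
               2 * log(3), tolerance = 1e-10)
  expect_error(activation(numeric(0), 5, 1, 0, 0.5), "non-empty")
  expect_error(activation(5, 5, 1, 0, 0.5), "strictly before")
  expect_error(activation(1, 5, 1, 0, 1), "strictly inside")
})

test_that("older instances lose activation as decay grows", {
  lag_long <- 8
  acts <- vapply(c(0, 0.5, 1, 2, 4), function(d) {
    activation(10 - lag_long, 10, d, sigma = 0, gamma = 0.5)
  }, numeric(1))
  expect_true(all(diff(acts) < 0))
  # at d = 0 a lag-1 and a lag-8 instance have equal activation
  expect_equal(activation(9, 10, 0, 0, 0.5), activation(2, 10, 0, 0, 0.5))
})

test_that("retrieval probabilities form the right simplex", {
  expect_equal(retrieval_probabilities(3.7, tau = 1), 1)
  expect_equal(retrieval_probabilities(c(1.2, 1.2), tau = 0.5), c(0.5, 0.5))
  expect_equal(retrieval_probabilities(c(0, log(2)), tau = 1),
               c(1 / 3, 2 / 3), tolerance = 1e-10)
  # hard-argmax limit with uniform ties
  expect_equal(retrieval_probabilities(c(1, 2, 2), tau = 0), c(0, 0.5, 0.5))
  withr::with_seed(7, {
    for (i in 1:20) {
      a <- rnorm(sample(1:4, 1), sd = 10)
      p <- retrieval_probabilities(a, tau = runif(1, 0.01, 3))
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  })
})

test_that("blended values are probability-weighted outcomes within range", {
  expect_equal(blended_value(1, 250), 250)
  expect_equal(blended_value(c(0.5, 0.5), c(0, 500)), 250)
  expect_equal(blended_value(c(1 / 3, 2 / 3), c(0, 500)), 1000 / 3,
               tolerance = 1e-10)
  expect_error(blended_value(c(0.5, 0.5), 250), "same length")
  withr::with_seed(8, {
    for (i in 1:20) {
      x <- sample(c(0, 250, 500), 3)
      w <- retrieval_probabilities(rnorm(3), tau = 1)
      v <- blended_value(w, x)
      expect_true(v >= min(x) && v <= max(x))
    }
  })
})

test_that("the equation chain equals a direct hand evaluation", {
  # memory: option saw 500 on trials {1, 4} and 0 on trial {3}; trial t = 6
  d <- 1.3
  sigma <- 0.7
  g <- c(0.3, 0.6)
  a500 <- sigma * log(0.7 / 0.3) + log(5^(-d) + 2^(-d))
  a0 <- sigma * log(0.4 / 0.6) + log(3^(-d))
  tau <- sigma * sqrt(2)
  w <- exp(a500 / tau) / (exp(a500 / tau) + exp(a0 / tau))
  direct <- w * 500
  chained <- blended_value(
    retrieval_probabilities(
      c(activation(c(1, 4), 6, d, sigma, g[1]),
        activation(3, 6, d, sigma, g[2])), tau),
    c(500, 0))
  expect_equal(chained, direct, tolerance = 1e-10)
})

test_that("choice is argmax with fair-coin tie breaking", {
  expect_equal(ibl_choose(c(dynamic = 300, reference = 250)), "dynamic")
  expect_equal(ibl_choose(c(dynamic = 0, reference = 250)), "reference")
  withr::with_seed(11, {
    picks <- replicate(10000, ibl_choose(c(dynamic = 250, reference = 250)))
  })
  expect_lt(abs(mean(picks == "dynamic") - 0.5), 0.02)
})

test_that("observation updates memory per the feedback regime", {
  mem <- new_ibl_memory(500)
  expect_true(mem$dynamic$prepop)
  mem <- ibl_observe(mem, 7, "dynamic", 500, feedback = "partial")
  expect_false(mem$dynamic$prepop)
  expect_equal(mem$dynamic$outcomes, 500)
  expect_equal(mem$dynamic$occ[[1]], 7L)     # pseudo-instance at 0 removed
  expect_true(mem$reference$prepop)          # untouched
  mem2 <- new_ibl_memory(500)
  mem2 <- ibl_observe(mem2, 7, "dynamic", 500, 250, feedback = "full")
  expect_equal(mem2$reference$outcomes, 250)
  expect_equal(mem2$reference$occ[[1]], 7L)
  expect_error(ibl_observe(new_ibl_memory(500), 1, "dynamic", 0,
                           feedback = "full"),
               "foregone")
})

test_that("simulation is reproducible and books the right instance counts", {
  cond <- condition("decreasing", "full")
  a <- simulate_ibl(ibl_params(0.5, 0.4), cond, seed = 21)
  b <- simulate_ibl(ibl_params(0.5, 0.4), cond, seed = 21)
  expect_identical(a, b)
  expect_false(anyNA(a$outcome_foregone))
  # full feedback: by trial t the two options jointly hold 2(t-1) instances
  snap <- choiceadapt:::ibl_history(a, cond)
  n_inst <- function(s) sum(lengths(s$dynamic$lags)) +
    sum(lengths(s$reference$lags))
  expect_equal(n_inst(snap[[60]]), 2 * 59)
  part <- condition("decreasing", "partial")
  c1 <- simulate_ibl(ibl_params(0.5, 0.4), part, seed = 22)
  expect_true(all(is.na(c1$outcome_foregone)))
  # partial feedback: one instance per trial once both prepops are gone
  snap <- choiceadapt:::ibl_history(c1, part)
  if (all(c("dynamic", "reference") %in% c1$choice[1:20])) {
    expect_equal(n_inst(snap[[60]]), 59)  # one real instance per past trial
  }
})

test_that("optimistic prepopulation forces early exploration", {
  cond <- condition("static", "partial")
  withr::with_seed(31, {
    tried_both <- vapply(1:200, function(i) {
      sim <- simulate_ibl(ibl_params(1, 0.25), cond)
      all(c("dynamic", "reference") %in% sim$choice[1:10])
    }, logical(1))
  })
  expect_gt(mean(tried_both), 0.9)
})

test_that("strong recency under decreasing probabilities abandons the risky option", {
  cond <- condition("decreasing", "full")
  withr::with_seed(33, {
    rates <- vapply(1:120, function(i) {
      sim <- simulate_ibl(ibl_params(5, 0.25), cond)
      risky <- sim$choice == "dynamic"
      mean(risky[71:100]) - mean(risky[1:30])
    }, numeric(1))
  })
  expect_lt(mean(rates), 0)
})

test_that("yoked predictions behave at the deterministic and symmetric limits", {
  cond <- condition("increasing", "full")
  sim <- simulate_ibl(ibl_params(1, 0.5), cond, seed = 41)
  p0 <- predict_ibl(ibl_params(1, 0), sim, cond, n_sims = 50, seed = 42,
                    clip = FALSE)
  expect_true(all(p0 %in% c(0, 0.5, 1)))
  # trial 1: both options hold only the 500 pseudo-instance, so values tie
  p <- predict_ibl(ibl_params(1, 0.5), sim, cond, n_sims = 200, seed = 43)
  expect_equal(p[1], 0.5)
})

test_that("predictions converge in the number of simulations", {
  cond <- condition("decreasing", "partial")
  sim <- simulate_ibl(ibl_params(1.2, 0.4), cond, seed = 51)
  par <- ibl_params(1.2, 0.4)
  p_small <- predict_ibl(par, sim, cond, n_sims = 100, seed = 52)
  p_big <- predict_ibl(par, sim, cond, n_sims = 4000, seed = 53)
  expect_lt(mean(abs(p_small - p_big)), 0.05)
})
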