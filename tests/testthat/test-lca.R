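test_that("the noise-free simulator reproduces the closed-form crossing times", {
  # free integrator: t* = a0 / I_correct = 1/2
  p1 <- lca_params(input_correct = 2, input_error = 1, leak = 0,
                   inhibition = 0, noise = 1e-6, threshold_initial = 1,
                   collapse_rate = 0, nondecision_time = 0.3)
  o1 <- deterministic_crossing_time(p1)
  expect_equal(o1$choice, "correct")
  expect_equal(o1$decision_time, 0.5, tolerance = p1$dt)
  set.seed(11)
  s1 <- simulate_lca_trial(p1)
  expect_equal(s1$choice, "correct")
  expect_equal(s1$rt, 0.8, tolerance = 2 * p1$dt)

  # leaky integrator: x(t) = (I/k)(1 - exp(-k t)), crossing 0.4 at
  # t = ln(5)/4
  p2 <- lca_params(input_correct = 2, input_error = 0, leak = 4,
                   inhibition = 0, noise = 1e-6, threshold_initial = 0.4,
                   collapse_rate = 0, nondecision_time = 0.3)
  o2 <- deterministic_crossing_time(p2)
  expect_equal(o2$choice, "correct")
  expect_equal(o2$decision_time, log(5) / 4, tolerance = 2 * p2$dt)
  set.seed(12)
  s2 <- simulate_lca_trial(p2)
  expect_equal(s2$rt, 0.3 + log(5) / 4, tolerance = 2 * p2$dt)
})

test_that("small-noise trials track the deterministic oracle across random parameter sets", {
  set.seed(21)
  for (rep in 1:3) {
    p <- lca_params(input_correct = runif(1, 1.5, 4),
                    input_error = runif(1, 0, 1),
                    leak = runif(1, 0, 6), inhibition = runif(1, 0, 6),
                    noise = 1e-6,
                    threshold_initial = runif(1, 0.5, 3),
                    collapse_rate = runif(1, 1, 4))
    o <- deterministic_crossing_time(p)
    s <- simulate_lca_trial(p)
    expect_equal(s$choice, o$choice)
    expect_equal(s$decision_time, o$decision_time, tolerance = 2 * p$dt)
    # collapsing threshold guarantees termination by a0/c
    expect_lte(o$decision_time,
               p$threshold_initial / p$collapse_rate + p$dt)
  }
})

test_that("symmetric inputs give a fair choice", {
  p <- lca_params(input_correct = 2, input_error = 2)
  s <- simulate_lca_condition(p, n_sims = 10000, seed = 31)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.5) / 10000
  expect_gte(s$accuracy, ci[1])
  expect_lte(s$accuracy, ci[2])
})

test_that("condition summaries are reproducible and degenerate cases behave", {
  p <- lca_variant_params("cb_lca_1", input_correct = 3, input_error = 1)
  a <- simulate_lca_condition(p, n_sims = 500, seed = 41)
  b <- simulate_lca_condition(p, n_sims = 500, seed = 41)
  expect_identical(a, b)
  expect_gt(a$accuracy, 0.5)
  expect_lt(a$accuracy, 1)

  one <- simulate_lca_condition(p, n_sims = 1, seed = 42)
  expect_true(one$accuracy %in% c(0, 1))
  expect_equal(is.na(one$mcrt) + is.na(one$mert), 1L)
})

test_that("named variants carry the published parameterizations", {
  nc <- lca_variant_params("no_collapse")
  expect_equal(nc$threshold_initial, 1)
  expect_equal(nc$collapse_rate, 0)
  expect_equal(nc$leak, 4)
  expect_equal(nc$inhibition, 4)

  c2 <- lca_variant_params("cb_lca_2")
  expect_equal(c2$threshold_initial, 3)
  expect_equal(c2$collapse_rate, 2)

  c1 <- lca_variant_params("cb_lca_1")
  expect_equal(c(c1$leak, c1$inhibition, c1$threshold_initial,
                 c1$collapse_rate), c(4, 4, 4, 4))
  expect_equal(c1$noise, 1)
  expect_equal(c1$nondecision_time, 0.3)
  expect_error(lca_variant_params("banana"))
})

test_that("the input-sum sweep splits the drifts as (s + d)/2 and (s - d)/2", {
  sw <- sweep_input_sum(lca_variant_params("cb_lca_1"), sums = c(2, 4),
                        difference = 2, n_sims = 50, seed = 51,
                        variant = "cb_lca_1")
  expect_equal(sw$input_sum, c(2, 4))
  expect_equal(nrow(sw), 2L)
  # boundary: sum = difference gives a zero-drift error accumulator
  expect_silent(sweep_input_sum(lca_variant_params("cb_lca_1"),
                                sums = 2, difference = 2, n_sims = 10,
                                seed = 52))
  expect_error(sweep_input_sum(lca_variant_params("cb_lca_1"),
                               sums = 1, difference = 2, n_sims = 10),
               "input sum")
})

test_that("parameter validation rejects non-terminating collapse setups", {
  expect_error(lca_params(threshold_initial = 4, collapse_rate = 0.1,
                          max_time = 10), "collapse to 0")
  expect_error(lca_params(dt = 0.02))
  expect_error(lca_params(threshold_initial = -1))
})

test_that("accuracy is stable under dt halving for the default model", {
  p1 <- lca_variant_params("cb_lca_1", input_correct = 4,
                           input_error = 2, dt = 0.002)
  p2 <- lca_variant_params("cb_lca_1", input_correct = 4,
                           input_error = 2, dt = 0.001)
  n <- 4000
  a1 <- simulate_lca_condition(p1, n, seed = 61)
  a2 <- simulate_lca_condition(p2, n, seed = 62)
  mc <- sqrt(a1$accuracy * (1 - a1$accuracy) / n +
               a2$accuracy * (1 - a2$accuracy) / n)
  expect_lt(abs(a1$accuracy - a2$accuracy), 3 * mc)
})
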