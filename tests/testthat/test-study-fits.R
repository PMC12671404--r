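test_that("the RT model recovers a known OV slope within its Wald interval", {
  cfg <- generator_config(n_participants = 40L,
                          n_trials_per_participant = 300L,
                          beta_ov_rt = -0.05, seed = 71)
  fit <- fit_rt_model(generate_glmm_study(cfg))
  expect_equal(fit$outcome, "rt")
  expect_equal(fit$method, "full_mixed")
  expect_true(fit$converged)
  expect_lt(abs(fit$b_ov - (-0.05)), 2 * fit$se_ov)
  expect_gt(fit$se_ov, 0)
  expect_false(is.na(fit$b_rv))  # RV varies, so the term is present
})

test_that("the accuracy model recovers a known OV log-odds slope", {
  cfg <- generator_config(n_participants = 20L,
                          n_trials_per_participant = 150L,
                          beta_ov_acc = 0.15, seed = 72)
  st <- generate_glmm_study(cfg)
  fit <- fit_acc_model(st)
  expect_lt(abs(fit$b_ov - 0.15), 2 * fit$se_ov)
  # equal-value trials are excluded from the accuracy fit
  expect_equal(fit$n_trials, sum(!is.na(st$accuracy)))
  expect_lt(fit$n_trials, nrow(st))
})

test_that("constant relative value drops the RV terms from the models", {
  set.seed(73)
  n <- 150
  va <- sample(1:7, n, TRUE)
  tr <- make_trials(va, va + 2,
                    participant_id = rep(paste0("p", 1:5), 30),
                    rt = exp(rnorm(n, 0, 0.3)),
                    chose_a = runif(n) < 0.3)
  tab <- build_predictors(tr)
  expect_true(attr(tab, "rv_constant"))
  fit <- fit_rt_model(tab)
  expect_true(is.na(fit$b_rv))
  facc <- fit_acc_model(tab)
  expect_true(is.na(facc$b_rv))
})

test_that("fitting preconditions are enforced with informative errors", {
  cfg <- generator_config(n_participants = 2L,
                          n_trials_per_participant = 30L, seed = 74)
  st <- generate_glmm_study(cfg)
  solo <- dplyr::filter(st, participant_id == "p01")
  expect_error(fit_rt_model(solo), "2 participants")
  expect_error(fit_rt_model(st[1:10, ] |>
                              dplyr::mutate(participant_id =
                                              rep(c("a", "b"), 5))),
               "usable trials")
  expect_error(fit_rt_model(dplyr::select(st, -ov_z, -rv_z)),
               "build_predictors")
  perfect <- dplyr::mutate(st,
                           accuracy = ifelse(is.na(accuracy), NA, TRUE),
                           chose_a = ifelse(is.na(accuracy), chose_a,
                                            value_a > value_b))
  expect_error(fit_acc_model(perfect), "separation")
})

test_that("the two-stage fallback agrees with the mixed fit on well-behaved data", {
  for (seed in 81:83) {
    cfg <- generator_config(n_participants = 15L,
                            n_trials_per_participant = 120L,
                            beta_ov_rt = -0.08, seed = seed)
    st <- generate_glmm_study(cfg)
    full <- fit_rt_model(st)
    ts <- valuesense:::two_stage_fit(st, log(rt) ~ ov_z + rv_z)
    b_ts <- ts$b_pool[ts$term == "ov_z"]
    se_ts <- ts$se_pool[ts$term == "ov_z"]
    expect_equal(sign(full$b_ov), sign(b_ts))
    expect_lt(abs(full$b_ov - b_ts), 1.5 * max(full$se_ov, se_ts))
  }
})

test_that("quadrupling trials per participant shrinks the OV standard error", {
  ses <- sapply(91:95, function(seed) {
    small <- generate_glmm_study(generator_config(
      n_participants = 12L, n_trials_per_participant = 40L, seed = seed))
    big <- generate_glmm_study(generator_config(
      n_participants = 12L, n_trials_per_participant = 160L, seed = seed))
    c(fit_rt_model(small)$se_ov, fit_rt_model(big)$se_ov)
  })
  expect_gte(median(1 - ses[2, ] / ses[1, ]), 0.25)
})

test_that("corpus fitting returns partial results with skip reasons", {
  spec <- corpus_spec(n_abstract = 2L, n_brightness = 0L, n_numbers = 0L,
                      n_preference = 0L, n_participants = 4L,
                      n_trials_per_participant = 40L)
  corp <- generate_corpus(spec, master_seed = 21)
  studies <- corp$studies
  studies[["broken"]] <- dplyr::filter(studies[[1]],
                                       participant_id == "p01")
  fc <- fit_corpus(studies, outcomes = "rt")
  expect_equal(nrow(fc$fits), 2L)
  expect_equal(fc$skipped$study_id, "broken")
  expect_match(fc$skipped$reason, "2 participants")
})

test_that("equal-alternatives fits apply the eligibility rule and recover RT slopes", {
  mk <- function(seed) {
    generate_glmm_study(generator_config(
      n_participants = 6L, n_trials_per_participant = 60L,
      equal_value_fraction = 0.5, beta_ov_rt = -0.1,
      sd_slope_ov_rt = 0, seed = seed))
  }
  studies <- list(a = mk(31), b = mk(32),
                  none = generate_glmm_study(generator_config(
                    n_participants = 6L, n_trials_per_participant = 60L,
                    equal_value_fraction = 0, seed = 33)))
  res <- fit_equal_alternatives_rt(studies, min_trials = 50L)
  expect_equal(sort(res$fits$study_id), c("a", "b"))
  expect_equal(res$fits$outcome, rep("rt_equal", 2))
  expect_equal(res$skipped$study_id, "none")
  expect_match(res$skipped$reason, "equal-value trials")
  # pooled equal-alternatives effect recovers the negative RT slope
  m <- pool_random_effects(res$fits, b = b_ov, se = se_ov)
  expect_lt(m$pooled_b, 0)
})
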