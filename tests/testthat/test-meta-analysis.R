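test_that("DerSimonian-Laird matches the hand-computed toy example", {
  toy <- tibble::tibble(b = c(0.1, 0.2, 0.3), se = 0.1)
  # Q = 100*(0.01 + 0 + 0.01) = 2 = k - 1, so tau2 = 0
  expect_equal(estimate_tau(toy, method = "DL"), 0)
  m <- pool_random_effects(toy, method = "DL")
  expect_equal(m$pooled_b, 0.2, tolerance = 1e-12)
  expect_equal(m$pooled_se, 1 / sqrt(300), tolerance = 1e-12)
  expect_equal(m$Q, 2, tolerance = 1e-12)
})

test_that("identical studies give tau = 0 and the plain mean under both estimators", {
  same <- tibble::tibble(b = rep(0.13, 6), se = rep(0.05, 6))
  for (meth in c("REML", "DL")) {
    m <- pool_random_effects(same, method = meth)
    expect_equal(m$tau, 0)
    expect_equal(m$pooled_b, 0.13)
    expect_equal(m$pooled_se, 0.05 / sqrt(6), tolerance = 1e-10)
  }
  expect_error(pool_random_effects(same[1, ]), "at least 2")
  expect_error(
    pool_random_effects(tibble::tibble(b = c(1, 2), se = c(0.1, 0))),
    "must be > 0")
})

test_that("REML tau2 matches a brute-force grid maximizer of the restricted likelihood", {
  # independent oracle: evaluate the restricted log-likelihood on a
  # fine tau2 grid and take the argmax
  grid_reml <- function(b, se, step = 1e-5) {
    tau2 <- seq(0, 1, by = step)
    ll <- vapply(tau2, function(t2) {
      w <- 1 / (se^2 + t2)
      bh <- sum(w * b) / sum(w)
      -0.5 * (sum(log(se^2 + t2)) + log(sum(w)) + sum(w * (b - bh)^2))
    }, numeric(1))
    tau2[which.max(ll)]
  }
  set.seed(101)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    d <- tibble::tibble(b = rnorm(k, 0, 0.2),
                        se = runif(k, 0.05, 0.2))
    expect_lt(abs(estimate_tau(d, method = "REML") -
                    grid_reml(d$b, d$se)), 2e-5)
  }
})

test_that("REML pooling agrees with metafor on the packaged 40-study table", {
  skip_if_not_installed("metafor")
  d <- load_table1_fixture()
  for (cols in list(c("brt", "se_brt"), c("bacc", "se_bacc"))) {
    dd <- tibble::tibble(b = d[[cols[1]]], se = d[[cols[2]]])
    own <- pool_random_effects(dd)
    ref <- metafor::rma(yi = dd$b, sei = dd$se, method = "REML")
    # metafor's Fisher-scoring REML stops at its own (looser)
    # threshold, so compare on an absolute scale
    expect_lt(abs(own$pooled_b - as.numeric(ref$beta)), 1e-6)
    expect_lt(abs(own$pooled_se - ref$se), 1e-5)
    expect_lt(abs(own$tau^2 - ref$tau2), 2e-6)
    ref_dl <- metafor::rma(yi = dd$b, sei = dd$se, method = "DL")
    expect_lt(abs(estimate_tau(dd, method = "DL") - ref_dl$tau2), 1e-8)
  }
})

test_that("pooling is order-invariant, sign-equivariant and stays inside the effect range", {
  set.seed(202)
  for (rep in 1:5) {
    d <- make_meta_input(k = 8, mu = 0.05, tau = 0.1, se = 0.08)
    m <- pool_random_effects(d)
    expect_gte(m$pooled_b, min(d$b))
    expect_lte(m$pooled_b, max(d$b))
    shuf <- pool_random_effects(d[sample(nrow(d)), ])
    expect_equal(shuf$pooled_b, m$pooled_b, tolerance = 1e-10)
    expect_equal(shuf$tau, m$tau, tolerance = 1e-8)
    flip <- pool_random_effects(dplyr::mutate(d, b = -b))
    expect_equal(flip$pooled_b, -m$pooled_b, tolerance = 1e-10)
  }
})

test_that("subgroup pooling treats groups independently and flags singletons", {
  set.seed(303)
  d <- make_meta_input(k = 6, mu = 0.1, tau = 0.05)
  two <- dplyr::bind_rows(dplyr::mutate(d, g = "a"),
                          dplyr::mutate(d, g = "b"))
  sg <- subgroup_meta(two, group = g)
  expect_equal(nrow(sg), 2L)
  expect_equal(sg$estimate[1], sg$estimate[2])
  expect_equal(sg$tau[1], sg$tau[2])
  single <- dplyr::bind_rows(d[1:4, ] |> dplyr::mutate(g = "a"),
                             d[5, ] |> dplyr::mutate(g = "solo"))
  expect_warning(sg2 <- subgroup_meta(single, group = g), "single study")
  expect_equal(sg2$k[sg2$label == "solo"], 1L)
  expect_true(is.na(sg2$tau[sg2$label == "solo"]))
})

test_that("the binary moderator test is calibrated under the null and powered under a 5-SE split", {
  set.seed(404)
  hits <- 0L
  for (rep in 1:20) {
    d <- dplyr::bind_rows(
      dplyr::mutate(make_meta_input(8, mu = 0.1, se = 0.1), flag = FALSE),
      dplyr::mutate(make_meta_input(8, mu = 0.1, se = 0.1), flag = TRUE))
    hits <- hits + (moderator_test(d, moderator = flag)$p.value < 0.05)
  }
  expect_lte(hits, 3L)

  set.seed(405)
  base <- make_meta_input(10, mu = 0, se = 0.1)
  # group means differ by 5 pooled SEs: pooled SE ~ 0.1/sqrt(10)
  shift <- 5 * 0.1 / sqrt(10) * sqrt(2)
  d <- dplyr::bind_rows(
    dplyr::mutate(base, flag = FALSE),
    dplyr::mutate(make_meta_input(10, mu = shift, se = 0.1), flag = TRUE))
  expect_lt(moderator_test(d, moderator = flag)$p.value, 0.05)

  allt <- dplyr::mutate(base, flag = TRUE)
  expect_error(moderator_test(allt, moderator = flag), "2 levels")
})

test_that("forest data carries per-study rows, pooled rows and exact Wald intervals", {
  d <- load_table1_fixture()
  fd <- forest_data(d, study_id = id, group = stimulus_type,
                    b = bacc, se = se_bacc)
  expect_equal(sum(fd$row_type == "study"), 40L)
  expect_equal(sum(fd$row_type == "pooled"), 5L)  # 4 subgroups + overall
  expect_equal(fd$ci_high - fd$ci_low, 2 * 1.96 * fd$se, tolerance = 1e-12)

  one <- forest_data(tibble::tibble(study_id = c("a", "b"),
                                    b = c(0, 0), se = c(1, 1)))
  expect_equal(one$ci_low[1], -1.96)
  expect_equal(one$ci_high[1], 1.96)
})
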