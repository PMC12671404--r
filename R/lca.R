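# Leaky Competing Accumulator with zero-truncated evidence and a
# linearly collapsing decision threshold, simulated by Euler-Maruyama.
#
# Dynamics (two accumulators, synchronous update, post-update clamp):
#   x_i <- max(0, x_i + (I_i - kappa*x_i - beta*x_j)*dt + sigma*sqrt(dt)*eps_i)
# Decision at the first step where any x_i >= a(t), with the threshold
#   a(t) = max(0, a0 - c*t).
# With c > 0 the threshold reaches 0 at t = a0/c, so every trial
# terminates; with c = 0 trials can run to max_time, where the tie rule
# forces a decision and the trial is flagged timed out.

#' Parameters of a collapsing-bound LCA condition
#'
#' @param input_correct,input_error Drift rates of the correct and error
#'   accumulators (evidence units per second).
#' @param leak Leak rate kappa (1/s), `>= 0`.
#' @param inhibition Lateral inhibition beta (1/s), `>= 0`.
#' @param noise Diffusion coefficient sigma (evidence units per sqrt
#'   second), `> 0`; may be set near 0 for oracle checks.
#' @param threshold_initial Initial threshold a0 (evidence units), `> 0`.
#' @param collapse_rate Linear collapse rate c (evidence units per
#'   second), `>= 0`. When positive the threshold hits 0 at `a0 / c`,
#'   which must not exceed `max_time`.
#' @param nondecision_time Constant t0 (s) added to the decision time.
#' @param dt Euler step (s), at most 0.01.
#' @param max_time Simulation horizon (s), binding only when
#'   `collapse_rate = 0`.
#' @return A validated `lca_params` list.
#' @export
lca_params <- function(input_correct = 3, input_error = 1, leak = 4,
                       inhibition = 4, noise = 1, threshold_initial = 4,
                       collapse_rate = 4, nondecision_time = 0.3,
                       dt = 0.001, max_time = 10) {
  p <- list(input_correct = input_correct, input_error = input_error,
            leak = leak, inhibition = inhibition, noise = noise,
            threshold_initial = threshold_initial,
            collapse_rate = collapse_rate,
            nondecision_time = nondecision_time, dt = dt,
            max_time = max_time)
  stopifnot(p$threshold_initial > 0, p$dt > 0, p$dt <= 0.01,
            p$max_time > 0, p$leak >= 0, p$inhibition >= 0, p$noise > 0,
            p$collapse_rate >= 0, p$nondecision_time >= 0)
  if (p$collapse_rate > 0 &&
      p$threshold_initial / p$collapse_rate > p$max_time) {
    stop("threshold must collapse to 0 within max_time ",
         "(a0/c = ", p$threshold_initial / p$collapse_rate, " s)",
         call. = FALSE)
  }
  structure(p, class = "lca_params")
}

#' Named LCA variants of the simulation study
#'
#' Returns the parameterization of one of the five model variants over
#' the defaults (leak 4, inhibition 4, initial threshold 4, collapse
#' rate 4, noise 1, nondecision time 0.3): `no_leak` sets the leak to 0;
#' `no_inhibition` sets inhibition to 0; `no_collapse` uses a fixed
#' threshold of 1 (collapse rate 0); `cb_lca_1` is all defaults;
#' `cb_lca_2` uses initial threshold 3 with collapse rate 2.
#'
#' @param name One of `"no_leak"`, `"no_inhibition"`, `"no_collapse"`,
#'   `"cb_lca_1"`, `"cb_lca_2"`.
#' @param ... Further overrides passed to [lca_params()] (e.g. the
#'   inputs or `dt`).
#' @return An `lca_params` object.
#' @export
lca_variant_params <- function(name = c("cb_lca_1", "cb_lca_2", "no_leak",
                                        "no_inhibition", "no_collapse"),
                               ...) {
  name <- match.arg(name)
  over <- switch(name,
    no_leak = list(leak = 0),
    no_inhibition = list(inhibition = 0),
    no_collapse = list(threshold_initial = 1, collapse_rate = 0),
    cb_lca_1 = list(),
    cb_lca_2 = list(threshold_initial = 3, collapse_rate = 2))
  do.call(lca_params, utils::modifyList(over, list(...)))
}

# Vectorized simulation of n trials under one parameter set, consuming
# the current global RNG stream. Returns decision times, choices
# (1 = correct accumulator, 2 = error accumulator) and timeout flags.
simulate_lca_engine <- function(params, n) {
  dt <- params$dt
  sqdt <- sqrt(dt)
  I1 <- params$input_correct; I2 <- params$input_error
  k <- params$leak; b <- params$inhibition; s <- params$noise
  a0 <- params$threshold_initial; cr <- params$collapse_rate
  n_steps <- ceiling(params$max_time / dt)
  x1 <- numeric(n); x2 <- numeric(n)
  active <- seq_len(n)
  choice <- integer(n); dtime <- numeric(n); timed_out <- logical(n)
  for (step in seq_len(n_steps)) {
    m <- length(active)
    eps <- rnorm(2L * m)
    nx1 <- pmax(0, x1 + (I1 - k * x1 - b * x2) * dt + s * sqdt * eps[1:m])
    nx2 <- pmax(0, x2 + (I2 - k * x2 - b * x1) * dt +
                  s * sqdt * eps[(m + 1L):(2L * m)])
    x1 <- nx1; x2 <- nx2
    t_now <- step * dt
    a_now <- max(0, a0 - cr * t_now)
    hit <- x1 >= a_now | x2 >= a_now
    if (any(hit)) {
      idx <- active[hit]
      choice[idx] <- resolve_choice(x1[hit], x2[hit])
      dtime[idx] <- t_now
      active <- active[!hit]
      x1 <- x1[!hit]; x2 <- x2[!hit]
      if (!length(active)) break
    }
  }
  if (length(active)) {
    choice[active] <- resolve_choice(x1, x2)
    dtime[active] <- n_steps * dt
    timed_out[active] <- TRUE
  }
  list(decision_time = dtime, choice = choice, timed_out = timed_out)
}

# Larger evidence state wins; exact ties resolved by a fair coin drawn
# from the same stream.
resolve_choice <- function(x1, x2) {
  ch <- ifelse(x1 > x2, 1L, 2L)
  tie <- x1 == x2
  if (any(tie)) ch[tie] <- 1L + (runif(sum(tie)) < 0.5)
  ch
}

#' Simulate a single LCA trial
#'
#' One Euler-Maruyama realization of the collapsing-bound LCA,
#' consuming the global RNG stream (seed with [set.seed()] for
#' reproducibility).
#'
#' @param params An [lca_params()] object.
#' @return A one-row tibble: `choice` (`"correct"`/`"error"`), `rt`
#'   (decision time + nondecision time), `decision_time`, `timed_out`.
#' @export
simulate_lca_trial <- function(params) {
  r <- simulate_lca_engine(params, 1L)
  tibble::tibble(
    choice = c("correct", "error")[r$choice],
    rt = r$decision_time + params$nondecision_time,
    decision_time = r$decision_time,
    timed_out = r$timed_out)
}

#' Simulate and summarize one LCA condition
#'
#' Runs `n_sims` independent trials and aggregates them into the
#' condition summary: accuracy, mean correct RT (MCRT), mean error RT
#' (MERT) and the timeout fraction.
#'
#' @param params An [lca_params()] object.
#' @param n_sims Number of simulated trials.
#' @param seed Integer seed; the summary is reproducible given
#'   `(params, n_sims, seed)`.
#' @return A one-row tibble: `accuracy`, `mcrt`, `mert` (NA when the
#'   corresponding response count is 0), `n_sims`, `timeout_fraction`,
#'   `mc_se_accuracy` and `mc_se_mcrt` (Monte-Carlo standard errors of
#'   the accuracy and of the mean correct RT).
#' @export
simulate_lca_condition <- function(params, n_sims, seed = NULL) {
  stopifnot(n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  r <- simulate_lca_engine(params, n_sims)
  rt <- r$decision_time + params$nondecision_time
  correct <- r$choice == 1L
  acc <- mean(correct)
  n_cor <- sum(correct)
  tibble::tibble(
    accuracy = acc,
    mcrt = if (n_cor > 0) mean(rt[correct]) else NA_real_,
    mert = if (n_cor < n_sims) mean(rt[!correct]) else NA_real_,
    n_sims = as.integer(n_sims),
    timeout_fraction = mean(r$timed_out),
    mc_se_accuracy = sqrt(acc * (1 - acc) / n_sims),
    mc_se_mcrt = if (n_cor > 1) stats::sd(rt[correct]) / sqrt(n_cor)
                 else NA_real_)
}

#' Sweep the LCA over a grid of input sums
#'
#' For each input sum `s`, sets the accumulator drifts to
#' `I_correct = (s + difference)/2` and `I_error = (s - difference)/2`
#' (so that their difference is fixed while their sum tracks overall
#' value) and summarizes the condition.
#'
#' @param base An [lca_params()] object; its inputs are overridden per
#'   sum.
#' @param sums Numeric vector of input sums; each must be at least
#'   `difference`.
#' @param difference Fixed drift difference between the accumulators
#'   (default 2), `> 0`.
#' @param n_sims Simulated trials per sum.
#' @param seed Integer seed; per-sum sub-seeds are derived from it.
#' @param variant Label recorded in the output.
#' @return A tibble with one row per sum: `variant`, `input_sum`,
#'   the [simulate_lca_condition()] summary columns.
#' @examples
#' \donttest{
#' sweep <- sweep_input_sum(lca_variant_params("cb_lca_1"),
#'                          sums = c(2, 6, 10), n_sims = 2000, seed = 1)
#' }
#' @export
sweep_input_sum <- function(base, sums, difference = 2, n_sims = 20000,
                            seed = NULL, variant = "custom") {
  stopifnot(difference > 0)
  if (any(sums < difference)) {
    stop("every input sum must be >= the drift difference (",
         difference, "); offending sums: ",
         paste(sums[sums < difference], collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(sums))
  purrr::map2(sums, sub_seeds, function(s, sd) {
    p <- base
    p$input_correct <- (s + difference) / 2
    p$input_error <- (s - difference) / 2
    dplyr::bind_cols(
      tibble::tibble(variant = variant, input_sum = s),
      simulate_lca_condition(p, n_sims, seed = sd))
  }) |>
    purrr::list_rbind()
}

#' Sweep every named LCA variant over an input-sum grid
#'
#' Convenience wrapper running [sweep_input_sum()] for each requested
#' variant at a common input-sum grid.
#'
#' @param variants Character vector of variant names
#'   (see [lca_variant_params()]).
#' @param sums Input-sum grid (default 2..10).
#' @param difference,n_sims,seed As in [sweep_input_sum()].
#' @param dt Euler step passed to every variant.
#' @return A tibble stacking the per-variant sweeps, classed
#'   `vs_lca_sweep` for [autoplot()][ggplot2::autoplot].
#' @export
lca_variant_sweep <- function(variants = c("no_leak", "no_inhibition",
                                           "no_collapse", "cb_lca_1",
                                           "cb_lca_2"),
                              sums = 2:10, difference = 2,
                              n_sims = 20000, seed = NULL, dt = 0.001) {
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(variants))
  out <- purrr::map2(variants, sub_seeds, function(v, sd) {
    sweep_input_sum(lca_variant_params(v, dt = dt), sums = sums,
                    difference = difference, n_sims = n_sims, seed = sd,
                    variant = v)
  }) |>
    purrr::list_rbind()
  class(out) <- c("vs_lca_sweep", class(out))
  out
}

#' Deterministic crossing time of the noise-free LCA
#'
#' Integrates the coupled ODE `dx_i/dt = I_i - kappa*x_i - beta*x_j`
#' (zero-truncated) with an Euler step of `dt/10` and returns the first
#' crossing of the collapsing threshold. Serves as the independent
#' oracle for [simulate_lca_trial()] in the small-noise limit.
#'
#' @param params An [lca_params()] object; its noise is ignored.
#' @return A list: `choice` (`"correct"`/`"error"`; exact ties resolve
#'   to `"correct"` and set `tie = TRUE`), `decision_time`, `tie`, and
#'   `crossed` (`FALSE` when no crossing occurs before `max_time`,
#'   possible only with collapse rate 0).
#' @export
deterministic_crossing_time <- function(params) {
  h <- params$dt / 10
  I1 <- params$input_correct; I2 <- params$input_error
  k <- params$leak; b <- params$inhibition
  a0 <- params$threshold_initial; cr <- params$collapse_rate
  n_steps <- ceiling(params$max_time / h)
  x1 <- 0; x2 <- 0
  for (step in seq_len(n_steps)) {
    nx1 <- max(0, x1 + (I1 - k * x1 - b * x2) * h)
    nx2 <- max(0, x2 + (I2 - k * x2 - b * x1) * h)
    x1 <- nx1; x2 <- nx2
    t_now <- step * h
    a_now <- max(0, a0 - cr * t_now)
    if (x1 >= a_now || x2 >= a_now) {
      return(list(choice = if (x1 >= x2) "correct" else "error",
                  decision_time = t_now, tie = x1 == x2, crossed = TRUE))
    }
  }
  list(choice = NA_character_, decision_time = NA_real_, tie = FALSE,
       crossed = FALSE)
}
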