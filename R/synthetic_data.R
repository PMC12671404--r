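# Synthetic trial-level corpora with the generative structure the
# per-study mixed models assume: participant-level heterogeneity in
# intercepts and OV slopes, log-normal RTs, Bernoulli accuracy through a
# logistic link, and integer option values producing the OV (sum) and
# RV (absolute difference) predictors.

#' Configuration of one synthetic study
#'
#' Defaults describe a desk-scale two-alternative study on a 1-10
#' integer rating scale with roughly 1-second responses and ~85%
#' accuracy; effect sizes are per SD of the standardized predictor,
#' anchored to the coefficient ranges typical of the 40-study corpus.
#'
#' @param n_participants,n_trials_per_participant Study size.
#' @param v_min,v_max Integer bounds of the discrete-uniform value law.
#' @param rt_intercept Mean log-RT (log seconds).
#' @param beta_ov_rt,beta_rv_rt Fixed-effect slopes on log-RT per SD of
#'   OV and RV.
#' @param alpha_acc Accuracy intercept (log-odds).
#' @param beta_ov_acc,beta_rv_acc Log-odds slopes per SD.
#' @param sd_intercept_rt,sd_slope_ov_rt SDs of the participant
#'   deviations of the log-RT intercept and OV slope.
#' @param sd_intercept_acc,sd_slope_ov_acc Same for the accuracy model.
#' @param resid_sd_logrt Residual SD of log-RT.
#' @param equal_value_fraction Proportion of trials forced to
#'   `value_a == value_b` (accuracy undefined there), in `[0, 1)`.
#' @param stimulus_type,domain Labels attached to every trial.
#' @param seed Integer seed making the study reproducible.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_participants = 9L,
                             n_trials_per_participant = 50L,
                             v_min = 1L, v_max = 10L,
                             rt_intercept = 0,
                             beta_ov_rt = -0.05, beta_rv_rt = -0.1,
                             alpha_acc = 2, beta_ov_acc = 0,
                             beta_rv_acc = 0.5,
                             sd_intercept_rt = 0.3, sd_slope_ov_rt = 0.05,
                             sd_intercept_acc = 0.5,
                             sd_slope_ov_acc = 0.25,
                             resid_sd_logrt = 0.4,
                             equal_value_fraction = 0.1,
                             stimulus_type = "preference",
                             domain = "preferential",
                             seed = 1L) {
  cfg <- as.list(environment())
  sds <- c(cfg$sd_intercept_rt, cfg$sd_slope_ov_rt, cfg$sd_intercept_acc,
           cfg$sd_slope_ov_acc, cfg$resid_sd_logrt)
  stopifnot(cfg$n_participants >= 1, cfg$n_trials_per_participant >= 1,
            cfg$v_min <= cfg$v_max, all(sds >= 0),
            cfg$equal_value_fraction >= 0, cfg$equal_value_fraction < 1)
  structure(cfg, class = "generator_config")
}

# Draw value pairs under the discrete-uniform law. A trial is
# equal-value with probability equal_value_fraction exactly; otherwise
# value_b is redrawn until it differs from value_a, so the configured
# fraction is the total fraction of ties.
draw_values <- function(n, cfg) {
  vals <- cfg$v_min:cfg$v_max
  draw <- function(m) vals[sample.int(length(vals), m, replace = TRUE)]
  value_a <- draw(n)
  value_b <- draw(n)
  eq <- runif(n) < cfg$equal_value_fraction
  value_b[eq] <- value_a[eq]
  if (length(vals) > 1L) {
    redo <- which(!eq & value_b == value_a)
    while (length(redo)) {
      value_b[redo] <- draw(length(redo))
      redo <- redo[value_b[redo] == value_a[redo]]
    }
  }
  list(value_a = value_a, value_b = value_b)
}

#' Generate one study from the mixed-model structure
#'
#' Simulates trials whose log-RT and accuracy follow exactly the mixed
#' regressions the fitting module estimates: per participant,
#' `log(rt) = rt_intercept + u_p + (beta_ov_rt + s_p) * ov_z +
#' beta_rv_rt * rv_z + eps`, and on unequal-value trials
#' `accuracy ~ Bernoulli(plogis(alpha_acc + a_p + (beta_ov_acc + g_p) *
#' ov_z + beta_rv_acc * rv_z))`. Predictors are z-scored within the
#' study (population SD). Equal-value trials get missing accuracy and a
#' fair-coin choice. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A trials tibble with `ov_z`/`rv_z` built.
#' @export
generate_glmm_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  np <- cfg$n_participants
  nt <- cfg$n_trials_per_participant
  n <- np * nt
  pid <- rep(sprintf("p%02d", seq_len(np)), each = nt)
  v <- draw_values(n, cfg)
  ov_z <- zscore_pop(v$value_a + v$value_b)
  rv_raw <- abs(v$value_a - v$value_b)
  rv_constant <- length(unique(rv_raw)) == 1L
  rv_z <- if (rv_constant) rep(0, n) else zscore_pop(rv_raw)

  u <- rnorm(np, 0, cfg$sd_intercept_rt)[rep(seq_len(np), each = nt)]
  s <- rnorm(np, 0, cfg$sd_slope_ov_rt)[rep(seq_len(np), each = nt)]
  a <- rnorm(np, 0, cfg$sd_intercept_acc)[rep(seq_len(np), each = nt)]
  g <- rnorm(np, 0, cfg$sd_slope_ov_acc)[rep(seq_len(np), each = nt)]

  rt <- exp(cfg$rt_intercept + u + (cfg$beta_ov_rt + s) * ov_z +
              cfg$beta_rv_rt * rv_z + rnorm(n, 0, cfg$resid_sd_logrt))
  p_acc <- stats::plogis(cfg$alpha_acc + a + (cfg$beta_ov_acc + g) * ov_z +
                           cfg$beta_rv_acc * rv_z)
  eq <- v$value_a == v$value_b
  accuracy <- rep(NA, n)
  accuracy[!eq] <- runif(sum(!eq)) < p_acc[!eq]
  chose_a <- logical(n)
  chose_a[eq] <- runif(sum(eq)) < 0.5
  a_higher <- v$value_a > v$value_b
  chose_a[!eq] <- ifelse(a_higher[!eq], accuracy[!eq], !accuracy[!eq])

  out <- tibble::tibble(
    study_id = paste0("synth_seed", cfg$seed),
    participant_id = pid,
    trial_index = as.integer(stats::ave(seq_len(n), pid,
                                        FUN = seq_along) - 1L),
    value_a = v$value_a, value_b = v$value_b,
    chose_a = chose_a, accuracy = as.logical(accuracy), rt = rt,
    stimulus_type = cfg$stimulus_type, domain = cfg$domain,
    ov_z = ov_z, rv_z = rv_z)
  attr(out, "rv_constant") <- rv_constant
  attr(out, "config") <- cfg
  out
}

#' Generate one study from the collapsing-bound LCA
#'
#' For each trial the accumulator drifts are
#' `I_i = value_to_input_scale * value_i` and one CB-LCA trial is
#' simulated to produce the choice and RT; accuracy derives from the
#' option values. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()] (only the size, value-law,
#'   equal-value and label fields are used).
#' @param lca An [lca_params()] object; its inputs are overridden per
#'   trial.
#' @param value_to_input_scale Multiplier mapping option value to drift
#'   (default 0.4, mapping the 1-10 value scale onto drifts 0.4-4).
#' @return A trials tibble with `ov_z`/`rv_z` built.
#' @export
generate_lca_study <- function(config, lca = lca_params(),
                               value_to_input_scale = 0.4) {
  stopifnot(inherits(config, "generator_config"),
            value_to_input_scale > 0)
  cfg <- config
  set.seed(cfg$seed)
  np <- cfg$n_participants
  nt <- cfg$n_trials_per_participant
  n <- np * nt
  pid <- rep(sprintf("p%02d", seq_len(np)), each = nt)
  v <- draw_values(n, cfg)
  # simulate per unique value pair so the engine stays vectorized
  pair_id <- paste(v$value_a, v$value_b)
  chose_a <- logical(n)
  rt <- numeric(n)
  timed_out <- logical(n)
  for (pr in unique(pair_id)) {
    idx <- which(pair_id == pr)
    p <- lca
    p$input_correct <- value_to_input_scale * v$value_a[idx[1]]
    p$input_error <- value_to_input_scale * v$value_b[idx[1]]
    r <- simulate_lca_engine(p, length(idx))
    chose_a[idx] <- r$choice == 1L       # accumulator 1 carries value_a
    rt[idx] <- r$decision_time + p$nondecision_time
    timed_out[idx] <- r$timed_out
  }
  ov_z <- zscore_pop(v$value_a + v$value_b)
  rv_raw <- abs(v$value_a - v$value_b)
  rv_constant <- length(unique(rv_raw)) == 1L
  out <- tibble::tibble(
    study_id = paste0("lca_seed", cfg$seed),
    participant_id = pid,
    trial_index = as.integer(stats::ave(seq_len(n), pid,
                                        FUN = seq_along) - 1L),
    value_a = v$value_a, value_b = v$value_b,
    chose_a = chose_a,
    accuracy = derive_accuracy(v$value_a, v$value_b, chose_a),
    rt = rt,
    stimulus_type = cfg$stimulus_type, domain = cfg$domain,
    ov_z = ov_z,
    rv_z = if (rv_constant) rep(0, n) else zscore_pop(rv_raw))
  attr(out, "rv_constant") <- rv_constant
  attr(out, "timeout_fraction") <- mean(timed_out)
  out
}

#' Specification of a synthetic multi-study corpus
#'
#' The default composition mirrors the 40-study reanalysis corpus:
#' 5 abstract, 7 brightness, 7 numbers and 21 preference studies.
#' Brightness studies carry a negative true OV effect on accuracy
#' (default -0.25) while all other types have none, mirroring the
#' subgroup pattern the end-to-end tests probe; all studies share the
#' remaining [generator_config()] defaults unless overridden.
#'
#' @param n_abstract,n_brightness,n_numbers,n_preference Study counts
#'   per stimulus type.
#' @param brightness_beta_ov_acc True accuracy OV effect (log-odds per
#'   SD) for brightness studies.
#' @param ... Overrides applied to every study's [generator_config()]
#'   (e.g. `n_participants`).
#' @return A `corpus_spec` list of per-study configs (seeds are filled
#'   in by [generate_corpus()]).
#' @export
corpus_spec <- function(n_abstract = 5L, n_brightness = 7L,
                        n_numbers = 7L, n_preference = 21L,
                        brightness_beta_ov_acc = -0.25, ...) {
  types <- c(rep("abstract", n_abstract), rep("brightness", n_brightness),
             rep("numbers", n_numbers), rep("preference", n_preference))
  configs <- purrr::map(types, function(ty) {
    generator_config(
      stimulus_type = ty,
      domain = if (ty == "brightness") "perceptual" else "preferential",
      beta_ov_acc = if (ty == "brightness") brightness_beta_ov_acc else 0,
      ...)
  })
  structure(list(configs = configs, types = types), class = "corpus_spec")
}

#' Generate a synthetic corpus of studies
#'
#' Instantiates every study of a [corpus_spec()] with per-study seeds
#' derived reproducibly from `master_seed`.
#'
#' @param spec A [corpus_spec()].
#' @param master_seed Integer master seed.
#' @param generator Per-study generator, by default
#'   [generate_glmm_study()].
#' @return A list with `studies` (named list of trials tibbles) and
#'   `manifest` (tibble: study_id, stimulus_type, domain, sizes, seed,
#'   true effects).
#' @export
generate_corpus <- function(spec = corpus_spec(), master_seed = 1L,
                            generator = generate_glmm_study) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, length(spec$configs))
  studies <- vector("list", length(spec$configs))
  manifest <- vector("list", length(spec$configs))
  for (i in seq_along(spec$configs)) {
    cfg <- spec$configs[[i]]
    cfg$seed <- seeds[i]
    study_id <- sprintf("study%02d_%s", i, cfg$stimulus_type)
    tab <- generator(cfg)
    tab$study_id <- study_id
    studies[[i]] <- tab
    manifest[[i]] <- tibble::tibble(
      study_id = study_id, stimulus_type = cfg$stimulus_type,
      domain = cfg$domain, n_participants = cfg$n_participants,
      n_trials = nrow(tab), seed = seeds[i],
      beta_ov_rt = cfg$beta_ov_rt, beta_ov_acc = cfg$beta_ov_acc)
  }
  names(studies) <- purrr::map_chr(manifest, "study_id")
  list(studies = studies, manifest = purrr::list_rbind(manifest))
}
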