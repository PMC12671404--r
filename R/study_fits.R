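# Per-study regressions of log response time and accuracy on the
# standardized OV and RV predictors, with by-participant random
# intercepts and slopes, producing the coefficient rows the
# meta-analysis consumes.
#
# Fallback ladder on convergence failure:
#   1. full random slopes (unstructured covariance),
#   2. random intercepts only,
#   3. two-stage: per-participant regression, then a precision-weighted
#      mean across participants.
# The step actually used is recorded in `method`.

#' Fitting options for the per-study models
#'
#' @param min_trials Minimum usable trials per outcome; smaller studies
#'   are refused (default 20).
#' @param re_structure `"unstructured"` (correlated random effects) or
#'   `"diagonal"` (independent), for the full-slopes model.
#' @param allow_fallback Apply the intercepts-only / two-stage ladder on
#'   convergence failure (default `TRUE`).
#' @return A `fit_config` list.
#' @export
fit_config <- function(min_trials = 20L,
                       re_structure = c("unstructured", "diagonal"),
                       allow_fallback = TRUE) {
  structure(list(min_trials = min_trials,
                 re_structure = match.arg(re_structure),
                 allow_fallback = allow_fallback),
            class = "fit_config")
}

# random-effects term for participant intercepts + slopes
re_term <- function(slopes, structure) {
  bar <- if (structure == "diagonal") "||" else "|"
  if (length(slopes) == 0L) sprintf("(1 | participant_id)")
  else sprintf("(1 + %s %s participant_id)",
               paste(slopes, collapse = " + "), bar)
}

# Extract the OV (and RV) fixed-effect rows from an lme4 fit.
wald_row <- function(fit, term) {
  co <- summary(fit)$coefficients
  if (!term %in% rownames(co)) return(c(NA_real_, NA_real_, NA_real_))
  b <- co[term, 1]; se <- co[term, 2]
  c(b, se, 2 * stats::pnorm(-abs(b / se)))
}

fit_converged <- function(fit) {
  if (is.null(fit)) return(FALSE)
  co <- try(summary(fit)$coefficients, silent = TRUE)
  if (inherits(co, "try-error") || any(!is.finite(co[, 2]))) return(FALSE)
  opt <- fit@optinfo$conv$opt
  isTRUE(opt == 0)
}

# Try one lme4 model; NULL on error.
try_fit <- function(expr) {
  fit <- tryCatch(suppressMessages(suppressWarnings(expr)),
                  error = function(e) NULL)
  if (fit_converged(fit)) fit else NULL
}

# Precision-weighted mean of per-participant OLS/GLM coefficients.
two_stage_fit <- function(data, formula, family = NULL) {
  per <- data |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_map(function(d, key) {
      fit <- tryCatch(
        if (is.null(family)) stats::lm(formula, data = d)
        else suppressWarnings(stats::glm(formula, data = d,
                                         family = family)),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      co <- summary(fit)$coefficients
      terms <- intersect(c("ov_z", "rv_z"), rownames(co))
      tibble::tibble(term = terms, b = co[terms, 1], se = co[terms, 2])
    }) |>
    purrr::compact() |>
    purrr::list_rbind() |>
    dplyr::filter(is.finite(.data$b), is.finite(.data$se), .data$se < 1e3)
  if (nrow(per) == 0L) stop("two-stage fit: no usable participant fits",
                            call. = FALSE)
  per |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      b_pool = sum(.data$b / .data$se^2) / sum(1 / .data$se^2),
      se_pool = 1 / sqrt(sum(1 / .data$se^2)), .groups = "drop")
}

# Shared ladder driver for the RT (gaussian on log RT) and accuracy
# (binomial) models.
fit_ladder <- function(data, outcome, rv_in_model, config) {
  slopes <- c("ov_z", if (rv_in_model) "rv_z")
  fixed <- paste(c("ov_z", if (rv_in_model) "rv_z"), collapse = " + ")
  lhs <- if (outcome == "rt") "log(rt)" else "accuracy"
  f_full <- stats::as.formula(
    paste(lhs, "~", fixed, "+", re_term(slopes, config$re_structure)))
  f_int <- stats::as.formula(
    paste(lhs, "~", fixed, "+ (1 | participant_id)"))
  fitter <- function(f) {
    if (outcome == "rt") lme4::lmer(f, data = data, REML = TRUE)
    else lme4::glmer(f, data = data, family = stats::binomial,
                     control = lme4::glmerControl(optimizer = "bobyqa",
                                                  calc.derivs = FALSE))
  }
  fit <- try_fit(fitter(f_full))
  method <- "full_mixed"
  if (is.null(fit) && config$allow_fallback) {
    fit <- try_fit(fitter(f_int))
    method <- "intercepts_only"
  }
  if (!is.null(fit)) {
    ov <- wald_row(fit, "ov_z")
    rv <- if (rv_in_model) wald_row(fit, "rv_z")
          else c(NA_real_, NA_real_, NA_real_)
    return(list(b_ov = ov[1], se_ov = ov[2], p_ov = ov[3],
                b_rv = rv[1], se_rv = rv[2], p_rv = rv[3],
                method = method, converged = TRUE))
  }
  if (!config$allow_fallback) {
    stop("mixed model did not converge and fallback is disabled",
         call. = FALSE)
  }
  f2 <- stats::as.formula(paste(lhs, "~", fixed))
  ts <- two_stage_fit(data, f2,
                      family = if (outcome == "rt") NULL
                               else stats::binomial)
  pick <- function(term, col) {
    v <- ts[[col]][ts$term == term]
    if (length(v)) v else NA_real_
  }
  b_ov <- pick("ov_z", "b_pool"); se_ov <- pick("ov_z", "se_pool")
  list(b_ov = b_ov, se_ov = se_ov,
       p_ov = 2 * stats::pnorm(-abs(b_ov / se_ov)),
       b_rv = pick("rv_z", "b_pool"), se_rv = pick("rv_z", "se_pool"),
       p_rv = {
         brv <- pick("rv_z", "b_pool"); serv <- pick("rv_z", "se_pool")
         if (is.na(brv)) NA_real_ else 2 * stats::pnorm(-abs(brv / serv))
       },
       method = "two_stage", converged = TRUE)
}

fit_result_row <- function(trials, outcome, res, n_trials) {
  tibble::tibble(
    study_id = trials$study_id[1], outcome = outcome,
    stimulus_type = trials$stimulus_type[1], domain = trials$domain[1],
    b_ov = res$b_ov, se_ov = res$se_ov, p_ov = res$p_ov,
    b_rv = res$b_rv, se_rv = res$se_rv, p_rv = res$p_rv,
    n_participants = dplyr::n_distinct(trials$participant_id),
    n_trials = n_trials, method = res$method, converged = res$converged)
}

check_fit_pre <- function(trials, config, n_usable) {
  if (!all(c("ov_z", "rv_z") %in% names(trials))) {
    stop("predictors not built; call build_predictors() first",
         call. = FALSE)
  }
  if (dplyr::n_distinct(trials$participant_id) < 2L) {
    stop("need at least 2 participants for participant random effects",
         call. = FALSE)
  }
  if (n_usable < config$min_trials) {
    stop("fewer than ", config$min_trials, " usable trials (",
         n_usable, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit the per-study response-time model
#'
#' Regresses log RT on standardized OV and RV with by-participant
#' random intercepts and slopes (the RV terms are omitted when the raw
#' relative value is constant), applying the convergence fallback
#' ladder when needed. p-values are Wald (normal approximation).
#'
#' @param trials A trials tibble with predictors built.
#' @param config A [fit_config()].
#' @return A one-row study-fit tibble (`outcome = "rt"`).
#' @export
fit_rt_model <- function(trials, config = fit_config()) {
  check_fit_pre(trials, config, nrow(trials))
  rv_in <- !rv_is_constant(trials)
  res <- fit_ladder(trials, "rt", rv_in, config)
  fit_result_row(trials, "rt", res, nrow(trials))
}

#' Fit the per-study accuracy model
#'
#' Logistic mixed regression of accuracy on standardized OV and RV over
#' the unequal-value trials (accuracy is undefined at equality), with
#' the same random-effects structure and fallback ladder as
#' [fit_rt_model()].
#'
#' @inheritParams fit_rt_model
#' @return A one-row study-fit tibble (`outcome = "accuracy"`;
#'   `n_trials` counts the unequal-value trials actually modelled).
#' @export
fit_acc_model <- function(trials, config = fit_config()) {
  usable <- dplyr::filter(trials, !is.na(.data$accuracy))
  check_fit_pre(trials, config, nrow(usable))
  if (dplyr::n_distinct(usable$accuracy) < 2L) {
    stop("complete separation: all retained responses are ",
         if (isTRUE(usable$accuracy[1])) "correct" else "errors",
         call. = FALSE)
  }
  rv_in <- !rv_is_constant(trials)
  res <- fit_ladder(usable, "accuracy", rv_in, config)
  fit_result_row(usable, "accuracy", res, nrow(usable))
}

#' Fit both per-study models
#'
#' @inheritParams fit_rt_model
#' @return A two-row tibble (`rt` and `accuracy` outcomes).
#' @export
fit_study <- function(trials, config = fit_config()) {
  dplyr::bind_rows(fit_rt_model(trials, config),
                   fit_acc_model(trials, config))
}

#' Fit every study of a corpus
#'
#' Applies [fit_study()] per study; failures never abort the corpus
#' run and are returned as skip records.
#'
#' @param studies Named list of trials tibbles (predictors built).
#' @param config A [fit_config()].
#' @param outcomes Outcomes to fit, subset of `c("rt", "accuracy")`.
#' @return A list: `fits` (stacked study-fit tibble) and `skipped`
#'   (tibble of study_id, outcome, reason).
#' @export
fit_corpus <- function(studies, config = fit_config(),
                       outcomes = c("rt", "accuracy")) {
  fits <- list(); skipped <- list()
  for (sid in names(studies)) {
    for (outc in outcomes) {
      f <- if (outc == "rt") fit_rt_model else fit_acc_model
      res <- tryCatch(f(studies[[sid]], config), error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <- tibble::tibble(
          study_id = sid, outcome = outc, reason = conditionMessage(res))
      } else {
        res$study_id <- sid   # key by corpus name, not embedded label
        fits[[length(fits) + 1L]] <- res
      }
    }
  }
  list(fits = purrr::list_rbind(fits),
       skipped = purrr::list_rbind(skipped))
}

#' Equal-alternatives response-time fits
#'
#' For each study with strictly more than `min_trials` equal-value
#' trials, regresses log RT on OV (re-standardized within the
#' equal-value subset, where RV is identically zero) with
#' by-participant random intercepts and OV slopes. Ineligible studies
#' are skipped with a logged reason.
#'
#' @param studies Named list of trials tibbles (predictors built).
#' @param config A [fit_config()].
#' @param min_trials Eligibility threshold (strictly more than this
#'   many equal-value trials; default 50).
#' @return A list: `fits` (study-fit tibble, `outcome = "rt_equal"`)
#'   and `skipped` (tibble with reasons).
#' @export
fit_equal_alternatives_rt <- function(studies, config = fit_config(),
                                      min_trials = 50L) {
  fits <- list(); skipped <- list()
  for (sid in names(studies)) {
    sub <- filter_equal_value_trials(studies[[sid]], min_trials)
    if (!attr(sub, "eligible")) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        study_id = sid, outcome = "rt_equal",
        reason = paste0("only ", nrow(sub), " equal-value trials ",
                        "(need > ", min_trials, ")"))
      next
    }
    res <- tryCatch({
      ov <- sub$value_a + sub$value_b
      if (length(unique(ov)) < 2L) stop("constant OV on equal trials")
      sub$ov_z <- zscore_pop(ov)
      r <- fit_ladder(sub, "rt", rv_in_model = FALSE, config = config)
      row <- fit_result_row(sub, "rt_equal", r, nrow(sub))
      row$study_id <- sid
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        study_id = sid, outcome = "rt_equal",
        reason = conditionMessage(res))
    } else {
      fits[[length(fits) + 1L]] <- res
    }
  }
  list(fits = purrr::list_rbind(fits),
       skipped = purrr::list_rbind(skipped))
}
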