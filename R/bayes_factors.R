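# Bayes-factor comparison of the accuracy model with an OV effect (H1)
# against the model without it (H0). H0 keeps the effect of the value
# difference (or, when the difference is constant across trials, only
# the intercept) and the SAME random-effects structure as H1, so the
# Bayes factor reflects support for the fixed effect of OV alone.
# Marginal likelihoods are approximated by the Schwarz/BIC criterion,
# bf10 = exp((BIC0 - BIC1) / 2): prior-free and reproducible.

#' Compute the OV Bayes factor for one study's accuracy data
#'
#' Fits the H1 (with OV) and H0 (without OV) logistic mixed models on
#' the unequal-value trials, both with by-participant random intercepts
#' and OV slopes, and returns the BIC-approximated Bayes factor with
#' its five-band evidence label.
#'
#' @param trials A trials tibble with predictors built.
#' @param config A [fit_config()] (only `min_trials` is used; no
#'   fallback ladder — the BF needs both models in the same family).
#' @return A one-row tibble: `study_id`, `b_ov_bayes` (the H1 OV
#'   coefficient), `bf10`, `label`, `h0_form`
#'   (`"rv_only"`/`"intercept_only"`), `approximation = "BIC"`.
#' @export
compute_bf <- function(trials, config = fit_config()) {
  usable <- dplyr::filter(trials, !is.na(.data$accuracy))
  check_fit_pre(trials, config, nrow(usable))
  if (dplyr::n_distinct(usable$accuracy) < 2L) {
    stop("complete separation: accuracy takes a single value",
         call. = FALSE)
  }
  rv_constant <- rv_is_constant(trials)
  re <- "(1 + ov_z | participant_id)"
  f1 <- stats::as.formula(paste(
    "accuracy ~ ov_z", if (!rv_constant) "+ rv_z", "+", re))
  f0 <- stats::as.formula(paste(
    "accuracy ~", if (rv_constant) "1" else "rv_z", "+", re))
  ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE)
  fit1 <- try_fit(lme4::glmer(f1, data = usable,
                              family = stats::binomial, control = ctrl))
  fit0 <- try_fit(lme4::glmer(f0, data = usable,
                              family = stats::binomial, control = ctrl))
  if (is.null(fit1) || is.null(fit0)) {
    stop("Bayes factor unavailable: ",
         if (is.null(fit1)) "H1" else "H0", " model did not converge",
         call. = FALSE)
  }
  bf10 <- exp((stats::BIC(fit0) - stats::BIC(fit1)) / 2)
  tibble::tibble(
    study_id = trials$study_id[1],
    b_ov_bayes = lme4::fixef(fit1)[["ov_z"]],
    bf10 = bf10, label = label_bf(bf10),
    h0_form = if (rv_constant) "intercept_only" else "rv_only",
    approximation = "BIC")
}

#' Five-band evidence label for a Bayes factor
#'
#' Classifies `bf10` using the classical guideline bands: (1, 3]
#' anecdotal, (3, 10] moderate, (10, 30] strong, (30, 100] very strong,
#' > 100 extreme evidence for H1, with the reciprocal bands mapping to
#' the H0 labels; `bf10 = 1` is "No evidence". Values exactly on a
#' boundary take the weaker category.
#'
#' @param bf10 Positive Bayes factor(s) for H1 over H0.
#' @return Character vector of labels.
#' @examples
#' label_bf(c(200, 2, 0.15))
#' @export
label_bf <- function(bf10) {
  if (anyNA(bf10) || any(bf10 <= 0)) {
    stop("bf10 must be positive", call. = FALSE)
  }
  band <- function(x) {
    # x > 1; weaker category at the boundary: band (1,3] -> Anecdotal
    if (x <= 3) "Anecdotal"
    else if (x <= 10) "Moderate"
    else if (x <= 30) "Strong"
    else if (x <= 100) "Very strong"
    else "Extreme"
  }
  vapply(bf10, function(x) {
    if (x == 1) return("No evidence")
    if (x > 1) paste(band(x), "evidence for H1")
    else paste(band(1 / x), "evidence for H0")
  }, character(1))
}

#' Bayes factors for a corpus
#'
#' Applies [compute_bf()] per study with the partial-results contract:
#' failures are collected, not raised.
#'
#' @param studies Named list of trials tibbles.
#' @param config A [fit_config()].
#' @return A list: `bf` (stacked tibble) and `skipped`.
#' @export
compute_bf_corpus <- function(studies, config = fit_config()) {
  out <- list(); skipped <- list()
  for (sid in names(studies)) {
    res <- tryCatch(compute_bf(studies[[sid]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        study_id = sid, outcome = "bf", reason = conditionMessage(res))
    } else {
      res$study_id <- sid
      out[[length(out) + 1L]] <- res
    }
  }
  list(bf = purrr::list_rbind(out), skipped = purrr::list_rbind(skipped))
}
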