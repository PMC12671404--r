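# Random-effects meta-analysis of per-study OV coefficients.
#
# The pooling model is the standard additive random-effects model:
#   b_i ~ Normal(mu, se_i^2 + tau^2),
# with inverse-variance weights w_i = 1 / (se_i^2 + tau^2). tau^2 is
# estimated by REML (primary) or DerSimonian-Laird (cross-check).

#' Estimate between-study variance (tau-squared)
#'
#' Estimates the between-study variance of true effects in a
#' random-effects meta-analysis, either by restricted maximum likelihood
#' (REML, bounded one-dimensional optimisation) or by the
#' DerSimonian-Laird moment estimator.
#'
#' @param data A data frame with one row per study.
#' @param b,se Columns of `data` holding the per-study effect and its
#'   standard error (tidy-eval; defaults `b` and `se`).
#' @param method `"REML"` (default) or `"DL"`.
#' @return The tau-squared estimate (a non-negative scalar).
#' @details The REML criterion maximised over tau^2 >= 0 is
#'   `-0.5 * (sum(log(se^2 + tau^2)) + log(sum(w)) + sum(w * (b - bhat)^2))`
#'   with `w = 1/(se^2 + tau^2)` and `bhat` the weighted mean at that
#'   tau^2. The DL estimator is
#'   `max(0, (Q - (k - 1)) / (sum(wf) - sum(wf^2)/sum(wf)))` with fixed
#'   weights `wf = 1/se^2` and Cochran's Q.
#' @examples
#' studies <- tibble::tibble(b = c(0.1, 0.2, 0.3), se = 0.1)
#' estimate_tau(studies, method = "DL")  # 0: Q equals its df
#' @export
estimate_tau <- function(data, b = b, se = se, method = c("REML", "DL")) {
  method <- match.arg(method)
  bi <- dplyr::pull(data, {{ b }})
  si <- dplyr::pull(data, {{ se }})
  check_meta_input(bi, si)
  switch(method, DL = tau2_dl(bi, si), REML = tau2_reml(bi, si))
}

check_meta_input <- function(bi, si) {
  if (length(bi) < 2L) {
    stop("meta-analysis needs at least 2 studies, got ", length(bi),
         call. = FALSE)
  }
  if (anyNA(bi) || anyNA(si)) {
    stop("effects and standard errors must be non-missing", call. = FALSE)
  }
  if (any(si <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  invisible(TRUE)
}

tau2_dl <- function(bi, si) {
  wf <- 1 / si^2
  bbar <- sum(wf * bi) / sum(wf)
  Q <- sum(wf * (bi - bbar)^2)
  k <- length(bi)
  C <- sum(wf) - sum(wf^2) / sum(wf)
  max(0, (Q - (k - 1)) / C)
}

# Restricted log-likelihood (up to a constant) of the random-effects model
reml_loglik <- function(tau2, bi, si) {
  w <- 1 / (si^2 + tau2)
  bhat <- sum(w * bi) / sum(w)
  -0.5 * (sum(log(si^2 + tau2)) + log(sum(w)) + sum(w * (bi - bhat)^2))
}

tau2_reml <- function(bi, si) {
  # Search on [0, upper]; upper generously exceeds the observed spread.
  upper <- max(10 * stats::var(bi), 10 * max(si)^2, 1e-6)
  opt <- stats::optimize(reml_loglik, c(0, upper), bi = bi, si = si,
                         maximum = TRUE, tol = 1e-10)
  # The optimum can sit on the tau2 = 0 boundary; optimize() never
  # returns the exact endpoint, so compare against it explicitly.
  if (reml_loglik(0, bi, si) >= opt$objective) return(0)
  opt$maximum
}

#' Pool per-study effects with a random-effects model
#'
#' Inverse-variance pooling of per-study coefficients, with weights
#' `1/(se^2 + tau^2)`. Returns a `"vs_meta"` object with
#' [tidy()][generics::tidy], `glance()`, `print()` and
#' [autoplot()][ggplot2::autoplot] methods.
#'
#' @inheritParams estimate_tau
#' @param label Label attached to the result (e.g. `"overall"` or a
#'   subgroup name).
#' @return A `vs_meta` object: pooled effect `pooled_b`, `pooled_se`,
#'   Wald `z` and two-sided `p`, `tau` (between-study SD), `tau2_method`,
#'   Cochran's `Q` with `p_Q` (chi-squared on k - 1 df), and `k`.
#' @examples
#' studies <- tibble::tibble(b = c(0.1, 0.2, 0.3), se = 0.1)
#' pool_random_effects(studies)
#' @export
pool_random_effects <- function(data, b = b, se = se,
                                method = c("REML", "DL"),
                                label = "overall") {
  method <- match.arg(method)
  bi <- dplyr::pull(data, {{ b }})
  si <- dplyr::pull(data, {{ se }})
  check_meta_input(bi, si)
  tau2 <- switch(method, DL = tau2_dl(bi, si), REML = tau2_reml(bi, si))
  w <- 1 / (si^2 + tau2)
  pooled_b <- sum(w * bi) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled_b / pooled_se
  # Cochran's Q with fixed-effect weights, against chi-squared(k - 1)
  wf <- 1 / si^2
  bf_ <- sum(wf * bi) / sum(wf)
  Q <- sum(wf * (bi - bf_)^2)
  k <- length(bi)
  structure(
    list(pooled_b = pooled_b, pooled_se = pooled_se, z = z,
         p = 2 * stats::pnorm(-abs(z)), tau = sqrt(tau2), tau2 = tau2,
         tau2_method = method, Q = Q,
         p_Q = stats::pchisq(Q, df = k - 1, lower.tail = FALSE), k = k,
         label = label, b_i = bi, se_i = si),
    class = "vs_meta")
}

#' @export
print.vs_meta <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (%s tau), %s: k = %d\n",
              x$tau2_method, x$label, x$k))
  cat(sprintf("  pooled b = %.4f (SE %.4f), z = %.2f, p = %.3g\n",
              x$pooled_b, x$pooled_se, x$z, x$p))
  cat(sprintf("  tau = %.4f;  Q(%d) = %.2f, p = %.3g\n",
              x$tau, x$k - 1L, x$Q, x$p_Q))
  invisible(x)
}

#' Tidy a pooled meta-analysis result
#'
#' @param x A `vs_meta` object.
#' @param ... Unused.
#' @return A one-row tibble with the pooled effect, its standard error,
#'   z statistic, p-value and 95% Wald confidence limits.
#' @export
tidy.vs_meta <- function(x, ...) {
  tibble::tibble(
    label = x$label, estimate = x$pooled_b, std.error = x$pooled_se,
    statistic = x$z, p.value = x$p,
    conf.low = x$pooled_b - 1.96 * x$pooled_se,
    conf.high = x$pooled_b + 1.96 * x$pooled_se)
}

#' Model-level summary of a pooled meta-analysis result
#'
#' @inheritParams tidy.vs_meta
#' @return A one-row tibble with `tau`, `tau2_method`, Cochran's `Q`,
#'   `p_Q` and the number of studies `k`.
#' @export
glance.vs_meta <- function(x, ...) {
  tibble::tibble(tau = x$tau, tau2_method = x$tau2_method, Q = x$Q,
                 p_Q = x$p_Q, k = x$k)
}

#' Subgroup random-effects meta-analysis
#'
#' Pools effects independently within each level of a grouping column,
#' each subgroup with its own tau-squared.
#'
#' @inheritParams pool_random_effects
#' @param group Grouping column of `data` (tidy-eval), e.g. stimulus type.
#' @return A tibble with one row per subgroup (tidy + glance columns).
#'   Singleton groups are kept with `k = 1`, the study's own effect and
#'   SE, and `tau = NA` (no heterogeneity is estimable).
#' @export
subgroup_meta <- function(data, group, b = b, se = se,
                          method = c("REML", "DL")) {
  method <- match.arg(method)
  data |>
    dplyr::group_by({{ group }}) |>
    dplyr::group_map(function(d, key) {
      lab <- as.character(key[[1]])
      if (nrow(d) < 2L) {
        bi <- dplyr::pull(d, {{ b }}); si <- dplyr::pull(d, {{ se }})
        warning("subgroup '", lab, "' has a single study; reported without tau",
                call. = FALSE)
        return(tibble::tibble(
          label = lab, estimate = bi, std.error = si, statistic = bi / si,
          p.value = 2 * stats::pnorm(-abs(bi / si)),
          conf.low = bi - 1.96 * si, conf.high = bi + 1.96 * si,
          tau = NA_real_, Q = NA_real_, p_Q = NA_real_, k = 1L))
      }
      m <- pool_random_effects(d, b = {{ b }}, se = {{ se }},
                               method = method, label = lab)
      dplyr::bind_cols(tidy(m), glance(m)[c("tau", "Q", "p_Q", "k")])
    }) |>
    purrr::list_rbind()
}

#' Binary-moderator meta-regression
#'
#' Mixed-effects meta-regression of per-study effects on a binary
#' moderator, with a 1-df Wald test (Q_M) on the moderator coefficient.
#' tau^2 is the residual (within-level) REML or DL estimate from the
#' moderated model.
#'
#' @inheritParams pool_random_effects
#' @param moderator Logical (or two-level) column of `data`.
#' @return A one-row tibble: moderator coefficient `estimate` (level-2
#'   minus level-1 mean effect), `std.error`, `Q_M`, `p.value`, residual
#'   `tau`, and the two level labels.
#' @export
moderator_test <- function(data, moderator, b = b, se = se,
                           method = c("REML", "DL")) {
  method <- match.arg(method)
  bi <- dplyr::pull(data, {{ b }})
  si <- dplyr::pull(data, {{ se }})
  mod <- dplyr::pull(data, {{ moderator }})
  check_meta_input(bi, si)
  lev <- sort(unique(mod))
  if (length(lev) != 2L) {
    stop("moderator must take exactly 2 levels, got ", length(lev),
         call. = FALSE)
  }
  x <- as.numeric(mod == lev[2])
  if (min(table(x)) < 2L) {
    stop("both moderator levels need at least 2 studies", call. = FALSE)
  }
  tau2 <- metareg_tau2(bi, si, x, method)
  w <- 1 / (si^2 + tau2)
  X <- cbind(1, x)
  XtWX <- crossprod(X, w * X)
  V <- solve(XtWX)
  beta <- drop(V %*% crossprod(X, w * bi))
  se_mod <- sqrt(V[2, 2])
  Q_M <- (beta[2] / se_mod)^2
  tibble::tibble(
    estimate = beta[2], std.error = se_mod, Q_M = Q_M,
    p.value = stats::pchisq(Q_M, df = 1, lower.tail = FALSE),
    tau = sqrt(tau2),
    level_ref = as.character(lev[1]), level_alt = as.character(lev[2]))
}

# Residual tau^2 for the two-group meta-regression: REML profiles the
# restricted likelihood with the moderated mean structure; DL uses the
# residual-Q moment estimator with p = 2 mean parameters.
metareg_tau2 <- function(bi, si, x, method) {
  X <- cbind(1, x)
  if (method == "DL") {
    wf <- 1 / si^2
    H <- solve(crossprod(X, wf * X))
    beta <- drop(H %*% crossprod(X, wf * bi))
    QE <- sum(wf * (bi - drop(X %*% beta))^2)
    # trace correction for weighted least squares (Raudenbush-style)
    P <- diag(wf) - (wf * X) %*% H %*% t(wf * X)
    return(max(0, (QE - (length(bi) - 2)) / sum(diag(P) / 1)))
  }
  ll <- function(tau2) {
    w <- 1 / (si^2 + tau2)
    XtWX <- crossprod(X, w * X)
    beta <- drop(solve(XtWX) %*% crossprod(X, w * bi))
    r <- bi - drop(X %*% beta)
    -0.5 * (sum(log(si^2 + tau2)) + determinant(XtWX)$modulus +
              sum(w * r^2))
  }
  upper <- max(10 * stats::var(bi), 10 * max(si)^2, 1e-6)
  opt <- stats::optimize(ll, c(0, upper), maximum = TRUE, tol = 1e-10)
  if (ll(0) >= opt$objective) 0 else opt$maximum
}

#' Forest-plot data for per-study and pooled effects
#'
#' Builds the plot-ready table behind a forest plot: one row per study
#' with a 95% Wald interval, followed by the pooled subgroup and overall
#' rows.
#'
#' @inheritParams pool_random_effects
#' @param group Subgrouping column (tidy-eval), e.g. stimulus type.
#' @param study_id Study identifier column.
#' @return A tibble with columns `study_id`, `group`, `b`, `se`,
#'   `ci_low`, `ci_high`, `row_type` (`"study"` or `"pooled"`), ordered
#'   by group then effect, with pooled rows last.
#' @export
forest_data <- function(data, study_id = study_id, group = NULL,
                        b = b, se = se, method = c("REML", "DL")) {
  method <- match.arg(method)
  has_group <- !rlang::quo_is_null(rlang::enquo(group))
  studies <- tibble::tibble(
    study_id = as.character(dplyr::pull(data, {{ study_id }})),
    group = if (has_group) as.character(dplyr::pull(data, {{ group }}))
            else "all",
    b = dplyr::pull(data, {{ b }}),
    se = dplyr::pull(data, {{ se }})) |>
    dplyr::mutate(ci_low = .data$b - 1.96 * .data$se,
                  ci_high = .data$b + 1.96 * .data$se,
                  row_type = "study") |>
    dplyr::arrange(.data$group, .data$b)
  pooled <- list()
  if (has_group) {
    sg <- subgroup_meta(data, group = {{ group }}, b = {{ b }},
                        se = {{ se }}, method = method)
    pooled <- list(tibble::tibble(
      study_id = paste0("pooled: ", sg$label), group = sg$label,
      b = sg$estimate, se = sg$std.error, ci_low = sg$conf.low,
      ci_high = sg$conf.high, row_type = "pooled"))
  }
  ov <- pool_random_effects(data, b = {{ b }}, se = {{ se }},
                            method = method)
  overall <- tibble::tibble(
    study_id = "pooled: overall", group = "overall", b = ov$pooled_b,
    se = ov$pooled_se, ci_low = ov$pooled_b - 1.96 * ov$pooled_se,
    ci_high = ov$pooled_b + 1.96 * ov$pooled_se, row_type = "pooled")
  dplyr::bind_rows(c(list(studies), pooled, list(overall)))
}
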