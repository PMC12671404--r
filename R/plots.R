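# ggplot2 views of the two result types: forest plots of per-study and
# pooled OV effects, and the accuracy/MCRT/MERT profiles of an LCA
# input-sum sweep.

#' Forest plot of per-study and pooled OV effects
#'
#' @param data A forest table from [forest_data()].
#' @param xlab x-axis label.
#' @return A ggplot object.
#' @export
plot_forest <- function(data, xlab = "OV coefficient (95% CI)") {
  data <- dplyr::mutate(data,
                        study_id = factor(.data$study_id,
                                          levels = rev(.data$study_id)))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$b, y = .data$study_id,
                                     colour = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$row_type), size = 2) +
    ggplot2::scale_shape_manual(values = c(study = 16, pooled = 18)) +
    ggplot2::labs(x = xlab, y = NULL, colour = "group",
                  shape = "row") +
    ggplot2::theme_minimal()
}

#' Plot an LCA input-sum sweep
#'
#' Accuracy, mean correct RT and mean error RT as functions of the
#' input sum, one line per model variant.
#'
#' @param object A `vs_lca_sweep` tibble from [lca_variant_sweep()] (or
#'   any [sweep_input_sum()] output).
#' @param ... Unused.
#' @return A ggplot object, faceted by summary measure.
#' @export
autoplot.vs_lca_sweep <- function(object, ...) {
  long <- object |>
    dplyr::select(dplyr::all_of(c("variant", "input_sum", "accuracy",
                                  "mcrt", "mert"))) |>
    tidyr::pivot_longer(c("accuracy", "mcrt", "mert"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(measure = factor(.data$measure,
                                   levels = c("accuracy", "mcrt", "mert"),
                                   labels = c("Accuracy", "MCRT (s)",
                                              "MERT (s)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$input_sum,
                                     y = .data$value,
                                     colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "input sum (overall value)", y = NULL,
                  colour = "variant") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vs_lca_sweep
#' @param x A `vs_lca_sweep` tibble.
#' @export
plot_lca_sweep <- function(x) autoplot.vs_lca_sweep(x)

#' Forest plot of a pooled meta-analysis result
#'
#' @param object A `vs_meta` object from [pool_random_effects()].
#' @param ... Unused.
#' @return A ggplot object showing the per-study inputs and the pooled
#'   diamond row.
#' @export
autoplot.vs_meta <- function(object, ...) {
  d <- tibble::tibble(
    study_id = c(paste0("study ", seq_along(object$b_i)),
                 paste0("pooled: ", object$label)),
    group = c(rep("study", length(object$b_i)), "pooled"),
    b = c(object$b_i, object$pooled_b),
    ci_low = c(object$b_i - 1.96 * object$se_i,
               object$pooled_b - 1.96 * object$pooled_se),
    ci_high = c(object$b_i + 1.96 * object$se_i,
                object$pooled_b + 1.96 * object$pooled_se),
    row_type = c(rep("study", length(object$b_i)), "pooled"))
  plot_forest(d)
}
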