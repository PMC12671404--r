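# The packaged 40-study summary table: per-study OV coefficients on log
# RT (brt) and accuracy (bacc) with their standard errors and p-values,
# study sizes, stimulus types, Bayesian OV coefficients and Bayes-factor
# evidence labels, as printed in the source reanalysis.

#' Load the packaged 40-study summary table
#'
#' Reads the per-study coefficient table shipped with the package
#' (40 two-alternative choice studies: 5 abstract, 7 brightness,
#' 7 numbers, 21 preference). Coefficient columns are kept at their
#' printed 3-decimal precision; the free-text `stimuli` and `domain`
#' columns are transcribed as printed and additionally normalized into
#' lower-case `stimulus_type` and `domain_norm` columns (typo-fixed)
#' for grouping.
#'
#' @param path Path to the TSV; defaults to the packaged copy.
#' @return A 40-row tibble with columns `id`, `study`, `domain`,
#'   `stimuli`, `n_ppt`, `n_trials`, `brt`, `se_brt`, `p_brt`, `bacc`,
#'   `se_bacc`, `p_bacc`, `bacc_bayes`, `bf_label`, plus the normalized
#'   `stimulus_type` and `domain_norm`.
#' @export
load_table1_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_fixture.tsv",
                        package = "valuesense", mustWork = TRUE)
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    id = "i", n_ppt = "i", n_trials = "i",
                    brt = "d", se_brt = "d", bacc = "d", se_bacc = "d",
                    bacc_bayes = "d", .default = "c")) |>
    dplyr::mutate(
      stimulus_type = tolower(.data$stimuli),
      domain_norm = dplyr::recode(tolower(.data$domain),
                                  peferential = "preferential"))
}
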