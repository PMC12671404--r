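# End-to-end orchestration: corpus (synthetic or CSV directory) ->
# per-study fits -> meta-analyses -> Bayes factors -> plot-ready
# tables, with seed control and a partial-results contract (per-study
# failures are recorded, never fatal).

#' Pipeline configuration
#'
#' @param corpus A [corpus_spec()] for synthetic input, or `NULL` when
#'   reading CSVs.
#' @param csv_dir Directory of per-study CSV files (used when `corpus`
#'   is `NULL`).
#' @param column_map Column mapping for CSV input
#'   (see [trial_column_map()]).
#' @param fit A [fit_config()].
#' @param tau_method `"REML"` or `"DL"`.
#' @param master_seed Integer seed controlling every random stage.
#' @param equal_min_trials Eligibility threshold for the
#'   equal-alternatives analysis.
#' @param moderator Optional named logical vector (study_id -> flag)
#'   for the binary moderator analysis.
#' @param out_dir Output directory; `NULL` suppresses file output.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus = corpus_spec(), csv_dir = NULL,
                            column_map = trial_column_map(),
                            fit = fit_config(),
                            tau_method = c("REML", "DL"),
                            master_seed = 1L, equal_min_trials = 50L,
                            moderator = NULL, out_dir = NULL) {
  structure(list(corpus = corpus, csv_dir = csv_dir,
                 column_map = column_map, fit = fit,
                 tau_method = match.arg(tau_method),
                 master_seed = master_seed,
                 equal_min_trials = equal_min_trials,
                 moderator = moderator, out_dir = out_dir),
            class = "pipeline_config")
}

meta_rows <- function(fits, outcome, tau_method) {
  d <- dplyr::filter(fits, .data$outcome == !!outcome,
                     is.finite(.data$b_ov), is.finite(.data$se_ov),
                     .data$se_ov > 0)
  if (nrow(d) < 2L) return(tibble::tibble())
  ov <- pool_random_effects(d, b = b_ov, se = se_ov, method = tau_method)
  overall <- dplyr::bind_cols(tidy(ov), glance(ov)[c("tau", "Q", "p_Q", "k")])
  sub <- tibble::tibble()
  if (dplyr::n_distinct(d$stimulus_type) > 1L &&
      all(table(d$stimulus_type) >= 2L)) {
    sub <- subgroup_meta(d, group = stimulus_type, b = b_ov, se = se_ov,
                         method = tau_method)
  }
  dplyr::bind_rows(
    dplyr::mutate(overall, label = "overall"), sub) |>
    dplyr::mutate(outcome = outcome, .before = 1)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the study corpus, fits the per-study RT and
#' accuracy models, pools them overall and by stimulus type, runs the
#' equal-alternatives RT analysis, the optional binary-moderator test
#' and the per-study Bayes factors, and assembles plot-ready forest
#' data. All stages are reproducible from `(config, master_seed)`.
#'
#' @param config A [pipeline_config()].
#' @param compute_bayes Compute per-study Bayes factors (default
#'   `TRUE`; the corpus-size-dependent slow stage).
#' @return A list: `manifest`, `study_fits`, `skipped`, `meta`
#'   (overall + subgroup rows for both outcomes), `equal_meta`,
#'   `moderator`, `bayes`, `forest`. When `config$out_dir` is set the
#'   tables are also written there as TSV/CSV.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         compute_bayes = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$corpus)) {
    corpus <- generate_corpus(config$corpus, config$master_seed)
    studies <- corpus$studies
    manifest <- corpus$manifest
  } else {
    files <- sort(list.files(config$csv_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (!length(files)) stop("no CSV files in ", config$csv_dir,
                             call. = FALSE)
    studies <- purrr::map(files, function(f) {
      build_predictors(load_study_csv(f, config$column_map))
    })
    names(studies) <- purrr::map_chr(studies, ~ .x$study_id[1])
    manifest <- purrr::map(studies, function(s) tibble::tibble(
      study_id = s$study_id[1], stimulus_type = s$stimulus_type[1],
      domain = s$domain[1],
      n_participants = dplyr::n_distinct(s$participant_id),
      n_trials = nrow(s), seed = NA_integer_)) |>
      purrr::list_rbind()
  }
  manifest$master_seed <- config$master_seed

  fc <- fit_corpus(studies, config$fit)
  eq <- fit_equal_alternatives_rt(studies, config$fit,
                                  config$equal_min_trials)
  meta <- dplyr::bind_rows(
    meta_rows(fc$fits, "rt", config$tau_method),
    meta_rows(fc$fits, "accuracy", config$tau_method))
  equal_meta <- if (!is.null(eq$fits) && nrow(eq$fits) >= 2L) {
    m <- pool_random_effects(eq$fits, b = b_ov, se = se_ov,
                             method = config$tau_method,
                             label = "equal_alternatives")
    dplyr::bind_cols(tidy(m), glance(m)[c("tau", "Q", "p_Q", "k")])
  } else tibble::tibble()

  moderator <- tibble::tibble()
  if (!is.null(config$moderator)) {
    d <- dplyr::filter(fc$fits, .data$outcome == "accuracy") |>
      dplyr::mutate(flag = unname(config$moderator[.data$study_id]))
    moderator <- moderator_test(d, moderator = flag, b = b_ov,
                                se = se_ov, method = config$tau_method)
  }

  bayes <- tibble::tibble()
  if (compute_bayes) {
    bc <- compute_bf_corpus(studies, config$fit)
    bayes <- bc$bf
  }

  acc_fits <- dplyr::filter(fc$fits, .data$outcome == "accuracy")
  forest <- if (nrow(acc_fits) >= 2L) {
    forest_data(acc_fits, study_id = study_id, group = stimulus_type,
                b = b_ov, se = se_ov, method = config$tau_method)
  } else tibble::tibble()

  out <- list(manifest = manifest, study_fits = fc$fits,
              skipped = dplyr::bind_rows(fc$skipped, eq$skipped),
              meta = meta, equal_meta = equal_meta,
              moderator = moderator, bayes = bayes, forest = forest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) {
    if (is.data.frame(x) && nrow(x)) {
      readr::write_tsv(x, file.path(config$out_dir, f), progress = FALSE)
    }
  }
  w(out$study_fits, "study_fits.tsv")
  w(out$meta, "meta.tsv")
  w(out$equal_meta, "equal_alternatives_meta.tsv")
  w(out$moderator, "moderator.tsv")
  w(out$bayes, "bayes.tsv")
  w(out$skipped, "skipped.tsv")
  if (nrow(out$forest)) {
    readr::write_csv(out$forest, file.path(config$out_dir,
                                           "forest_data.csv"),
                     progress = FALSE)
  }
  manifest <- out$manifest
  manifest$config_hash <- rlang::hash(config)
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(config$out_dir)
}

#' Combined per-study report table
#'
#' Assembles one row per study in the layout of the packaged 40-study
#' summary table (ID, Study, Domain, Stimuli, Nppt, Ntrials, brt,
#' SEbrt, pbrt, bacc, SEbacc, pbacc, baccBayes, BFacc). Studies with a
#' skipped outcome keep their row with NA cells and the skip reason.
#'
#' @param outputs The list returned by [run_pipeline()].
#' @return A tibble with the layout above plus a `note` column carrying
#'   skip reasons.
#' @export
report_table <- function(outputs) {
  man <- outputs$manifest
  rt <- dplyr::filter(outputs$study_fits, .data$outcome == "rt")
  ac <- dplyr::filter(outputs$study_fits, .data$outcome == "accuracy")
  bf <- outputs$bayes
  skips <- outputs$skipped
  rows <- purrr::imap(man$study_id, function(sid, i) {
    r <- rt[rt$study_id == sid, ]; a <- ac[ac$study_id == sid, ]
    b <- if (is.data.frame(bf) && nrow(bf)) bf[bf$study_id == sid, ]
         else bf
    sk <- if (is.data.frame(skips) && nrow(skips)) {
      paste(skips$reason[skips$study_id == sid], collapse = "; ")
    } else ""
    g <- function(d, col) if (nrow(d)) d[[col]][1] else NA_real_
    tibble::tibble(
      ID = i, Study = sid, Domain = man$domain[i],
      Stimuli = man$stimulus_type[i], Nppt = man$n_participants[i],
      Ntrials = man$n_trials[i],
      brt = g(r, "b_ov"), SEbrt = g(r, "se_ov"), pbrt = g(r, "p_ov"),
      bacc = g(a, "b_ov"), SEbacc = g(a, "se_ov"), pbacc = g(a, "p_ov"),
      baccBayes = if (is.data.frame(b) && nrow(b)) b$b_ov_bayes[1]
                  else NA_real_,
      BFacc = if (is.data.frame(b) && nrow(b)) b$label[1]
              else NA_character_,
      note = sk)
  })
  purrr::list_rbind(rows)
}
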