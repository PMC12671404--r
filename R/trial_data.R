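# Trial-level data model: loading, validation, and construction of the
# standardized overall-value (OV) and relative-value (RV) predictors.

#' Default column mapping for trial-level CSV files
#'
#' Maps the canonical trial columns onto the column names used in a
#' source file. Override entries to absorb heterogeneous source formats,
#' e.g. `trial_column_map(rt = "reaction_time")`.
#'
#' @param ... Named overrides, one per canonical column.
#' @return A named character vector (canonical name -> source name).
#' @export
trial_column_map <- function(...) {
  map <- c(study_id = "study_id", participant_id = "participant_id",
           trial_index = "trial_index", value_a = "value_a",
           value_b = "value_b", chose_a = "chose_a", accuracy = "accuracy",
           rt = "rt", stimulus_type = "stimulus_type", domain = "domain")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(map))
    if (length(bad)) stop("unknown column-map entries: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    map[names(over)] <- over
  }
  map
}

#' Load a trial-level study CSV
#'
#' Reads one study's trials from a comma-separated file (UTF-8, header
#' row required), renaming columns through `column_map`. Rows whose RT
#' is missing, non-numeric or not strictly positive are dropped and
#' counted, as are rows with a missing choice; nothing is imputed.
#'
#' @param path Path to the CSV file.
#' @param column_map Named mapping from canonical to source column
#'   names, as built by [trial_column_map()]. The columns
#'   `participant_id`, `value_a`, `value_b`, `chose_a` and `rt` are
#'   required; the rest are filled with defaults when absent.
#' @return A trials tibble. The number of dropped rows is attached as
#'   attribute `n_dropped` and reported via a message.
#' @export
load_study_csv <- function(path, column_map = trial_column_map()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols())
  required <- c("participant_id", "value_a", "value_b", "chose_a", "rt")
  for (col in required) {
    if (!column_map[[col]] %in% names(raw)) {
      stop("missing mapped column '", col, "' (mapped to '",
           column_map[[col]], "')", call. = FALSE)
    }
  }
  present <- column_map[column_map %in% names(raw)]
  # a named all_of() selection renames source -> canonical in one step
  trials <- dplyr::select(raw, dplyr::all_of(present))
  n0 <- nrow(trials)
  trials <- trials |>
    dplyr::mutate(
      rt = suppressWarnings(as.numeric(.data$rt)),
      chose_a = as.logical(.data$chose_a)) |>
    dplyr::filter(!is.na(.data$rt), .data$rt > 0, !is.na(.data$chose_a))
  n_dropped <- n0 - nrow(trials)
  if (nrow(trials) == 0L) {
    stop("no retained trials in ", path, " (", n_dropped, " dropped)",
         call. = FALSE)
  }
  defaults <- list(study_id = basename_no_ext(path),
                   trial_index = seq_len(nrow(trials)) - 1L,
                   accuracy = NA, stimulus_type = "preference",
                   domain = "preferential")
  for (col in names(defaults)) {
    if (!col %in% names(trials)) trials[[col]] <- defaults[[col]]
  }
  trials <- trials |>
    dplyr::mutate(
      study_id = as.character(.data$study_id),
      participant_id = as.character(.data$participant_id),
      accuracy = as.logical(.data$accuracy)) |>
    dplyr::select(dplyr::all_of(c("study_id", "participant_id",
                                  "trial_index", "value_a", "value_b",
                                  "chose_a", "accuracy", "rt",
                                  "stimulus_type", "domain")))
  if (n_dropped > 0) {
    message("load_study_csv: dropped ", n_dropped,
            " trial(s) with invalid RT or choice from ", basename(path))
  }
  attr(trials, "n_dropped") <- n_dropped
  trials
}

basename_no_ext <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Write a study table to CSV
#'
#' Inverse of [load_study_csv()]: writes the canonical columns (plus
#' `ov_z`/`rv_z` when present) with RT rounded to 6 decimals.
#'
#' @param trials A trials tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(trials, path) {
  out <- dplyr::mutate(trials, rt = round(.data$rt, 6))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Derive accuracy from option values and choice
#'
#' Accuracy is defined as choosing the option with the higher value
#' (for preference tasks, the higher stated rating); it is `NA` on
#' equal-value trials, where correctness is undefined.
#'
#' @param value_a,value_b Option values.
#' @param chose_a Logical, `TRUE` when option A was chosen.
#' @return Logical vector with `NA` where `value_a == value_b`.
#' @export
derive_accuracy <- function(value_a, value_b, chose_a) {
  dplyr::if_else(value_a == value_b, NA,
                 (chose_a & value_a > value_b) |
                   (!chose_a & value_b > value_a))
}

#' Build standardized OV and RV predictors
#'
#' Appends `ov_z`, the z-scored overall value (`value_a + value_b`), and
#' `rv_z`, the z-scored absolute relative value (`|value_a - value_b|`),
#' both standardized over the study's retained trials with the
#' population SD (divide by n). When the raw relative value is constant
#' across trials, `rv_z` is set to all zeros and the attribute
#' `rv_constant` is `TRUE`, so downstream models drop the RV term.
#'
#' @param trials A trials tibble (one study).
#' @return The tibble with `ov_z` and `rv_z` columns and a logical
#'   `rv_constant` attribute. Idempotent.
#' @export
build_predictors <- function(trials) {
  if (nrow(trials) < 2L) {
    stop("need at least 2 trials to standardize predictors", call. = FALSE)
  }
  ov <- trials$value_a + trials$value_b
  rv <- abs(trials$value_a - trials$value_b)
  if (length(unique(ov)) < 2L) {
    stop("overall value is constant across trials; the OV effect is ",
         "unidentifiable", call. = FALSE)
  }
  rv_constant <- length(unique(rv)) == 1L
  trials$ov_z <- zscore_pop(ov)
  trials$rv_z <- if (rv_constant) rep(0, length(rv)) else zscore_pop(rv)
  attr(trials, "rv_constant") <- rv_constant
  trials
}

# z-score with the population SD (divide by n, not n - 1)
zscore_pop <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  (x - mean(x)) / s
}

#' Is the relative value constant in a study?
#'
#' Recomputed from the raw values so it survives any dplyr operation
#' that drops attributes.
#'
#' @param trials A trials tibble.
#' @return `TRUE` when `|value_a - value_b|` takes a single value.
#' @export
rv_is_constant <- function(trials) {
  length(unique(abs(trials$value_a - trials$value_b))) == 1L
}

#' Subset a study to its equal-value trials
#'
#' Returns the trials with `value_a == value_b`. The attribute
#' `eligible` flags studies with strictly more than `min_trials`
#' equal-value trials, the inclusion rule for the equal-alternatives RT
#' meta-analysis.
#'
#' @param trials A trials tibble with predictors built.
#' @param min_trials Eligibility threshold; a study qualifies only with
#'   more than this many equal-value trials (default 50).
#' @return The equal-value subset (possibly empty) with attribute
#'   `eligible`.
#' @export
filter_equal_value_trials <- function(trials, min_trials = 50L) {
  sub <- dplyr::filter(trials, .data$value_a == .data$value_b)
  attr(sub, "eligible") <- nrow(sub) > min_trials
  sub
}

#' Validate the trial-level invariants
#'
#' Checks that RTs are strictly positive, that accuracy is missing
#' exactly on equal-value trials, and that accuracy agrees with the
#' higher-value-chosen rule everywhere it is defined.
#'
#' @param trials A trials tibble.
#' @return `TRUE` invisibly; otherwise an error naming the violated
#'   invariant.
#' @export
validate_trials <- function(trials) {
  if (any(trials$rt <= 0)) stop("invariant violated: rt > 0", call. = FALSE)
  eq <- trials$value_a == trials$value_b
  if (any(is.na(trials$accuracy) != eq)) {
    stop("invariant violated: accuracy must be missing iff values are equal",
         call. = FALSE)
  }
  expect <- derive_accuracy(trials$value_a, trials$value_b, trials$chose_a)
  if (!identical(as.logical(trials$accuracy[!eq]),
                 as.logical(expect[!eq]))) {
    stop("invariant violated: accuracy must equal the ",
         "higher-value-chosen rule", call. = FALSE)
  }
  invisible(TRUE)
}
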