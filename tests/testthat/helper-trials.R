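# Builders for small in-code fixtures.

# A fully specified trial table from value pairs; accuracy follows the
# higher-value-chosen rule, RT is an arbitrary positive sequence.
make_trials <- function(value_a, value_b, participant_id = NULL,
                        rt = NULL, chose_a = NULL) {
  n <- length(value_a)
  if (is.null(participant_id)) {
    participant_id <- rep(c("p1", "p2"), length.out = n)
  }
  if (is.null(rt)) rt <- seq(0.4, 1.4, length.out = n)
  if (is.null(chose_a)) chose_a <- value_a >= value_b
  tibble::tibble(
    study_id = "s1", participant_id = participant_id,
    trial_index = seq_len(n) - 1L,
    value_a = value_a, value_b = value_b, chose_a = chose_a,
    accuracy = derive_accuracy(value_a, value_b, chose_a),
    rt = rt, stimulus_type = "preference", domain = "preferential")
}

write_trials_csv <- function(trials, path = tempfile(fileext = ".csv")) {
  readr::write_csv(trials, path, progress = FALSE)
  path
}

# Synthetic meta-analysis inputs: k studies, true effects mu + tau*u_i,
# observed with standard error se.
make_meta_input <- function(k, mu = 0, tau = 0, se = 0.1) {
  tibble::tibble(
    study_id = paste0("s", seq_len(k)),
    b = rnorm(k, mu, tau) + rnorm(k, 0, se),
    se = rep(se, k))
}
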