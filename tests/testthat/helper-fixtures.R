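# Shared small synthetic study, built once per test run.
.fixture_env <- new.env()

tiny_config <- function(seed = 42L, ...) {
  study_config(n_subjects = 3, sessions_per_subject = c(8, 8, 8),
               audio_sessions_per_subject = c(8, 8, 8),
               ecg_sessions_per_subject = c(8, 8, 8),
               rng_seed = seed, ...)
}

tiny_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- simulate_study(tiny_config())
  }
  .fixture_env$study
}

# heart-rate percentile table + call table for perievent tests
study_signal_tables <- function(study) {
  hr <- purrr::map_dfr(study$sessions, function(b) {
    if (!isTRUE(b$has_ecg) || length(b$beat_times) < 2) return(NULL)
    h <- hr_percentiles(rate_from_beats(correct_intervals(b$beat_times),
                                        b$duration_s))
    h$session <- b$session_id
    h
  })
  calls <- purrr::map_dfr(study$sessions, "calls")
  list(hr = hr, calls = calls)
}

ground_truth_classification <- function() {
  tibble::tibble(
    behavior = c("cry", "phee", "righting_reflex", "hindlimb_support",
                 "crawling", "walking"),
    classification = c("immature", "mature", "immature", "mature",
                       "immature", "mature"))
}

study_events <- function(study) {
  purrr::map_dfr(study$sessions, function(b) {
    dplyr::bind_rows(
      dplyr::mutate(
        b$calls[, c("subject", "session", "pnd", "onset_s", "offset_s")],
        category = "vocal", behavior = b$calls$call_type),
      b$behaviors)
  })
}
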