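#' Study-design bookkeeping table
#'
#' Per-subject session, audio-session, call, behavior-instance and
#' ECG-session counts of the reference study design that the synthetic
#' generator's defaults emulate: 220 observation sessions across 7 subjects
#' over postnatal days 1-61, audio for 192 sessions (10,956 calls), video
#' scoring yielding 3,195 behavior instances, and ECG for 149 sessions.
#'
#' @return Tibble with one row per subject and a `totals` attribute.
#' @export
study_design <- function() {
  d <- tibble::tibble(
    subject = paste0("S", 1:7),
    sessions = c(29, 29, 34, 34, 31, 31, 32),
    audio_sessions = c(28, 29, 21, 20, 31, 31, 32),
    calls = c(1100, 801, 1604, 1021, 1657, 2199, 2574),
    behavior_instances = c(662, 635, 414, 574, 207, 427, 276),
    ecg_sessions = c(16, 14, 21, 19, 26, 25, 28)
  )
  attr(d, "totals") <- purrr::map_dbl(d[-1], sum)
  d
}

#' Write a study to a directory of plain-text files
#'
#' `manifest.csv` plus per-session `calls.csv`, `behaviors.csv`,
#' `motion_raw.csv`, `beats.csv` (true heartbeat times; raw ECG waveforms
#' are synthesized on demand by [simulate_ecg()] rather than stored), and
#' `ground_truth.json`. All times are seconds from session start, intervals
#' half-open `[onset, offset)`.
#'
#' @param study A `vocomotor_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- study_manifest(study)
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  for (b in study$sessions) {
    sd <- file.path(dir, b$session_id)
    dir.create(sd, showWarnings = FALSE)
    readr::write_csv(b$calls, file.path(sd, "calls.csv"))
    if (!is.null(b$behaviors) && nrow(b$behaviors)) {
      readr::write_csv(b$behaviors, file.path(sd, "behaviors.csv"))
    }
    readr::write_csv(b$motion_raw, file.path(sd, "motion_raw.csv"))
    readr::write_csv(tibble::tibble(beat_s = b$beat_times),
                     file.path(sd, "beats.csv"))
  }
  gt <- study$ground_truth
  for (nm in c("transition_days", "coupling", "arousal_effects")) {
    if (!is.null(gt[[nm]])) gt[[nm]] <- as.list(gt[[nm]])  # keep names in JSON
  }
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a study from a manifest directory
#'
#' Reads `manifest.csv` and the per-session files written by
#' [write_study()]. Sessions with missing files are kept but flagged
#' (`complete = FALSE`) and the run continues; an empty manifest yields an
#' empty study with a warning.
#'
#' @param dir Study directory containing `manifest.csv`.
#' @return A `vocomotor_study`.
#' @export
load_study <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  man <- readr::read_csv(mpath, show_col_types = FALSE)
  required <- c("subject", "pnd", "session_id")
  miss <- setdiff(required, names(man))
  if (length(miss)) {
    stop("manifest is missing required columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(man) == 0L) warning("empty manifest: study has no sessions")
  sessions <- purrr::pmap(man, function(subject, pnd, session_id, ...) {
    extra <- list(...)
    sd <- file.path(dir, session_id)
    read_or_null <- function(f) {
      p <- file.path(sd, f)
      if (file.exists(p)) readr::read_csv(p, show_col_types = FALSE) else NULL
    }
    calls <- read_or_null("calls.csv")
    motion <- read_or_null("motion_raw.csv")
    beats <- read_or_null("beats.csv")
    list(subject = subject, pnd = pnd, session_id = session_id,
         duration_s = extra$duration_s %||%
           (if (!is.null(motion)) max(motion$t_s) + 0.5 else NA_real_),
         calls = calls %||% tibble::tibble(subject = character(0),
                                           session = character(0), pnd = numeric(0),
                                           onset_s = numeric(0), offset_s = numeric(0),
                                           call_type = character(0)),
         behaviors = read_or_null("behaviors.csv"),
         motion_raw = motion,
         beat_times = if (!is.null(beats)) beats$beat_s else numeric(0),
         has_audio = isTRUE(extra$has_audio),
         has_ecg = isTRUE(extra$has_ecg),
         complete = !is.null(calls) && !is.null(motion))
  })
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE)
  structure(list(sessions = sessions, ground_truth = gt, config = NULL),
            class = "vocomotor_study")
}

#' Prepare the analysis tables a study implies
#'
#' Runs the per-session stages (activity index, heart rate and percentiles,
#' call annotation with per-call average locomotor activity and arousal,
#' behavior/call proportions) and assembles the tables consumed by the
#' mixed-model suite and the peri-event analyses. Heart rate comes from the
#' session's validated beat times ([correct_intervals()] +
#' [rate_from_beats()]); sessions without ECG, or failing the 50% coverage
#' rule, carry `NaN` percentiles and are excluded from arousal analyses.
#'
#' @param study A `vocomotor_study`.
#' @return Named list of tibbles: `activity`, `heart_rate`, `calls`,
#'   `locomotor_events`, `proportions_vocal` / `_postural` / `_locomotor`,
#'   `classification`, `maturity_points`, `events`.
#' @export
prepare_tables <- function(study) {
  bundles <- study$sessions
  age_bins <- function(pnd) dplyr::case_when(
    pnd >= 1 & pnd <= 10 ~ "early",
    pnd >= 52 & pnd <= 61 ~ "late",
    TRUE ~ NA_character_)

  per_sess <- purrr::map(bundles, function(b) {
    act <- activity_series(b$motion_raw)
    act$session <- b$session_id
    hr <- NULL
    if (isTRUE(b$has_ecg) && length(b$beat_times) > 1L) {
      beats <- correct_intervals(b$beat_times)
      hr <- rate_from_beats(beats, session_duration_s = b$duration_s)
      hr <- if (coverage_ok(hr)) hr_percentiles(hr) else dplyr::mutate(hr, percentile = NaN)
      hr$session <- b$session_id
    }
    mean_over <- function(series, col, on, off) {
      if (is.null(series)) return(rep(NA_real_, length(on)))
      purrr::map2_dbl(on, off, function(a, z) {
        v <- sample_1hz(series[[col]], seq(floor(a) + 0.5, max(floor(a), floor(z)) + 0.5))
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      })
    }
    calls <- b$calls
    if (nrow(calls)) {
      calls <- dplyr::mutate(calls,
        duration_s = .data$offset_s - .data$onset_s,
        locomotor_activity = mean_over(act, "activity", .data$onset_s, .data$offset_s),
        hr_percentile = mean_over(hr, "percentile", .data$onset_s, .data$offset_s),
        age_group = age_bins(.data$pnd))
    }
    loco <- NULL
    if (!is.null(b$behaviors) && nrow(b$behaviors)) {
      loco <- dplyr::filter(b$behaviors, .data$category == "locomotor")
      if (nrow(loco)) {
        loco <- dplyr::mutate(loco,
          hr_percentile = mean_over(hr, "percentile", .data$onset_s, .data$offset_s),
          age_group = age_bins(.data$pnd))
      }
    }
    list(act = act, hr = hr, calls = calls, loco = loco, behaviors = b$behaviors)
  })

  calls <- purrr::map_dfr(per_sess, "calls")
  events <- dplyr::bind_rows(
    dplyr::mutate(
      dplyr::select(calls, dplyr::any_of(c("subject", "session", "pnd",
                                           "onset_s", "offset_s", "call_type"))),
      category = "vocal", behavior = .data$call_type),
    purrr::map_dfr(per_sess, "behaviors"))
  props <- category_proportions(events)
  cls <- classify_behaviors(props)
  mat <- maturity_points(events, cls) |>
    dplyr::mutate(total_time = .data$m_time + .data$im_time)

  list(
    activity = purrr::map_dfr(per_sess, "act"),
    heart_rate = purrr::map_dfr(per_sess, "hr"),
    calls = calls,
    locomotor_events = purrr::map_dfr(per_sess, "loco"),
    proportions_vocal = dplyr::filter(props, .data$category == "vocal"),
    proportions_postural = dplyr::filter(props, .data$category == "postural"),
    proportions_locomotor = dplyr::filter(props, .data$category == "locomotor"),
    classification = cls,
    maturity_points = mat,
    events = events
  )
}

#' Run the full analysis pipeline on a study
#'
#' acoustics/annotation -> motion -> heart rate -> maturity trajectories ->
#' peri-event dynamics -> mixed-model suite. The peri-event stages use
#' `n_rep` bootstrap replicates; `seed` fixes every stochastic step.
#'
#' @param study A `vocomotor_study` (e.g. from [simulate_study()] or
#'   [load_study()]).
#' @param n_rep Bootstrap/scramble replicates.
#' @param seed Integer seed.
#' @param do_perievent Run the peri-event band analyses (the expensive
#'   stage; default TRUE).
#' @return Named list: the [prepare_tables()] tables plus `trajectories`
#'   (per-category `trajectory_fit`s), `transition_days`, `models`
#'   ([fit_suite()] output), and (if requested) `band_locomotor_calls`,
#'   `band_arousal_calls` spline bands; `provenance` records the seed and
#'   replicate count.
#' @export
run_pipeline <- function(study, n_rep = 200, seed = 1L, do_perievent = TRUE) {
  tabs <- prepare_tables(study)
  trajectories <- purrr::map(
    rlang::set_names(c("vocal", "postural", "locomotor")),
    function(cat) {
      pts <- dplyr::filter(tabs$maturity_points, .data$category == cat)
      if (nrow(pts) < 4L) return(NULL)
      fit_trajectory(pts, level = "population")
    })
  transition_days <- purrr::map_dbl(trajectories,
                                    ~ if (is.null(.x)) NA_real_ else .x$transition_day)
  models <- fit_suite(tabs)
  out <- c(tabs, list(trajectories = trajectories,
                      transition_days = transition_days,
                      models = models))
  if (do_perievent) {
    act <- dplyr::rename(tabs$activity, value = "activity")
    calls <- tabs$calls
    out$band_locomotor_calls <- perievent_dynamics(
      act, calls, kind = "locomotor", n_rep = n_rep, seed = seed)
    hr <- tabs$heart_rate
    if (!is.null(hr) && nrow(hr)) {
      hrv <- dplyr::rename(hr, value = "percentile")
      hr_calls <- dplyr::semi_join(calls, dplyr::distinct(hrv, .data$session),
                                   by = "session")
      if (nrow(hr_calls)) {
        out$band_arousal_calls <- perievent_dynamics(
          hrv, hr_calls, kind = "heartrate", n_rep = n_rep, seed = seed + 1L)
      }
    }
  }
  out$provenance <- list(seed = seed, n_rep = n_rep, timestamp = format(Sys.time()),
                         n_sessions = length(study$sessions))
  out
}

#' Write pipeline outputs as CSV/JSON
#'
#' @param results Output of [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) if (!is.null(x) && is.data.frame(x) && nrow(x)) {
    readr::write_csv(x, file.path(dir, f))
  }
  wr(results$calls, "calls.csv")
  wr(results$activity, "activity.csv")
  wr(results$heart_rate, "heart_rate.csv")
  wr(results$maturity_points, "maturity.csv")
  wr(results$classification, "classification.csv")
  wr(results$models, "models.csv")
  wr(results$band_locomotor_calls, "perievent_locomotor.csv")
  wr(results$band_arousal_calls, "perievent_arousal.csv")
  traj <- purrr::imap(results$trajectories, function(f, nm) {
    if (is.null(f)) return(NULL)
    list(category = nm, p = f$p, transition_day = f$transition_day,
         knots = f$spline$knots, values = f$spline$values,
         second_derivs = f$spline$gamma)
  })
  jsonlite::write_json(list(trajectories = traj, provenance = results$provenance),
                       file.path(dir, "trajectories.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
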