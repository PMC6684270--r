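#' Configuration for a synthetic developmental study
#'
#' Defines the study layout and the generative ground truth for a synthetic
#' cohort of infant marmosets observed repeatedly over postnatal days (PND)
#' 1-61 in 10-minute isolation sessions. Defaults reproduce the real study
#' design: 7 subjects with 29, 29, 34, 34, 31, 31, 32 sessions (220 total),
#' audio for 192 and ECG for 149 of them, and immature-to-mature logistic
#' transitions with midpoints at PND 10 (vocal), 19 (postural) and 21
#' (locomotor).
#'
#' Call types follow the logistic maturation schedule: the probability that
#' a call at PND `d` is a phee (rather than a cry) is
#' `plogis(maturation_slope * (d - vocal_midpoint_day))`. Locomotor activity
#' is multiplicatively coupled to ongoing calls
#' (`coupling_locomotor_cry`, `coupling_locomotor_phee`), and instantaneous
#' heart rate is elevated by `arousal_effect_phee` beats/min around phees and
#' `arousal_effect_locomotion` around locomotor events, on top of a slowly
#' fluctuating baseline. Simulated instantaneous rate is clipped to
#' \[180, 570\] beats/min so inter-beat intervals always satisfy the
#' 100-400 ms validation bounds.
#'
#' @param n_subjects Number of subjects.
#' @param sessions_per_subject Integer vector of session counts per subject.
#' @param audio_sessions_per_subject,ecg_sessions_per_subject Number of
#'   sessions per subject with usable audio / ECG.
#' @param pnd_range Postnatal-day span, inclusive.
#' @param session_duration_s Session length, s.
#' @param vocal_midpoint_day,postural_midpoint_day,locomotor_midpoint_day
#'   Logistic maturation midpoints, days.
#' @param maturation_slope Logistic slope, 1/days.
#' @param call_rate Mean call rate, calls/min.
#' @param cry_params,phee_params Lists: `dur_mean`, `dur_sd` (s),
#'   `entropy` (target Wiener entropy level).
#' @param coupling_locomotor_cry,coupling_locomotor_phee Dimensionless
#'   multiplicative effects on raw activity during calls (> -1).
#' @param arousal_effect_phee,arousal_effect_locomotion Heart-rate
#'   elevations, beats/min.
#' @param hr_base_bpm Baseline heart rate, beats/min.
#' @param hr_fluct_sd Slow within-session rate fluctuation sd, beats/min.
#' @param baseline_motion Mean raw luminance difference at rest.
#' @param behavior_rate Postural/locomotor event rate per category,
#'   events/session.
#' @param ecg_fs_hz Native ECG sampling rate, Hz.
#' @param ecg_noise_sd ECG additive noise sd (pulse peak is 1).
#' @param artifact_fraction Fraction of each ECG session masked as artifact.
#' @param rng_seed Integer seed; fixing it fixes every generated artifact.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(n_subjects = 7,
                         sessions_per_subject = c(29, 29, 34, 34, 31, 31, 32),
                         audio_sessions_per_subject = c(28, 29, 21, 20, 31, 31, 32),
                         ecg_sessions_per_subject = c(16, 14, 21, 19, 26, 25, 28),
                         pnd_range = c(1, 61),
                         session_duration_s = 600,
                         vocal_midpoint_day = 10,
                         postural_midpoint_day = 19,
                         locomotor_midpoint_day = 21,
                         maturation_slope = 0.3,
                         call_rate = 5.7,
                         cry_params = list(dur_mean = 0.4, dur_sd = 0.1, entropy = -1.5),
                         phee_params = list(dur_mean = 1.5, dur_sd = 0.4, entropy = -4),
                         coupling_locomotor_cry = 0.5,
                         coupling_locomotor_phee = -0.5,
                         arousal_effect_phee = 30,
                         arousal_effect_locomotion = 20,
                         hr_base_bpm = 400,
                         hr_fluct_sd = 40,
                         baseline_motion = 0.05,
                         behavior_rate = 7,
                         ecg_fs_hz = 40000,
                         ecg_noise_sd = 0.05,
                         artifact_fraction = 0.05,
                         rng_seed = 1L) {
  cfg <- as.list(environment())
  check_pos_count <- function(x, nm) {
    if (!is.numeric(x) || any(x <= 0) || any(x != round(x))) {
      stop("invalid study_config field `", nm, "`: must be positive count(s)")
    }
  }
  check_pos_count(cfg$n_subjects, "n_subjects")
  check_pos_count(cfg$sessions_per_subject, "sessions_per_subject")
  if (length(cfg$sessions_per_subject) != cfg$n_subjects) {
    stop("invalid study_config field `sessions_per_subject`: length must equal n_subjects")
  }
  for (nm in c("audio_sessions_per_subject", "ecg_sessions_per_subject")) {
    if (length(cfg[[nm]]) != cfg$n_subjects || any(cfg[[nm]] < 0) ||
        any(cfg[[nm]] > cfg$sessions_per_subject)) {
      stop("invalid study_config field `", nm,
           "`: per-subject counts must lie in [0, sessions_per_subject]")
    }
  }
  if (cfg$session_duration_s <= 0) {
    stop("invalid study_config field `session_duration_s`: must be > 0")
  }
  for (nm in c("vocal_midpoint_day", "postural_midpoint_day", "locomotor_midpoint_day")) {
    if (cfg[[nm]] < cfg$pnd_range[1] || cfg[[nm]] > cfg$pnd_range[2]) {
      stop("invalid study_config field `", nm, "`: midpoint outside pnd_range")
    }
  }
  if (cfg$artifact_fraction < 0 || cfg$artifact_fraction >= 1) {
    stop("invalid study_config field `artifact_fraction`: must lie in [0, 1)")
  }
  if (cfg$coupling_locomotor_cry <= -1 || cfg$coupling_locomotor_phee <= -1) {
    stop("invalid study_config field `coupling_locomotor_*`: must exceed -1")
  }
  structure(cfg, class = "study_config")
}

# immature/mature behavior pairs per category
behavior_pairs <- function() {
  tibble::tibble(
    category = c("postural", "postural", "locomotor", "locomotor"),
    behavior = c("righting_reflex", "hindlimb_support", "crawling", "walking"),
    maturity = c("immature", "mature", "immature", "mature")
  )
}

#' Simulate a complete synthetic study
#'
#' Generates one session bundle per (subject, session): a call-event table
#' (renewal process, exponential inter-call gaps, type drawn from the
#' logistic maturation schedule), a postural/locomotor behavior log, a raw
#' per-second luminance-difference series coupled to the calls, and true
#' heartbeat times whose instantaneous rate is elevated around phees and
#' locomotor events. Deterministic under the config's `rng_seed`.
#'
#' @param config A [study_config()].
#' @return A list of class `vocomotor_study` with elements `sessions` (list
#'   of session bundles), `ground_truth` (configured transition days,
#'   couplings, per-session beat times), and `config`.
#' @export
simulate_study <- function(config = study_config()) {
  if (!inherits(config, "study_config")) {
    stop("`config` must be a study_config object")
  }
  set.seed(config$rng_seed)
  sessions <- list()
  truth_beats <- list()
  sid <- 0L
  for (i in seq_len(config$n_subjects)) {
    n_i <- config$sessions_per_subject[i]
    pnds <- round(seq(config$pnd_range[1], config$pnd_range[2], length.out = n_i))
    has_audio <- seq_len(n_i) %in% sample(n_i, config$audio_sessions_per_subject[i])
    has_ecg <- seq_len(n_i) %in% sample(n_i, config$ecg_sessions_per_subject[i])
    for (j in seq_len(n_i)) {
      sid <- sid + 1L
      b <- simulate_session(subject = paste0("S", i), pnd = pnds[j],
                            session_id = sprintf("S%d_%03d", i, j),
                            has_audio = has_audio[j], has_ecg = has_ecg[j],
                            config = config)
      sessions[[sid]] <- b
      truth_beats[[b$session_id]] <- b$beat_times
    }
  }
  structure(list(
    sessions = sessions,
    ground_truth = list(
      transition_days = c(vocal = config$vocal_midpoint_day,
                          postural = config$postural_midpoint_day,
                          locomotor = config$locomotor_midpoint_day),
      coupling = c(cry = config$coupling_locomotor_cry,
                   phee = config$coupling_locomotor_phee),
      arousal_effects = c(phee = config$arousal_effect_phee,
                          locomotion = config$arousal_effect_locomotion),
      beat_times = truth_beats
    ),
    config = config
  ), class = "vocomotor_study")
}

# One session: calls, behavior log, motion, true beats.
simulate_session <- function(subject, pnd, session_id, has_audio, has_ecg, config) {
  dur <- config$session_duration_s
  # The logistic schedule governs the expected share of vocal TIME that is
  # phee (maturity indices are time shares). The per-call phee probability
  # is derived from it via the mean durations, so the maturity index
  # crosses 0.5 at the configured midpoint by construction.
  share <- stats::plogis(config$maturation_slope * (pnd - config$vocal_midpoint_day))
  mu_c <- config$cry_params$dur_mean
  mu_p <- config$phee_params$dur_mean
  p_phee <- share * mu_c / (share * mu_c + (1 - share) * mu_p)

  # calls: renewal process with exponential inter-call intervals
  onsets <- offsets <- numeric(0)
  types <- character(0)
  t <- stats::rexp(1, rate = config$call_rate / 60)
  while (t < dur) {
    is_phee <- stats::runif(1) < p_phee
    pars <- if (is_phee) config$phee_params else config$cry_params
    d <- max(0.05, stats::rnorm(1, pars$dur_mean, pars$dur_sd))
    if (t + d >= dur) break
    onsets <- c(onsets, t); offsets <- c(offsets, t + d)
    types <- c(types, if (is_phee) "phee" else "cry")
    t <- t + d + stats::rexp(1, rate = config$call_rate / 60)
  }
  calls <- tibble::tibble(subject = subject, session = session_id, pnd = pnd,
                          onset_s = onsets, offset_s = offsets, call_type = types,
                          wiener_entropy = stats::rnorm(
                            length(types),
                            mean = ifelse(types == "phee",
                                          config$phee_params$entropy,
                                          config$cry_params$entropy),
                            sd = 0.5))

  # postural/locomotor behavior log: logistic immature->mature schedules
  pairs <- behavior_pairs()
  beh <- purrr::map_dfr(c("postural", "locomotor"), function(cat) {
    mid <- if (cat == "postural") config$postural_midpoint_day else config$locomotor_midpoint_day
    p_mat <- stats::plogis(config$maturation_slope * (pnd - mid))
    n_ev <- stats::rpois(1, config$behavior_rate)
    if (n_ev == 0L) return(NULL)
    on <- sort(stats::runif(n_ev, 0, dur - 10))
    d <- stats::rgamma(n_ev, shape = 4, scale = 1.25)  # mean 5 s
    mat <- stats::runif(n_ev) < p_mat
    lab <- pairs$behavior[match(paste(cat, ifelse(mat, "mature", "immature")),
                                paste(pairs$category, pairs$maturity))]
    tibble::tibble(subject = subject, session = session_id, pnd = pnd,
                   category = cat, behavior = lab,
                   onset_s = on, offset_s = pmin(on + d, dur))
  })

  motion_raw <- simulate_motion(calls, config, duration_s = dur)
  # beat times are only consumed for ECG-bearing sessions
  beat_times <- if (has_ecg) simulate_beats(calls, beh, config, duration_s = dur) else numeric(0)

  list(subject = subject, pnd = pnd, session_id = session_id,
       duration_s = dur, calls = calls, behaviors = beh,
       motion_raw = motion_raw, beat_times = beat_times,
       has_audio = has_audio, has_ecg = has_ecg)
}

#' Simulate a raw per-second luminance-difference series
#'
#' Baseline lognormal activity, multiplicatively scaled by
#' `1 + coupling_locomotor_cry` during seconds overlapping cries and
#' `1 + coupling_locomotor_phee` during phees. Values are nonnegative; zero
#' coupling makes the series independent of call timing.
#'
#' @param call_events Tibble with `onset_s`, `offset_s`, `call_type`.
#' @param config A [study_config()].
#' @param duration_s Session length, s.
#' @return Tibble `t_s` (1 Hz bin centers), `raw`.
#' @export
simulate_motion <- function(call_events, config, duration_s = config$session_duration_s) {
  n <- floor(duration_s)
  t_s <- seq_len(n) - 0.5
  raw <- config$baseline_motion * stats::rlnorm(n, meanlog = -0.125, sdlog = 0.5)
  if (nrow(call_events)) {
    for (k in seq_len(nrow(call_events))) {
      cpl <- if (call_events$call_type[k] == "cry") {
        config$coupling_locomotor_cry
      } else {
        config$coupling_locomotor_phee
      }
      hit <- t_s >= call_events$onset_s[k] - 0.5 & t_s < call_events$offset_s[k] + 0.5
      raw[hit] <- raw[hit] * (1 + cpl)
    }
  }
  tibble::tibble(t_s = t_s, raw = raw)
}

# True heartbeat times: slowly fluctuating baseline rate plus event-locked
# elevations, integrated as an inhomogeneous renewal process.
simulate_beats <- function(calls, behaviors, config, duration_s) {
  grid <- seq(0, duration_s, by = 0.25)
  knots <- seq(0, duration_s, by = 10)
  slow <- stats::spline(knots, stats::rnorm(length(knots), 0, config$hr_fluct_sd),
                        xout = grid, method = "natural")$y
  r <- config$hr_base_bpm + slow
  bump <- function(r, on, off, amp) {
    # smooth elevation spanning the event plus a ramp of +-3 s
    hit <- grid >= on - 3 & grid <= off + 3
    r[hit] <- r[hit] + amp
    r
  }
  if (nrow(calls)) {
    for (k in which(calls$call_type == "phee")) {
      r <- bump(r, calls$onset_s[k], calls$offset_s[k], config$arousal_effect_phee)
    }
  }
  loco <- if (!is.null(behaviors) && nrow(behaviors) &&
              "category" %in% names(behaviors)) {
    behaviors[behaviors$category == "locomotor", ]
  }
  if (!is.null(loco) && nrow(loco)) {
    for (k in seq_len(nrow(loco))) {
      r <- bump(r, loco$onset_s[k], loco$offset_s[k], config$arousal_effect_locomotion)
    }
  }
  r <- pmin(pmax(r, 180), 570)   # keeps every ISI inside the 100-400 ms bounds
  beats <- numeric(ceiling(duration_s * 10))
  t <- stats::runif(1, 0, 0.15)
  nb <- 0L
  while (t < duration_s) {
    nb <- nb + 1L
    beats[nb] <- t
    t <- t + 60 / r[min(length(r), floor(t / 0.25) + 1L)]
  }
  beats[seq_len(nb)]
}

#' Synthesize a raw ECG recording from beat times
#'
#' Places one stereotyped biphasic pulse (~20 ms wide, one full sine cycle,
#' peak amplitude 1) at each beat time, adds white noise, and zeroes/flags
#' masked regions. The second channel carries the same pulses attenuated to
#' 0.3 with 1.5x noise, emulating the poorer electrode pair, so channel
#' selection has a right answer.
#'
#' @param beat_times Strictly increasing beat times, s.
#' @param duration_s Recording length, s.
#' @param fs Sampling rate, Hz.
#' @param noise_sd Additive noise sd.
#' @param artifact_mask Tibble `onset_s`, `offset_s` of masked intervals.
#' @param seed Optional integer seed for the noise.
#' @return An [ecg_recording()].
#' @export
simulate_ecg <- function(beat_times, duration_s, fs = 40000, noise_sd = 0.05,
                         artifact_mask = NULL, seed = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) && (is.unsorted(beat_times, strictly = TRUE))) {
    stop("beat times must be strictly increasing")
  }
  if (length(beat_times) && (min(beat_times) < 0 || max(beat_times) > duration_s)) {
    stop("beat times must lie within [0, duration_s]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration_s * fs)
  width_s <- 0.02
  tmpl_t <- seq(0, width_s, by = 1 / fs)
  # biphasic with a dominant positive lobe (like an R-S complex), peak 1
  tmpl <- sin(2 * pi * tmpl_t / width_s) * (1 - 0.6 * tmpl_t / width_s)
  tmpl <- tmpl / max(abs(tmpl))
  pulses <- numeric(n)
  for (b in beat_times) {
    i0 <- round((b - width_s / 2) * fs) + 1L
    idx <- seq(i0, i0 + length(tmpl) - 1L)
    ok <- idx >= 1L & idx <= n
    pulses[idx[ok]] <- pulses[idx[ok]] + tmpl[ok]
  }
  ch1 <- pulses + stats::rnorm(n, 0, noise_sd)
  ch2 <- 0.3 * pulses + stats::rnorm(n, 0, 1.5 * noise_sd)
  if (is.null(artifact_mask)) {
    artifact_mask <- tibble::tibble(onset_s = numeric(0), offset_s = numeric(0))
  }
  bad <- mask_to_logical(artifact_mask, n, fs)
  ch1[bad] <- 0; ch2[bad] <- 0
  ecg_recording(list(ch1, ch2), fs = fs, mask = artifact_mask)
}

#' Draw random artifact intervals covering a given fraction of a session
#'
#' @param duration_s Session length, s.
#' @param fraction Total masked fraction in \[0, 1).
#' @param n_intervals Number of masked intervals.
#' @return Tibble `onset_s`, `offset_s` (non-overlapping).
#' @export
random_artifact_mask <- function(duration_s, fraction, n_intervals = 3) {
  if (fraction <= 0) return(tibble::tibble(onset_s = numeric(0), offset_s = numeric(0)))
  len <- fraction * duration_s / n_intervals
  slot <- duration_s / n_intervals
  on <- (seq_len(n_intervals) - 1) * slot +
    stats::runif(n_intervals, 0, slot - len)
  tibble::tibble(onset_s = on, offset_s = on + len)
}

#' @export
print.vocomotor_study <- function(x, ...) {
  cat("<vocomotor_study> ", length(x$sessions), " sessions, ",
      x$config$n_subjects, " subjects, PND ",
      x$config$pnd_range[1], "-", x$config$pnd_range[2], "\n", sep = "")
  invisible(x)
}

#' Session-level summary of a synthetic or loaded study
#'
#' @param study A `vocomotor_study`.
#' @return Tibble with one row per session: subject, pnd, session_id, call
#'   and behavior counts, modality flags.
#' @export
study_manifest <- function(study) {
  purrr::map_dfr(study$sessions, function(b) {
    tibble::tibble(subject = b$subject, pnd = b$pnd, session_id = b$session_id,
                   duration_s = b$duration_s,
                   n_calls = nrow(b$calls),
                   n_behaviors = if (is.null(b$behaviors)) 0L else nrow(b$behaviors),
                   has_audio = b$has_audio, has_ecg = b$has_ecg)
  })
}
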