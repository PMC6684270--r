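test_that("default config reproduces the study layout", {
  st <- tiny_study()
  man <- study_manifest(st)
  expect_equal(nrow(man), 24)
  expect_equal(as.numeric(table(man$subject)), c(8, 8, 8))
  expect_true(all(man$pnd >= 1 & man$pnd <= 61))
  expect_true(all(man$duration_s == 600))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(study_config(n_subjects = 0), "n_subjects")
  expect_error(study_config(sessions_per_subject = c(5, 5)), "sessions_per_subject")
  expect_error(study_config(vocal_midpoint_day = 99), "vocal_midpoint_day")
  expect_error(study_config(artifact_fraction = 1.2), "artifact_fraction")
  expect_error(study_config(audio_sessions_per_subject = rep(99, 7)),
               "audio_sessions_per_subject")
  expect_error(simulate_study(list()), "study_config")
})

test_that("a fixed seed makes the whole study reproducible bit-exactly", {
  a <- simulate_study(tiny_config(seed = 99L))
  b <- simulate_study(tiny_config(seed = 99L))
  expect_identical(purrr::map_dfr(a$sessions, "calls"),
                   purrr::map_dfr(b$sessions, "calls"))
  expect_identical(purrr::map_dfr(a$sessions, "motion_raw"),
                   purrr::map_dfr(b$sessions, "motion_raw"))
  expect_identical(a$ground_truth$beat_times, b$ground_truth$beat_times)
})

test_that("an infinitely steep maturation schedule is a step function", {
  cfg <- study_config(n_subjects = 1, sessions_per_subject = 6,
                      audio_sessions_per_subject = 6, ecg_sessions_per_subject = 0,
                      maturation_slope = 1e6, vocal_midpoint_day = 30,
                      rng_seed = 5L)
  st <- simulate_study(cfg)
  calls <- purrr::map_dfr(st$sessions, "calls")
  expect_true(all(calls$call_type[calls$pnd < 30] == "cry"))
  expect_true(all(calls$call_type[calls$pnd > 30] == "phee"))
})

test_that("phee time share rises through 0.5 near the configured midpoint", {
  cfg <- study_config(n_subjects = 1, sessions_per_subject = 61,
                      audio_sessions_per_subject = 61, ecg_sessions_per_subject = 0,
                      rng_seed = 6L)
  st <- simulate_study(cfg)
  share <- purrr::map_dfr(st$sessions, function(b) {
    d <- b$calls$offset_s - b$calls$onset_s
    tibble::tibble(pnd = b$pnd,
                   share = sum(d[b$calls$call_type == "phee"]) / sum(d))
  })
  # smooth the session shares and find the 0.5 crossing
  f <- fit_spline(share$pnd, share$share, p = 0.01)
  grid <- seq(1, 61, by = 0.1)
  cross <- grid[which(predict(f, grid) >= 0.5)[1]]
  expect_lt(abs(cross - cfg$vocal_midpoint_day), 2)
  # monotone in expectation: early third below late third
  expect_lt(mean(share$share[share$pnd <= 20]), mean(share$share[share$pnd >= 40]))
})

test_that("simulated inter-beat intervals respect the 100-400 ms validation bounds", {
  st <- tiny_study()
  for (b in st$sessions[purrr::map_lgl(st$sessions, "has_ecg")][1:6]) {
    isi <- diff(b$beat_times)
    expect_true(all(isi > 0.100 & isi < 0.400))
  }
})

test_that("motion coupling raises activity during cries relative to baseline", {
  cfg <- study_config(rng_seed = 8L)
  set.seed(8)
  calls <- tibble::tibble(onset_s = seq(5, 560, by = 5),
                          offset_s = seq(5, 560, by = 5) + 1.2,
                          call_type = "cry")   # > 100 calls
  m <- simulate_motion(calls, cfg)
  during <- m$raw[sapply(m$t_s, function(t) any(t >= calls$onset_s - 0.5 & t < calls$offset_s + 0.5))]
  expect_gt(mean(during), mean(m$raw))

  # zero coupling: no association with call timing
  cfg0 <- study_config(coupling_locomotor_cry = 0, coupling_locomotor_phee = 0)
  set.seed(9)
  m0 <- simulate_motion(calls, cfg0)
  during0 <- m0$raw[sapply(m0$t_s, function(t) any(t >= calls$onset_s & t < calls$offset_s))]
  expect_lt(abs(mean(during0) - mean(m0$raw)) / stats::sd(m0$raw), 0.35)

  # zero baseline, no events: all-zero series
  cfg_z <- study_config(baseline_motion = 0)
  expect_equal(simulate_motion(calls[0, ], cfg_z)$raw, rep(0, 600))
})

test_that("synthetic ECG places one pulse per beat and honors masks", {
  bt <- seq(0.25, 9.75, by = 0.25)
  rec <- simulate_ecg(bt, 10, fs = 40000, noise_sd = 0, seed = 1)
  expect_s3_class(rec, "ecg_recording")
  x <- rec$channels[[1]]
  # noiseless: detected beats after decimation coincide with simulated ones
  sp <- detect_beats(preprocess_ecg(rec, channel = 1))
  m <- match_beats(sp, bt)
  expect_equal(unname(m["recall"]), 1)
  expect_equal(length(sp), length(bt))

  # empty beat list: flat noise
  rec0 <- simulate_ecg(numeric(0), 2, fs = 40000, noise_sd = 0.1, seed = 2)
  expect_lt(max(abs(rec0$channels[[1]])), 1)
  expect_error(simulate_ecg(c(1, 20), 10), "within")
  expect_error(simulate_ecg(c(2, 1), 10), "increasing")

  mask <- tibble::tibble(onset_s = 2, offset_s = 4)
  recm <- simulate_ecg(bt, 10, fs = 40000, noise_sd = 0.1, artifact_mask = mask, seed = 3)
  t_n <- (seq_along(recm$channels[[1]]) - 1) / 40000
  expect_true(all(recm$channels[[1]][t_n >= 2 & t_n < 4] == 0))
})
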