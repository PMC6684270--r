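test_that("select_channel prefers the spiky cardiac channel and breaks ties low", {
  set.seed(1)
  n <- 40000 * 2
  pulses <- numeric(n)
  pulses[seq(1000, n, by = 10000)] <- 1
  clean <- pulses + stats::rnorm(n, 0, 0.02)
  noise <- stats::rnorm(n, 0, 0.2)
  expect_equal(as.integer(select_channel(ecg_recording(list(clean, noise)))), 1L)
  expect_equal(as.integer(select_channel(ecg_recording(list(noise, clean)))), 2L)
  expect_equal(as.integer(select_channel(ecg_recording(list(noise, noise)))), 1L)
  full_mask <- tibble::tibble(onset_s = 0, offset_s = 2)
  expect_error(select_channel(ecg_recording(list(clean, noise), mask = full_mask)),
               "fully masked")
})

test_that("preprocessing attenuates drift and line noise but passes the QRS band", {
  fs <- 40000
  t <- seq(0, 4, by = 1 / fs)[-1]
  gain_db <- function(freq) {
    rec <- ecg_recording(list(sin(2 * pi * freq * t), stats::rnorm(length(t), 0, 1e-6)))
    y <- preprocess_ecg(rec, channel = 1)
    mid <- y[abs(attr(y, "fs") * 2 - seq_along(y)) < 1500]  # interior second
    20 * log10(stats::sd(mid, na.rm = TRUE) / stats::sd(sin(2 * pi * freq * t)))
  }
  expect_lt(gain_db(5), -20)    # baseline wander removed
  expect_lt(gain_db(60), -20)   # line noise notched
  expect_gt(gain_db(120), -3)   # cardiac band preserved
})

test_that("masked regions propagate as NaN without leaking into valid data", {
  fs <- 40000
  t <- seq(0, 3, by = 1 / fs)[-1]
  mask <- tibble::tibble(onset_s = 1.0, offset_s = 1.5)
  rec <- ecg_recording(list(sin(2 * pi * 100 * t), stats::rnorm(length(t), 0, 1e-6)),
                       mask = mask)
  y <- preprocess_ecg(rec, channel = 1)
  fs_out <- attr(y, "fs")
  t_out <- (seq_along(y) - 1) / fs_out
  expect_true(all(is.nan(y[t_out > 1.01 & t_out < 1.49])))
  expect_true(all(is.finite(y[t_out > 0.2 & t_out < 0.9])))
  expect_true(all(is.finite(y[t_out > 1.6 & t_out < 2.9])))
})

test_that("detect_beats finds noiseless pulses exactly and nothing in silence", {
  fs <- 1500
  dur <- 5
  true_t <- seq(0.25, dur - 0.25, by = 0.25)      # 4 Hz train
  x <- numeric(dur * fs)
  tmpl_t <- seq(0, 0.02, by = 1 / fs)
  tmpl <- sin(2 * pi * tmpl_t / 0.02) * (1 - 0.6 * tmpl_t / 0.02)
  for (b in true_t) {
    i <- round((b - 0.01) * fs) + 1
    x[i:(i + length(tmpl) - 1)] <- tmpl
  }
  sp <- detect_beats(x, fs)
  expect_equal(length(sp), length(true_t))
  peak_off <- (which.max(abs(tmpl)) - 1) / fs    # spike lands on the |max| sample
  expect_true(all(abs(sp - (true_t - 0.01 + peak_off)) <= 1.5 / fs))
  expect_equal(length(detect_beats(numeric(3000), fs)), 0)
})

test_that("beat detection at 10:1 pulse-to-noise recovers >= 99% of beats", {
  set.seed(33)
  bt <- cumsum(stats::runif(200, 0.15, 0.35))  # spans the whole recording
  bt <- bt[bt < 40 - 0.1]
  rec <- simulate_ecg(bt, 40, fs = 40000, noise_sd = 0.1, seed = 34)
  x <- preprocess_ecg(rec)
  sp <- detect_beats(x)
  m <- match_beats(sp, bt)   # pulse |peak| sits within ~5 ms of the beat time
  expect_gte(m["recall"], 0.99)
  expect_gte(m["precision"], 0.99)
})

test_that("interval correction applies the midpoint and gap rules", {
  out <- correct_intervals(c(1.00, 1.05, 1.30))
  expect_equal(out$beat_times, c(1.025, 1.30))
  out2 <- correct_intervals(c(1.0, 1.6))
  expect_equal(out2$beat_times, c(1.0, 1.6))
  expect_equal(nrow(out2$invalid_intervals), 1)
  expect_equal(out2$invalid_intervals$onset_s, 1.0)
  # after correction no valid consecutive interval is out of bounds
  set.seed(14)
  for (i in 1:25) {
    t <- cumsum(stats::runif(60, 0.02, 0.6))
    b <- correct_intervals(t)
    isi <- diff(b$beat_times)
    inv <- b$invalid_intervals
    valid <- !sapply(seq_along(isi), function(k) {
      any(inv$onset_s <= b$beat_times[k] & inv$offset_s >= b$beat_times[k + 1])
    })
    expect_true(all(isi[valid] >= 0.100 - 1e-12 & isi[valid] <= 0.400 + 1e-12))
  }
})

test_that("interval correction matches the exhaustive oracle on random trains", {
  set.seed(15)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    t <- cumsum(stats::runif(n, 0.02, 0.55))
    got <- correct_intervals(t)
    want <- oracle_isi(t)
    expect_equal(got$beat_times, want$beat_times, tolerance = 1e-12)
    expect_equal(nrow(got$invalid_intervals), nrow(want$invalid))
  }
})

test_that("rate_from_beats reproduces a constant-rate train and the kernel-sum oracle", {
  bt <- seq(0.25, 59.75, by = 0.25)
  hr <- rate_from_beats(bt, 60)
  interior <- hr$bpm[hr$t_s > 2 & hr$t_s < 58]
  expect_true(all(abs(interior - 240) < 0.5))

  expect_equal(rate_from_beats(numeric(0), 30)$bpm, rep(0, 30))

  set.seed(16)
  bt2 <- sort(stats::runif(200, 0, 60))
  hr2 <- rate_from_beats(structure(list(beat_times = bt2,
                                        invalid_intervals = tibble::tibble(
                                          onset_s = numeric(0), offset_s = numeric(0))),
                                   class = "beat_series"), 60)
  pick <- sample(which(hr2$t_s > 1 & hr2$t_s < 59), 50)
  want <- oracle_rate(bt2, 60, hr2$t_s[pick])
  expect_equal(hr2$bpm[pick], want, tolerance = 1e-9)
})

test_that("rate estimation commutes with time translation away from edges", {
  set.seed(17)
  bt <- sort(stats::runif(120, 5, 55))
  h1 <- rate_from_beats(bt, 70)
  h2 <- rate_from_beats(bt + 7, 70)
  a <- h1$bpm[h1$t_s > 6 & h1$t_s < 54]
  b <- h2$bpm[h2$t_s > 13 & h2$t_s < 61]
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("coverage rule is inclusive at exactly 50%", {
  mk <- function(ndef, n = 600) tibble::tibble(t_s = seq_len(n) - 0.5,
                                               bpm = c(rep(300, ndef), rep(NaN, n - ndef)))
  expect_false(coverage_ok(mk(299)))
  expect_true(coverage_ok(mk(300)))
  expect_false(coverage_ok(mk(0)))
  expect_equal(attr(coverage_ok(mk(300)), "coverage"), 0.5)
})

test_that("percentile transform matches the rank oracle and its conventions", {
  set.seed(18)
  hr <- tibble::tibble(t_s = seq_len(600) - 0.5,
                       bpm = stats::runif(600, 200, 500))
  out <- hr_percentiles(hr)
  expect_equal(out$percentile, oracle_percentile(hr$bpm), tolerance = 1e-9)
  expect_equal(min(out$percentile), 0)
  expect_equal(max(out$percentile), 100)
  # strictly increasing series: percentile of sample k ~ 100 k / n
  inc <- tibble::tibble(t_s = seq_len(600) - 0.5, bpm = seq(200, 500, length.out = 600))
  pct <- hr_percentiles(inc)$percentile
  expect_equal(pct, 100 * (0:599) / 599, tolerance = 1e-9)
  # ties: constant series maps to 50
  const <- tibble::tibble(t_s = seq_len(600) - 0.5, bpm = rep(321, 600))
  expect_equal(unique(hr_percentiles(const)$percentile), 50)
  # invariance under strictly monotone transforms
  mono <- dplyr::mutate(hr, bpm = exp(bpm / 100))
  expect_equal(hr_percentiles(mono)$percentile, out$percentile, tolerance = 1e-9)
  # NaN preserved, coverage enforced
  hr$bpm[1:400] <- NaN
  expect_error(hr_percentiles(hr), "exclude")
})
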