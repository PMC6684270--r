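#' Construct a two-channel ECG recording
#'
#' Lightweight container for one session's raw surface ECG: two channels
#' sampled at a common (native 40 kHz) rate, plus artifact masks — half-open
#' `[onset_s, offset_s)` intervals in which the signal is invalid (motion
#' artifacts, signal loss). Masks may be shared or per channel.
#'
#' @param channels Numeric matrix (samples x 2) or list of two equal-length
#'   numeric vectors.
#' @param fs Sampling rate, Hz (native acquisition rate 40000).
#' @param mask Data frame with `onset_s`, `offset_s` applied to both
#'   channels, or a list of two such data frames (one per channel).
#' @param subject,session,pnd Optional metadata carried through.
#' @return An object of class `ecg_recording`.
#' @export
ecg_recording <- function(channels, fs = 40000, mask = NULL,
                          subject = NA, session = NA, pnd = NA) {
  if (is.matrix(channels)) channels <- list(channels[, 1], channels[, 2])
  stopifnot(length(channels) == 2L,
            length(channels[[1]]) == length(channels[[2]]))
  empty_mask <- tibble::tibble(onset_s = numeric(0), offset_s = numeric(0))
  if (is.null(mask)) mask <- empty_mask
  if (is.data.frame(mask)) mask <- list(mask, mask)
  mask <- purrr::map(mask, tibble::as_tibble)
  dur <- length(channels[[1]]) / fs
  for (m in mask) {
    if (nrow(m) && (any(m$onset_s < 0) || any(m$offset_s > dur + 1e-9) ||
                    any(m$offset_s <= m$onset_s))) {
      stop("mask intervals must be half-open [onset, offset) within the recording")
    }
  }
  structure(list(channels = channels, fs = fs, mask = mask,
                 duration_s = dur, subject = subject, session = session,
                 pnd = pnd),
            class = "ecg_recording")
}

mask_to_logical <- function(mask, n, fs) {
  bad <- logical(n)
  if (nrow(mask)) {
    for (k in seq_len(nrow(mask))) {
      i0 <- max(1L, floor(mask$onset_s[k] * fs) + 1L)
      i1 <- min(n, ceiling(mask$offset_s[k] * fs))
      if (i1 >= i0) bad[i0:i1] <- TRUE
    }
  }
  bad
}

#' Choose the ECG channel with the better signal-to-noise proxy
#'
#' Electrode contact varies with movement, so signal quality differs between
#' the dorsal and ventral electrode pairs session by session. The proxy is
#' the ratio of the 95th percentile to the median of the absolute amplitude,
#' computed on the extent valid in both channels (a spiky cardiac signal has
#' a heavy-tailed amplitude distribution, pure noise does not). Ties go to
#' the first channel.
#'
#' @param rec An [ecg_recording()].
#' @return Integer channel index (1 or 2) with attribute `snr_proxy`.
#' @export
select_channel <- function(rec) {
  stopifnot(inherits(rec, "ecg_recording"))
  n <- length(rec$channels[[1]])
  bad <- mask_to_logical(rec$mask[[1]], n, rec$fs) |
    mask_to_logical(rec$mask[[2]], n, rec$fs)
  if (all(bad)) stop("both ECG channels fully masked; no valid extent")
  proxy <- purrr::map_dbl(rec$channels, function(x) {
    a <- abs(x[!bad])
    med <- stats::median(a)
    if (med == 0) med <- .Machine$double.eps
    stats::quantile(a, 0.95, names = FALSE) / med
  })
  ch <- which.max(proxy)  # which.max returns the first maximum: tie -> lowest
  structure(as.integer(ch), snr_proxy = proxy)
}

# RBJ biquad notch, zero-phase via filtfilt
notch_coefs <- function(freq, fs, Q = 30) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Preprocess one ECG channel for beat detection
#'
#' Anti-aliased resampling from the native 40 kHz to 1500 Hz, zero-phase
#' 4th-order Butterworth high-pass at 15 Hz (preserves the rapid heartbeat
#' waveform while removing baseline wander), and a zero-phase 60 Hz IIR
#' notch (Q = 30) for line noise. Masked regions propagate as `NaN`; each
#' contiguous valid segment is filtered independently so artifacts never
#' leak across gaps. Segments too short to filter (< 0.1 s) become `NaN`.
#'
#' @param rec An [ecg_recording()] with `fs = 40000` (use
#'   `allow_any_fs = TRUE` to override for already-decimated test signals).
#' @param channel Channel index (default: [select_channel()]).
#' @param target_fs Output rate, Hz (default 1500).
#' @param highpass_hz,notch_hz Filter frequencies (defaults 15, 60).
#' @param allow_any_fs Skip the native-rate check.
#' @return Numeric vector at `target_fs` with `NaN` in masked regions;
#'   attributes `fs` and `channel`.
#' @export
preprocess_ecg <- function(rec, channel = NULL, target_fs = 1500,
                           highpass_hz = 15, notch_hz = 60,
                           allow_any_fs = FALSE) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (rec$fs != 40000 && !allow_any_fs) {
    stop("native sampling rate is ", rec$fs,
         " Hz, expected 40000 (set allow_any_fs = TRUE to override)")
  }
  if (is.null(channel)) channel <- select_channel(rec)
  x <- rec$channels[[channel]]
  n <- length(x)
  bad <- mask_to_logical(rec$mask[[channel]], n, rec$fs)
  x[bad] <- NA_real_

  n_out <- floor(rec$duration_s * target_fs)
  t_out <- (seq_len(n_out) - 1) / target_fs
  out <- rep(NaN, n_out)

  # anti-alias + decimate each valid segment, then high-pass and notch at 1500 Hz
  lp <- if (rec$fs > 2 * target_fs) {
    signal::butter(4, (0.4 * target_fs) / (rec$fs / 2), type = "low")
  } else NULL
  hp <- signal::butter(4, highpass_hz / (target_fs / 2), type = "high")
  nf <- notch_coefs(notch_hz, target_fs)

  runs <- rle(!is.na(x))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if ((i1 - i0 + 1L) / rec$fs < 0.1) next
    seg <- x[i0:i1]
    if (!is.null(lp)) seg <- signal::filtfilt(lp, seg)
    t_seg <- (seq(i0, i1) - 1) / rec$fs
    j <- which(t_out >= t_seg[1] & t_out <= t_seg[length(t_seg)])
    if (length(j) < ceiling(0.1 * target_fs)) next
    y <- stats::approx(t_seg, seg, xout = t_out[j])$y
    y <- signal::filtfilt(hp, y)
    y <- signal::filtfilt(signal::Arma(b = nf$b, a = nf$a), y)
    out[j] <- y
  }
  attr(out, "fs") <- target_fs
  attr(out, "channel") <- as.integer(channel)
  out
}

#' Detect candidate heartbeat spikes with a per-second adaptive threshold
#'
#' Within every 1 s window, the threshold is the 95th percentile of the
#' signal amplitude in that window; samples strictly above their window's
#' threshold form candidate regions, and one spike per contiguous region is
#' reported at the maximum of the absolute filtered signal. "Amplitude" is a
#' short RMS envelope by default (`envelope_s` = 10 ms), which suppresses
#' isolated noise maxima; set `amplitude = "abs"` for the raw absolute value.
#' Regions closer than `min_sep_s` are merged before peak picking. `NaN`
#' windows yield no spikes.
#'
#' @param x Filtered waveform (from [preprocess_ecg()]).
#' @param fs Sampling rate, Hz (default from `x`'s attribute, else 1500).
#' @param amplitude `"envelope"` (default) or `"abs"`.
#' @param envelope_s RMS envelope window, s.
#' @param min_sep_s Candidate regions closer than this merge, s.
#' @return Numeric vector of spike times (s), strictly increasing.
#' @export
detect_beats <- function(x, fs = attr(x, "fs") %||% 1500,
                         amplitude = c("envelope", "abs"),
                         envelope_s = 0.01, min_sep_s = 0.02) {
  amplitude <- match.arg(amplitude)
  n <- length(x)
  if (n == 0L) stop("empty signal")
  amp <- if (amplitude == "envelope") {
    k <- max(1L, round(envelope_s * fs))
    e <- stats::filter(ifelse(is.na(x), 0, x)^2, rep(1 / k, k), sides = 2)
    e[is.na(e)] <- 0
    e <- sqrt(as.numeric(e))
    e[is.na(x)] <- NA_real_
    e
  } else {
    abs(x)
  }
  win <- pmin(floor(((seq_len(n) - 1) / fs)), ceiling(n / fs) - 1)  # 1 s windows
  thr_by_win <- tapply(amp, win, function(a) {
    if (all(is.na(a))) Inf else stats::quantile(a, 0.95, na.rm = TRUE, names = FALSE)
  })
  thr <- as.numeric(thr_by_win)[win + 1L]
  supra <- !is.na(amp) & amp > thr
  if (!any(supra)) return(numeric(0))
  runs <- rle(supra)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  on <- starts[runs$values]; off <- ends[runs$values]
  # merge regions separated by short sub-threshold gaps (biphasic waveforms)
  if (length(on) > 1L) {
    gap <- (on[-1] - off[-length(off)]) / fs
    grp <- cumsum(c(1, gap >= min_sep_s))
    on <- as.numeric(tapply(on, grp, min))
    off <- as.numeric(tapply(off, grp, max))
  }
  times <- purrr::map2_dbl(on, off, function(a, b) {
    seg <- abs(x[a:b])
    (a + which.max(seg) - 2) / fs
  })
  sort(times)
}

#' Validate inter-spike intervals against physiological bounds
#'
#' Marmoset heart rate lies between 150 and 600 beats/min, i.e. inter-beat
#' intervals between 100 and 400 ms. If an inter-spike interval is below
#' 100 ms the two spikes are replaced with a single spike at their midpoint
#' (applied iteratively left-to-right, re-checking after each merge, until
#' no short interval remains). If an interval exceeds 400 ms the interval is
#' marked invalid: heart rate is undefined (`NaN`) there.
#'
#' @param spike_times Sorted spike times, s.
#' @param min_isi_s,max_isi_s Bounds, s (defaults 0.100 and 0.400).
#' @return A list of class `beat_series`: `beat_times` (strictly increasing)
#'   and `invalid_intervals` (tibble `onset_s`, `offset_s`).
#' @export
correct_intervals <- function(spike_times, min_isi_s = 0.100, max_isi_s = 0.400) {
  t <- sort(as.numeric(spike_times))
  i <- 1L
  while (i < length(t)) {
    if (t[i + 1L] - t[i] < min_isi_s) {
      t[i] <- (t[i] + t[i + 1L]) / 2
      t <- t[-(i + 1L)]
      i <- max(i - 1L, 1L)     # the merged spike may now crowd its left neighbor
    } else {
      i <- i + 1L
    }
  }
  isi <- diff(t)
  long <- which(isi > max_isi_s)
  structure(list(
    beat_times = t,
    invalid_intervals = tibble::tibble(onset_s = t[long], offset_s = t[long + 1L])
  ), class = "beat_series")
}

#' Inter-spike interval to heart rate
#'
#' @param isi_s Interval, s.
#' @return Rate in beats/min (`60 / isi_s`).
#' @export
isi_to_bpm <- function(isi_s) 60 / isi_s

#' @rdname isi_to_bpm
#' @param bpm Rate, beats/min.
#' @export
bpm_to_isi <- function(bpm) 60 / bpm

#' 1 Hz heart rate from validated beats
#'
#' Builds a binary beat-count series at `fs` (default 1500 Hz), convolves it
#' with a unit-area Gaussian kernel of 1 s nominal width (sigma = 1/6 s, so
#' +-3 sigma spans 1 s), scales to beats/min and samples at the 1 Hz bin
#' centers (0.5, 1.5, ... s). `NaN` inside invalid intervals, including
#' leading/trailing gaps longer than the maximum valid interval when at
#' least one beat exists. The convolution is evaluated only at the output
#' grid, which is exact for a truncated kernel.
#'
#' @param beats A `beat_series` from [correct_intervals()], or a numeric
#'   vector of beat times (no invalid intervals).
#' @param session_duration_s Session length, s.
#' @param fs Rate of the intermediate binary series, Hz.
#' @param sigma_s Gaussian kernel sigma, s.
#' @return Tibble `t_s`, `bpm` of length `floor(session_duration_s)`.
#' @export
rate_from_beats <- function(beats, session_duration_s, fs = 1500, sigma_s = 1 / 6) {
  if (!inherits(beats, "beat_series")) {
    beats <- structure(list(beat_times = sort(as.numeric(beats)),
                            invalid_intervals = tibble::tibble(onset_s = numeric(0),
                                                               offset_s = numeric(0))),
                       class = "beat_series")
  }
  bt <- beats$beat_times
  if (length(bt) && (min(bt) < 0 || max(bt) > session_duration_s)) {
    stop("beat times must lie within [0, session_duration_s]")
  }
  t_out <- seq(0.5, by = 1, length.out = floor(session_duration_s))
  bpm <- rep(0, length(t_out))
  if (length(bt)) {
    W <- ceiling(4 * sigma_s * fs)
    kern <- stats::dnorm(seq(-W, W) / fs, sd = sigma_s)
    kern <- kern / (sum(kern) / fs)            # unit area on the discrete grid
    b_idx <- round(bt * fs)                    # beat -> nearest binary sample
    o_idx <- round(t_out * fs)
    # each beat reaches at most the output bins within W samples; with 1 Hz
    # output and W < fs that is the neighboring bin centers only
    reach <- ceiling(W / fs)
    acc <- numeric(length(t_out))
    base <- floor(bt) + 1L                     # output bin holding the beat
    for (o in seq(-reach, reach)) {
      j <- base + o
      ok <- j >= 1L & j <= length(t_out)
      if (!any(ok)) next
      d <- o_idx[j[ok]] - b_idx[ok]
      inside <- abs(d) <= W
      if (!any(inside)) next
      contrib <- rowsum(kern[d[inside] + W + 1L], j[ok][inside])
      at <- as.integer(rownames(contrib))
      acc[at] <- acc[at] + contrib[, 1L]
    }
    bpm <- 60 * acc
    inv <- beats$invalid_intervals
    lead <- tibble::tibble(onset_s = numeric(0), offset_s = numeric(0))
    if (min(bt) > 0.4) lead <- dplyr::add_row(lead, onset_s = 0, offset_s = min(bt))
    if (session_duration_s - max(bt) > 0.4) {
      lead <- dplyr::add_row(lead, onset_s = max(bt), offset_s = session_duration_s)
    }
    inv <- dplyr::bind_rows(inv, lead)
    if (nrow(inv)) {
      for (k in seq_len(nrow(inv))) {
        bpm[t_out >= inv$onset_s[k] & t_out < inv$offset_s[k]] <- NaN
      }
    }
  }
  tibble::tibble(t_s = t_out, bpm = bpm)
}

#' Does a heart-rate series cover enough of the session?
#'
#' Sessions are usable only when heart rate is defined at least 50% of the
#' time (inclusive).
#'
#' @param hr Tibble with a `bpm` column.
#' @param min_coverage Minimum defined fraction (default 0.5).
#' @return Logical; attribute `coverage` holds the fraction.
#' @export
coverage_ok <- function(hr, min_coverage = 0.5) {
  cov <- mean(is.finite(hr$bpm))
  structure(cov >= min_coverage, coverage = cov)
}

#' Within-session heart-rate percentiles (arousal index)
#'
#' Heart rate differs across individuals and ages, so each session's defined
#' 1 Hz values are rescaled to percentiles within that session: 0 = the
#' session's lowest rate, 100 = its highest, ties get mid-ranks (a constant
#' series maps to 50 everywhere). `NaN` samples stay `NaN`. Errors if the
#' session fails the coverage rule, directing the caller to exclude it.
#'
#' @param hr Tibble with `t_s`, `bpm`.
#' @param check_coverage Enforce the 50% rule (default TRUE).
#' @return The input with a `percentile` column in \[0, 100\].
#' @export
hr_percentiles <- function(hr, check_coverage = TRUE) {
  if (check_coverage && !coverage_ok(hr)) {
    stop("heart rate defined < 50% of the session; exclude this session")
  }
  v <- hr$bpm
  ok <- is.finite(v)
  pct <- rep(NaN, length(v))
  n <- sum(ok)
  if (n == 1L) {
    pct[ok] <- 50
  } else if (n > 1L) {
    pct[ok] <- 100 * (rank(v[ok], ties.method = "average") - 1) / (n - 1)
  }
  dplyr::mutate(hr, percentile = pct)
}

#' Run the full ECG chain for one session
#'
#' Channel selection, preprocessing, adaptive beat detection, inter-beat
#' interval validation, Gaussian-kernel heart rate and within-session
#' percentiles.
#'
#' @param rec An [ecg_recording()].
#' @param ... Passed to [preprocess_ecg()].
#' @return Tibble `t_s`, `bpm`, `percentile` with attributes `channel`,
#'   `coverage`, `n_beats`; if the session fails the coverage rule, the
#'   `percentile` column is `NaN` and attribute `coverage_ok` is `FALSE`.
#' @export
process_ecg <- function(rec, ...) {
  ch <- select_channel(rec)
  x <- preprocess_ecg(rec, channel = ch, ...)
  spikes <- detect_beats(x)
  beats <- correct_intervals(spikes)
  hr <- rate_from_beats(beats, session_duration_s = rec$duration_s)
  cov <- coverage_ok(hr)
  hr <- if (cov) hr_percentiles(hr) else dplyr::mutate(hr, percentile = NaN)
  attr(hr, "channel") <- as.integer(ch)
  attr(hr, "coverage") <- attr(cov, "coverage")
  attr(hr, "coverage_ok") <- isTRUE(cov)
  attr(hr, "n_beats") <- length(beats$beat_times)
  hr
}
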