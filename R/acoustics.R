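#' Power spectrum of an audio segment
#'
#' Single-taper periodogram with a Hann window over the whole segment. The DC
#' bin is excluded (offsets are acquisition artifacts); only positive
#' frequencies up to Nyquist are returned.
#'
#' @param segment Numeric waveform samples (length >= 2).
#' @param fs Sampling rate in Hz.
#' @return A tibble with columns `frequency` (Hz) and `power` (nonnegative).
#' @export
power_spectrum <- function(segment, fs) {
  if (length(segment) < 2L) stop("audio segment must have at least 2 samples")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be a positive sampling rate")
  n <- length(segment)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1L))  # Hann, no zero endpoints
  xw <- segment * win
  sp <- Mod(stats::fft(xw))^2 / (sum(win^2) * fs)
  nyq <- floor(n / 2)
  idx <- seq(2L, nyq + 1L)  # drop DC; keep positive freqs through Nyquist
  tibble::tibble(
    frequency = (idx - 1L) * fs / n,
    power = sp[idx]
  )
}

#' Wiener entropy (spectral flatness) of a power spectrum
#'
#' The natural logarithm of the ratio of the geometric to the arithmetic mean
#' of the power values. Always nonpositive, equal to zero only for a flat
#' spectrum, strongly negative for tonal sounds. Zero bins are floored at
#' machine epsilon times the maximum power before the geometric mean so that
#' pure synthetic tones yield a finite (very negative) value rather than
#' `-Inf`; set `floor_zeros = FALSE` to get the `-Inf` sentinel instead.
#'
#' @param spectrum A data frame with a `power` column (as from
#'   [power_spectrum()]) or a bare numeric vector of nonnegative powers.
#' @param floor_zeros Replace zero bins with `eps * max(power)` (default TRUE).
#' @return A single nonpositive number (natural-log scale).
#' @examples
#' wiener_entropy(c(4, 1))  # log(2 / 2.5)
#' @export
wiener_entropy <- function(spectrum, floor_zeros = TRUE) {
  power <- if (is.data.frame(spectrum)) spectrum$power else as.numeric(spectrum)
  if (length(power) < 2L) stop("need at least 2 spectral bins")
  if (any(!is.finite(power)) || any(power < 0)) {
    stop("power values must be finite and nonnegative")
  }
  if (all(power == 0)) stop("all-zero spectrum: Wiener entropy undefined")
  if (floor_zeros) {
    power <- pmax(power, .Machine$double.eps * max(power))
  } else if (any(power == 0)) {
    return(-Inf)
  }
  # log geometric mean = mean(log); guard against overflow by scale invariance
  min(mean(log(power)) - log(mean(power)), 0)
}

#' Annotate a call table with acoustic features
#'
#' For each call event, computes the duration and the Wiener entropy of the
#' waveform over the half-open interval \[onset, offset). Events that fall
#' outside the audio extent are kept but flagged (`feature_ok = FALSE`) with
#' `NA` entropy; processing continues.
#'
#' @param events Data frame with columns `onset_s`, `offset_s` (seconds from
#'   recording start), plus any identifier columns, which are preserved.
#' @param audio Numeric waveform.
#' @param fs Sampling rate in Hz.
#' @return The input as a tibble with added columns `duration_s`,
#'   `wiener_entropy`, `entropy_log_base` (always "natural"), `feature_ok`.
#' @export
annotate_calls <- function(events, audio, fs) {
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0L) {
    return(dplyr::mutate(events,
      duration_s = numeric(0), wiener_entropy = numeric(0),
      entropy_log_base = character(0), feature_ok = logical(0)))
  }
  stopifnot(all(c("onset_s", "offset_s") %in% names(events)))
  if (any(events$offset_s <= events$onset_s)) {
    stop("call events must satisfy offset_s > onset_s")
  }
  n <- length(audio)
  feats <- purrr::pmap(list(events$onset_s, events$offset_s), function(on, off) {
    i0 <- floor(on * fs) + 1L
    i1 <- ceiling(off * fs)  # half-open [onset, offset)
    if (i0 < 1L || i1 > n || i1 - i0 < 1L) {
      return(list(we = NA_real_, ok = FALSE))
    }
    seg <- audio[i0:min(i1, n)]
    we <- tryCatch(wiener_entropy(power_spectrum(seg, fs)),
                   error = function(e) NA_real_)
    list(we = we, ok = is.finite(we))
  })
  dplyr::mutate(events,
    duration_s = .data$offset_s - .data$onset_s,
    wiener_entropy = purrr::map_dbl(feats, "we"),
    entropy_log_base = "natural",
    feature_ok = purrr::map_lgl(feats, "ok"))
}

#' Segment candidate calls from a waveform by amplitude envelope
#'
#' A convenience detector: maximal runs of the smoothed RMS envelope above a
#' dB threshold (relative to the session median envelope), closed over gaps
#' shorter than `min_gap_s`, discarded if shorter than `min_dur_s`. The
#' pipeline's canonical input is a provided, verified call table; this
#' function exists for exploratory use on raw audio.
#'
#' @param audio Numeric waveform (nonempty).
#' @param fs Sampling rate, Hz.
#' @param threshold_db Envelope threshold in dB above the median envelope.
#' @param min_gap_s Gaps shorter than this are bridged (s).
#' @param min_dur_s Events shorter than this are dropped (s).
#' @param smooth_s RMS smoothing window (s).
#' @return Tibble with `onset_s`, `offset_s` (half-open intervals, seconds).
#' @export
segment_calls <- function(audio, fs, threshold_db = 20, min_gap_s = 0.05,
                          min_dur_s = 0.05, smooth_s = 0.01) {
  if (length(audio) == 0L) stop("audio must be nonempty")
  k <- max(1L, round(smooth_s * fs))
  env <- sqrt(stats::filter(audio^2, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  ref <- stats::median(env[env > 0])
  if (!isTRUE(ref > 0)) {
    return(tibble::tibble(onset_s = numeric(0), offset_s = numeric(0)))
  }
  above <- as.numeric(env) > ref * 10^(threshold_db / 20)
  runs <- rle(above)
  # bridge short gaps between active runs
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gap <- !runs$values & runs$lengths < min_gap_s * fs
  interior <- seq_along(runs$values) > 1 & seq_along(runs$values) < length(runs$values)
  above[unlist(purrr::map2(starts[gap & interior], ends[gap & interior], seq))] <- TRUE
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_dur_s * fs
  tibble::tibble(
    onset_s = (starts[keep] - 1L) / fs,
    offset_s = ends[keep] / fs
  )
}
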