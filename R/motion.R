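#' Per-second luminance difference from video frames
#'
#' For every second of video, takes the sum of absolute RGB differences
#' between the first and last frame of that second and divides by the number
#' of pixels, giving the average luminance difference per pixel per second.
#' By default channels are summed and the divisor is the pixel count (not
#' pixels x channels); set `per_channel = TRUE` to divide by pixels x channels
#' instead — the convention used is recorded in the `normalization` attribute.
#'
#' @param first_frames,last_frames Lists of numeric arrays (height x width or
#'   height x width x channels), one pair per second, all sharing dimensions.
#' @param per_channel Divide by pixel x channel count instead of pixel count.
#' @return Tibble with `t_s` (1 Hz bin centers: 0.5, 1.5, ...) and `raw`
#'   (nonnegative mean absolute difference).
#' @export
frame_difference <- function(first_frames, last_frames, per_channel = FALSE) {
  if (length(first_frames) != length(last_frames)) {
    stop("need one (first, last) frame pair per second")
  }
  dims <- unique(c(purrr::map(first_frames, dim), purrr::map(last_frames, dim)))
  if (length(dims) > 1L) stop("all frames must share dimensions")
  raw <- purrr::map2_dbl(first_frames, last_frames, function(a, b) {
    d <- dim(a)
    npix <- d[1] * d[2]
    if (per_channel && length(d) >= 3L) npix <- npix * d[3]
    sum(abs(a - b)) / npix
  })
  out <- tibble::tibble(t_s = seq_along(raw) - 0.5, raw = raw)
  attr(out, "normalization") <- if (per_channel) "pixels_x_channels" else "pixels"
  out
}

#' Binarize raw activity at the session 90th percentile
#'
#' Values strictly above the session's own 90th percentile (linear
#' interpolation between order statistics, `stats::quantile` type 7) become
#' 1, all others 0. The threshold is per session, never global, so the index
#' is comparable across individuals and ages; a constant series binarizes to
#' all zeros (the threshold equals every value and the comparison is strict).
#'
#' @param raw Numeric vector of nonnegative per-second values (length >= 10).
#' @param probs Threshold percentile (default 0.9).
#' @return Integer vector of 0/1 of the same length.
#' @export
binarize_activity <- function(raw, probs = 0.9) {
  if (length(raw) < 10L) stop("need at least 10 values to binarize")
  thr <- stats::quantile(raw, probs = probs, na.rm = TRUE, names = FALSE, type = 7)
  as.integer(raw > thr)
}

#' Smooth a binary activity series into a [0, 1] activity index
#'
#' Fits the penalized cubic smoothing spline ([fit_spline()], smoothing
#' parameter 0.10 by default) to the binary series on its 1 Hz grid and
#' clamps the result to \[0, 1\] (splines through binary data can overshoot).
#'
#' @param binary Numeric/integer 0-1 vector (>= 4 non-NA values).
#' @param p Smoothing parameter (default 0.10).
#' @param t_s Optional time grid (default 1 Hz bin centers).
#' @return Numeric activity values in \[0, 1\] on `t_s`.
#' @export
smooth_activity <- function(binary, p = 0.10, t_s = seq_along(binary) - 0.5) {
  ok <- !is.na(binary)
  if (sum(ok) < 4L) stop("need at least 4 non-NA values to smooth")
  fit <- fit_spline(t_s[ok], as.numeric(binary[ok]), p = p)
  pmin(pmax(predict(fit, t_s), 0), 1)
}

#' Full locomotor-activity pipeline for one session
#'
#' raw luminance differences -> per-session 90th-percentile binarization ->
#' spline smoothing, returning all three stages.
#'
#' @param motion Data frame with `t_s` and `raw` columns (1 Hz), or a bare
#'   numeric vector of raw values.
#' @param p Spline smoothing parameter (default 0.10).
#' @return Tibble with `t_s`, `raw`, `binary`, `activity` (in \[0, 1\]).
#' @export
activity_series <- function(motion, p = 0.10) {
  if (!is.data.frame(motion)) {
    motion <- tibble::tibble(t_s = seq_along(motion) - 0.5, raw = as.numeric(motion))
  }
  motion <- tibble::as_tibble(motion)
  stopifnot(all(c("t_s", "raw") %in% names(motion)))
  if (any(motion$raw < 0, na.rm = TRUE)) stop("raw activity must be nonnegative")
  bin <- binarize_activity(motion$raw)
  dplyr::mutate(motion,
    binary = bin,
    activity = smooth_activity(bin, p = p, t_s = motion$t_s))
}

#' Plot a locomotor-activity series
#'
#' @param object A tibble from [activity_series()].
#' @export
plot_activity <- function(object) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_s)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$binary), width = 1,
                      fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$activity), linewidth = 0.8) +
    ggplot2::labs(x = "time in session (s)", y = "locomotor activity [0, 1]") +
    ggplot2::theme_minimal()
}
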