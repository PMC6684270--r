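#' Peri-event window bounds by signal kind
#'
#' Locomotor activity is extracted from -20 to +5 s around call onsets and
#' -5 to +20 s around offsets; heart-rate percentiles from -10 to +5 s
#' around onsets and -5 to +10 s around offsets.
#'
#' @param kind `"locomotor"` or `"heartrate"`.
#' @return List with `onset` and `offset` windows (2-vectors, s).
#' @export
perievent_windows <- function(kind = c("locomotor", "heartrate")) {
  kind <- match.arg(kind)
  if (kind == "locomotor") {
    list(onset = c(-20, 5), offset = c(-5, 20))
  } else {
    list(onset = c(-10, 5), offset = c(-5, 10))
  }
}

# value of a 1 Hz series (bin centers 0.5, 1.5, ...) at absolute times;
# NA outside the session
sample_1hz <- function(values, times) {
  bin <- floor(times) + 1L
  out <- rep(NA_real_, length(times))
  ok <- !is.na(bin) & bin >= 1L & bin <= length(values)
  out[ok] <- values[bin[ok]]
  out
}

#' Extract peri-event traces from a 1 Hz signal
#'
#' Two traces per event: one anchored at the onset, one at the offset, with
#' the window bounds of the signal kind. Windows are clipped at session
#' edges (`NA`-padded).
#'
#' @param signal Tibble with `t_s` and a `value` column (or the column named
#'   in `value_col`), at 1 Hz bin centers.
#' @param events Tibble with `onset_s`, `offset_s`.
#' @param kind `"locomotor"` or `"heartrate"`.
#' @param value_col Name of the signal column (default `"value"`).
#' @return Tibble `event`, `anchor` (`"onset"`/`"offset"`), `rel_t`, `value`.
#' @export
extract_windows <- function(signal, events, kind = c("locomotor", "heartrate"),
                            value_col = "value") {
  kind <- match.arg(kind)
  win <- perievent_windows(kind)
  v <- signal[[value_col]]
  if (nrow(events) == 0L) {
    return(tibble::tibble(event = integer(0), anchor = character(0),
                          rel_t = numeric(0), value = numeric(0)))
  }
  purrr::map_dfr(c("onset", "offset"), function(a) {
    rel <- seq(win[[a]][1], win[[a]][2])
    anchor_t <- if (a == "onset") events$onset_s else events$offset_s
    tibble::tibble(
      event = rep(seq_along(anchor_t), each = length(rel)),
      anchor = a,
      rel_t = rep(rel, times = length(anchor_t)),
      value = sample_1hz(v, rep(anchor_t, each = length(rel)) + rel)
    )
  })
}

#' Stitch onset- and offset-anchored traces onto one display axis
#'
#' Builds the -W..+W axis used for call-centered figures: times at or before
#' the call (rel_t <= 0) come from the onset-anchored trace, times after the
#' call (rel_t > 0) from the offset-anchored trace; the call interior is
#' excluded from band statistics.
#'
#' @param traces Output of [extract_windows()] (both anchors present).
#' @param half_width Display half-axis, s (defaults to the largest pre-onset
#'   extent present).
#' @return Tibble `event`, `rel_t`, `value`, `segment` (`"pre"`/`"post"`).
#' @export
stitch_call_axis <- function(traces, half_width = NULL) {
  if (!all(c("onset", "offset") %in% unique(traces$anchor))) {
    stop("stitching needs paired onset- and offset-anchored traces")
  }
  if (is.null(half_width)) half_width <- -min(traces$rel_t)
  pre <- dplyr::filter(traces, .data$anchor == "onset",
                       .data$rel_t >= -half_width, .data$rel_t <= 0)
  post <- dplyr::filter(traces, .data$anchor == "offset",
                        .data$rel_t > 0, .data$rel_t <= half_width)
  if (!setequal(unique(pre$event), unique(post$event))) {
    stop("unpaired traces: every event needs both anchors")
  }
  dplyr::bind_rows(
    dplyr::mutate(dplyr::select(pre, -"anchor"), segment = "pre"),
    dplyr::mutate(dplyr::select(post, -"anchor"), segment = "post")
  ) |>
    dplyr::arrange(.data$event, .data$rel_t)
}

#' Session and population splines over peri-event traces
#'
#' The session spline (smoothing parameter 0.1) is fit to all of a session's
#' trace points pooled on the relative-time grid; the population spline
#' (smoothing parameter 0.3) is fit to all session splines evaluated on the
#' common grid.
#'
#' @param traces Tibble `rel_t`, `value` (one session's stitched traces).
#' @param p Smoothing parameter.
#' @return A `csaps_spline`.
#' @export
session_spline <- function(traces, p = 0.1) {
  fit_spline(traces$rel_t, traces$value, p = p)
}

#' @rdname session_spline
#' @param session_splines List of `csaps_spline`s, one per session.
#' @param grid Common evaluation grid.
#' @export
population_spline <- function(session_splines, grid, p = 0.3) {
  vals <- purrr::map(session_splines, predict, newdata = grid)
  fit_spline(rep(grid, length(vals)), unlist(vals), p = p)
}

# --- fast fixed-grid engine used by the resampling loops ------------------
# Weighted csaps on a fixed grid via a cached smoother matrix; pooling n
# points at one site equals a weight-n fit at that site.
smoother_cache <- new.env(parent = emptyenv())

csaps_grid_fit <- function(grid, ybar, w, p) {
  ok <- is.finite(ybar) & w > 0
  if (sum(ok) == length(grid) && length(unique(w)) == 1L) {
    key <- paste0(length(grid), "_", grid[1], "_", grid[length(grid)], "_",
                  p, "_", w[1])
    S <- smoother_cache[[key]]
    if (is.null(S)) {
      S <- csaps_smoother(grid, p, rep(w[1], length(grid)))
      smoother_cache[[key]] <- S
    }
    return(as.numeric(S %*% ybar))
  }
  if (sum(ok) < 4L) return(rep(NA_real_, length(grid)))
  fit <- fit_spline(grid[ok], ybar[ok], p = p, w = w[ok])
  predict(fit, grid)
}

# stitched window means per session: returns ybar/w on grid -W..W
stitched_means <- function(values, onsets, offsets, half_width) {
  rel_pre <- seq(-half_width, 0)
  rel_post <- seq(1, half_width)
  n <- length(values)
  take <- function(anchors, rel) {
    bin <- outer(rel, anchors, `+`)           # rel x events, absolute times
    bin <- floor(bin) + 1L
    m <- matrix(NA_real_, nrow(bin), ncol(bin))
    ok <- bin >= 1L & bin <= n
    m[ok] <- values[bin[ok]]
    m
  }
  M <- rbind(take(onsets, rel_pre), take(offsets, rel_post))
  w <- rowSums(!is.na(M))
  ybar <- ifelse(w > 0, rowMeans(M, na.rm = TRUE), NA_real_)
  list(grid = c(rel_pre, rel_post), ybar = ybar, w = w)
}

#' Scramble one session's event timing
#'
#' Independently permutes the sequence of event durations and the sequence
#' of inter-event gaps (the gap before the first event counts as a gap) and
#' reassembles a pseudo-timeline from the session start. The number and
#' lengths of events — and hence total occupied time — are preserved; only
#' their timing is destroyed. With a single event and a single gap there are
#' at most two distinct layouts (here exactly one: the original).
#'
#' @param onsets,offsets Sorted event bounds, s (half-open intervals).
#' @return List `onset_s`, `offset_s` of the pseudo-events.
#' @export
scramble_events <- function(onsets, offsets) {
  d <- offsets - onsets
  gaps <- c(onsets[1], onsets[-1] - offsets[-length(offsets)])
  if (length(d) > 1L) d <- sample(d)
  if (length(gaps) > 1L) gaps <- sample(gaps)
  new_on <- cumsum(gaps) + cumsum(c(0, d[-length(d)]))
  list(onset_s = new_on, offset_s = new_on + d)
}

#' Event-aligned population dynamics with bootstrap CI and scramble null
#'
#' The central real-time analysis: per-event signal windows are stitched
#' onto a call-centered axis, summarized by per-session splines (smoothing
#' parameter `p_session`) and one population spline (`p_pop`). The 95%
#' confidence band resamples `k_per_session` traces per session with
#' replacement, refits the population spline, and takes pointwise
#' 2.5th/97.5th percentiles across `n_rep` replicates. The null band
#' scrambles each session's event timing (independently permuting call
#' durations and inter-call gaps, preserving number and lengths while
#' destroying timing), refits, and takes the same percentiles. Grid points
#' where the observed spline leaves the null band are flagged.
#'
#' @param signal Tibble `session`, `t_s`, `value` (1 Hz).
#' @param events Tibble `session`, `onset_s`, `offset_s`.
#' @param kind `"locomotor"` or `"heartrate"` (sets window bounds).
#' @param n_rep Bootstrap replicates for each band.
#' @param k_per_session Traces resampled per session for the CI.
#' @param seed Integer seed; fixing it fixes both bands bit-exactly.
#' @param p_session,p_pop Session/population smoothing parameters.
#' @return A tibble of class `spline_band`: `rel_t`, `observed`, `ci_lo`,
#'   `ci_hi`, `null_lo`, `null_hi`, `flag` (`"above"`/`"below"`/`"inside"`).
#' @export
perievent_dynamics <- function(signal, events, kind = c("locomotor", "heartrate"),
                               n_rep = 1000, k_per_session = 10, seed = 1L,
                               p_session = 0.1, p_pop = 0.3) {
  kind <- match.arg(kind)
  half_width <- -perievent_windows(kind)$onset[1]
  sessions <- intersect(unique(signal$session), unique(events$session))
  sig_by <- split(signal$value, signal$session)
  ev_by <- split(events[c("onset_s", "offset_s")], events$session)
  sessions <- sessions[purrr::map_int(ev_by[sessions], nrow) > 0]
  if (length(sessions) == 0L) stop("no session has both signal and events")
  grid <- seq(-half_width, half_width)

  set.seed(seed)
  # observed
  sess_fit <- function(values, on, off) {
    sm <- stitched_means(values, on, off, half_width)
    csaps_grid_fit(sm$grid, sm$ybar, sm$w, p_session)
  }
  obs_sess <- purrr::map(sessions, function(s) {
    sess_fit(sig_by[[s]], ev_by[[s]]$onset_s, ev_by[[s]]$offset_s)
  })
  pop_fit <- function(sess_vals) {
    M <- do.call(rbind, sess_vals)
    w <- colSums(is.finite(M))
    ybar <- ifelse(w > 0, colMeans(M, na.rm = TRUE), NA_real_)
    csaps_grid_fit(grid, ybar, w, p_pop)
  }
  observed <- pop_fit(obs_sess)

  # confidence band: resample k traces per session with replacement
  trace_mats <- purrr::map(sessions, function(s) {
    on <- ev_by[[s]]$onset_s; off <- ev_by[[s]]$offset_s
    v <- sig_by[[s]]; n <- length(v)
    per_event <- function(k) {
      t_abs <- c(on[k] + seq(-half_width, 0), off[k] + seq(1, half_width))
      sample_1hz(v, t_abs)
    }
    do.call(cbind, purrr::map(seq_along(on), per_event))  # grid x events
  })
  ci_rep <- matrix(NA_real_, n_rep, length(grid))
  for (r in seq_len(n_rep)) {
    sess_vals <- purrr::map(trace_mats, function(M) {
      pick <- sample.int(ncol(M), k_per_session, replace = TRUE)
      Mk <- M[, pick, drop = FALSE]
      w <- rowSums(!is.na(Mk))
      ybar <- ifelse(w > 0, rowMeans(Mk, na.rm = TRUE), NA_real_)
      csaps_grid_fit(grid, ybar, w, p_session)
    })
    ci_rep[r, ] <- pop_fit(sess_vals)
  }

  # scramble null: permute durations and gaps within each session
  null_rep <- matrix(NA_real_, n_rep, length(grid))
  for (r in seq_len(n_rep)) {
    sess_vals <- purrr::map(sessions, function(s) {
      sc <- scramble_events(ev_by[[s]]$onset_s, ev_by[[s]]$offset_s)
      sess_fit(sig_by[[s]], sc$onset_s, sc$offset_s)
    })
    null_rep[r, ] <- pop_fit(sess_vals)
  }

  band <- tibble::tibble(
    rel_t = grid,
    observed = observed,
    ci_lo = apply(ci_rep, 2, stats::quantile, 0.025, na.rm = TRUE),
    ci_hi = apply(ci_rep, 2, stats::quantile, 0.975, na.rm = TRUE),
    null_lo = apply(null_rep, 2, stats::quantile, 0.025, na.rm = TRUE),
    null_hi = apply(null_rep, 2, stats::quantile, 0.975, na.rm = TRUE)
  )
  band$flag <- exceedance(band$observed, band$null_lo, band$null_hi)$flag
  class(band) <- c("spline_band", class(band))
  attr(band, "kind") <- kind
  attr(band, "n_rep") <- n_rep
  attr(band, "seed") <- seed
  band
}

#' Developmental curve of a per-event quantity with CI and scramble null
#'
#' Each event contributes its window-average signal value; session means are
#' computed per session and a spline over postnatal day (smoothing parameter
#' 0.0001) models the population change. The CI resamples `k_per_session`
#' per-event values per session; the null scrambles event timing before
#' averaging.
#'
#' @param signal Tibble `session`, `t_s`, `value`.
#' @param events Tibble `session`, `pnd`, `onset_s`, `offset_s`.
#' @param n_rep,k_per_session,seed As in [perievent_dynamics()].
#' @param p Developmental smoothing parameter (default 0.0001).
#' @return A `spline_band` tibble over `pnd`; empty (zero rows, attribute
#'   `status = "no_sessions"`) when no session has both signal and events.
#' @export
developmental_curve <- function(signal, events, n_rep = 1000,
                                k_per_session = 10, seed = 1L, p = 1e-4) {
  sessions <- intersect(unique(signal$session), unique(events$session))
  ev_by <- split(events, events$session)
  sig_by <- split(signal$value, signal$session)
  sessions <- sessions[purrr::map_int(ev_by[sessions], nrow) > 0]
  if (length(sessions) == 0L) {
    out <- tibble::tibble(pnd = numeric(0), observed = numeric(0),
                          ci_lo = numeric(0), ci_hi = numeric(0),
                          null_lo = numeric(0), null_hi = numeric(0),
                          flag = character(0))
    class(out) <- c("spline_band", class(out))
    attr(out, "status") <- "no_sessions"
    return(out)
  }
  set.seed(seed)
  event_means <- function(values, on, off) {
    purrr::map2_dbl(on, off, function(a, b) {
      mean(sample_1hz(values, seq(floor(a) + 0.5, floor(b) + 0.5)), na.rm = TRUE)
    })
  }
  per_sess <- purrr::map(sessions, function(s) {
    ev <- ev_by[[s]]
    list(pnd = ev$pnd[1],
         vals = event_means(sig_by[[s]], ev$onset_s, ev$offset_s),
         on = ev$onset_s, off = ev$offset_s)
  })
  pnd <- purrr::map_dbl(per_sess, "pnd")
  grid <- seq(min(pnd), max(pnd))
  fit_curve <- function(sess_means) {
    ok <- is.finite(sess_means)
    if (sum(ok) < 4L) return(rep(NA_real_, length(grid)))
    predict(fit_spline(pnd[ok], sess_means[ok], p = p), grid)
  }
  observed <- fit_curve(purrr::map_dbl(per_sess, ~ mean(.x$vals, na.rm = TRUE)))

  ci_rep <- matrix(NA_real_, n_rep, length(grid))
  for (r in seq_len(n_rep)) {
    m <- purrr::map_dbl(per_sess, function(ps) {
      mean(ps$vals[sample.int(length(ps$vals), k_per_session, replace = TRUE)],
           na.rm = TRUE)
    })
    ci_rep[r, ] <- fit_curve(m)
  }
  null_rep <- matrix(NA_real_, n_rep, length(grid))
  for (r in seq_len(n_rep)) {
    m <- purrr::map2_dbl(per_sess, sessions, function(ps, s) {
      sc <- scramble_events(ps$on, ps$off)
      mean(event_means(sig_by[[s]], sc$onset_s, sc$offset_s), na.rm = TRUE)
    })
    null_rep[r, ] <- fit_curve(m)
  }
  band <- tibble::tibble(
    pnd = grid,
    observed = observed,
    ci_lo = apply(ci_rep, 2, stats::quantile, 0.025, na.rm = TRUE),
    ci_hi = apply(ci_rep, 2, stats::quantile, 0.975, na.rm = TRUE),
    null_lo = apply(null_rep, 2, stats::quantile, 0.025, na.rm = TRUE),
    null_hi = apply(null_rep, 2, stats::quantile, 0.975, na.rm = TRUE)
  )
  band$flag <- exceedance(band$observed, band$null_lo, band$null_hi)$flag
  class(band) <- c("spline_band", class(band))
  attr(band, "n_rep") <- n_rep
  attr(band, "seed") <- seed
  band
}

#' Flag where an observed curve leaves a null band
#'
#' @param observed,null_lo,null_hi Aligned numeric vectors.
#' @return List: `flag` (per-point `"above"`/`"below"`/`"inside"`, `NA`
#'   where undefined) and `runs` (tibble of contiguous above/below runs with
#'   start/end indices).
#' @export
exceedance <- function(observed, null_lo, null_hi) {
  if (length(observed) != length(null_lo) || length(observed) != length(null_hi)) {
    stop("grids of observed and null bands must align")
  }
  flag <- dplyr::case_when(
    !is.finite(observed) | !is.finite(null_lo) | !is.finite(null_hi) ~ NA_character_,
    observed > null_hi ~ "above",
    observed < null_lo ~ "below",
    TRUE ~ "inside"
  )
  r <- rle(ifelse(is.na(flag), "na", flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("above", "below")
  list(flag = flag,
       runs = tibble::tibble(flag = r$values[keep],
                             start = starts[keep], end = ends[keep]))
}

#' Plot a spline band (observed curve, CI, scramble-null band)
#'
#' @param object A `spline_band` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spline_band <- function(object, ...) {
  xvar <- if ("rel_t" %in% names(object)) "rel_t" else "pnd"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$null_lo, ymax = .data$null_hi),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), linewidth = 0.9) +
    ggplot2::geom_point(data = dplyr::filter(object, .data$flag != "inside"),
                        ggplot2::aes(y = .data$observed), colour = "firebrick",
                        size = 1.2) +
    ggplot2::labs(x = if (xvar == "rel_t") "time from event (s)" else "postnatal day",
                  y = "signal") +
    ggplot2::theme_minimal()
}
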