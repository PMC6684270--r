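#' Per-session behavior proportions within each motor category
#'
#' For every session and category (vocal, postural, locomotor), each
#' behavior's total duration is divided by the category's total scored
#' duration in that session. Overlapping events of the same category are
#' summed per behavior without de-overlapping (the scored logs treat each
#' instance as its own bout); sessions with zero time in a category
#' contribute no rows for it.
#'
#' @param events Tibble with `subject`, `pnd`, `session`, `category`,
#'   `behavior`, `onset_s`, `offset_s` (half-open). Call tables can be
#'   mapped in with `category = "vocal"`, `behavior = call_type`.
#' @return Tibble of `subject`, `pnd`, `session`, `category`, `behavior`,
#'   `proportion` (in \[0, 1\], summing to 1 per session x category).
#' @export
category_proportions <- function(events) {
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0L) {
    return(tibble::tibble(subject = character(0), pnd = numeric(0),
                          session = character(0), category = character(0),
                          behavior = character(0), proportion = numeric(0)))
  }
  if (any(events$offset_s <= events$onset_s)) {
    stop("events must have half-open intervals with offset_s > onset_s")
  }
  events |>
    dplyr::mutate(dur = .data$offset_s - .data$onset_s) |>
    dplyr::group_by(.data$subject, .data$pnd, .data$session, .data$category,
                    .data$behavior) |>
    dplyr::summarise(time_s = sum(.data$dur), .groups = "drop_last") |>
    dplyr::mutate(proportion = .data$time_s / sum(.data$time_s)) |>
    dplyr::ungroup() |>
    dplyr::select(-"time_s")
}

#' Classify behaviors as immature or mature from developmental trends
#'
#' A behavior is mature if its share of category time increases with
#' postnatal day and immature if it decreases, judged by the fixed-effect
#' day slope of a linear mixed model `proportion ~ day + (day | subject)`
#' with Holm-adjusted p-values within each category (alpha 0.05); behaviors
#' with no reliable trend are `NA`.
#'
#' @param props Output of [category_proportions()].
#' @param alpha Familywise significance level (default 0.05).
#' @return Tibble `category`, `behavior`, `beta_day`, `p_raw`, `p_adj`,
#'   `classification` in `{immature, mature, NA}`.
#' @export
classify_behaviors <- function(props, alpha = 0.05) {
  fits <- props |>
    dplyr::group_by(.data$category, .data$behavior) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(res = purrr::map(.data$data, function(d) {
      if (dplyr::n_distinct(d$subject) < 2L || nrow(d) < 8L) {
        return(tibble::tibble(beta_day = NA_real_, p_raw = NA_real_))
      }
      fit <- fit_mixed_model(
        model_spec("trend", proportion ~ pnd + (pnd | subject), family = "gaussian",
                   fallbacks = list(. ~ . - (pnd | subject) + (1 | subject))),
        d)
      row <- dplyr::filter(fit, .data$term == "pnd")
      tibble::tibble(beta_day = row$beta, p_raw = row$p_raw)
    })) |>
    dplyr::select(-"data") |>
    tidyr::unnest("res")
  fits |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(p_adj = holm_adjust(.data$p_raw)) |>
    dplyr::ungroup() |>
    dplyr::mutate(classification = dplyr::case_when(
      is.na(.data$p_adj) | .data$p_adj >= alpha ~ NA_character_,
      .data$beta_day > 0 ~ "mature",
      .data$beta_day < 0 ~ "immature",
      TRUE ~ NA_character_
    ))
}

#' Maturity index
#'
#' The fraction of time in mature behavior relative to all immature plus
#' mature behavior, `m / (m + im)`. Below 0.5 the individual produced more
#' immature behavior; above 0.5 more mature behavior. Undefined (error) when
#' both times are zero; rescaling both times by a common factor leaves the
#' index unchanged.
#'
#' @param m_time,im_time Nonnegative times (s) in mature / immature behavior.
#' @return Value(s) in \[0, 1\].
#' @export
maturity_index <- function(m_time, im_time) {
  if (any(m_time < 0) || any(im_time < 0)) stop("times must be nonnegative")
  tot <- m_time + im_time
  if (any(tot == 0)) stop("maturity index undefined when m_time + im_time == 0; skip the session")
  m_time / tot
}

#' Per-session maturity points for every category
#'
#' Sums mature and immature time per session and category using a
#' classification table, and computes the maturity index. Sessions with zero
#' classified time in a category contribute no point.
#'
#' @param events Event tibble as for [category_proportions()].
#' @param classification Tibble `behavior`, `classification` (from
#'   [classify_behaviors()] or ground truth); behaviors classified `NA` are
#'   ignored.
#' @return Tibble `subject`, `pnd`, `session`, `category`, `m_time`,
#'   `im_time`, `index`.
#' @export
maturity_points <- function(events, classification) {
  cls <- dplyr::select(tibble::as_tibble(classification), "behavior", "classification")
  events |>
    tibble::as_tibble() |>
    dplyr::inner_join(cls, by = "behavior") |>
    dplyr::filter(!is.na(.data$classification)) |>
    dplyr::mutate(dur = .data$offset_s - .data$onset_s) |>
    dplyr::group_by(.data$subject, .data$pnd, .data$session, .data$category) |>
    dplyr::summarise(
      m_time = sum(.data$dur[.data$classification == "mature"]),
      im_time = sum(.data$dur[.data$classification == "immature"]),
      .groups = "drop") |>
    dplyr::filter(.data$m_time + .data$im_time > 0) |>
    dplyr::mutate(index = maturity_index(.data$m_time, .data$im_time))
}

#' Fit a developmental maturity trajectory
#'
#' Penalized cubic smoothing spline of maturity index over postnatal day:
#' smoothing parameter 0.03 for individual-level fits, 0.01 for the
#' population fit (which pools every subject's session points).
#'
#' @param points Tibble with `pnd` and `index` columns (one category).
#' @param level `"population"` or `"individual"`.
#' @param p Smoothing parameter; default by level.
#' @return List of class `trajectory_fit`: `spline` ([fit_spline()] object),
#'   `level`, `p`, `transition_day` ([transition_day()]).
#' @export
fit_trajectory <- function(points, level = c("population", "individual"),
                           p = NULL) {
  level <- match.arg(level)
  if (is.null(p)) p <- if (level == "population") 0.01 else 0.03
  points <- dplyr::filter(tibble::as_tibble(points),
                          is.finite(.data$pnd), is.finite(.data$index))
  if (nrow(points) < 4L) stop("need at least 4 maturity points to fit a trajectory")
  sp <- fit_spline(points$pnd, points$index, p = p)
  fit <- structure(list(spline = sp, level = level, p = p,
                        pnd_range = range(points$pnd)),
                   class = "trajectory_fit")
  fit$transition_day <- transition_day(fit)
  fit
}

#' Estimated immature-to-mature transition day
#'
#' The earliest day at which the trajectory spline reaches a maturity index
#' of 0.5 and stays at or above 0.5 for the next `persist_days` days (a
#' persistence guard against noise-driven first crossings); `NA` if the
#' trajectory never does so.
#'
#' @param fit A `trajectory_fit` (or `csaps_spline`).
#' @param range_days Evaluation range, days (default \[1, 61\]).
#' @param persist_days Persistence requirement, days (default 3).
#' @param step Evaluation grid step, days.
#' @return Day (numeric) or `NA`.
#' @export
transition_day <- function(fit, range_days = c(1, 61), persist_days = 3,
                           step = 0.1) {
  sp <- if (inherits(fit, "trajectory_fit")) fit$spline else fit
  grid <- seq(range_days[1], range_days[2], by = step)
  v <- predict(sp, grid)
  ok <- v >= 0.5
  k <- round(persist_days / step)
  for (i in seq_along(grid)) {
    if (ok[i] && all(ok[i:min(length(grid), i + k)])) return(grid[i])
  }
  NA_real_
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("<trajectory_fit> level = ", x$level, ", p = ", format(x$p),
      ", transition day = ",
      if (is.na(x$transition_day)) "none" else format(x$transition_day),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.trajectory_fit <- function(x, ...) tidy(x$spline)

#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble::tibble(level = x$level, p = x$p, transition_day = x$transition_day,
                 pnd_min = x$pnd_range[1], pnd_max = x$pnd_range[2])
}

#' Plot maturity points and a fitted trajectory
#'
#' @param points Maturity points (tibble with `pnd`, `index`).
#' @param fit Optional `trajectory_fit`.
#' @return A ggplot.
#' @export
plot_trajectory <- function(points, fit = NULL) {
  g <- ggplot2::ggplot(points, ggplot2::aes(x = .data$pnd, y = .data$index)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "postnatal day", y = "maturity index") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- seq(fit$pnd_range[1], fit$pnd_range[2], by = 0.25)
    curve <- tibble::tibble(pnd = grid, index = predict(fit$spline, grid))
    g <- g + ggplot2::geom_line(data = curve, linewidth = 1, colour = "firebrick")
    if (!is.na(fit$transition_day)) {
      g <- g + ggplot2::geom_vline(xintercept = fit$transition_day,
                                   linetype = 3, colour = "firebrick")
    }
  }
  g
}
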