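#' Holm (step-down Bonferroni) adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "holm")`, which applies the
#' step-down procedure with monotonicity enforcement and maps results back
#' to input positions. `NA`s are passed through.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Declare one mixed-model specification
#'
#' @param name Short label (e.g. the appendix id).
#' @param formula Model formula with lme4 random-effects terms.
#' @param family `"gaussian"` (fit by REML) or `"binomial"` (logit link).
#' @param weights_col Name of a weights column (binomial proportion
#'   responses use the number of observed seconds), or `NULL`.
#' @param subset_expr Optional one-sided formula whose RHS filters the data.
#' @param fallbacks List of simpler random-structure formulas to try, in
#'   order, if the primary fit is singular or fails to converge.
#' @param holm_group Label of the family of tests this model's p-value is
#'   Holm-corrected within (or `NA`).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(name, formula, family = c("gaussian", "binomial"),
                       weights_col = NULL, subset_expr = NULL,
                       fallbacks = list(), holm_group = NA_character_) {
  family <- match.arg(family)
  structure(list(name = name, formula = formula, family = family,
                 weights_col = weights_col, subset_expr = subset_expr,
                 fallbacks = fallbacks, holm_group = holm_group),
            class = "model_spec")
}

#' The developmental mixed-model suite
#'
#' Twelve model groups: per-behavior proportion trends within each motor
#' category (1.1 vocal, 1.2 postural, 1.3 locomotor:
#' `proportion ~ day + (day | subject)`); the logistic GLMM comparing
#' maturation time courses across categories (1.4:
#' `maturity index ~ behavior type + day + (behavior type | subject) +
#' (day | subject)`); acoustics vs locomotion (1.5 call duration, 1.6 Wiener
#' entropy: `acoustic parameter ~ locomotor activity +
#' (locomotor activity | day/subject)`); call-type contrasts (1.7 locomotor
#' activity, 1.9 heart-rate percentile: `... ~ call type +
#' (call type | day/subject)`); early (PND 1-10) vs late (PND 52-61) age
#' groups (1.8 locomotion during phees, 1.10 arousal during phees, 1.11
#' arousal during locomotor events); and arousal vs locomotion during
#' mature calls (1.12: `heart rate ~ locomotor activity +
#' (locomotor activity | day/subject)`), rerun on the first (PND 1-30) and
#' second (PND 31-61) months.
#'
#' @return A tibble with columns `appendix_id`, `spec` (list of
#'   [model_spec()]), `data_role` (which pipeline table the model consumes),
#'   `per_behavior` (fit once per behavior label).
#' @export
build_suite <- function() {
  nest_fallbacks <- function(x) list(
    stats::as.formula(paste0(". ~ . - (", x, " | pnd / subject) + (1 | pnd / subject)")),
    stats::as.formula(paste0(". ~ . - (", x, " | pnd / subject) + (1 | pnd) + (1 | subject)"))
  )
  slope_fallbacks <- function(x) list(
    stats::as.formula(paste0(". ~ . - (", x, " | subject) + (1 | subject)"))
  )
  early_late <- function(pnd) dplyr::case_when(
    pnd >= 1 & pnd <= 10 ~ "early", pnd >= 52 & pnd <= 61 ~ "late",
    TRUE ~ NA_character_)
  specs <- list(
    list("1.1", model_spec("vocal_trend", proportion ~ pnd + (pnd | subject),
                           fallbacks = slope_fallbacks("pnd"), holm_group = "vocal"),
         "proportions_vocal", TRUE),
    list("1.2", model_spec("postural_trend", proportion ~ pnd + (pnd | subject),
                           fallbacks = slope_fallbacks("pnd"), holm_group = "postural"),
         "proportions_postural", TRUE),
    list("1.3", model_spec("locomotor_trend", proportion ~ pnd + (pnd | subject),
                           fallbacks = slope_fallbacks("pnd"), holm_group = "locomotor"),
         "proportions_locomotor", TRUE),
    list("1.4", model_spec("maturity_glmm",
                           index ~ category + pnd + (category | subject) + (pnd | subject),
                           family = "binomial", weights_col = "total_time",
                           fallbacks = list(
                             . ~ . - (category | subject) - (pnd | subject) + (1 | subject))),
         "maturity_points", FALSE),
    list("1.5", model_spec("duration_vs_locomotion",
                           duration_s ~ locomotor_activity + (locomotor_activity | pnd / subject),
                           fallbacks = nest_fallbacks("locomotor_activity"),
                           holm_group = "acoustics"),
         "calls", FALSE),
    list("1.6", model_spec("entropy_vs_locomotion",
                           wiener_entropy ~ locomotor_activity + (locomotor_activity | pnd / subject),
                           fallbacks = nest_fallbacks("locomotor_activity"),
                           holm_group = "acoustics"),
         "calls", FALSE),
    list("1.7", model_spec("locomotion_by_call_type",
                           locomotor_activity ~ call_type + (call_type | pnd / subject),
                           fallbacks = nest_fallbacks("call_type")),
         "calls", FALSE),
    list("1.8", model_spec("locomotion_by_age_group",
                           locomotor_activity ~ age_group + (age_group | pnd / subject),
                           subset_expr = ~ call_type == "phee" & !is.na(age_group),
                           fallbacks = nest_fallbacks("age_group")),
         "calls", FALSE),
    list("1.9", model_spec("arousal_by_call_type",
                           hr_percentile ~ call_type + (call_type | pnd / subject),
                           fallbacks = nest_fallbacks("call_type")),
         "calls", FALSE),
    list("1.10", model_spec("arousal_by_age_group_calls",
                            hr_percentile ~ age_group + (age_group | pnd / subject),
                            subset_expr = ~ call_type == "phee" & !is.na(age_group),
                            fallbacks = nest_fallbacks("age_group")),
         "calls", FALSE),
    list("1.11", model_spec("arousal_by_age_group_locomotion",
                            hr_percentile ~ age_group + (age_group | pnd / subject),
                            subset_expr = ~ !is.na(age_group),
                            fallbacks = nest_fallbacks("age_group")),
         "locomotor_events", FALSE),
    list("1.12", model_spec("arousal_vs_locomotion",
                            hr_percentile ~ locomotor_activity + (locomotor_activity | pnd / subject),
                            subset_expr = ~ call_type == "phee",
                            fallbacks = nest_fallbacks("locomotor_activity"),
                            holm_group = "coordination"),
         "calls", FALSE),
    list("1.12", model_spec("arousal_vs_locomotion_month1",
                            hr_percentile ~ locomotor_activity + (locomotor_activity | pnd / subject),
                            subset_expr = ~ call_type == "phee" & pnd >= 1 & pnd <= 30,
                            fallbacks = nest_fallbacks("locomotor_activity"),
                            holm_group = "coordination"),
         "calls", FALSE),
    list("1.12", model_spec("arousal_vs_locomotion_month2",
                            hr_percentile ~ locomotor_activity + (locomotor_activity | pnd / subject),
                            subset_expr = ~ call_type == "phee" & pnd >= 31 & pnd <= 61,
                            fallbacks = nest_fallbacks("locomotor_activity"),
                            holm_group = "coordination"),
         "calls", FALSE)
  )
  out <- tibble::tibble(
    appendix_id = purrr::map_chr(specs, 1),
    spec = purrr::map(specs, 2),
    data_role = purrr::map_chr(specs, 3),
    per_behavior = purrr::map_lgl(specs, 4)
  )
  attr(out, "age_group_bins") <- list(early = c(1, 10), late = c(52, 61))
  attr(out, "month_bins") <- list(month1 = c(1, 30), month2 = c(31, 61))
  attr(out, "early_late") <- early_late
  out
}

#' Fit one mixed-model specification
#'
#' Gaussian responses are fit by REML with `lme4::lmer`; binomial responses
#' by `lme4::glmer` with a logit link (proportion responses carry
#' observation weights). If the primary random structure is singular or
#' fails to converge, the spec's fallback ladder is walked in order and the
#' fallback used is recorded. p-values for gaussian terms use a normal
#' approximation to the t statistic by default; `df_method =
#' "satterthwaite"` uses `lmerTest` denominator degrees of freedom instead.
#'
#' @param spec A [model_spec()].
#' @param data Data frame with the spec's columns.
#' @param df_method `"normal"` or `"satterthwaite"`.
#' @return Tibble with one row per fixed-effect term: `model`, `term`,
#'   `beta`, `se`, `stat`, `p_raw`, `n_obs`, `converged`, `fallback_used`.
#' @export
fit_mixed_model <- function(spec, data, df_method = c("normal", "satterthwaite")) {
  stopifnot(inherits(spec, "model_spec"))
  df_method <- match.arg(df_method)
  data <- tibble::as_tibble(data)
  if (!is.null(spec$subset_expr)) {
    keep <- rlang::eval_tidy(spec$subset_expr[[2]], data = data)
    data <- data[!is.na(keep) & keep, ]
  }
  needed <- all.vars(spec$formula)
  miss <- setdiff(needed, names(data))
  if (length(miss)) {
    stop("model `", spec$name, "` is missing columns: ", paste(miss, collapse = ", "))
  }
  data <- tidyr::drop_na(data, dplyr::any_of(needed))
  grp_vars <- unique(unlist(purrr::map(lme4::findbars(spec$formula), all.vars)))
  grp_vars <- setdiff(grp_vars, all.vars(lme4::nobars(spec$formula)))
  if (nrow(data) < 8L) stop("model `", spec$name, "`: too few rows after filtering")

  formulas <- c(list(spec$formula),
                purrr::map(spec$fallbacks, ~ stats::update(spec$formula, .x)))
  w <- if (!is.null(spec$weights_col)) data[[spec$weights_col]] else NULL

  fit1 <- function(f) {
    ok <- TRUE
    fit <- withCallingHandlers(
      tryCatch(suppressMessages({
        if (spec$family == "gaussian") {
          if (df_method == "satterthwaite") {
            lmerTest::lmer(f, data = data, REML = TRUE)
          } else {
            lme4::lmer(f, data = data, REML = TRUE)
          }
        } else {
          dat2 <- data
          dat2$`(w)` <- w
          lme4::glmer(f, data = dat2, family = stats::binomial(),
                      weights = `(w)`)
        }
      }), error = function(e) e),
      warning = function(w_) { ok <<- FALSE; invokeRestart("muffleWarning") })
    if (inherits(fit, "error")) return(list(fit = NULL, clean = FALSE))
    if (lme4::isSingular(fit, tol = 1e-4)) ok <- FALSE
    list(fit = fit, clean = ok)
  }

  fit <- NULL; fallback_used <- NA_character_; converged <- FALSE
  first_usable <- NULL
  for (k in seq_along(formulas)) {
    res <- fit1(formulas[[k]])
    if (is.null(first_usable) && !is.null(res$fit)) {
      first_usable <- list(fit = res$fit, k = k)
    }
    if (res$clean) {
      fit <- res$fit; converged <- TRUE
      if (k > 1L) fallback_used <- deparse1(lme4::nobars(formulas[[k]]))
      break
    }
  }
  if (is.null(fit)) {
    if (is.null(first_usable)) {
      stop("model `", spec$name, "` could not be fit with any random structure; ",
           "n = ", nrow(data), ", groups = ", paste(grp_vars, collapse = "/"))
    }
    fit <- first_usable$fit
    if (first_usable$k > 1L) {
      fallback_used <- deparse1(lme4::nobars(formulas[[first_usable$k]]))
    }
  }

  co <- stats::coef(summary(fit))
  terms <- rownames(co)
  stat <- co[, grep("^(t|z) value$", colnames(co))]
  p <- if (spec$family == "gaussian" && df_method == "satterthwaite" &&
           "Pr(>|t|)" %in% colnames(co)) {
    co[, "Pr(>|t|)"]
  } else if ("Pr(>|z|)" %in% colnames(co)) {
    co[, "Pr(>|z|)"]
  } else {
    2 * stats::pnorm(-abs(stat))
  }
  tibble::tibble(model = spec$name, term = terms,
                 beta = co[, "Estimate"], se = co[, "Std. Error"],
                 stat = as.numeric(stat), p_raw = as.numeric(p),
                 n_obs = nrow(data), converged = converged,
                 fallback_used = fallback_used)
}

#' Fit the whole suite on prepared pipeline tables
#'
#' @param tables Named list of data frames keyed by the suite's `data_role`
#'   values (`proportions_vocal`, `proportions_postural`,
#'   `proportions_locomotor`, `maturity_points`, `calls`,
#'   `locomotor_events`). Missing tables are skipped with a message.
#' @param df_method Passed to [fit_mixed_model()].
#' @return Tibble of term rows across all fitted models with Holm-adjusted
#'   p-values (`p_adj`) within each spec's Holm group (slope/contrast terms
#'   only; intercepts are reported unadjusted).
#' @export
fit_suite <- function(tables, df_method = "normal") {
  suite <- build_suite()
  rows <- purrr::pmap_dfr(suite, function(appendix_id, spec, data_role, per_behavior) {
    d <- tables[[data_role]]
    if (is.null(d)) {
      message("skipping ", spec$name, ": no `", data_role, "` table")
      return(NULL)
    }
    fits <- if (per_behavior) {
      purrr::map_dfr(split(d, d$behavior), function(db) {
        out <- tryCatch(fit_mixed_model(spec, db, df_method = df_method),
                        error = function(e) NULL)
        if (!is.null(out)) out$behavior <- db$behavior[1]
        out
      })
    } else {
      out <- tryCatch(fit_mixed_model(spec, d, df_method = df_method),
                      error = function(e) {
                        message("model ", spec$name, " failed: ", conditionMessage(e))
                        NULL
                      })
      if (!is.null(out)) out$behavior <- NA_character_
      out
    }
    if (!is.null(fits) && nrow(fits)) {
      fits$appendix_id <- appendix_id
      fits$holm_group <- spec$holm_group
    }
    fits
  })
  if (nrow(rows) == 0L) return(rows)
  rows <- dplyr::mutate(rows, .row = dplyr::row_number())
  adj <- rows |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::group_by(grp = dplyr::coalesce(.data$holm_group,
                                          paste0("solo_", .data$model))) |>
    dplyr::mutate(p_adj = holm_adjust(.data$p_raw)) |>
    dplyr::ungroup() |>
    dplyr::select(".row", "p_adj")
  rows |>
    dplyr::left_join(adj, by = ".row") |>
    dplyr::mutate(p_adj = dplyr::coalesce(.data$p_adj, .data$p_raw)) |>
    dplyr::select(-".row")
}
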