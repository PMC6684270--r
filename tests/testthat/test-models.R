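test_that("holm adjustment has its closed forms and matches the oracle", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.05), 0.05)
  set.seed(40)
  for (i in 1:200) {
    p <- stats::runif(sample(1:6, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-12))  # below Bonferroni
  }
  # order invariance up to the position mapping
  p <- c(0.03, 0.2, 0.008, 0.6)
  o <- sample(4)
  expect_equal(holm_adjust(p)[o], holm_adjust(p[o]))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the suite enumerates the twelve model groups with their subsets", {
  suite <- build_suite()
  expect_equal(dplyr::n_distinct(suite$appendix_id), 12)
  expect_equal(nrow(suite), 14)  # 1.12 carries the two month-split reruns
  expect_setequal(unique(suite$appendix_id), paste0("1.", 1:12))
  specs <- rlang::set_names(suite$spec, purrr::map_chr(suite$spec, "name"))
  # early/late age bins: PND 1-10 and 52-61
  d <- tibble::tibble(call_type = "phee", pnd = c(5, 30, 55),
                      age_group = c("early", NA, "late"))
  keep <- rlang::eval_tidy(specs$arousal_by_age_group_calls$subset_expr[[2]], data = d)
  expect_equal(keep, c(TRUE, FALSE, TRUE))
  bins <- attr(suite, "age_group_bins")
  expect_equal(bins$early, c(1, 10))
  expect_equal(bins$late, c(52, 61))
  # month splits: PND 1-30 and 31-61
  d2 <- tibble::tibble(call_type = "phee", pnd = c(10, 30, 31, 61))
  k1 <- rlang::eval_tidy(specs$arousal_vs_locomotion_month1$subset_expr[[2]], data = d2)
  k2 <- rlang::eval_tidy(specs$arousal_vs_locomotion_month2$subset_expr[[2]], data = d2)
  expect_equal(k1, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(k2, c(FALSE, FALSE, TRUE, TRUE))
  # maturity GLMM is the logistic model with observation-time weights
  expect_equal(specs$maturity_glmm$family, "binomial")
  expect_equal(specs$maturity_glmm$weights_col, "total_time")
})

test_that("null data yield near-zero effects and honest uncertainty", {
  set.seed(41)
  d <- purrr::map_dfr(paste0("S", 1:6), function(s)
    tibble::tibble(subject = s, pnd = rep(seq(2, 60, by = 2), each = 1),
                   proportion = stats::rnorm(30, 0.5, 0.1)))
  spec <- model_spec("null", proportion ~ pnd + (pnd | subject),
                     fallbacks = list(. ~ . - (pnd | subject) + (1 | subject)))
  out <- fit_mixed_model(spec, d)
  slope <- dplyr::filter(out, term == "pnd")
  expect_lt(abs(slope$stat), 2)
  expect_lt(abs(slope$beta), 0.005)
  expect_equal(out$n_obs[1], 180)
})

test_that("binomial maturity model recovers a step-function day effect", {
  set.seed(42)
  d <- purrr::map_dfr(paste0("S", 1:6), function(s)
    tibble::tibble(subject = s, pnd = seq(1, 61, by = 3),
                   category = "vocal",
                   index = pmin(1, pmax(0, ifelse(pnd > 25, 0.9, 0.1) +
                                          stats::rnorm(21, 0, 0.05))),
                   total_time = round(stats::runif(21, 30, 120))))
  spec <- model_spec("mat", index ~ pnd + (pnd | subject), family = "binomial",
                     weights_col = "total_time",
                     fallbacks = list(. ~ . - (pnd | subject) + (1 | subject)))
  out <- fit_mixed_model(spec, d)
  expect_gt(dplyr::filter(out, term == "pnd")$beta, 0)
  expect_lt(dplyr::filter(out, term == "pnd")$p_raw, 0.05)
})

test_that("missing columns and unusable data produce structured errors", {
  spec <- model_spec("m", y ~ x + (x | g))
  expect_error(fit_mixed_model(spec, tibble::tibble(y = 1:10, g = 1)),
               "missing columns: x")
  expect_error(fit_mixed_model(spec, tibble::tibble(y = 1:4, x = 1:4, g = "a")),
               "too few rows")
})

test_that("the full suite runs on a synthetic study and adjusts within families", {
  st <- tiny_study()
  tabs <- prepare_tables(st)
  res <- suppressMessages(fit_suite(tabs))
  expect_true(all(c("appendix_id", "term", "beta", "se", "stat",
                    "p_raw", "p_adj", "n_obs") %in% names(res)))
  eff <- dplyr::filter(res, term != "(Intercept)")
  expect_true(all(eff$p_adj >= eff$p_raw - 1e-12))
  expect_true(all(res$p_raw >= 0 & res$p_raw <= 1))
  # the acoustics family (1.5, 1.6) shares one Holm correction
  ac <- dplyr::filter(eff, appendix_id %in% c("1.5", "1.6"))
  expect_equal(sort(ac$p_adj), sort(oracle_holm(ac$p_raw)), tolerance = 1e-9)
  # cry/phee trends carry opposite signs
  tr <- dplyr::filter(res, appendix_id == "1.1", term == "pnd")
  expect_lt(tr$beta[tr$behavior == "cry"], 0)
  expect_gt(tr$beta[tr$behavior == "phee"], 0)
})
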