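test_that("window extraction uses the stated bounds and clips at edges", {
  sig <- tibble::tibble(t_s = seq_len(600) - 0.5, value = seq_len(600))
  ev <- tibble::tibble(onset_s = 30, offset_s = 32)
  tr <- extract_windows(sig, ev, kind = "locomotor")
  on <- dplyr::filter(tr, anchor == "onset")
  expect_equal(range(on$rel_t), c(-20, 5))
  # absolute coverage [10, 35]: first sample is the bin holding t = 10
  expect_equal(on$value[on$rel_t == -20], 11)  # bin centered 10.5
  off <- dplyr::filter(tr, anchor == "offset")
  expect_equal(range(off$rel_t), c(-5, 20))

  hw <- perievent_windows("heartrate")
  expect_equal(hw$onset, c(-10, 5))
  expect_equal(hw$offset, c(-5, 10))

  edge <- extract_windows(sig, tibble::tibble(onset_s = 5, offset_s = 6), "locomotor")
  lead <- dplyr::filter(edge, anchor == "onset", rel_t < -5)
  expect_true(all(is.na(lead$value)))
  expect_equal(nrow(extract_windows(sig, ev[0, ], "locomotor")), 0)
})

test_that("stitching joins pre-onset and post-offset halves consistently", {
  sig <- tibble::tibble(t_s = seq_len(200) - 0.5, value = rep(4.2, 200))
  ev <- tibble::tibble(onset_s = 100, offset_s = 101)
  tr <- extract_windows(sig, ev, "locomotor")
  stitched <- stitch_call_axis(tr)
  expect_true(all(stitched$value == 4.2))
  expect_equal(sort(unique(stitched$segment)), c("post", "pre"))
  expect_true(all(stitched$rel_t[stitched$segment == "pre"] <= 0))
  expect_true(all(stitched$rel_t[stitched$segment == "post"] > 0))

  # a step at call onset: pre side flat low, post side elevated
  sig2 <- tibble::tibble(t_s = seq_len(200) - 0.5,
                         value = as.numeric(seq_len(200) - 0.5 >= 100))
  st2 <- stitch_call_axis(extract_windows(sig2, ev, "locomotor"))
  expect_true(all(st2$value[st2$rel_t < -1] == 0))
  expect_true(all(st2$value[st2$rel_t > 1] == 1))

  # stitched mean identity with the anchored means on each half-axis
  set.seed(30)
  sig3 <- tibble::tibble(t_s = seq_len(300) - 0.5, value = stats::rnorm(300))
  ev3 <- tibble::tibble(onset_s = c(50, 120, 200), offset_s = c(53, 122, 207))
  tr3 <- extract_windows(sig3, ev3, "locomotor")
  st3 <- stitch_call_axis(tr3)
  pre_mean <- mean(dplyr::filter(tr3, anchor == "onset", rel_t <= 0)$value)
  post_mean <- mean(dplyr::filter(tr3, anchor == "offset", rel_t > 0,
                                  rel_t <= 20)$value)
  expect_equal(mean(st3$value[st3$segment == "pre"]), pre_mean)
  expect_equal(mean(st3$value[st3$segment == "post"]), post_mean)

  expect_error(stitch_call_axis(dplyr::filter(tr3, anchor == "onset")),
               "paired")
})

test_that("population spline of identical sessions equals the shared curve", {
  grid <- seq(-20, 20)
  curve <- sin(grid / 6)
  sess <- replicate(5, fit_spline(grid, curve, p = 1), simplify = FALSE)
  pop <- population_spline(sess, grid, p = 0.3)
  # pooled identical points: smoothing at p = 0.3 with weight 5 stays close
  expect_lt(max(abs(predict(pop, grid) - curve)), 0.02)
  pop1 <- population_spline(sess[1], grid, p = 1)
  expect_equal(predict(pop1, grid), curve, tolerance = 1e-6)
})

test_that("timing scrambles preserve durations and gaps but not order", {
  set.seed(31)
  on <- c(3, 10, 25, 40)
  off <- c(5, 14, 30, 41)
  sc <- scramble_events(on, off)
  expect_equal(sort(sc$offset_s - sc$onset_s), sort(off - on))
  gaps0 <- c(on[1], on[-1] - off[-4])
  gaps1 <- c(sc$onset_s[1], sc$onset_s[-1] - sc$offset_s[-4])
  expect_equal(sort(gaps1), sort(gaps0))
  expect_true(all(diff(sc$onset_s) > 0))
  # one event, one gap: the layout is unique
  sc1 <- scramble_events(7, 9)
  expect_equal(sc1$onset_s, 7)
  expect_equal(sc1$offset_s, 9)
})

test_that("bands are deterministic under a seed and degenerate for constant data", {
  sig <- purrr::map_dfr(c("a", "b"), function(s)
    tibble::tibble(session = s, t_s = seq_len(300) - 0.5, value = 2.5))
  ev <- purrr::map_dfr(c("a", "b"), function(s)
    tibble::tibble(session = s, onset_s = c(60, 150, 220),
                   offset_s = c(62, 153, 224)))
  b1 <- perievent_dynamics(sig, ev, "heartrate", n_rep = 50, seed = 4)
  b2 <- perievent_dynamics(sig, ev, "heartrate", n_rep = 50, seed = 4)
  expect_identical(b1, b2)
  # zero-variance signal: every band collapses onto the observed curve
  expect_equal(b1$ci_lo, b1$observed, tolerance = 1e-9)
  expect_equal(b1$ci_hi, b1$observed, tolerance = 1e-9)
  expect_equal(b1$null_lo, b1$observed, tolerance = 1e-9)
  expect_true(all(b1$flag == "inside"))
  b3 <- perievent_dynamics(sig, ev, "heartrate", n_rep = 50, seed = 5)
  expect_false(identical(attr(b1, "seed"), attr(b3, "seed")))
})

test_that("an injected dip around events is localized by the population spline", {
  set.seed(32)
  sessions <- paste0("s", 1:4)
  ev <- purrr::map_dfr(sessions, function(s)
    tibble::tibble(session = s, onset_s = seq(40, 560, by = 40) +
                     round(stats::runif(14, -5, 5)),
                   offset_s = NA))
  ev$offset_s <- ev$onset_s + 2
  sig <- purrr::map_dfr(sessions, function(s) {
    v <- stats::rnorm(600, 0, 0.2)
    for (o in ev$onset_s[ev$session == s]) {
      idx <- seq(max(1, o - 1), min(600, o + 2))
      v[idx] <- v[idx] - 1           # dip centered on the event
    }
    tibble::tibble(session = s, t_s = seq_len(600) - 0.5, value = v)
  })
  band <- perievent_dynamics(sig, ev, "locomotor", n_rep = 60, seed = 6)
  expect_lt(abs(band$rel_t[which.min(band$observed)]), 2)
  expect_true(any(band$flag[abs(band$rel_t) <= 3] == "below"))
})

test_that("developmental curve is flat for constant signals and flags trends", {
  sessions <- tibble::tibble(session = paste0("s", 1:12),
                             pnd = seq(5, 60, by = 5))
  sig <- purrr::map_dfr(seq_len(12), function(i)
    tibble::tibble(session = sessions$session[i], t_s = seq_len(300) - 0.5,
                   value = 7))
  ev <- purrr::map_dfr(seq_len(12), function(i)
    tibble::tibble(session = sessions$session[i], pnd = sessions$pnd[i],
                   onset_s = c(50, 120, 200), offset_s = c(55, 126, 209)))
  flat <- developmental_curve(sig, ev, n_rep = 40, seed = 7)
  expect_equal(flat$observed, rep(7, nrow(flat)), tolerance = 1e-9)
  expect_true(all(flat$flag == "inside"))

  # linear increase with age: fitted curve slope is positive
  sig2 <- purrr::map_dfr(seq_len(12), function(i)
    tibble::tibble(session = sessions$session[i], t_s = seq_len(300) - 0.5,
                   value = sessions$pnd[i] * 0.5 + stats::rnorm(300, 0, 0.1)))
  rising <- developmental_curve(sig2, ev, n_rep = 40, seed = 8)
  expect_gt(rising$observed[nrow(rising)], rising$observed[1])

  empty <- developmental_curve(sig, ev[0, ], n_rep = 10, seed = 9)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "status"), "no_sessions")
})

test_that("exceedance flags agree with a naive per-point comparison", {
  set.seed(33)
  obs <- stats::rnorm(50)
  lo <- obs - stats::runif(50, 0, 1)
  hi <- obs + stats::runif(50, 0, 1)
  lo[5:9] <- obs[5:9] + 0.1    # force 'below'
  hi[20:24] <- obs[20:24] - 0.1  # force 'above'
  ex <- exceedance(obs, lo, hi)
  naive <- ifelse(obs > hi, "above", ifelse(obs < lo, "below", "inside"))
  expect_equal(ex$flag, naive)
  expect_true(all(c("above", "below") %in% ex$runs$flag))
  runs_above <- dplyr::filter(ex$runs, flag == "above")
  expect_true(any(runs_above$start == 20 & runs_above$end == 24))
  expect_error(exceedance(obs, lo[-1], hi), "align")
  # observed exactly on the midline of a symmetric band: all inside
  ex0 <- exceedance(rep(0, 10), rep(-1, 10), rep(1, 10))
  expect_true(all(ex0$flag == "inside"))
})
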