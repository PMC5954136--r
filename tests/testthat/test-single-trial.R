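test_that("noiseless step trials recover exact boundaries and rates", {
  counts <- rep(0L, 90); counts[11:20] <- 3L  # bins 10..19, 0-based
  bt <- structure(list(counts = counts, bin_width_s = 1, window_s = 90),
                  class = "binned_trial")
  f <- three_state_fit(bt)
  expect_equal(f$start_s, 10)
  expect_equal(f$stop_s, 19)
  expect_equal(f$spread_s, 9)
  expect_equal(c(f$r1, f$r2, f$r3), c(0, 3, 0))
  expect_equal(f$objective_value, 0)
  expect_true(f$qualifies)
  expect_true(qualifies(f))

  # all-zero trial: no segmentation makes r2 dominate
  z <- three_state_fit(structure(list(counts = rep(0L, 90),
                                      bin_width_s = 1, window_s = 90),
                                 class = "binned_trial"))
  expect_false(z$qualifies)

  expect_error(three_state_constraints(window_s = 5), "shorter")
})

test_that("the production search equals a naive exhaustive oracle", {
  set.seed(2024)
  n_checked <- 0
  for (seed in c(11, 23)) {
    set.seed(seed)
    for (i in 1:30) {
      lam <- stats::runif(1, 0.1, 2)
      counts <- stats::rpois(90, lam)
      f <- three_state_fit(structure(
        list(counts = counts, bin_width_s = 1, window_s = 90),
        class = "binned_trial"))
      o <- naive_three_state(counts)
      expect_identical(c(f$start_s, f$stop_s),
                       c(o$start_s, o$stop_s))
      n_checked <- n_checked + 1
      # same under the duration-weighted index objective
      fi <- three_state_fit(structure(
        list(counts = counts, bin_width_s = 1, window_s = 90),
        class = "binned_trial"), objective = "index")
      oi <- naive_three_state(counts, objective = "index")
      expect_identical(c(fi$start_s, fi$stop_s),
                       c(oi$start_s, oi$stop_s))
    }
  }
  expect_gte(n_checked, 60)
})

test_that("fits dominate the flat model and respect the constraints", {
  set.seed(5)
  for (i in 1:40) {
    counts <- stats::rpois(90, stats::runif(1, 0.2, 1.5))
    f <- three_state_fit(structure(
      list(counts = counts, bin_width_s = 1, window_s = 90),
      class = "binned_trial"))
    flat_sse <- sum((counts - mean(counts))^2)
    expect_lte(f$objective_value, flat_sse + 1e-9)
    expect_gte(f$start_s, 1)              # leading low state >= 1 s
    expect_lte(f$stop_s, 88)              # trailing low state >= 1 s
    expect_gte(f$stop_s - f$start_s + 1, 4)  # high state >= 4 s
    expect_equal(f$spread_s, f$stop_s - f$start_s)
  }
})

test_that("the inclusion filter is strict and counted exactly", {
  mk <- function(r1, r2, r3) {
    counts <- c(rep(r1, 20), rep(r2, 40), rep(r3, 30))
    three_state_fit(structure(list(counts = counts, bin_width_s = 1,
                                   window_s = 90),
                              class = "binned_trial"))
  }
  expect_true(qualifies(mk(0, 2, 0)))
  f <- mk(2, 2, 2)           # no dominance possible on a flat trial
  expect_false(qualifies(f))

  # hand-built fixture: 7 of 10 trials satisfy r2 > max(r1, r3)
  highs <- c(5, 5, 4, 4, 3, 3, 2)   # qualifying high rates
  qual <- lapply(highs, function(h) mk(1, h, 1))
  nonq <- list(mk(2, 2, 2), mk(3, 3, 3), mk(0, 0, 0))
  s <- summarize_block(c(qual, nonq))
  expect_equal(s$proportion_qualifying, 0.7)
  expect_equal(s$n_qualifying, 7L)
})

test_that("block summaries report medians, IQRs and per-trial ratios", {
  res <- data.frame(start_s = c(10, 20, 30), stop_s = c(40, 44, 60),
                    spread_s = c(30, 24, 30),
                    r1 = c(0.2, 0.4, 0.3), r2 = c(2, 4, 3),
                    r3 = c(0.4, 0.8, 0.6), qualifies = TRUE)
  s <- summarize_block(res)
  expect_equal(s$median_start_s, 20)
  expect_equal(s$iqr_start_s, 10)   # quantile type 7 on {10,20,30}
  expect_equal(s$initiation_ratio, 0.1)
  expect_equal(s$suppression_ratio, 0.2)
  expect_equal(s$proportion_qualifying, 1)

  # a single qualifying trial has zero IQRs
  one <- summarize_block(res[2, ])
  expect_equal(one$iqr_start_s, 0)
  expect_equal(one$median_spread_s, 24)

  # no qualifying trials: absent fields, proportion 0
  res$qualifies <- FALSE
  s0 <- summarize_block(res)
  expect_equal(s0$proportion_qualifying, 0)
  expect_true(is.na(s0$median_start_s))
})

test_that("generative median start is recovered from simulated blocks", {
  pk <- simulate_peak_session("m", peak_gen_params(
    memory_cv = 0.2, threshold_jitter_cv = 0, omit_prob = 0,
    n_probe = 36), seed = 14)
  s <- summarize_block(three_state_trials(pk))
  expect_lt(abs(s$median_start_s - 21), 3)
  expect_gt(s$proportion_qualifying, 0.9)
})

test_that("bracketed correlations match a hand-computed Pearson r", {
  res <- data.frame(start_s = c(20, 25, 22, 28),
                    stop_s = c(40, 50, 44, 55))
  res$spread_s <- res$stop_s - res$start_s
  res$qualifies <- TRUE
  cc <- bracketed_correlations(res, fi_s = 30)
  expect_equal(cc$n_bracketed, 4L)
  # textbook formula written out: r = S_xy / sqrt(S_xx S_yy)
  hand_r <- function(x, y) {
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(cc$start_stop_r, hand_r(res$start_s, res$stop_s),
               tolerance = 1e-12)
  expect_equal(cc$start_spread_r, hand_r(res$start_s, res$spread_s),
               tolerance = 1e-12)

  # constant spread: zero variance is flagged, not NaN-propagated
  res$stop_s <- res$start_s + 20
  res$spread_s <- 20
  cc2 <- bracketed_correlations(res, fi_s = 30)
  expect_true(is.na(cc2$start_spread_r))
  expect_match(cc2$note, "zero variance")

  # fewer than 3 bracketed trials: absent, flagged
  few <- data.frame(start_s = c(5, 10), stop_s = c(40, 50),
                    spread_s = c(35, 40), qualifies = TRUE)
  cc3 <- bracketed_correlations(few, fi_s = 30)
  expect_true(is.na(cc3$start_stop_r))
  expect_match(cc3$note, "fewer than 3")

  # bracketing is strict: start < fi < stop
  edge <- data.frame(start_s = c(30, 10, 12, 14),
                     stop_s = c(50, 30, 40, 45),
                     spread_s = c(20, 20, 28, 31), qualifies = TRUE)
  expect_equal(bracketed_correlations(edge, 30)$n_bracketed, 2L)
})

test_that("generator noise propagates to start-time variability", {
  iqr_for <- function(cv) {
    starts <- unlist(lapply(1:3, function(sd) {
      pk <- simulate_peak_session("n", peak_gen_params(
        memory_cv = cv, threshold_jitter_cv = 0, omit_prob = 0,
        n_probe = 36), seed = 100 + sd)
      three_state_trials(pk)$start_s
    }))
    stats::IQR(starts)
  }
  v <- vapply(c(0.05, 0.2, 0.4), iqr_for, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("zero-noise fits stay inside the generative press span", {
  pk <- simulate_peak_session("z", peak_gen_params(
    memory_cv = 0, threshold_jitter_cv = 0, r1 = 0, r2 = 1, r3 = 0,
    omit_prob = 0, n_probe = 36), seed = 9)
  pr <- pk[pk$trial_type == "probe", ]
  starts <- numeric(0); stops <- numeric(0)
  for (i in seq_len(nrow(pr))) {
    p <- pr$press_times[[i]]
    f <- three_state_fit(p)
    # the high state can only trim sparse Poisson edges, never extend
    # into the zero-rate surround
    expect_gte(f$start_s, floor(min(p)))
    expect_lte(f$stop_s, floor(max(p)))
    expect_true(f$qualifies)
    starts <- c(starts, f$start_s); stops <- c(stops, f$stop_s)
  }
  # generative boundaries 21 and 45: medians land on the enclosing bins
  expect_lt(abs(stats::median(starts) - 21), 2)
  expect_lt(abs(stats::median(stops) - 44), 2)
})
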