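test_that("pseudologistic curve matches its closed form and anchors the PSE", {
  # independent evaluation of the closed form via the standard-logistic
  # CDF: logistic((pi/sqrt(3)) * (t - T50)/(g*t))
  p_ref <- function(t, T50, g)
    stats::plogis((base::pi / sqrt(3)) * (t - T50) / (g * t))
  for (g in c(0.05, 0.2, 0.7)) for (t in c(2, 3.2, 4, 6.3, 8)) {
    expect_equal(pseudologistic_p_long(t, 4, g), p_ref(t, 4, g),
                 tolerance = 1e-12)
  }
  # the curve passes through 0.5 exactly at T50
  expect_equal(pseudologistic_p_long(4, 4, 0.2), 0.5)
  expect_equal(pseudologistic_p_long(5.7, 5.7, 1.3), 0.5)
  # step-function limit as gamma -> 0
  expect_gt(pseudologistic_p_long(4 * 1.01, 4, 1e-6), 1 - 1e-9)
  expect_lt(pseudologistic_p_long(4 * 0.99, 4, 1e-6), 1e-9)
  # strict monotonicity over a fine grid; sigma-at-T50 variant too
  for (sig in c("t", "t50")) {
    tt <- seq(1, 10, by = 0.01)
    expect_true(all(diff(pseudologistic_p_long(tt, 4, 0.2, sig)) > 0))
  }
  # larger gamma flattens the slope at the PSE
  slope_at_pse <- function(g) {
    h <- 1e-5
    (pseudologistic_p_long(4 + h, 4, g) -
        pseudologistic_p_long(4 - h, 4, g)) / (2 * h)
  }
  s <- vapply(c(0.1, 0.2, 0.4, 0.8), slope_at_pse, numeric(1))
  expect_true(all(diff(s) < 0))
  expect_error(pseudologistic_p_long(-1, 4, 0.2), "positive")
})

test_that("noiseless proportions are fitted back exactly", {
  durs <- c(2, 2.5, 3.2, 4, 5, 6.3, 8)
  d <- data.frame(stimulus_duration_s = durs,
                  n_trials = c(120, 12, 12, 12, 12, 12, 120),
                  n_responded = c(120, 12, 12, 12, 12, 12, 120),
                  p_respond = 1,
                  p_long = pseudologistic_p_long(durs, 4, 0.2))
  fit <- fit_pseudologistic(d)
  expect_equal(coef(fit)[["T50_s"]], 4, tolerance = 1e-4)
  expect_equal(coef(fit)[["gamma"]], 0.2, tolerance = 1e-4)
  expect_gt(fit$r_squared, 1 - 1e-8)
  expect_true(fit$usable)
  # PSE anchoring of the fitted curve
  expect_equal(predict(fit, coef(fit)[["T50_s"]]), 0.5,
               tolerance = 1e-12)
})

test_that("a coarse grid search confirms the least-squares optimum", {
  tt <- simulate_bisection_subject("g1", T50_s = 4, gamma = 0.25,
                                   seed = 77)
  s <- summarize_test(tt)
  fit <- fit_pseudologistic(s)
  sse <- function(T50, g)
    sum((s$p_long - pseudologistic_p_long(s$stimulus_duration_s,
                                          T50, g))^2)
  grid <- expand.grid(T50 = seq(2.1, 7.9, by = 0.05),
                      g = seq(0.02, 1.5, by = 0.02))
  grid_min <- min(mapply(sse, grid$T50, grid$g))
  fit_sse <- sse(coef(fit)[["T50_s"]], coef(fit)[["gamma"]])
  expect_lte(fit_sse, grid_min + 1e-10)
})

test_that("recovery error shrinks as trials per duration increase", {
  err <- sapply(c(12, 120, 1200), function(n) {
    des <- bisection_design(n_anchor = n, n_intermediate = n)
    e <- sapply(1:8, function(i) {
      tt <- simulate_bisection_subject("r", 4, 0.2, design = des,
                                       seed = 9000 + 13 * i + n)
      abs(coef(fit_pseudologistic(summarize_test(tt)))[["T50_s"]] - 4)
    })
    mean(e)
  })
  expect_gt(err[1], err[2])
  expect_gt(err[2], err[3])
})

test_that("monotone-decreasing choice curves are gated unusable", {
  durs <- c(2, 2.5, 3.2, 4, 5, 6.3, 8)
  d <- data.frame(stimulus_duration_s = durs, n_trials = 12,
                  n_responded = 12, p_respond = 1,
                  p_long = rev(pseudologistic_p_long(durs, 4, 0.2)))
  fit <- fit_pseudologistic(d)
  expect_lte(fit$r_squared, 0.5)
  expect_false(fit$usable)
})

test_that("fit usability applies inclusive exclusion at the bound", {
  skeleton <- fit_pseudologistic(data.frame(
    stimulus_duration_s = c(2, 3.2, 5, 8), n_trials = 10,
    n_responded = 10, p_respond = 1,
    p_long = c(0.05, 0.3, 0.8, 0.95)))
  f <- skeleton
  f$r_squared <- 0.95; f$converged <- TRUE
  expect_true(classify_fit(f))
  f$r_squared <- 0.5
  expect_false(classify_fit(f))  # R^2 <= 0.5 is excluded
  f$r_squared <- 0.95; f$converged <- FALSE
  expect_false(classify_fit(f))
})

test_that("discrimination summaries count correct free-choice responses", {
  # 80 trials, 72 correct -> 90%
  durs <- rep(c(2, 8), each = 40)
  lever <- ifelse(durs == 2, "short", "long")
  wrong <- c(1:4, 41:44)
  lever[wrong] <- ifelse(durs[wrong] == 2, "long", "short")
  tt <- trial_table("d1", 1L, 1:80, "bisection_free", durs,
                    press_times = as.list(durs + 0.5),
                    chosen_lever = lever, response_latency_s = 0.5,
                    reinforced = lever == ifelse(durs == 2, "short",
                                                 "long"))
  s <- summarize_discrimination(tt)
  expect_equal(s$percent_correct, 90)
  expect_equal(s$mean_latency_correct_ms, 500)
  expect_equal(s$mean_latency_incorrect_ms, 500)

  # all unanswered: 0% correct, latencies absent
  none <- trial_table("d2", 1L, 1:10, "bisection_free",
                      rep(c(2, 8), 5), rep(list(numeric(0)), 10),
                      chosen_lever = "none")
  s0 <- summarize_discrimination(none)
  expect_equal(s0$percent_correct, 0)
  expect_true(is.na(s0$mean_latency_correct_ms))

  # near-step psychometric subject scores essentially perfectly
  des <- bisection_design(n_anchor = 500, n_intermediate = 0)
  sim <- simulate_bisection_subject("d3", 4, 1e-6, design = des,
                                    seed = 21)
  anch <- sim[sim$trial_type == "bisection_free", ]
  expect_gte(summarize_discrimination(anch)$percent_correct, 99)

  expect_error(summarize_discrimination(
    trial_table("x", 1L, 1L, "bisection_free", 5, list(5.2),
                chosen_lever = "long")), "anchor")
})

test_that("test summaries pool sessions and track omission", {
  tt <- rbind(simulate_bisection_subject("s", seed = 1),
              simulate_bisection_subject("s", session_index = 2,
                                         seed = 2))
  class(tt) <- c("trial_table", "data.frame")
  s <- summarize_test(tt)
  expect_equal(s$stimulus_duration_s, c(2, 2.5, 3.2, 4, 5, 6.3, 8))
  expect_equal(s$n_trials, c(120, 24, 24, 24, 24, 24, 120))
  expect_equal(s$p_respond, rep(1, 7))

  # all-long responding
  all_long <- trial_table("s", 1L, 1:8, "bisection_test",
                          rep(c(2.5, 4, 5, 6.3), 2),
                          as.list(rep(5, 8)), chosen_lever = "long")
  expect_equal(summarize_test(all_long)$p_long, rep(1, 4))

  # 40% omission -> p_respond about 0.6 within binomial error
  des <- bisection_design(n_anchor = 500, n_intermediate = 100)
  om <- simulate_bisection_subject("s", omit_prob = 0.4, design = des,
                                   seed = 33)
  so <- summarize_test(om)
  n_tot <- sum(so$n_trials)
  p_hat <- sum(so$n_responded) / n_tot
  expect_lt(abs(p_hat - 0.6), 3 * sqrt(0.6 * 0.4 / n_tot))
  expect_error(summarize_test(tt[0, ]), "bisection")
})
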