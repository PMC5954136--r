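# Single-trial low-high-low decomposition of probe-trial responding:
# exhaustive change-point search under minimum state durations, the
# r2-dominance inclusion filter, block summaries and bracketed
# correlations.

#' Constraints of the three-state model
#'
#' @param bin_width_s analysis bin width (1 s by convention).
#' @param min_high_s minimum duration of the high-rate state (4 s).
#' @param min_low_s minimum duration of each low-rate state (1 s).
#' @param window_s probe window (90 s).
#' @return A `three_state_constraints` list.
#' @export
three_state_constraints <- function(bin_width_s = 1, min_high_s = 4,
                                    min_low_s = 1, window_s = 90) {
  stopifnot(min_high_s >= bin_width_s, min_low_s >= bin_width_s)
  if (window_s < min_high_s + 2 * min_low_s)
    stop("window shorter than the minimum low + high + low durations")
  structure(list(bin_width_s = bin_width_s, min_high_s = min_high_s,
                 min_low_s = min_low_s, window_s = window_s),
            class = "three_state_constraints")
}

#' Three-state change-point fit of a single probe trial
#'
#' Decomposes a trial's 1-s binned lever pressing into a
#' low-high-low piecewise-constant rate profile by exhaustive search over
#' all admissible high-state placements. For every pair (s, e) of first
#' and last high-state bins respecting the minimum state durations, the
#' three segment rates are the segment mean press rates; the default
#' objective minimizes the residual sum of squares of the
#' piecewise-constant model (equivalently maximizes the
#' between-segment sum of squares). The alternative
#' `objective = "index"` maximizes the classic duration-weighted index
#' \eqn{d_1(r - r_1) + d_2(r_2 - r) + d_3(r - r_3)} with \eqn{r} the
#' whole-trial mean rate. Ties are broken by earliest start, then
#' earliest stop.
#'
#' Start and stop are reported as the left edges (seconds, 0-based) of
#' the first and last high-state bins; spread is their difference. A
#' trial qualifies for analysis when the high-state rate strictly
#' exceeds both low-state rates (`r2 > r1` and `r2 > r3`).
#'
#' @param trial a `binned_trial` (see [bin_trial()]), a single-row
#'   `trial_table`, or a numeric vector of press times.
#' @param constraints a [three_state_constraints()] object.
#' @param objective `"sse"` (default) or `"index"`.
#' @return An object of class `three_state_fit`: `start_s`, `stop_s`,
#'   `spread_s`, `r1`, `r2`, `r3` (presses/s), `objective_value` (the
#'   model SSE for `"sse"`, the index for `"index"`), `qualifies`,
#'   `counts`, `constraints`. Supports `print`, `coef`, `fitted`,
#'   `residuals`, `plot`.
#' @export
three_state_fit <- function(trial, constraints = three_state_constraints(),
                            objective = c("sse", "index")) {
  objective <- match.arg(objective)
  stopifnot(inherits(constraints, "three_state_constraints"))
  bt <- if (inherits(trial, "binned_trial")) trial
  else bin_trial(trial, constraints$bin_width_s, constraints$window_s)
  if (bt$bin_width_s != constraints$bin_width_s ||
      bt$window_s != constraints$window_s)
    stop("binned trial does not match the constraints' bin width/window")
  x <- bt$counts
  n <- length(x)
  w <- constraints$bin_width_s
  k_low <- as.integer(round(constraints$min_low_s / w))
  k_high <- as.integer(round(constraints$min_high_s / w))
  cs <- c(0, cumsum(x))
  total <- cs[n + 1]
  xbar <- total / n

  # admissible first/last high bins, 1-based
  s_range <- (k_low + 1):(n - k_low - k_high + 1)
  best <- NULL
  best_q <- -Inf
  tol <- 1e-9
  for (s in s_range) {
    e_range <- (s + k_high - 1):(n - k_low)
    sum1 <- cs[s]
    len1 <- s - 1
    sum2 <- cs[e_range + 1] - cs[s]
    len2 <- e_range - s + 1
    sum3 <- total - cs[e_range + 1]
    len3 <- n - e_range
    q <- if (objective == "sse") {
      # maximizing the between-segment SS minimizes the model SSE
      sum1^2 / len1 + sum2^2 / len2 + sum3^2 / len3
    } else {
      r1 <- sum1 / len1; r2 <- sum2 / len2; r3 <- sum3 / len3
      len1 * (xbar - r1) + len2 * (r2 - xbar) + len3 * (xbar - r3)
    }
    # earliest stop achieving this start's maximum; earliest start wins
    # overall ties because an update requires strict improvement
    j <- which(q >= max(q) - tol)[1]
    if (q[j] > best_q + tol) {
      best_q <- q[j]
      best <- c(s, e_range[j])
    }
  }
  s <- best[1]; e <- best[2]
  r1 <- cs[s] / ((s - 1) * w)
  r2 <- (cs[e + 1] - cs[s]) / ((e - s + 1) * w)
  r3 <- (total - cs[e + 1]) / ((n - e) * w)
  sse <- {
    fitted_counts <- c(rep(cs[s] / (s - 1), s - 1),
                       rep((cs[e + 1] - cs[s]) / (e - s + 1), e - s + 1),
                       rep((total - cs[e + 1]) / (n - e), n - e))
    sum((x - fitted_counts)^2)
  }
  obj_val <- if (objective == "sse") sse else best_q
  structure(list(
    start_s = (s - 1) * w,
    stop_s = (e - 1) * w,
    spread_s = (e - s) * w,
    r1 = r1, r2 = r2, r3 = r3,
    objective = objective,
    objective_value = obj_val,
    qualifies = r2 > r1 && r2 > r3,
    counts = x,
    constraints = constraints),
    class = "three_state_fit")
}

#' Inclusion filter for single-trial fits
#'
#' A trial enters the individual-trial analysis only when the high-state
#' response rate strictly exceeds both low-state rates.
#'
#' @param result a `three_state_fit`.
#' @return Logical.
#' @export
qualifies <- function(result) {
  stopifnot(inherits(result, "three_state_fit"))
  result$r2 > result$r1 && result$r2 > result$r3
}

#' @export
coef.three_state_fit <- function(object, ...)
  c(start_s = object$start_s, stop_s = object$stop_s,
    spread_s = object$spread_s, r1 = object$r1, r2 = object$r2,
    r3 = object$r3)

#' @export
fitted.three_state_fit <- function(object, ...) {
  w <- object$constraints$bin_width_s
  n <- length(object$counts)
  s <- object$start_s / w + 1
  e <- object$stop_s / w + 1
  c(rep(object$r1, s - 1), rep(object$r2, e - s + 1),
    rep(object$r3, n - e)) * w
}

#' @export
residuals.three_state_fit <- function(object, ...)
  object$counts - fitted(object)

#' @export
print.three_state_fit <- function(x, ...) {
  cat("Three-state (low-high-low) trial fit\n")
  cat(sprintf("  start %.0f s  stop %.0f s  spread %.0f s\n",
              x$start_s, x$stop_s, x$spread_s))
  cat(sprintf("  rates r1 %.3f  r2 %.3f  r3 %.3f presses/s  qualifies: %s\n",
              x$r1, x$r2, x$r3, x$qualifies))
  invisible(x)
}

#' @export
plot.three_state_fit <- function(x, ...) {
  w <- x$constraints$bin_width_s
  t <- (seq_along(x$counts) - 1) * w
  graphics::plot(t, x$counts / w, type = "h",
                 xlab = "Time from cue onset (s)",
                 ylab = "Responses per second", ...)
  graphics::lines(t, fitted(x) / w, type = "s", col = 2, lwd = 2)
  graphics::abline(v = c(x$start_s, x$stop_s), lty = 3)
  invisible(x)
}

#' Fit the three-state model to every probe trial of a table
#'
#' @param trials a `trial_table`; only probe trials are analyzed.
#' @inheritParams three_state_fit
#' @return Data frame with one row per probe trial: identifiers,
#'   `start_s`, `stop_s`, `spread_s`, `r1`, `r2`, `r3`,
#'   `objective_value`, `qualifies`.
#' @export
three_state_trials <- function(trials,
                               constraints = three_state_constraints(),
                               objective = c("sse", "index")) {
  objective <- match.arg(objective)
  stopifnot(inherits(trials, "trial_table"))
  trials <- trials[trials$trial_type == "probe", ]
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    f <- three_state_fit(trials$press_times[[i]], constraints, objective)
    data.frame(subject_id = trials$subject_id[i],
               session_index = trials$session_index[i],
               trial_index = trials$trial_index[i],
               start_s = f$start_s, stop_s = f$stop_s,
               spread_s = f$spread_s, r1 = f$r1, r2 = f$r2, r3 = f$r3,
               objective_value = f$objective_value,
               qualifies = f$qualifies, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Block-level summary of single-trial fits
#'
#' Medians and interquartile ranges of start, stop and spread over the
#' qualifying trials of one subject and block, mean state rates, the
#' response initiation ratio (r1/r2) and suppression ratio (r3/r2)
#' computed per trial and then averaged, and the proportion of trials
#' qualifying. Quantiles use linear interpolation (R's default type 7).
#' A ratio of 1 indicates no response differentiation between states,
#' 0 perfect differentiation.
#'
#' @param results data frame from [three_state_trials()] (all trials of
#'   the block, qualifying or not), or a list of `three_state_fit`s.
#' @return List of class `block_summary`: `n_trials`, `n_qualifying`,
#'   `proportion_qualifying`, `median_start_s`, `median_stop_s`,
#'   `median_spread_s`, `iqr_start_s`, `iqr_stop_s`, `iqr_spread_s`,
#'   `mean_r1`, `mean_r2`, `mean_r3`, `initiation_ratio`,
#'   `suppression_ratio`. Fields other than counts are `NA` when no
#'   trial qualifies.
#' @export
summarize_block <- function(results) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, function(f)
      data.frame(start_s = f$start_s, stop_s = f$stop_s,
                 spread_s = f$spread_s, r1 = f$r1, r2 = f$r2, r3 = f$r3,
                 qualifies = f$qualifies)))
  stopifnot(is.data.frame(results))
  q <- results[results$qualifies, , drop = FALSE]
  n_q <- nrow(q)
  out <- list(n_trials = nrow(results), n_qualifying = n_q,
              proportion_qualifying = if (nrow(results) > 0)
                n_q / nrow(results) else NA_real_)
  if (n_q == 0) {
    out <- c(out, list(median_start_s = NA_real_, median_stop_s = NA_real_,
                       median_spread_s = NA_real_, iqr_start_s = NA_real_,
                       iqr_stop_s = NA_real_, iqr_spread_s = NA_real_,
                       mean_r1 = NA_real_, mean_r2 = NA_real_,
                       mean_r3 = NA_real_, initiation_ratio = NA_real_,
                       suppression_ratio = NA_real_))
  } else {
    out <- c(out, list(
      median_start_s = stats::median(q$start_s),
      median_stop_s = stats::median(q$stop_s),
      median_spread_s = stats::median(q$spread_s),
      iqr_start_s = stats::IQR(q$start_s),
      iqr_stop_s = stats::IQR(q$stop_s),
      iqr_spread_s = stats::IQR(q$spread_s),
      mean_r1 = mean(q$r1), mean_r2 = mean(q$r2), mean_r3 = mean(q$r3),
      # per-trial ratios averaged; r2 > r1 >= 0 on qualifying trials so
      # division is always defined
      initiation_ratio = mean(q$r1 / q$r2),
      suppression_ratio = mean(q$r3 / q$r2)))
  }
  structure(out, class = "block_summary")
}

#' @export
print.block_summary <- function(x, ...) {
  cat("Single-trial block summary:", x$n_qualifying, "of", x$n_trials,
      "trials qualify\n")
  if (x$n_qualifying > 0) {
    cat(sprintf("  median start/stop/spread: %.1f / %.1f / %.1f s\n",
                x$median_start_s, x$median_stop_s, x$median_spread_s))
    cat(sprintf("  IQR start/stop/spread: %.1f / %.1f / %.1f s\n",
                x$iqr_start_s, x$iqr_stop_s, x$iqr_spread_s))
    cat(sprintf("  mean rates r1/r2/r3: %.3f / %.3f / %.3f presses/s\n",
                x$mean_r1, x$mean_r2, x$mean_r3))
    cat(sprintf("  initiation ratio %.3f  suppression ratio %.3f\n",
                x$initiation_ratio, x$suppression_ratio))
  }
  invisible(x)
}

#' Start-stop and start-spread correlations over bracketed trials
#'
#' Pearson correlations computed over the qualifying trials whose start
#' and stop strictly bracket the criterion time (`start < fi < stop`),
#' the standard constraint for these correlations. Requires at least 3
#' bracketed trials; degenerate (zero-variance) inputs yield `NA` with a
#' note.
#'
#' @param results data frame from [three_state_trials()].
#' @param fi_s criterion (fixed-interval) time in seconds, default 30.
#' @return List: `n_bracketed`, `start_stop_r`, `start_spread_r`,
#'   `note` (`NA` or the reason a correlation is absent).
#' @export
bracketed_correlations <- function(results, fi_s = 30) {
  stopifnot(is.data.frame(results))
  q <- results[results$qualifies & results$start_s < fi_s &
                 results$stop_s > fi_s, , drop = FALSE]
  out <- list(n_bracketed = nrow(q), start_stop_r = NA_real_,
              start_spread_r = NA_real_, note = NA_character_)
  if (nrow(q) < 3) {
    out$note <- "fewer than 3 bracketed trials"
    return(out)
  }
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b)
  }
  out$start_stop_r <- safe_cor(q$start_s, q$stop_s)
  out$start_spread_r <- safe_cor(q$start_s, q$spread_s)
  if (any(is.na(c(out$start_stop_r, out$start_spread_r))))
    out$note <- "zero variance in start, stop or spread"
  out
}
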