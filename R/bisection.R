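# Temporal bisection: discrimination summaries and pseudologistic
# psychometric fitting (PSE / T50 and the gamma sensitivity parameter).

#' Pseudologistic psychometric function
#'
#' Probability of classifying a stimulus duration `t` as "long" under the
#' scalar-timing pseudologistic model with negligible constant and Poisson
#' variance components:
#' \deqn{p(\mathrm{long}\mid t) =
#'   \frac{1}{1 + \exp(-\pi (t - T_{50}) / (\sqrt{3}\,\gamma\,\sigma))}}
#' where the timing spread \eqn{\sigma} is the probe duration `t` itself
#' (Weber-proportional noise, the default) or the fixed `T50` when
#' `sigma_at = "t50"`. `gamma` is proportional to the Weber fraction:
#' larger gamma means poorer temporal sensitivity. The curve always passes
#' through 0.5 at `t = T50` (the point of subjective equality).
#'
#' @param t stimulus duration(s) in seconds, strictly positive.
#' @param T50_s point of subjective equality in seconds.
#' @param gamma positive sensitivity parameter.
#' @param sigma_at where the Weber spread is evaluated: at the probe
#'   duration `"t"` (default) or at `"t50"`.
#' @return Probabilities in (0, 1), strictly increasing in `t`.
#' @export
pseudologistic_p_long <- function(t, T50_s, gamma, sigma_at = c("t", "t50")) {
  sigma_at <- match.arg(sigma_at)
  if (any(t <= 0)) stop("stimulus durations must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  sigma <- if (sigma_at == "t") t else T50_s
  1 / (1 + exp(-pi * (t - T50_s) / (sqrt(3) * gamma * sigma)))
}

#' Per-duration choice summaries for bisection-test sessions
#'
#' Pools trials across the supplied sessions before computing proportions:
#' for each distinct stimulus duration, the number of trials, the number
#' with a response, the response probability, and the proportion of
#' "long" classifications among responded trials only.
#'
#' @param trials a `trial_table` of bisection trials (free-choice anchors
#'   and/or intermediate test trials).
#' @return Data frame of class `duration_summary` with columns
#'   `stimulus_duration_s`, `n_trials`, `n_responded`, `p_respond`,
#'   `p_long` (`NA` when no trial of that duration drew a response).
#' @export
summarize_test <- function(trials) {
  stopifnot(inherits(trials, "trial_table"))
  trials <- trials[startsWith(trials$trial_type, "bisection"), ]
  if (nrow(trials) == 0) stop("no bisection trials supplied")
  durs <- sort(unique(trials$cue_duration_s))
  out <- do.call(rbind, lapply(durs, function(d) {
    tr <- trials[trials$cue_duration_s == d, ]
    responded <- tr$chosen_lever != "none"
    n_resp <- sum(responded)
    data.frame(
      stimulus_duration_s = d,
      n_trials = nrow(tr),
      n_responded = n_resp,
      p_respond = n_resp / nrow(tr),
      p_long = if (n_resp > 0)
        mean(tr$chosen_lever[responded] == "long") else NA_real_)
  }))
  class(out) <- c("duration_summary", "data.frame")
  out
}

#' Discrimination performance over free-choice anchor trials
#'
#' Percent correct over all free-choice trials of one session (unanswered
#' trials count as not correct) and mean response latencies in
#' milliseconds, split by outcome and computed over responded trials.
#' A response is correct when the chosen lever matches the lever assigned
#' to the trial's anchor duration (short lever for the short anchor).
#'
#' @param trials free-choice bisection trials of one session.
#' @param anchors the two trained anchor durations in seconds,
#'   `c(short, long)`.
#' @return List with `session_index`, `n_trials`, `percent_correct`,
#'   `mean_latency_correct_ms`, `mean_latency_incorrect_ms` (the latter
#'   `NA` when there is no responded trial of that outcome).
#' @export
summarize_discrimination <- function(trials, anchors = c(2, 8)) {
  stopifnot(inherits(trials, "trial_table"))
  if (nrow(trials) == 0) stop("no trials supplied")
  if (!all(trials$cue_duration_s %in% anchors))
    stop("free-choice discrimination trials must use anchor durations")
  correct_lever <- ifelse(trials$cue_duration_s == anchors[1],
                          "short", "long")
  correct <- trials$chosen_lever == correct_lever
  responded <- trials$chosen_lever != "none"
  lat_ms <- trials$response_latency_s * 1000
  mean_or_na <- function(x) if (length(x) > 0) mean(x) else NA_real_
  list(session_index = trials$session_index[1],
       n_trials = nrow(trials),
       percent_correct = 100 * mean(correct),
       mean_latency_correct_ms = mean_or_na(lat_ms[responded & correct]),
       mean_latency_incorrect_ms = mean_or_na(lat_ms[responded & !correct]))
}

#' Fit the pseudologistic psychometric model to bisection data
#'
#' Estimates the point of subjective equality (`T50_s`) and the
#' sensitivity parameter `gamma` from per-duration proportions of "long"
#' responses. The default objective is unweighted least squares on the
#' per-duration proportions (matching the R-squared semantics of standard
#' curve-fitting software); binomial maximum likelihood on the responded
#' counts is available with `objective = "ml"`. Durations with no
#' responded trial are excluded from the fit rather than imputed.
#'
#' Optimization is bounded L-BFGS-B seeded from the best point of a
#' coarse (T50, gamma) grid; T50 is constrained to the observed duration
#' range and gamma to (1e-3, 2).
#'
#' @param data a `duration_summary` (from [summarize_test()]) or a
#'   `trial_table` of bisection trials, which is summarized first.
#' @param objective `"ls"` (least squares on proportions, default) or
#'   `"ml"` (binomial likelihood).
#' @param weights `"none"` (default) or `"trials"` to weight each
#'   duration's squared residual by its responded-trial count.
#' @param sigma_at passed to [pseudologistic_p_long()].
#' @param threshold usable-fit R-squared threshold, see [classify_fit()].
#' @return An object of class `bisection_fit` with components
#'   `coefficients` (`T50_s`, `gamma`), `r_squared`, `converged`,
#'   `usable`, `per_duration` (the summaries used), `objective`,
#'   `sigma_at`. Supports `print`, `summary`, `coef`, `predict`, `plot`,
#'   `fitted`, `residuals`.
#' @examples
#' s <- summarize_test(simulate_bisection_subject("r1", seed = 1))
#' fit <- fit_pseudologistic(s)
#' coef(fit)
#' predict(fit, newdata = c(2.5, 4, 6.3))
#' @export
fit_pseudologistic <- function(data, objective = c("ls", "ml"),
                               weights = c("none", "trials"),
                               sigma_at = c("t", "t50"),
                               threshold = 0.5) {
  objective <- match.arg(objective)
  weights <- match.arg(weights)
  sigma_at <- match.arg(sigma_at)
  if (inherits(data, "trial_table")) data <- summarize_test(data)
  stopifnot(is.data.frame(data),
            all(c("stimulus_duration_s", "p_long") %in% names(data)))
  d <- data[!is.na(data$p_long), , drop = FALSE]
  if (nrow(d) < 4)
    stop("need at least 4 distinct durations with responded trials")
  t <- d$stimulus_duration_s
  p <- d$p_long
  n <- if ("n_responded" %in% names(d)) d$n_responded else rep(1, nrow(d))
  w <- if (weights == "trials") n else rep(1, nrow(d))

  loss <- function(par) {
    pr <- pseudologistic_p_long(t, par[1], par[2], sigma_at)
    if (objective == "ls") sum(w * (p - pr)^2)
    else {
      # binomial deviance on responded counts
      k <- p * n
      eps <- 1e-12
      -2 * sum(k * log(pr + eps) + (n - k) * log(1 - pr + eps))
    }
  }
  lower <- c(min(t), 1e-3)
  upper <- c(max(t), 2)
  # coarse grid start guards against local optima in flat likelihoods
  grid <- expand.grid(T50 = exp(seq(log(min(t)), log(max(t)),
                                    length.out = 15))[2:14],
                      gamma = c(0.05, 0.1, 0.2, 0.3, 0.5, 0.8, 1.2))
  gv <- apply(grid, 1, loss)
  start <- as.numeric(grid[which.min(gv), ])
  geo <- sqrt(min(t) * max(t))
  if (loss(c(geo, 0.3)) < min(gv)) start <- c(geo, 0.3)
  opt <- stats::optim(start, loss, method = "L-BFGS-B",
                      lower = lower + c(1e-6, 0), upper = upper)
  if (opt$convergence != 0) {
    # the L-BFGS-B line search can abort when started at (or carried
    # into) a numerically exact minimum; verify with a derivative-free
    # polish and accept the point if it cannot be improved
    clamp <- function(par) pmin(pmax(par, lower + c(1e-6, 0)), upper)
    nm <- stats::optim(opt$par, function(par) loss(clamp(par)),
                       method = "Nelder-Mead",
                       control = list(maxit = 500))
    if (nm$value < opt$value)
      opt <- list(par = clamp(nm$par), value = nm$value,
                  convergence = opt$convergence)
    if (nm$value >= opt$value - 1e-10 * (1 + abs(opt$value)))
      opt$convergence <- 0
  }
  pr_hat <- pseudologistic_p_long(t, opt$par[1], opt$par[2], sigma_at)
  sse <- sum((p - pr_hat)^2)
  sst <- sum((p - mean(p))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  fit <- structure(list(
    coefficients = c(T50_s = opt$par[1], gamma = opt$par[2]),
    r_squared = r2,
    converged = opt$convergence == 0,
    usable = NA,
    per_duration = d,
    objective = objective, weights = weights, sigma_at = sigma_at,
    threshold = threshold,
    value = opt$value),
    class = "bisection_fit")
  fit$usable <- classify_fit(fit, threshold)
  if (!fit$converged)
    warning("psychometric fit did not converge; parameters are reported ",
            "but flagged")
  fit
}

#' Usability gate for a psychometric fit
#'
#' A fit is usable when it converged and its R-squared strictly exceeds
#' the threshold; fits with R-squared at or below the threshold are
#' excluded from parameter analyses (inclusive exclusion at the bound).
#'
#' @param fit a `bisection_fit`.
#' @param threshold R-squared exclusion threshold (default 0.5).
#' @return Logical.
#' @export
classify_fit <- function(fit, threshold = 0.5) {
  stopifnot(inherits(fit, "bisection_fit"))
  isTRUE(fit$converged) && !is.na(fit$r_squared) &&
    fit$r_squared > threshold
}

#' @export
coef.bisection_fit <- function(object, ...) object$coefficients

#' @export
predict.bisection_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$per_duration$stimulus_duration_s
  else if (is.data.frame(newdata)) newdata[[1]]
  else as.numeric(newdata)
  pseudologistic_p_long(t, object$coefficients[["T50_s"]],
                        object$coefficients[["gamma"]], object$sigma_at)
}

#' @export
fitted.bisection_fit <- function(object, ...) predict(object)

#' @export
residuals.bisection_fit <- function(object, ...)
  object$per_duration$p_long - fitted(object)

#' @export
print.bisection_fit <- function(x, ...) {
  cat("Pseudologistic psychometric fit\n")
  cat(sprintf("  T50 (PSE): %.3f s   gamma: %.4f\n",
              x$coefficients[["T50_s"]], x$coefficients[["gamma"]]))
  cat(sprintf("  R-squared: %.4f   converged: %s   usable: %s\n",
              x$r_squared, x$converged, x$usable))
  invisible(x)
}

#' @export
summary.bisection_fit <- function(object, ...) {
  print(object)
  cat("  objective:", object$objective, "  sigma at:", object$sigma_at,
      "\n  per-duration data:\n")
  df <- object$per_duration
  df$fitted <- fitted(object)
  print(format(df, digits = 3), row.names = FALSE)
  invisible(object)
}

#' @export
plot.bisection_fit <- function(x, ...) {
  d <- x$per_duration
  tt <- seq(min(d$stimulus_duration_s), max(d$stimulus_duration_s),
            length.out = 200)
  graphics::plot(d$stimulus_duration_s, d$p_long, log = "x",
                 xlab = "Stimulus duration (s)", ylab = "p(long)",
                 ylim = c(0, 1), pch = 19, ...)
  graphics::lines(tt, predict(x, tt))
  graphics::abline(h = 0.5, v = x$coefficients[["T50_s"]], lty = 3)
  invisible(x)
}

#' Fit psychometric functions for every subject in a trial table
#'
#' @param trials a `trial_table` of bisection trials for one or more
#'   subjects; trials are pooled across sessions within subject.
#' @param ... passed to [fit_pseudologistic()].
#' @return Data frame, one row per subject: `subject_id`, `T50_s`,
#'   `gamma`, `r_squared`, `converged`, `usable`.
#' @export
fit_bisection_subjects <- function(trials, ...) {
  stopifnot(inherits(trials, "trial_table"))
  subjects <- unique(trials$subject_id)
  do.call(rbind, lapply(subjects, function(s) {
    fit <- fit_pseudologistic(trials[trials$subject_id == s, ], ...)
    data.frame(subject_id = s,
               T50_s = fit$coefficients[["T50_s"]],
               gamma = fit$coefficients[["gamma"]],
               r_squared = fit$r_squared,
               converged = fit$converged,
               usable = fit$usable,
               stringsAsFactors = FALSE)
  }))
}
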