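# Molar peak-interval analysis: block-averaged response-rate curves,
# temporal discrimination index, and Gaussian + ramp fitting.

#' Block-averaged molar response-rate curve
#'
#' Averages probe-trial lever pressing of a two-session block into a mean
#' response-rate curve: presses per 2-s bin per trial, divided by the bin
#' width to give presses per second.
#'
#' @param trials probe trials of the block (a `trial_table`; FI trials
#'   are rejected — only probe trials enter molar curves).
#' @param bin_width_s bin width, 2 s by convention.
#' @param window_s probe window, 90 s.
#' @param block_id optional block label (e.g. the pair of session indices).
#' @return A `molar_curve`: list with `bin_centers_s`, `rate_per_s`,
#'   `n_trials`, `bin_width_s`, `window_s`, `block_id`.
#' @export
average_block <- function(trials, bin_width_s = 2, window_s = 90,
                          block_id = NULL) {
  stopifnot(inherits(trials, "trial_table"))
  if (nrow(trials) == 0) stop("empty block: no probe trials supplied")
  if (!all(trials$trial_type == "probe"))
    stop("molar curves are computed over probe trials only")
  counts <- bin_trials(trials, bin_width_s, window_s)
  rate <- colMeans(counts) / bin_width_s
  n_bins <- ncol(counts)
  structure(list(
    bin_centers_s = (seq_len(n_bins) - 0.5) * bin_width_s,
    rate_per_s = as.numeric(rate),
    n_trials = nrow(trials),
    bin_width_s = bin_width_s, window_s = window_s,
    block_id = block_id),
    class = "molar_curve")
}

#' @export
print.molar_curve <- function(x, ...) {
  cat("Molar response-rate curve:", length(x$rate_per_s), "bins of",
      x$bin_width_s, "s over", x$n_trials, "probe trials\n")
  cat(sprintf("  peak bin rate %.3f presses/s at %.0f s; mean %.3f\n",
              max(x$rate_per_s),
              x$bin_centers_s[which.max(x$rate_per_s)],
              mean(x$rate_per_s)))
  invisible(x)
}

#' @export
plot.molar_curve <- function(x, ...) {
  graphics::plot(x$bin_centers_s, x$rate_per_s, type = "s",
                 xlab = "Time from cue onset (s)",
                 ylab = "Responses per second", ...)
  invisible(x)
}

#' Temporal discrimination index of a molar curve
#'
#' Maximum response rate divided by the mean response rate; 1 for a flat
#' curve, larger as responding concentrates around the criterion time.
#'
#' @param curve a `molar_curve`.
#' @return Scalar `>= 1`.
#' @export
discrimination_index <- function(curve) {
  stopifnot(inherits(curve, "molar_curve"))
  m <- mean(curve$rate_per_s)
  if (m == 0) stop("discrimination index undefined for an all-zero curve")
  max(curve$rate_per_s) / m
}

#' Gaussian + ramp response-rate model
#'
#' \deqn{R(t) = a\,\exp(-\tfrac12 ((t - t_0)/b)^2) + c\,(t - t_0) + d}
#' The Gaussian component carries the timed response (center `t0`,
#' spread `b`); the linear ramp absorbs the slow drift in baseline
#' responding across the probe.
#'
#' @param t time(s) in seconds.
#' @param a Gaussian amplitude (presses/s).
#' @param t0 Gaussian center, the peak time (s).
#' @param b Gaussian standard deviation (s), strictly positive.
#' @param c ramp slope (presses/s per s).
#' @param d offset (presses/s).
#' @return Model rate at `t`.
#' @export
gaussian_ramp <- function(t, a, t0, b, c, d) {
  if (b <= 0) stop("Gaussian width b must be positive")
  a * exp(-0.5 * ((t - t0) / b)^2) + c * (t - t0) + d
}

#' Fit the Gaussian + ramp model to a molar curve
#'
#' Least-squares fit of [gaussian_ramp()] over the curve's bins via
#' bounded Levenberg-Marquardt ([minpack.lm::nlsLM()]), started from the
#' curve's argmax (t0), b = 10 s, d = minimum rate, c = 0,
#' a = max - min; t0 is bounded to the probe window and b to (0.5, 90) s.
#' If the bounded fit fails, a Nelder-Mead fallback on the same objective
#' is tried; a flat or degenerate curve is returned with
#' `converged = FALSE`.
#'
#' Reported peak time is the Gaussian center `t0` (the component the
#' width is read from), not the argmax of the composite curve; set
#' `peak_time = "argmax"` for the composite maximum. Width is twice the
#' Gaussian standard deviation and the coefficient of variation is
#' width / peak time.
#'
#' @param curve a `molar_curve`.
#' @param peak_time `"center"` (default) or `"argmax"`.
#' @return An object of class `peak_fit`: `coefficients`
#'   (`a`, `t0`, `b`, `c`, `d`), `peak_time_s`, `peak_rate_per_s`,
#'   `width_s` (= 2b), `cv` (= width / peak time), `r_squared`,
#'   `converged`, and the `curve`. Supports `print`, `summary`, `coef`,
#'   `predict`, `plot`, `fitted`, `residuals`.
#' @export
fit_gaussian_ramp <- function(curve, peak_time = c("center", "argmax")) {
  peak_time <- match.arg(peak_time)
  stopifnot(inherits(curve, "molar_curve"))
  t <- curve$bin_centers_s
  y <- curve$rate_per_s
  make_result <- function(par, converged) {
    yhat <- gaussian_ramp(t, par[1], par[2], par[3], par[4], par[5])
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum((y - yhat)^2) / sst else NA_real_
    t0 <- par[2]
    pt <- if (peak_time == "center") t0 else {
      tt <- seq(0, curve$window_s, by = 0.01)
      tt[which.max(gaussian_ramp(tt, par[1], par[2], par[3], par[4],
                                 par[5]))]
    }
    structure(list(
      coefficients = c(a = par[1], t0 = par[2], b = par[3],
                       c = par[4], d = par[5]),
      peak_time_s = pt,
      peak_rate_per_s = gaussian_ramp(pt, par[1], par[2], par[3],
                                      par[4], par[5]),
      width_s = 2 * par[3],
      cv = 2 * par[3] / pt,
      r_squared = r2,
      converged = converged,
      peak_time_def = peak_time,
      curve = curve),
      class = "peak_fit")
  }
  if (max(y) == min(y))  # flat curve: the Gaussian component is undefined
    return(make_result(c(0, t[which.max(y)], 10, 0, mean(y)), FALSE))
  start <- list(a = max(y) - min(y), t0 = t[which.max(y)], b = 10,
                c = 0, d = min(y))
  lower <- c(a = 0, t0 = 0, b = 0.5, c = -Inf, d = -Inf)
  upper <- c(a = Inf, t0 = curve$window_s, b = 90, c = Inf, d = Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-0.5 * ((t - t0) / b)^2) +
                        c * (t - t0) + d,
                      data = data.frame(t = t, y = y),
                      start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit))
    return(make_result(as.numeric(stats::coef(fit)), TRUE))
  obj <- function(par) {
    if (par[3] <= 0) return(Inf)
    sum((y - gaussian_ramp(t, par[1], par[2], par[3], par[4], par[5]))^2)
  }
  opt <- stats::optim(unlist(start), obj,
                      control = list(maxit = 2000))
  make_result(opt$par, opt$convergence == 0 && opt$par[3] > 0)
}

#' @export
coef.peak_fit <- function(object, ...) object$coefficients

#' @export
predict.peak_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$curve$bin_centers_s
  else if (is.data.frame(newdata)) newdata[[1]]
  else as.numeric(newdata)
  p <- object$coefficients
  gaussian_ramp(t, p[["a"]], p[["t0"]], p[["b"]], p[["c"]], p[["d"]])
}

#' @export
fitted.peak_fit <- function(object, ...) predict(object)

#' @export
residuals.peak_fit <- function(object, ...)
  object$curve$rate_per_s - fitted(object)

#' @export
print.peak_fit <- function(x, ...) {
  cat("Gaussian + ramp peak fit\n")
  cat(sprintf("  peak time %.2f s  peak rate %.3f/s  width %.2f s  CV %.3f\n",
              x$peak_time_s, x$peak_rate_per_s, x$width_s, x$cv))
  cat(sprintf("  R-squared %.4f  converged: %s\n", x$r_squared,
              x$converged))
  invisible(x)
}

#' @export
summary.peak_fit <- function(object, ...) {
  print(object)
  cat("  coefficients:\n")
  print(round(object$coefficients, 5))
  invisible(object)
}

#' @export
plot.peak_fit <- function(x, ...) {
  plot(x$curve, ...)
  tt <- seq(0, x$curve$window_s, length.out = 400)
  graphics::lines(tt, predict(x, tt), col = 2, lwd = 2)
  graphics::abline(v = x$peak_time_s, lty = 3)
  invisible(x)
}

#' Proportion of probe trials with at least one response
#'
#' @param trials probe trials of one session (a `trial_table`).
#' @return Fraction in \[0, 1\].
#' @export
response_proportion <- function(trials) {
  stopifnot(inherits(trials, "trial_table"))
  trials <- trials[trials$trial_type == "probe", ]
  if (nrow(trials) == 0) stop("no probe trials supplied")
  mean(vapply(trials$press_times, length, integer(1)) > 0)
}
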