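# Seeded generative models of bisection and peak-interval behavior.
# These define the simulated study conditions used throughout the test
# suite: every analysis stage is validated by recovering the generating
# parameters from this module's output.

#' Bisection test-session design
#'
#' Default design of one bisection test session: anchors at 2 and 8 s
#' (60 reinforced free-choice trials each) plus five intermediate probe
#' durations (2.5, 3.2, 4, 5, 6.3 s; 12 unreinforced test trials each),
#' i.e. two randomized blocks of 90 trials.
#'
#' @param anchor_s the two anchor durations (seconds).
#' @param n_anchor trials per anchor.
#' @param intermediate_s intermediate probe durations (seconds).
#' @param n_intermediate trials per intermediate duration.
#' @return Data frame with `duration_s`, `n_trials`, `trial_type`.
#' @export
bisection_design <- function(anchor_s = c(2, 8), n_anchor = 60,
                             intermediate_s = c(2.5, 3.2, 4, 5, 6.3),
                             n_intermediate = 12) {
  rbind(
    data.frame(duration_s = anchor_s, n_trials = n_anchor,
               trial_type = "bisection_free"),
    data.frame(duration_s = intermediate_s, n_trials = n_intermediate,
               trial_type = "bisection_test"))
}

# lognormal with a given mean and coefficient of variation
.rlnorm_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate one subject's bisection test session
#'
#' Choices are Bernoulli draws with success probability
#' [pseudologistic_p_long()] at the trial's duration; a trial is omitted
#' (no response) with probability `omit_prob`. Response latency is
#' lognormal from cue offset; correct anchor responses are reinforced.
#' Trial order is randomized over the whole design.
#'
#' @param subject_id subject label.
#' @param T50_s,gamma generating psychometric parameters.
#' @param omit_prob trial-level probability of response omission.
#' @param design a [bisection_design()] data frame.
#' @param session_index session number for the event log.
#' @param latency_mean_s,latency_cv lognormal response-latency model.
#' @param seed integer seed; identical seeds give identical logs.
#' @param sigma_at passed to [pseudologistic_p_long()].
#' @return A `trial_table` with a `truth` attribute recording the
#'   generating parameters.
#' @export
simulate_bisection_subject <- function(subject_id = "s1", T50_s = 4,
                                       gamma = 0.2, omit_prob = 0,
                                       design = bisection_design(),
                                       session_index = 1,
                                       latency_mean_s = 0.5,
                                       latency_cv = 0.4,
                                       seed = NULL,
                                       sigma_at = "t") {
  if (omit_prob < 0 || omit_prob > 1) stop("omit_prob must be in [0, 1]")
  if (gamma <= 0 || T50_s <= 0) stop("T50_s and gamma must be positive")
  if (!is.null(seed)) set.seed(seed)
  durs <- rep(design$duration_s, design$n_trials)
  types <- rep(design$trial_type, design$n_trials)
  ord <- sample.int(length(durs))
  durs <- durs[ord]; types <- types[ord]
  n <- length(durs)
  omitted <- stats::runif(n) < omit_prob
  p <- pseudologistic_p_long(durs, T50_s, gamma, sigma_at)
  long <- stats::runif(n) < p
  latency <- .rlnorm_cv(n, latency_mean_s, latency_cv)
  lever <- ifelse(omitted, "none", ifelse(long, "long", "short"))
  anchors <- design$duration_s[design$trial_type == "bisection_free"]
  correct_lever <- ifelse(durs == min(anchors), "short",
                          ifelse(durs == max(anchors), "long", NA))
  reinforced <- !omitted & types == "bisection_free" &
    lever == correct_lever & !is.na(correct_lever)
  press_times <- lapply(seq_len(n), function(i) {
    if (omitted[i]) numeric(0) else durs[i] + latency[i]
  })
  out <- trial_table(subject_id, session_index, seq_len(n), types, durs,
                     press_times, chosen_lever = lever,
                     response_latency_s = ifelse(omitted, NA_real_,
                                                 latency),
                     reinforced = reinforced)
  attr(out, "truth") <- list(T50_s = T50_s, gamma = gamma,
                             omit_prob = omit_prob, seed = seed)
  out
}

#' Generative parameters of the peak-interval simulator
#'
#' The per-trial timing model is the scalar two-threshold account: a
#' remembered criterion sample `m` is drawn lognormally with mean `fi_s`
#' and coefficient of variation `memory_cv`; the trial's high-state
#' boundaries are `start = start_threshold * m * j1` and
#' `stop = stop_threshold * m * j2` with independent multiplicative
#' lognormal jitters (`threshold_jitter_cv`) on each threshold. Because
#' every timing quantity is multiplicative in the criterion, start-time
#' variability scales with the interval timed (the scalar property).
#' Within each state, presses are a homogeneous Poisson process at that
#' state's rate.
#'
#' @param fi_s fixed-interval criterion (s).
#' @param probe_window_s probe-trial tone duration (s).
#' @param fi_tone_max_s maximum FI-trial tone duration (s).
#' @param memory_cv coefficient of variation of the remembered criterion.
#' @param start_threshold,stop_threshold multipliers of the criterion
#'   sample giving the high-state boundaries (`start < stop` required).
#' @param threshold_jitter_cv CV of the independent per-trial jitter on
#'   each threshold.
#' @param r1,r2,r3 press rates (per second) in the initial-low, high and
#'   final-low states.
#' @param omit_prob probability a probe trial draws no responding at all.
#' @param n_fi,n_probe trial counts per session.
#' @param iti_range_s uniform inter-trial-interval range (s).
#' @return A `peak_gen_params` list.
#' @export
peak_gen_params <- function(fi_s = 30, probe_window_s = 90,
                            fi_tone_max_s = 60,
                            memory_cv = 0.2,
                            start_threshold = 0.7, stop_threshold = 1.5,
                            threshold_jitter_cv = 0.3,
                            r1 = 0.1, r2 = 1.5, r3 = 0.1,
                            omit_prob = 0.05,
                            n_fi = 37, n_probe = 18,
                            iti_range_s = c(10, 30)) {
  if (start_threshold >= stop_threshold)
    stop("start_threshold must be below stop_threshold")
  stopifnot(fi_s > 0, probe_window_s > fi_s, memory_cv >= 0,
            omit_prob >= 0, omit_prob <= 1, r1 >= 0, r2 >= 0, r3 >= 0)
  structure(as.list(environment()), class = "peak_gen_params")
}

#' Stress-session perturbation
#'
#' Stress is modelled as parameter perturbation: omission probability,
#' psychometric gamma and response rates are multiplied by the given
#' factors, and `n_shocks` foot-shock events are logged in inter-trial
#' intervals at least 10 s before the following cue onset. Shock events
#' are recorded so pipelines can locate them; analyses ignore them apart
#' from session labelling.
#'
#' @param n_shocks number of inter-trial foot-shocks.
#' @param omit_prob_multiplier,gamma_multiplier,rate_multiplier
#'   nonnegative perturbation factors.
#' @param min_gap_s minimum time between a shock and the next cue onset.
#' @param shock_amp_label metadata label (e.g. "0.25 mA, 0.5 s").
#' @return A `stress_config` list.
#' @export
stress_config <- function(n_shocks = 10, omit_prob_multiplier = 4,
                          gamma_multiplier = 1.5, rate_multiplier = 0.8,
                          min_gap_s = 10,
                          shock_amp_label = "0.25 mA, 0.5 s") {
  stopifnot(omit_prob_multiplier >= 0, gamma_multiplier >= 0,
            rate_multiplier >= 0)
  structure(as.list(environment()), class = "stress_config")
}

# draw one trial's piecewise-Poisson press train over [0, horizon)
.piecewise_poisson <- function(start, stop, horizon, r1, r2, r3) {
  seg <- rbind(c(0, min(start, horizon), r1),
               c(min(start, horizon), min(stop, horizon), r2),
               c(min(stop, horizon), horizon, r3))
  presses <- numeric(0)
  for (k in 1:3) {
    len <- seg[k, 2] - seg[k, 1]
    if (len <= 0 || seg[k, 3] <= 0) next
    m <- stats::rpois(1, seg[k, 3] * len)
    if (m > 0)
      presses <- c(presses, seg[k, 1] + sort(stats::runif(m, 0, len)))
  }
  sort(presses)
}

#' Simulate one peak-interval session
#'
#' FI and probe trials are shuffled together. On FI trials the tone lasts
#' at most `fi_tone_max_s` and the first press at or after `fi_s` is
#' reinforced and ends the trial; on probe trials the tone runs the full
#' `probe_window_s` unreinforced. Responding follows the low-high-low
#' generative model of [peak_gen_params()]. With a [stress_config()],
#' omission and rates are perturbed and shock events are interleaved in
#' ITIs respecting the minimum gap before a cue.
#'
#' @param subject_id subject label.
#' @param params a [peak_gen_params()] object.
#' @param stress optional [stress_config()].
#' @param session_index session number.
#' @param seed integer seed.
#' @return A `trial_table`; attribute `truth` is a data frame of the
#'   generative per-trial start/stop (probe trials; `NA` for omitted).
#' @export
simulate_peak_session <- function(subject_id = "s1",
                                  params = peak_gen_params(),
                                  stress = NULL, session_index = 1,
                                  seed = NULL) {
  stopifnot(inherits(params, "peak_gen_params"))
  if (!is.null(seed)) set.seed(seed)
  omit_prob <- params$omit_prob
  r <- c(params$r1, params$r2, params$r3)
  if (!is.null(stress)) {
    stopifnot(inherits(stress, "stress_config"))
    omit_prob <- min(1, omit_prob * stress$omit_prob_multiplier)
    r <- r * stress$rate_multiplier
  }
  n <- params$n_fi + params$n_probe
  types <- sample(c(rep("fi", params$n_fi),
                    rep("probe", params$n_probe)))
  itis <- stats::runif(n, params$iti_range_s[1], params$iti_range_s[2])
  shock_trials <- integer(0)
  if (!is.null(stress) && stress$n_shocks > 0)
    shock_trials <- sort(sample.int(n, min(stress$n_shocks, n)))
  press_times <- vector("list", n)
  shock_times <- rep(list(numeric(0)), n)
  reinforced <- logical(n)
  cue_dur <- numeric(n)
  truth <- data.frame(trial_index = seq_len(n), trial_type = types,
                      gen_start_s = NA_real_, gen_stop_s = NA_real_,
                      omitted = FALSE)
  for (i in seq_len(n)) {
    # per-trial scalar timing sample and jittered thresholds;
    # redraw on the rare jitter crossing so start < stop by construction
    repeat {
      m <- .rlnorm_cv(1, params$fi_s, params$memory_cv)
      j1 <- .rlnorm_cv(1, 1, params$threshold_jitter_cv)
      j2 <- .rlnorm_cv(1, 1, params$threshold_jitter_cv)
      start <- params$start_threshold * m * j1
      stop_t <- params$stop_threshold * m * j2
      if (start < stop_t) break
    }
    start <- min(start, params$probe_window_s)
    stop_t <- min(stop_t, params$probe_window_s)
    omitted <- stats::runif(1) < omit_prob
    if (types[i] == "probe") {
      cue_dur[i] <- params$probe_window_s
      press_times[[i]] <- if (omitted) numeric(0)
      else .piecewise_poisson(start, stop_t, params$probe_window_s,
                              r[1], r[2], r[3])
      truth$gen_start_s[i] <- start
      truth$gen_stop_s[i] <- stop_t
      truth$omitted[i] <- omitted
    } else {
      p <- if (omitted) numeric(0)
      else .piecewise_poisson(start, stop_t, params$fi_tone_max_s,
                              r[1], r[2], r[3])
      hit <- p[p >= params$fi_s]
      if (length(hit) > 0) {
        reinforced[i] <- TRUE
        cue_dur[i] <- hit[1]
        press_times[[i]] <- p[p <= hit[1]]
      } else {
        cue_dur[i] <- params$fi_tone_max_s
        press_times[[i]] <- p
      }
    }
    if (i %in% shock_trials)
      shock_times[[i]] <- -stats::runif(1, stress$min_gap_s,
                                        max(itis[i], stress$min_gap_s +
                                              0.5))
  }
  out <- trial_table(subject_id, session_index, seq_len(n), types,
                     cue_dur, press_times, reinforced = reinforced,
                     shock_times = shock_times)
  attr(out, "truth") <- truth
  attr(out, "params") <- params
  out
}

#' Simulate a multi-subject peak-interval study
#'
#' Child seeds are derived deterministically from the root seed by
#' subject index, so per-subject streams are independent and the whole
#' study is reproducible from one integer.
#'
#' @param n_subjects number of subjects.
#' @param n_sessions sessions per subject.
#' @param params a [peak_gen_params()].
#' @param stress optional [stress_config()] applied to every session.
#' @param seed root integer seed.
#' @return List with `trials` (combined `trial_table`) and `truth`
#'   (combined generative data frame with subject and session columns).
#' @export
simulate_peak_study <- function(n_subjects = 20, n_sessions = 2,
                                params = peak_gen_params(),
                                stress = NULL, seed = 1) {
  all_trials <- list(); all_truth <- list()
  for (i in seq_len(n_subjects)) {
    for (s in seq_len(n_sessions)) {
      child <- (seed + 7919L * i + 104729L * s) %% .Machine$integer.max
      tt <- simulate_peak_session(sprintf("sim%02d", i), params, stress,
                                  session_index = s, seed = child)
      tr <- attr(tt, "truth")
      tr$subject_id <- sprintf("sim%02d", i)
      tr$session_index <- s
      all_trials[[length(all_trials) + 1L]] <- tt
      all_truth[[length(all_truth) + 1L]] <- tr
    }
  }
  trials <- do.call(rbind, all_trials)
  class(trials) <- c("trial_table", "data.frame")
  list(trials = trials, truth = do.call(rbind, all_truth))
}

#' Generative scalar-property check
#'
#' Draws `n` generative start times at each criterion duration and
#' reports their coefficient of variation with a Monte-Carlo standard
#' error. Under the multiplicative timing model the CV is invariant to
#' the criterion (the scalar property); with zero memory noise and zero
#' jitter it is exactly 0.
#'
#' @param params a [peak_gen_params()]; its `fi_s` is overridden by each
#'   value of `fi_values_s`.
#' @param fi_values_s criterion durations to probe (seconds).
#' @param n start times drawn per criterion (>= 100).
#' @param seed integer seed.
#' @return Data frame: `fi_s`, `n`, `mean_start_s`, `cv_start`,
#'   `cv_se` (asymptotic Monte-Carlo standard error of the CV).
#' @export
scalar_property_check <- function(params = peak_gen_params(),
                                  fi_values_s = c(15, 30, 60),
                                  n = 5000, seed = 1) {
  stopifnot(n >= 100)
  set.seed(seed)
  rows <- lapply(fi_values_s, function(fi) {
    m <- .rlnorm_cv(n, fi, params$memory_cv)
    j <- .rlnorm_cv(n, 1, params$threshold_jitter_cv)
    start <- params$start_threshold * m * j
    mu <- mean(start)
    s <- stats::sd(start)
    cv <- s / mu
    # delta-method (influence function) standard error of the sample
    # CV; valid for any parent distribution, unlike the normal-theory
    # formula, which understates the error for skewed draws
    se <- if (s == 0) 0 else {
      psi <- ((start - mu)^2 - s^2) / (2 * s * mu) -
        s * (start - mu) / mu^2
      stats::sd(psi) / sqrt(n)
    }
    data.frame(fi_s = fi, n = n, mean_start_s = mu,
               cv_start = cv, cv_se = se)
  })
  do.call(rbind, rows)
}
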