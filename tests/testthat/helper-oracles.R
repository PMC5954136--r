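# Independent oracles and small fixture builders used across tests.

# Naive exhaustive three-state search: a deliberately plain double loop
# that recomputes every segment sum from scratch, with the same
# tie-breaking rule as the production search (earliest start, then
# earliest stop, strict improvement beyond a small tolerance).
naive_three_state <- function(counts, min_low = 1L, min_high = 4L,
                              objective = "sse") {
  n <- length(counts)
  xbar <- mean(counts)
  best_q <- -Inf
  best <- NULL
  tol <- 1e-9
  for (s in seq_len(n)) {
    if (s - 1 < min_low) next
    for (e in s:n) {
      if (e - s + 1 < min_high) next
      if (n - e < min_low) next
      sum1 <- sum(counts[seq_len(s - 1)])
      sum2 <- sum(counts[s:e])
      sum3 <- sum(counts[seq(e + 1, n)])
      len1 <- s - 1; len2 <- e - s + 1; len3 <- n - e
      q <- if (objective == "sse") {
        sum1^2 / len1 + sum2^2 / len2 + sum3^2 / len3
      } else {
        len1 * (xbar - sum1 / len1) + len2 * (sum2 / len2 - xbar) +
          len3 * (xbar - sum3 / len3)
      }
      if (q > best_q + tol) {
        best_q <- q
        best <- c(s, e)
      }
    }
  }
  list(start_bin = best[1], stop_bin = best[2],
       start_s = best[1] - 1, stop_s = best[2] - 1,
       q = best_q)
}

# single-trial table wrapper for a vector of press times
press_trial <- function(press, type = "probe", cue = 90, id = "t1",
                        trial = 1L) {
  trial_table(id, 1L, trial, type, cue, list(press))
}

# a synthetic molar curve directly from a rate vector
make_curve <- function(rate, bin_width_s = 2, window_s = 90,
                       n_trials = 1) {
  structure(list(
    bin_centers_s = (seq_along(rate) - 0.5) * bin_width_s,
    rate_per_s = as.numeric(rate), n_trials = n_trials,
    bin_width_s = bin_width_s, window_s = window_s, block_id = NULL),
    class = "molar_curve")
}
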