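# titrate

Analysis of rodent interval-timing experiments: temporal-bisection
psychometrics, peak-interval molar curves, and single-trial
change-point decomposition of timed responding — with a seeded
generative model of both tasks for validating every estimator by
parameter recovery.

## Who this is for

Behavioral neuroscientists and psychophysicists running the two
classic interval-timing procedures in operant chambers:

* **Temporal bisection** — animals classify tone durations as closer
  to a trained short (2 s) or long (8 s) anchor; intermediate probe
  durations (2.5, 3.2, 4, 5, 6.3 s) trace out a psychometric function
  of p(long) versus duration.
* **Peak interval (PI)** — fixed-interval (FI 30 s) reinforced trials
  are intermixed with long (90 s) unreinforced probe trials; averaged
  probe responding peaks near the criterion time, and single trials
  show an abrupt low–high–low response pattern.

The package takes long-format event logs (one CSV row per
time-stamped event) and produces tidy per-subject parameter tables
ready for whatever group-level statistics you run elsewhere.

## The models

**Bisection.** Choice data are fitted with the pseudologistic
psychometric function of scalar expectancy theory, with constant and
Poisson variance components set to zero:

```
p(long | t) = 1 / (1 + exp(-π (t − T50) / (√3 · γ · t)))
```

`T50` is the point of subjective equality (PSE, the duration judged
equally often short and long) and `γ` (gamma) is proportional to the
Weber fraction — larger gamma, poorer temporal sensitivity. Fits with
R² ≤ 0.5 are flagged unusable, mirroring standard exclusion practice.

**Molar PI analysis.** Probe-trial pressing is averaged in 2-s bins
across each two-session block (36 probe trials). A temporal
discrimination index (max rate / mean rate) tracks acquisition, and
the final block is fitted with a Gaussian + linear ramp,

```
R(t) = a·exp(−((t − t0)² / 2b²)) + c·(t − t0) + d
```

yielding peak time `t0`, peak rate `R(t0)`, width `2b` (twice the
Gaussian SD) and coefficient of variation `2b / t0`.

**Single-trial analysis.** Each probe trial's 1-s binned pressing is
decomposed into a low–high–low three-state profile by exhaustive
change-point search (minimum high-state duration 4 s, minimum
low-state durations 1 s), minimizing the residual sum of squares of
the piecewise-constant rate model. The first and last high-state bins
give the trial's start and stop times; spread = stop − start. Trials
qualify only when the high rate strictly exceeds both low rates
(r2 > r1, r2 > r3). Per block the package reports medians and IQRs of
start/stop/spread, mean state rates, the response initiation (r1/r2)
and suppression (r3/r2) ratios, and Pearson start–stop and
start–spread correlations over trials bracketing the criterion.

## Worked example

```r
library(titrate)

## two simulated bisection test sessions for one subject
s1 <- simulate_bisection_subject("rat01", T50_s = 4, gamma = 0.2, seed = 42)
s2 <- simulate_bisection_subject("rat01", T50_s = 4, gamma = 0.2,
                                 session_index = 2, seed = 43)
trials <- rbind(s1, s2); class(trials) <- c("trial_table", "data.frame")
fit <- fit_pseudologistic(summarize_test(trials))
fit
#> Pseudologistic psychometric fit
#>   T50 (PSE): 3.906 s   gamma: 0.1989
#>   R-squared: 0.9964   converged: TRUE   usable: TRUE
```

The PSE lands within a tenth of a second of the generative 4 s and
gamma within 1% of the generative 0.2; `usable` applies the R² > 0.5
gate.

```r
## a peak-interval block: molar curve and single-trial decomposition
pk <- simulate_peak_study(n_subjects = 1, n_sessions = 2, seed = 42)
probes <- pk$trials[pk$trials$trial_type == "probe", ]
curve <- average_block(probes)        # 36 probe trials, 2-s bins
discrimination_index(curve)
#> [1] 2.677485
fit_gaussian_ramp(curve)
#> Gaussian + ramp peak fit
#>   peak time 33.32 s  peak rate 1.103/s  width 27.42 s  CV 0.823
#>   R-squared 0.9127  converged: TRUE

res <- three_state_trials(pk$trials)  # per-trial start/stop/spread
summarize_block(res)
#> Single-trial block summary: 33 of 36 trials qualify
#>   median start/stop/spread: 23.0 / 41.0 / 18.0 s
#>   IQR start/stop/spread: 6.0 / 21.0 / 21.0 s
#>   mean rates r1/r2/r3: 0.134 / 1.867 / 0.165 presses/s
#>   initiation ratio 0.074  suppression ratio 0.096
```

The fitted peak sits a few seconds past the 30-s criterion (the
generative start/stop thresholds at 0.7 and 1.5 times the criterion
center the high state at ~33 s), responding starts at a median 23 s
and stops at 41 s, and the near-zero ratios show clean low–high–low
differentiation.

A thin command-line wrapper drives the same stages end to end:

```sh
Rscript inst/scripts/titrate.R all --out out/ --seed 42
```

writing event logs, truth tables, psychometric fits, peak fits,
single-trial tables and a run manifest into `out/`.

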