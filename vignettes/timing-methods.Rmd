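---
title: "Models and methods for interval-timing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for interval-timing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titrate)
```

This vignette documents the statistical models the package implements,
the choices made where the methods literature leaves the details open,
and what the simulation-based validation does and does not establish.

## Data model

All analyses operate on cue-relative time: every trial's clock starts
at cue (tone) onset, and inter-trial events such as foot-shocks carry
negative times on the following trial. Time bins are half-open and
zero-based, bin *k* covering $[kw, (k+1)w)$; a press exactly on an
edge belongs to the later bin. The choice is arbitrary but must be
fixed, because start/stop times are reported as bin edges. Lever
identity is stored semantically (short/long) rather than physically
(left/right): counterbalanced physical assignment is session metadata
that no timing analysis consumes. FI trials are retained in event
logs but excluded from all timing analyses, which use probe trials
only.

## The pseudologistic psychometric model

Bisection choices are modelled as

$$p(\mathrm{long}\mid t) = \frac{1}{1 + \exp\!\big(-\pi\,(t - T_{50})
  \,/\, (\sqrt{3}\,\gamma\,\sigma(t))\big)},$$

the logistic approximation to a scalar-timing observer whose constant
and Poisson variance components are negligible. Two readings of the
spread term exist in the source literature: $\sigma(t) = \gamma t$
(Weber-proportional noise, evaluated at the probe duration) and
$\sigma = \gamma T_{50}$. The package defaults to the former — it is
what "gamma proportional to the Weber fraction" implies — and exposes
the latter via `sigma_at = "t50"`. Both anchor the curve at
$p = 0.5$ exactly when $t = T_{50}$, which is the definition of the
point of subjective equality and is asserted to machine precision in
the tests.

Fitting minimizes unweighted least squares on the per-duration
proportions of "long" responses among responded trials. This mirrors
the R² semantics of the curve-fitting software conventionally used
for these fits; since anchors contribute ten times the trials of each
intermediate duration, a `weights = "trials"` option and a
trial-level binomial likelihood (`objective = "ml"`) are available
for sensitivity analysis, but the default reproduces the
proportion-based R². Durations with no responded trial are dropped,
never imputed. Optimization is L-BFGS-B bounded to
$T_{50} \in (\min t, \max t)$ and $\gamma \in (10^{-3}, 2)$, started
from the best point of a coarse log-spaced grid; a Nelder–Mead polish
guards against the line-search failure L-BFGS-B exhibits when the
start is already a numerically exact minimum (noiseless data). Fits
with $R^2 \le 0.5$ or failed convergence are flagged `usable = FALSE`
and excluded from parameter summaries — the exclusion is inclusive at
the bound.

## Molar peak-interval analysis

Probe-trial pressing is averaged in 2-s bins across a two-session
block (36 probe trials at the standard 18 probes/session design) and
expressed as presses per second. The temporal discrimination index is
max rate / mean rate, which is 1 exactly for flat responding and
grows as responding concentrates; it is undefined (and signalled) for
an all-zero curve.

The final block is fitted with
$R(t) = a e^{-\frac12((t-t_0)/b)^2} + c(t-t_0) + d$. The model family
is standard for peak-interval curves; the exact parameterization is
fixed here so that width and CV have unambiguous meaning: width
$= 2b$ (twice the Gaussian SD) and CV $= 2b/t_0$. Peak time is
reported as the Gaussian center $t_0$, not the argmax of the
composite curve — the width is read from the Gaussian component, so
the peak should be too; `peak_time = "argmax"` exposes the
alternative. Rates are fitted in presses/s (this scales $a, c, d$ but
not $t_0$ or $b$). The nonlinear least-squares engine is bounded
Levenberg–Marquardt started at the curve argmax with $b = 10$ s,
$d = \min$ rate, $c = 0$; $t_0$ is confined to the probe window and
$b \in (0.5, 90)$ s. A flat curve has no identifiable Gaussian and is
returned with `converged = FALSE` rather than an arbitrary answer.

## Single-trial three-state decomposition

Each probe trial's 1-s binned counts are segmented into
low–high–low by exhaustive search over all placements $(s, e)$ of the
first and last high-state bins, subject to a minimum high-state
duration of 4 s and minimum low-state durations of 1 s each. Segment
rates are segment means. The default objective minimizes the residual
sum of squares of the piecewise-constant model, equivalently
maximizes $\sum_k (\text{sum}_k)^2/\text{len}_k$; the classic
duration-weighted index
$d_1(\bar r - r_1) + d_2(r_2 - \bar r) + d_3(\bar r - r_3)$ is
available as `objective = "index"`, because the original custom
programs in this literature are described only as "regression" and
either reading is defensible. Ties (exactly equal objectives, which
occur on sparse trials) are broken deterministically: earliest start,
then earliest stop. The production search uses cumulative sums; the
test suite proves it identical to a naive double loop that recomputes
every segment sum from scratch, on hundreds of random Poisson trials.

Start and stop are the left edges, in whole seconds, of the first and
last high bins, so spread = (number of high bins − 1) s; the
right-edge alternative would shift stop and spread by one bin and is
a documented deviation point, not an option hidden in defaults.
Trials qualify for summaries only when $r_2 > r_1$ and $r_2 > r_3$,
strictly. Block summaries use medians and IQRs; quantiles use linear
interpolation (R's default type 7) — IQR values in small blocks
depend on this convention, so it is fixed and stated. Initiation
(r1/r2) and suppression (r3/r2) ratios are computed per trial and
then averaged, which is robust when rates vary across trials; the
ratio-of-mean-rates alternative is a one-line change on the tidy
per-trial table. Bracketed correlations use the strict condition
start < FI < stop and require at least three bracketed trials;
zero-variance degeneracies yield flagged `NA`s, never silent `NaN`s.

## The synthetic generator

The generator exists to close the loop: every estimator in the
package is validated by recovering the parameters that generated
simulated data. Its defaults are the task designs themselves —
bisection sessions of 60 trials per anchor plus 12 per intermediate
duration (two randomized blocks of 90), PI sessions of 37 FI and 18
probe trials with ITIs uniform on 10–30 s, FI tones capped at 60 s
with the first press after 30 s reinforced, 90-s unreinforced probes.

Per probe trial the timing model is the scalar two-threshold account:
a remembered criterion $m \sim$ lognormal with mean 30 s and CV
`memory_cv` (default 0.2), start $= 0.7\,m\,j_1$ and stop
$= 1.5\,m\,j_2$ with independent lognormal jitters $j_1, j_2$ of CV
`threshold_jitter_cv` (default 0.3). Multiplicativity gives the
scalar property exactly: the CV of start times is invariant to the
criterion duration. The jitter default deliberately exceeds the
memory CV because threshold variability dominating memory variability
is the standard account of the robustly negative start–spread
correlation (and weak start–stop correlation) seen in real PI data —
with shared memory noise only, start and spread would correlate
positively. Pressing within each state is homogeneous Poisson at
rates $r_1 = r_3 = 0.1$ and $r_2 = 1.5$ presses/s, a clean
late-training profile; baseline response omission is 5% of probe
trials. Stress sessions perturb parameters (omission ×4, rates ×0.8,
gamma ×1.5 by default) and log 10 inter-trial shocks at least 10 s
before the next cue; these multipliers are directional calibration
knobs, not estimates of any measured effect size.

Two propagation subtleties surfaced during validation and are part of
the package's documented behavior rather than bugs:

* With $r_1 = r_3 = 0$ the fitted high state is always *contained* in
  the span of the trial's presses (extending into empty bins strictly
  lowers the between-segment sum of squares), but it does not enclose
  the span on every trial — the SSE optimum legitimately trims a
  sparse Poisson edge. Exact-enclosure holds only for deterministic
  step trials; for stochastic trials the tests assert containment,
  oracle equality, and medians on the generative boundaries.
* Per-trial start-estimation error is dominated by Poisson press
  noise and is nearly flat in `memory_cv`; what grows with generator
  noise is the across-trial spread (IQR) of fitted starts
  (≈3 → 6 → 14 s at CV 0.05/0.2/0.4), and that is the monotonicity
  the tests check.

What the generator does **not** emulate: learning dynamics within or
across sessions (acquisition must be emulated by block-level
parameter schedules), post-reinforcement pausing, bout structure or
refractoriness in pressing (presses are Poisson within states),
physical lever position effects, and any mechanistic fear process —
stress is a parameter change. Passing recovery tests therefore shows
the estimators are correct for data satisfying the stated generative
assumptions, not that real rats satisfy them.

## Problem sizes and determinism

The validation suite uses 20 simulated subjects for psychometric and
peak-time recovery, 200+ random trials across three seeds for the
change-point oracle equivalence, 5000 draws per criterion duration
for the scalar-property check, and 36-probe-trial blocks throughout —
sizes at which every stochastic band in the tests is comfortably
resolved while the whole suite runs in well under a minute of compute.
All randomness flows from explicit integer seeds; multi-subject
studies derive per-subject child seeds deterministically from the
root seed, and the pipeline writes byte-identical outputs when rerun
with the same seed and configuration. Monte-Carlo standard errors for
the scalar-property CVs use the distribution-free influence-function
(delta-method) estimator, since normal-theory CV standard errors
understate the error for skewed lognormal draws.

## Known limitations

* The pseudologistic fit offers no lapse-rate or bias terms; subjects
  with asymptotes far from 0/1 will be caught by the R² gate rather
  than modelled.
* Start/stop resolution is the 1-s analysis bin; sub-second timing
  structure is invisible to the three-state model.
* The three-state model is exactly three states: double peaks or
  resurgent responding within a probe trial are fitted as a single
  widened high state.
* Bisection response latency is stored as recorded (from cue offset);
  the package does not attempt to reconstruct lever-insertion timing.
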