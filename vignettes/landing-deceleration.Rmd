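---
title: "Landing deceleration analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landing deceleration analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taulanding)
```

## The guidance laws

A flying insect approaching a vertical surface at perpendicular distance
$y$ with approach speed $V = -\dot y$ experiences a relative rate of
optical expansion $r = V/y$ (s$^{-1}$); its inverse is the instantaneous
time to contact $\tau = y/V$. Both are available from optic flow without
knowing $y$ or $V$ separately, which is what makes them plausible control
variables. Three idealized deceleration laws follow:

* **constant-r**: hold $r$ at a set point $r^*$. Then
  $y(t) = y_0 e^{-r^* t}$ and speed falls linearly with distance. Touchdown
  is asymptotic: the approach is safe but slow.
* **constant-$\dot\tau$**: hold $\dot\tau$ at a constant $c \in (-1, 0)$.
  Then $\tau(t) = \tau_0 + ct$, $y(t) = y_0 (1 + ct/\tau_0)^{-1/c}$, and
  contact occurs in finite time $\tau_0/|c|$ with zero terminal speed.
  Along such an approach $\ln r$ is an exact affine function of $\ln y$
  with slope $c$ — the key identity this package exploits for estimation.
* **hybrid**: a sequence of constant-r bouts whose set points step upward
  as distance shrinks, with the bout set points placed on a
  constant-$\dot\tau$ schedule $\ln r^*_k = c \ln y^*_k + \beta$. The
  per-track analysis implemented here exists to detect these bouts and to
  estimate $c$ from the detected $(y^*, r^*)$ pairs.

For a span from $y_a$ down to $y_b$ the closed-form traversal times are
$t_r = \ln(y_a/y_b)/r^*$ and
$t_{\dot\tau} = (\tau_0/c)\,[(y_b/y_a)^{-c} - 1]$, with
$t_{\dot\tau} < t_r$ strictly for every $c \in (-1,0)$ when the references
are speed-matched at the span start ($\tau_0 = 1/r^*$). The speed-ratio
stage builds directly on these forms.

## Pipeline overview

1. **Simulation** (`simulate_constant_r()`, `simulate_constant_taudot()`,
   `simulate_hybrid()`, `generate_dataset()`) — closed-form trajectory
   generators plus a treatment-design dataset generator with ground-truth
   bout annotations.
2. **Kinematics** (`compute_state_variables()`) — Savitzky-Golay smoothing
   and differentiation of the position series; per-sample $V$, $A$, $r$,
   $\tau$; deceleration-phase isolation.
3. **Segment detection** (`detect_constant_r_segments()`) — the per-track
   extraction of constant-r segments, governed by the sensitivity factor
   $f$.
4. **Set-point dynamics** (`fit_loglog_model()`, `marginal_means()`,
   `fit_gamma_setpoints()`, `transition_statistics()`) — the mixed-model
   estimate of $\dot\tau$ and the distributional summaries.
5. **Strategy comparison** (`speed_ratios()`) — observed mean speed over
   two-segment spans against the two pure references.
6. **Average-per-treatment analysis** (`bin_average_tracks()`,
   `window_mean_expansion_rate()`, `treatment_comparison()`) — the
   literature method, retained for contrast.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `sampling_rate` | 200 | Hz | track sampling; unspecified in field recordings of this kind, chosen high enough that discretization error is far below tracking noise |
| `smooth_window` | 21 | samples | Savitzky-Golay window (~0.105 s); scales with sampling rate |
| `smooth_order` | 3 | — | SG polynomial order; a cubic removes the leading-order derivative bias a quadratic leaves on exponential-like decays (measured: 0.11% bias in $r$ at order 2 vs 4e-7 at order 3, same window) |
| `f` | 1 | — | sensitivity of segment detection; both admissibility tolerances scale with it |
| `tol_r` | 0.10 | — | admissible normalized spread of $r$: $(\max r - \min r)/(2\,\bar r) \le f\,\mathrm{tol}_r$ |
| `tol_slope` | 0.20 | s$^{-1}$ per unit $\bar r$ | drift guard: admissible $|\mathrm{slope}(r\!\sim\!t)|/\bar r$; rejects windows that trend monotonically with small range |
| `dy_min`, `t_min` | 0.01 m, 0.05 s | | minimum displacement and duration of a segment; `dy_min` is about a third of a typical single-bout displacement so real bouts pass while single-sample flukes do not |
| `y_td` | 0.005 | m | touchdown threshold (no numerical definition exists in the field literature) |
| `eps_v`, `gap_max` | 1e-3 m/s, 0.05 s | | approach-speed floor and the hysteresis gap for merging deceleration phases |
| `window_lo`, `window_hi` | 0.04, 0.11 | m | fixed distance window of the average-per-treatment estimate |
| `y_ref` | 0.15 | m | reference distance for marginal set-point predictions |

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure of a foraging-arena
landing experiment: approaches start 0.25–0.41 m from a vertical platform;
each track holds 1–3 constant-r bouts (probabilities 0.72/0.22/0.06,
matching the observed frequency of multi-segment maneuvers); a bout covers
13% of the approach displacement and a transition about 16.5%; first-bout
set points are gamma-distributed (shape 3.59, scale 0.65) and shifted on
the log scale by a light-level offset (0 / +0.08 / +0.17 for
low/medium/high); the schedule $\dot\tau$ differs by landing type
(takeoff −0.94, free flight −0.73) and platform pattern (±0.045); positions
carry 0.2 mm white Gaussian tracking noise.

Design notes, in the package's own words:

* **Lead-in and tail follow the schedule.** Before the first bout and after
  the last one the track follows its own constant-$\dot\tau$ schedule
  continuously; the bouts hold piecewise-constant what the schedule
  prescribes continuously. An earlier design that relaxed $r$ from an
  arbitrary start value toward the first set point produced long
  pseudo-bouts at the first set point but at too-large distances — points
  off the schedule that biased $\dot\tau$ recovery. With the schedule
  lead-in the start speed is implied rather than drawn (≈0.1–0.7 m/s at
  the default geometry).
* **Transitions** relax $r$ first-order toward the next set point (time
  constant 0.15 s). Nothing quantitative is known about real transition
  dynamics; these are free knobs of the generator, not claims about bees.
  An optional `"dip"` mode lets the approach speed sag toward 0.05 m/s
  mid-transition, for robustness tests against transitions that contain
  near-zero approach velocity.
* **Set-point schedules are exact.** Bout set points sit exactly on the
  track's log-log line. Real set points scatter around the population
  schedule; consequences for inference are discussed under Limitations.
* **The takeoff-cell $\dot\tau$ default is −0.94**, inside the soft-touchdown
  regime $(-1, 0)$ that the idealized law requires; an empirical fitted
  slope at or below −1 cannot be a generator parameter of this law.
* **What the generator does not emulate**: body dynamics and wingbeat
  kinematics, lateral guidance (x and z receive a small smooth drift plus
  noise only), aborted or re-targeted approaches, correlated tracking
  error, and biological scatter of set points around the schedule. Passing
  recovery tests on these tracks therefore demonstrates correctness of the
  extraction machinery under the idealized generating law — not performance
  on every feature of real trajectories.

## Segment detection

Within each deceleration phase every window of at least `dy_min`
displacement and `t_min` duration is tested for admissibility (spread and
drift criteria above, both scaled by $f$). Among admissible windows the
detector selects the non-overlapping set with **maximum total sample
coverage** by exact dynamic programming, then merges adjacent selections
whose pooled window is itself admissible. A greedy longest-first heuristic
was evaluated and rejected: it can return as little as 68% of the
attainable coverage on plausible tracks, and its yield is not monotone in
$f$, both of which contradict properties the detector should guarantee
(raising $f$ must never detect less). Max-coverage selection provides both
guarantees at the same asymptotic cost; `brute_force_segments()` remains an
independently coded oracle (naive enumeration, separate interval-scheduling
dynamic programme) used by the tests to cross-validate enumeration and
selection.

Two admissibility facts shape what detection can and cannot see:

* A constant-$\dot\tau$ arc is locally indistinguishable from constant-r
  when a window's log-distance span is small; short windows on such arcs
  pass at moderate $f$. Pure constant-$\dot\tau$ control tracks are still
  mostly rejected (covered fraction well under half at $f = 1$), but
  fragments do occur, mainly at low $r$.
* A set point can only be detected if it is held long enough. Bouts
  shorter than about twice `t_min` (after smoothing has consumed a
  half-window at each edge) are systematically missed. Recovery tests
  therefore generate bouts of at least 0.1 s; the same selection effect in
  a field dataset means the detected set-point distribution is truncated
  relative to the set points bees aim for.

## Estimating the time-to-contact rate

`fit_loglog_model()` fits $\ln r^* \sim \ln y^*$ with treatment main
effects, optional treatment-by-$\ln y^*$ interactions, and a random
intercept per track (REML via `lme4`). Factors enter with sum-to-zero
contrasts so the $\ln y^*$ coefficient is the average slope across cells —
the $\dot\tau$ estimate; `emmeans` provides cell-specific slopes and
marginal predictions at `y_ref`, back-transformed without smearing
correction (declared; segment-level log residuals are small and
symmetric). Starting from the full interaction set, each interaction is
dropped when a likelihood-ratio test on ML refits gives p > 0.05; both the
full and the minimal fits are kept. Per-track identity is the only
grouping available (individual identity does not exist in either the
synthetic or typical field data); no multiple-testing correction is
applied across contrasts. Both raw segments and per-track means can be fed
to the model; raw segments with the track random effect are the default.

The gamma fit to the set-point distribution uses the profile-equation MLE
(Newton on $\log a - \psi(a) = \log \bar x - \overline{\log x}$, scale
$\bar x / a$), with percentile bootstrap confidence intervals from
nonparametric resampling (default 1000 resamples, seeded). The solver is
vectorized across bootstrap resamples, which keeps calibration experiments
with hundreds of replicates cheap; tests cross-check it against
`fitdistrplus`.

## Numerical choices and degenerate inputs

* Savitzky-Golay endpoints: the half-window at each track end is masked,
  as are samples at or past `y_td`; $\tau$ is undefined wherever
  $V \le$ `eps_v`.
* Track validation: non-uniform sampling (relative jitter above 1e-6)
  skips the track with a structured warning; inconsistent metadata within
  a track is a hard error; tracks shorter than the smoothing window are
  rejected at the kinematics stage.
* Tie-breaks in selection resolve toward longer, earlier windows, making
  detection fully deterministic.
* The minimum-duration threshold is applied with a 1e-9 s epsilon: at
  200 Hz, `0.05 / 0.005` does not evaluate to 10 in binary arithmetic.
* Degenerate spans in `speed_ratios()` (non-positive duration or
  displacement) are skipped with a warning; an empty pair list yields
  `n = 0` transition statistics, not an error.
* CSV round-trips write 17 significant digits, enough for exact double
  round-trips.

## Problem sizes used by the tests

The recovery and calibration experiments run at sizes chosen to give the
assertions comfortable statistical margins: 200 tracks for detector
recovery (with 50 constant-$\dot\tau$ controls), 100 random tracks for the
selection-oracle comparison, ~500 tracks for $\dot\tau$ point recovery
with 25 replicate datasets of 120 tracks for CI calibration, 6000 draws
for the gamma MLE with 200 replicates of 500 for bootstrap calibration,
and 900 tracks across six treatment cells for the end-to-end ordering
check.

## Known limitations

* **CI under-coverage for $\dot\tau$ under the idealized generator.** With
  set points exactly on the schedule, within-track residual variance is
  nearly zero and the mixed-model slope standard error becomes very small
  (~0.003 at a few hundred tracks). Two small deterministic detection
  effects — asymmetric window clipping at bout edges (strongest where the
  final bout meets the steep touchdown arc) and low-$r$ arc fragments —
  bias the slope by −0.01 to −0.03. The point estimate remains well within
  practical tolerance, but a nominal 95% Wald interval under-covers the
  generator value badly, and the calibration test records this honestly.
  On real data, biological scatter of set points around the schedule would
  dominate both effects; on the idealized generator it is absent by
  construction.
* **Selection truncation.** Detected set points are those held long
  enough to detect; distributional summaries (gamma fit, medians) describe
  the detected population, not the aimed-for one.
* **The detection algorithm is this package's own concrete definition.**
  The field describes such detectors only qualitatively (more and wider
  segments at higher sensitivity); spread-plus-drift admissibility with
  max-coverage selection is one defensible realisation, and all tolerances
  are exposed in `pipeline_config()`.
* Whether $r^*$ should be the windowed mean of $r$ (default) or a
  through-origin slope of $V$ on $y$ is not settled; both are available
  (`r_star_estimator`).
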