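---
title: "Methods: linear information dynamics of a physiological network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear information dynamics of a physiological network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netinfodyn)
```

## The model and its assumptions

`netinfodyn` treats the seven extracted node series — cardiac period
(RR), respiration (RESP), pulse arrival time (PAT) and the four EEG
band powers (delta, theta, alpha, beta) — as one realization of a
stationary, jointly Gaussian vector stochastic process that is Markov
of order $m$. Under these assumptions every information measure has an
exact closed form in terms of variances and partial variances, and the
decomposition

$$H_j = S_j + T_j + N_j$$

holds identically: the entropy of a node splits into what its own past
predicts (storage $S_j$), what the rest of the network adds (joint
transfer $T_j$) and what remains unpredictable (new information $N_j$).
All measures are reported in nats (natural logarithm throughout).

Three assumptions deserve emphasis. *Stationarity* is screened, not
guaranteed (see below). *Gaussianity* is an approximation — band-power
series in particular are right-skewed — under which transfer entropy
coincides with Granger causality; the measures remain meaningful as
linear-prediction quantities even when it fails. *Finite Markov order*
is chosen by AIC per window; the state-space submodels then account
exactly for the fact that a *sub*-network of a VAR is not itself a VAR
but a VARMA process with infinite autoregressive representation.

## From VAR fit to partial variances

The standardized $7 \times 300$ window is fit by least squares (no
intercept, residual covariance normalized by $1/(N-m)$). The fitted
VAR(m) is rewritten in innovations form: state $z_n$ = the $m$ stacked
lags, observation $x_n = C z_n + e_n$. Removing rows of the observation
equation and solving the discrete algebraic Riccati equation (DARE) of
the reduced model gives the steady-state innovation covariance of the
kept processes — the exact partial variance of the target given only
those processes' pasts. Four variances per target produce all measures:
the Lyapunov process variance, the own-past variance (keep only the
target), the leave-one-source-out variances, and $\Sigma_{jj}$ from the
unreduced fit (the full model *is* the unreduced submodel, so no DARE
is needed there). The reduced models keep the full state and the same
$m$; nothing is re-selected.

Two backends expose the same surface:

- **state-space** (default): the submodel/DARE route above, evaluated
  on the fitted coefficients. Within this backend the process variance
  used in $H_j$ and $S_j$ is the *model-implied* (Lyapunov) variance,
  not the sample variance. This is a deliberate choice: with one
  consistent set of variances the log-ratios telescope and
  $H = S + T + N$ holds to machine precision; mixing the sample
  variance in would leave an $O(1/N)$ residual and could push $S_j$
  slightly negative. After standardization the two candidates differ
  negligibly anyway.
- **regression**: explicit nested least squares of the target's present
  on each lag set, computed from one cross-moment matrix. It is exact
  in finite samples (every nesting inequality holds by construction)
  and serves as the verification oracle for the state-space route; the
  two agree to well under 2% in relative partial variance on long
  realizations and to ~0.02 nats on 300-sample windows.

## Numerical choices

- **DARE solver**: structure-preserving doubling after absorbing the
  state/observation noise cross-covariance; convergence when successive
  iterates change by less than $10^{-12}$, typically ~20 (quadratic)
  iterations. A fixed-point iteration of the Riccati recursion is the
  fallback. The final Riccati residual is always checked
  ($<10^{-8}$ relative), so non-convergence raises an error rather than
  returning a silently wrong value. The doubling method matters in
  practice: fitted windows are often near unit root
  ($\rho \approx 0.98$–$0.999$), where plain fixed-point iteration
  stalls.
- **Lyapunov equation**: doubling recursion, tolerance $10^{-12}$.
- **AIC**: $AIC(p) = N_{\mathrm{eff}}\ln\det\hat\Sigma(p) + 2pM^2$ over
  $p = 1..12$; ties resolve to the smallest order. The maximum order 12
  is a configuration default (the order is re-selected per
  subject-state window and logged in the result's provenance).
- **Unstable fits**: if the fitted companion matrix has spectral radius
  $\ge 1$ the state-space measures are undefined. The pipeline then
  computes the window's measures with the regression backend, flags the
  window `unstable_fit`, and excludes it from the consensus counts —
  never silently shrinking coefficients, which would bias transfer
  values.
- **F-tests**: restricted models are re-estimated (true nested OLS, not
  coefficient zeroing); $q = m\,|\mathrm{removed}|$,
  $d = (N-m) - Mm$, no intercept. No multiple-testing correction is
  applied across the 42 directed pairs, matching the per-test
  $p < 0.05$ rule whose family-wise looseness is controlled by the
  cross-subject consensus thresholds (at least 7 of 18 subjects for a
  link, more than 12 for a strong one); an FDR adjustment can be
  applied downstream to the exported p-values if desired.

## Preprocessing parameters

| stage | default | why |
|---|---|---|
| ECG band-pass | 1–20 Hz half-power, 4th-order, forward–backward | baseline and noise removal with zero phase, preserving R-peak timing |
| R-peak template | ±60 ms around the 20 largest provisional peaks; provisional threshold 0.6 × 95th percentile of the rectified signal, refractory 250 ms | builds the matched filter from the data itself |
| match acceptance | normalized cross-correlation > 0.6 *and* peak height > 0.4 × the template beats' median height | correlation alone is scale-invariant and accepts bump-shaped noise; the amplitude gate removes those |
| ectopy rule | RR outside [0.7, 1.3] × 11-beat running median → merge split pairs, spline-bridge the rest | reproducible surrogate for manual beat editing |
| PAT search | window (peak, peak + min(next RR, 0.6 s)); steepest rise located on a 3-point smoothed first difference with parabolic refinement | wrist arrival times are far below 0.6 s; the refinement gives sub-sample localization |
| resampling | cubic splines on the integer-second grid | reproduces linear trends exactly; beats arrive faster than 1 Hz so this interpolates, never extrapolates |
| band power | 2 s epochs, 1 s hop, mean-removed rectangular-window periodogram; half-open bands [0.5,3), [3,8), [8,12), [12,25) Hz | one value per second; half-open edges prevent double counting at the 3/8/12 Hz boundaries |
| epoch edges | a duration-D record yields D−1 values at epoch centers t = 1..D−1; the spline grid is cropped to the same timestamps | exact synchrony of all seven rows without padding |
| windows | 300 samples; REST offset 180 s, task offset 60 s (configurable 60–120 s) | avoids transients after state changes |
| standardization | zero mean, unit variance with the 1/N convention | makes the entropy of a standardized row exactly $\tfrac12\ln 2\pi e$ |

The stationarity screen draws 10 random 50-sample subwindows and runs
two tests per subwindow against the pooled remainder: Welch's t for the
mean and a Brown–Forsythe-type test (Welch's t on absolute deviations
from each group's median) for the variance. The series fails when more
than 3 of the 20 tests reject at 0.05. The bound was calibrated by
Monte Carlo so that i.i.d. Gaussian series pass in >90% of replicates —
the 20 tests share data, so a binomial account would be wrong — while a
3-SD level step or a 4-SD linear trend essentially always fails. The
Brown–Forsythe form was chosen because the classical variance F-test
over-rejects grossly on the $\chi^2$-tailed band-power rows. Because
band powers are also serially correlated (overlapping epochs) and
slowly modulated, they still get flagged in a substantial fraction of
windows; a flag logs a warning and marks the subject but never stops
the analysis.

## What the synthetic generator emulates — and what it does not

The generator produces the four raw channels at the wearable-sensor rates (ECG
250 Hz, respiration 25 Hz, BVP 64 Hz, EEG 256 Hz) with full ground
truth:

- **Beats**: cardiac periods
  $RR_n = \overline{RR}\,(1 + g\sin\varphi_{\mathrm{resp}}) + \varepsilon$,
  the simplest respiratory phase coupling the transfer analysis can
  detect; defaults $\overline{RR} = 0.8$ s, jitter SD 0.03 s, RSA gain
  0.05.
- **Respiration**: quasi-periodic — the instantaneous frequency drifts
  as a slow AR(1) (~5% SD around 0.25 Hz). A pure sinusoid would put
  poles of the extracted series exactly on the unit circle and make
  every fitted VAR unstable; real breathing is never a pure tone.
- **ECG**: 40 ms raised-cosine spikes of amplitude 1 on noise of SD
  0.05 — a sharp, unambiguous template-matching target.
- **BVP**: one gamma-like pulse per beat
  ($\tau^2 e^{-\tau/b}$, $b = 0.08$ s) whose inflection lags the R peak
  by the stored per-beat PAT (base 0.25 s, slow drifting-phase
  variation scaled so that zero variation gives an exactly constant
  PAT). The shape scale was chosen so the derivative maximum is sharp
  enough to be localized within one sample at 64 Hz — the property
  "maximum derivative" needs to be well defined for PAT to be a
  meaningful target.
- **EEG**: sum of four FFT-masked band-limited noise carriers scaled by
  log-AR(1) envelopes (one value per second, $\phi = 0.7$, SD 0.1).
  The envelope statistics are free design choices, not fits to any
  recording.

Durations default to the protocol phases: 720 s for REST (the window
starts at 180 s and needs 300 samples), 420 s for tasks. Cohort
generation draws subject-level means (cardiac period, respiratory rate,
baseline PAT) uniformly over healthy ranges.

Not emulated: ECG morphology beyond the R spike (no P/T waves),
ectopic beats and motion artifacts, multi-electrode EEG, calibrated
respiratory volume, and any genuine brain–periphery coupling in the
*recording* generator (the VAR presets carry the coupled topologies).
Passing the recording-level tests therefore demonstrates that the
extraction chain recovers known beat times, intervals and envelopes —
not that it would survive clinical-grade artifacts.

## Benchmark presets

`independent` (7 uncoupled AR(1) nodes), `chain3`
(X1 → X2 → X3, so the 1 → 3 transfer conditional on node 2 is exactly
zero — the mediation null), and `paperlike7`, a 7-node network with
bidirectional RR/RESP coupling, RR → PAT, RESP → PAT and two
brain-to-peripheral links (coefficients 0.3–0.6) whose self-dynamics
give the storage ordering RR > RESP > PAT > bands. The RR/RESP loop is
a negative feedback (+0.35 / −0.30): with self-coefficients this high a
positive 2-cycle is unstable, while the negative loop gives a stable
complex pole pair (modulus ≈ 0.87) — incidentally a more physiological
picture of the phase-coupled cardiorespiratory loop. Presets are fully
deterministic; the `seed` argument of `benchmark_preset()` exists for
interface uniformity only.

The regression *oracle* (`oracle_measures`) estimates every partial
variance on a long simulated realization with a wide lag window
(`max(20, 4m)` lags, not $m$): reduced sub-processes are VARMA, so a
truncated own-order regression would be biased — the long window makes
truncation error negligible against sampling error at the default
$10^5$–$10^6$ samples.

## Problem sizes

Validation uses 300-sample windows (five-minute analysis
windows at 1 Hz) for all finite-sample checks, $10^5$–$10^6$-sample realizations
for oracle agreement, 1000 replicates for F-test calibration, and 20
replicate 18-subject studies for consensus-topology recovery. A full
synthetic study (18 subjects × 3 states, raw signals to consensus
graphs) runs in about a minute on one CPU.

## Known limitations

- All estimators are linear; nonlinear storage or transfer is invisible
  to them, and zero-lag (instantaneous) effects are not modeled.
- Differential entropies can be negative; `N_j < 0` simply means the
  full-network prediction error variance is below $1/2\pi e$ (common
  for the nearly deterministic respiration series).
- The group-level two-way ANOVA across states and nodes is out of
  scope; the pipeline exports the tidy per-subject measure table such a
  test would consume.
- Consensus thresholds (7/12) are display conventions for an
  18-subject cohort, not inferential corrections; with other cohort
  sizes they should be rescaled by the user.
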