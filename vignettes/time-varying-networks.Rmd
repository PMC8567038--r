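---
title: "Time-varying directed EEG networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying directed EEG networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`adtfnet` analyses how task conditions reshape directed cortical information
flow in event-related EEG. It covers three branches that share one epoch
container: ERP preprocessing and component statistics, behavioural
response-time tests, and — the core of the package — time-varying effective
connectivity via Kalman-filtered tv-MVAAR models and the Adaptive Directed
Transfer Function (ADTF). This vignette explains the models, the parameters
that matter, what the synthetic generator does and does not emulate, and the
design decisions taken where conventions differ across the literature.

## The time-varying MVAR model and its Kalman estimator

A multichannel epoch `X(t)` (n channels) is modelled as a time-varying
multivariate adaptive autoregressive (tv-MVAAR) process

```
X(t) = sum_{i=1..p} A(i, t) X(t - i) + E(t),
```

where the `A(i, t)` are n x n coefficient matrices allowed to change at every
sample and `E(t)` is Gaussian white innovation noise. `fit_tvmvar_kalman()`
tracks the coefficients with a random-walk-state Kalman filter:

* the state is the stacked coefficient entries; the state transition is the
  identity (coefficients drift, they are not forecast);
* process noise is `update_constant` times the identity, so `update_constant`
  (default **0.02**, dimensionless, in (0, 1)) is the single knob trading
  tracking speed against estimation variance;
* all channels share the same lagged regressor, so one error-covariance
  recursion serves every channel; the innovation covariance is smoothed
  exponentially with the same constant and supplies the observation-noise
  variance;
* initialisation is zero coefficients, unit state covariance, unit innovation
  covariance.

At `update_constant = 0.02` a coefficient step of 0.8 is typically passed at
its half-way point within a few tens of samples (the package's tests measure
this directly). On *time-constant* data there is nothing to track, and a
small constant (the static-limit checks use `1e-4`) makes the filter an
almost-growing-memory estimator whose time-averaged ADTF agrees with the
classical DTF of the true coefficients to within 0.05 per entry; at 0.02 the
steady-state estimation noise inflates that gap several-fold. Users analysing
data where the dynamics of interest are slow should lower the constant
accordingly.

The model order `p` is chosen by `select_model_order()`, which minimises the
mean across trials of `log det(Sigma_p) + 2 p n^2 / N` from stationary
least-squares fits — an AIC for the VAR family. On white noise it selects the
minimum candidate; on a strongly autoregressive third-order process it
selects 3 (occasionally 4) at realistic sample counts.

## From coefficients to directed flow

For each retained time point the lag polynomial is assembled as

```
A(f, t) = I - sum_{k=1..p} A_k(t) exp(-i 2 pi f k / fs)
```

and inverted to the transfer matrix `H(f, t) = A(f, t)^{-1}`. Conventions for
the lag-0 term differ across the directed-transfer-function literature; this
package pins the identity-minus-sum form above, under which zero coefficients
give `H = I` and a univariate AR(1) with coefficient `a` gives
`|H(f)|^2 = 1 / |1 - a e^{-i 2 pi f / fs}|^2`.

The ADTF normalises squared magnitudes per *target* row:

```
gamma2_ij(f, t) = |H_ij(f, t)|^2 / sum_m |H_im(f, t)|^2,
```

so every entry lies in [0, 1] and each target's source-sum is exactly 1 — an
invariant the test suite asserts to 1e-9 on both random and fitted tensors. A
degenerate all-zero row (possible only if the transfer matrix itself is
zero) maps to zeros and is counted, not silently renormalised.

Band integration averages `gamma2` over the grid frequencies inside
`[f1, f2]` inclusive. The integral's printed normalisation is ambiguous in
parts of the literature (a span `f2 - f1` in the denominator versus the
number of grid points actually summed); `integrate_adtf()` deliberately uses
the arithmetic mean over included grid points, which keeps the row sums of
the integrated network `Theta2_ij(t)` at exactly 1. The default grid is 1 Hz
steps over **1–10 Hz** — the delta-through-alpha band that carries the P300 —
evaluated at the **25 Hz** network rate (40 ms between adjacent time points).

Estimation is strictly per trial, and per-trial integrated networks are then
averaged within condition (`average_networks()`): estimate-then-average, not
a joint multi-trial fit. Because band integration is a fixed linear
operation, averaging `gamma2` before integration or `Theta2` after is
mathematically identical; the package integrates first.

`summarize_substages()` reduces a network to source-node statements: for each
named substage the outflow of node j is the sum of its off-diagonal outgoing
weights over the substage's time points, the node with maximal outflow is the
stage's source (ties are flagged, not broken silently), and the `top_k`
strongest directed edges (default 10) are listed. The default substages are
the decision-process (200–320 ms) and neuronal-response (320–440 ms) windows
bracketing the P3 peak; at the 25 Hz rate each contains 3 time points.

Networks are normally built on a 20-electrode subset of the 10–20 montage
(`network_montage_20()`), a standard mitigation of volume conduction; the
20th label defaults to Oz and is configurable because published electrode
lists for this subset vary.

## Preprocessing

The ERP chain is band-pass filter -> (segment) -> baseline-correct -> reject
-> re-reference, with these numerical choices:

* **Filtering** is zero-phase (forward–backward Butterworth: 2nd-order
  high-pass cascaded with a 4th-order low-pass, default band 0.1–30 Hz).
  Because a 0.1 Hz corner is far below the length of a 1-s epoch, the 0 Hz
  component is removed exactly (demeaning) before the recursive filter runs;
  otherwise the filter transient would dominate the epoch.
* **Segmentation** uses half-open ms intervals with the mapping
  `sample = floor((t - window_start) * fs / 1000)`; an epoch on [-200, 800) ms
  at 500 Hz holds exactly 500 samples. Markers too close to a recording edge
  are skipped with a warning.
* **Baseline** correction subtracts the per-trial, per-channel mean over
  [-200, 0) ms.
* **Artifact rejection** removes trials whose peak absolute amplitude on any
  channel strictly exceeds 75 uV; a trial peaking exactly at the threshold is
  kept. Rejection runs after baseline correction; for artifacts well above
  the threshold the order does not change the kept set (a property the tests
  check).
* **Decimation** to the 25 Hz network rate low-pass filters at 0.8 of each
  stage's new Nyquist and decimates in stages of at most 5 (factor 20 = 5 x 4),
  because single-stage high-order IIR designs at 0.04 of Nyquist degenerate
  numerically.
* **Re-referencing** supports the common average and named channel lists
  (e.g. the mastoid pair TP9/TP10). The Reference Electrode Standardization
  Technique is out of scope; the configurable re-reference stands in its
  place, which is the one deliberate departure from the original recording
  pipeline and the main reason reproduction of absolute amplitudes on real
  data carries a tolerance.

## ERP and behavioural statistics

Component quantification uses mean amplitudes over half-open windows — P2
140–200 ms and LPC 500–700 ms on a fronto-central cluster (F3, F4, FC1, FC2,
Fz, C3, C4, Cz), P3 300–400 ms on a centro-parietal cluster (C3, C4, CP1,
CP2, Cz, P3, P4, Pz) — averaged trial -> participant -> group, so each
participant contributes equally to grand averages.

`rm_anova_2xK()` implements the 2 (condition) x K (electrode) fully
within-subjects ANOVA from the classical sums-of-squares decomposition, each
effect tested against its own effect-by-subject stratum. The
Greenhouse–Geisser epsilon comes from the covariance of orthonormal-contrast
scores (Kronecker contrasts for the interaction) and is clamped to
[1/(K-1), 1]; it is applied to factors with more than two levels (a 2-level
factor has epsilon = 1 by construction). Effect sizes are partial eta
squared. The implementation is cross-checked in the tests against base R's
`aov()` error strata and against hand-computed definitional sums of squares.

Post-hoc condition contrasts are per-electrode paired t-tests, unadjusted by
default because that matches common reporting practice for these designs; any
`p.adjust` method (e.g. Bonferroni) can be switched on. The Wilcoxon
signed-rank test drops zero differences, assigns average ranks, and reports a
continuity-corrected Z using the classical variance `n(n+1)(2n+1)/24`; the
two-sided p-value is exact (signed-rank distribution) for n <= 25 without
ties, normal otherwise. The pairing unit is whatever rows the caller pairs —
the synthetic behavioural table pairs trials by trial id; with |Z| in the
tens, trial-level pairing across a whole study is implied, and participant-
level pairing is equally possible by aggregating first.

## The synthetic generator: what it emulates and what it does not

`make_erp_epochs()` builds condition templates from Gaussian component bumps
(P2 at 170 +/- 15 ms, P3 at 350 +/- 35 ms, LPC at 600 +/- 60 ms) over the
clusters above, with full amplitude on the cluster and 0.3 of it elsewhere,
plus independent Gaussian noise (default 10 uV per sample, a realistic
single-trial EEG scale). P2 amplitudes are 2.034 uV (low-information, LAI)
vs 1.606 uV (high-information, HAI) — the one component for which printed
condition means were available; P3 (5 vs 3.5 uV) and LPC (3 vs 4.2 uV) are
plausible values chosen once, with LAI > HAI for P2/P3 and HAI > LAI for LPC.

`simulate_tvmvar()` draws epochs from a piecewise-constant MVAR schedule with
half-open segments that must tile the window, rejecting unstable segments
(companion spectral radius >= 1) and non-positive-definite innovation
covariances. Each trial discards a burn-in of 10p samples generated under the
first segment, and each trial has its own RNG substream so the trial count
never reshuffles earlier trials. The headline fixture
(`switching_source_schedule()`) has three nodes with the driver switching
from node 1 to node 2 mid-epoch (coupling 0.5, diagonals 0.5, unit noise).
It is generated **at the 25 Hz network rate over a 4 s window** (100 samples,
switch at 2 s, evaluation substages 1–2 s and 3–4 s): ground truth defined at
the analysis rate, with enough post-switch samples for the default adaptation
constant to re-converge. Decimating a fast-sampled MVAR process does not
preserve its coefficients, so defining truth at the analysis rate is the
honest construction for a recovery benchmark; the MVAR fixture is a test
harness, not a claim about the generative physiology of EEG.

`simulate_behavior()` draws condition-specific log-normal response times
censored at the 4,000 ms deadline (censored trials flagged as non-responses).
Default locations/scales are set so the analytic median and mean are
950/1106.68 ms (LAI) and 1390/1511.69 ms (HAI); a two-parameter log-normal
cannot simultaneously match the reported standard deviations, so mean and
median were preferred.

The generator does **not** emulate volume conduction or a forward head model,
realistic artifact morphology (only amplitude outliers), correlated
spatio-temporal noise, or inter-participant variability in component latency.
Passing tests therefore demonstrate that the estimators recover known ground
truth under their own model class and that the statistics match their
definitions — not that any particular real dataset will reproduce published
values.

## Problem sizes and runtime

The shipped checks use sizes chosen to exercise the asymptotics while staying
desk-scale: the static-limit comparison uses 3 channels, 50 trials of 2,000
samples; source recovery uses 50 seeded runs of 20 trials; the ERP recovery
check uses 100 trials/condition at 5 uV noise; the demonstration pipeline
uses 60 ERP trials/condition across 10 participants, 20 network trials per
condition and 200 behavioural trials per condition. At the demo scale the
large P3/LPC condition effects are reliably detected while the small
(~0.14 uV after re-referencing) P2 effect typically is not — an expected
power limitation, not an estimator defect.

## Known limitations

* The Kalman hyperparameters (state model, noise scaling, initialisation) are
  one reasonable choice among several published variants; update constants
  other than the default may suit other data regimes.
* Order selection uses stationary fits; heavily nonstationary epochs can
  favour smaller orders than the generating process.
* No surrogate-based statistical thresholding of edges is provided; substage
  summaries rank outflow but do not test it.
* The BrainVision reader covers multiplexed IEEE_FLOAT_32 / INT_16 binary
  data, the common export formats, and nothing else.
* Reproduction of published absolute component amplitudes from shared raw
  data requires the original reference scheme; with the substituted
  average/mastoid reference, amplitudes shift by the reference mean and only
  condition *differences* are comparable.
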