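---
title: "Methods: wavelet coherence, surrogate nulls and Bayesian inference in dyadsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet coherence, surrogate nulls and Bayesian inference in dyadsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dyadsync` analyses two-person (hyperscanning) fNIRS experiments in which a
dyad's interbrain synchrony is quantified by wavelet transform coherence
(WTC), compared against a pseudo-dyad surrogate null, and related to
behaviour (laughter annotations) and social outcomes through Bayesian
hierarchical models and Bayesian mediation. This vignette documents the
models, the defaults and why they were chosen, the numerical decisions, and
what the synthetic-data generator does and does not emulate.

## The synchrony estimator

### Continuous wavelet transform

Signals are transformed with the analytic Morlet wavelet
$\psi(u) = \pi^{-1/4} e^{i\omega_0 u} e^{-u^2/2}$ with $\omega_0 = 6$, the
field-standard choice that balances time and frequency resolution and makes
the Fourier period essentially equal to the scale
($\lambda = 4\pi/(\omega_0 + \sqrt{2+\omega_0^2}) \approx 1.033$, so
$s = P/\lambda$). The transform is implemented as correlation with the
time-sampled kernel, truncated at $\pm 6$ scale SDs (relative truncation
error $e^{-18} \approx 10^{-8}$) and evaluated by FFT on a zero-padded
buffer; this is bit-identical to direct convolution, which is how the test
suite's brute-force oracle checks it (agreement to $10^{-15}$ on 64-sample
signals).

The scale grid uses 12 voices per octave (config-exposed), a smooth
coverage for band averaging.

### Coherence and smoothing

$$R^2(s,t) = \frac{\left|S\!\left(s^{-1} W_{xy}\right)\right|^2}
 {S\!\left(s^{-1}|W_x|^2\right)\, S\!\left(s^{-1}|W_y|^2\right)}$$

with the standard two-step smoothing operator $S$: a Gaussian in time with
SD $s/\sqrt{2}$ (matched to the wavelet's envelope at each scale) followed
by a 0.6-octave boxcar across scale. Because all three spectra share one
set of non-negative smoothing weights, $R^2$ is bounded in $[0,1]$ by
Cauchy–Schwarz and self-coherence is identically 1 — both asserted in the
tests. Phase is discarded; only coherence magnitude is analysed.

Smoothing is what gives coherence its statistical meaning, and it also sets
the null level: two independent white-noise series at 7.81 Hz average a
band (8–75 s) coherence around 0.43 (recomputed by
`scripts/acceptance.R` as `white_noise_band_mean_wtc`). Band-averaged WTC
values must therefore always be read against the pseudo-dyad null, never
against zero.

### Adaptive band and cone of influence

The analysed period band runs from 8 s up to one quarter of the segment
duration, so the slowest analysed fluctuation completes at least four
cycles: a 300-s interval gives 8–75 s (≈ 0.0133–0.125 Hz). Segments shorter
than 32 s are rejected. Edge-affected cells are excluded with the Morlet
e-folding criterion: a cell at scale $s$ is valid only when it lies more
than $\sqrt{2}\,s$ from both segment edges. Excluded cells are removed from
the average, not zero-filled, and the number of valid cells is reported per
value. Each interval is COI-masked independently.

### From channels to one value per dyad, ROI pair, phase and interval

Each ROI's signal is the mean of its good channels ("channels-first"; the
alternative of averaging per-channel coherences is not the default because
one value per ROI pair is the analysis target and channel averaging first
raises SNR before the nonlinear coherence step). Heterologous pairs are
computed in both cross-assignments (A.roi1–B.roi2 and A.roi2–B.roi1) and
averaged, since dyad members are exchangeable. Phases are split into two
equal intervals, each with its own adaptive band.

## The pseudo-dyad surrogate null

Every participant is paired with `n_surrogates` (default 100) randomly
chosen participants who are neither themselves nor their true partner,
drawing with replacement (and logging it) when the pool is smaller. The
coherence *matrices* of these pairings are averaged elementwise and then
band/COI-averaged — matrix-then-scalar order. Series of unequal length are
truncated to the shorter one so the adaptive band stays valid. The pool is
unrestricted by condition or gender; config flags can restrict it. Real and
surrogate values are compared with a Gaussian two-group model (±0.5 effect
coding, no random term).

## Preprocessing

The chain is a deliberately simplified, fully parameterized stand-in for
the conventional Homer2-style pipeline, in fixed order: intensity → optical
density → motion detection → spline correction → wavelet despiking →
zero-phase band-pass → modified Beer–Lambert. No step changes length or
sampling rate. Defaults (all config-exposed): motion window 1 s, SD factor
13.5, amplitude threshold 0.4, spline tracking 0.99, despike IQR factor
1.5, band 0.01–0.5 Hz, DPF 6/6, 3 cm separation, extinction coefficients
for 760/850 nm.

Numerical decisions worth knowing:

* **Motion detection** thresholds the rolling range against a robust noise
  SD estimated from *first differences* (MAD(diff)/√2) so the estimate is
  not inflated by the artifacts being detected.
* **Spline correction** interprets its smoothing parameter in the
  near-interpolating sense (0.99 tracks the artifact closely); the
  artifact-trend residual is pinned to zero at both segment ends and
  re-anchored on the line joining the neighbouring clean samples, so
  corrected segments join continuously.
* **Despiking** uses a hand-written periodized Daubechies-4 DWT (no
  discrete-wavelet dependency): detail coefficients beyond 1.5 IQR of
  their level are zeroed. Spikes lose more than half their amplitude while
  20-s oscillations pass within 5%.
* **Band-pass** is an exact zero-phase FFT filter with raised-cosine
  transitions (10% of each cutoff). An IIR filter at a normalized low
  cutoff of 0.0026 would be numerically fragile; the FFT filter is exact
  and trivially zero-phase.
* **MBLL** solves the 2×2 extinction system per sample; the forward/inverse
  round trip is exact to $10^{-10}$.

Quality gating: a channel is bad if its intensity coefficient of variation
exceeds 0.15 or it is flat or saturated; an ROI is bad when all four of its
channels are; a dyad drops out of exactly those ROI pairs that touch a bad
ROI — reproducing per-pair sample sizes.

## Bayesian inference

All models are Gaussian: $y = X\beta + u_{group} + \varepsilon$ with
$u \sim N(0, \tau^2)$ when a `(1|dyad)` term is present. Two-level factors
are effect-coded ±0.5 so main effects are means of simple effects and the
full factorial `*` expansion keeps its usual reading. Priors: normal on
coefficients, half-normal on SDs. Unset prior fields resolve from the
response scale (intercept $N(\bar y, 5\,\mathrm{sd}(y))$, coefficients
$N(0, 5\,\mathrm{sd}(y))$, SDs half-normal$(5\,\mathrm{sd}(y))$) — weakly
informative on the data's own scale. `synchrony_priors()` ships a
pilot-style intercept prior $N(0.3, 0.2)$, reflecting where band-averaged
WTC values concentrate under null coupling.

Sampling is MCMC via JAGS (≥ 2 chains; default 4 × 1000 after warm-up).
Convergence is gated on rank-normalized split R-hat ≤ 1.01 (bulk and
folded) and ESS ≥ 400; prior- and posterior-predictive checks compare the
observed mean with replicate means.

### Bayes factors

Two routes, chosen automatically:

* **Savage–Dickey** for a nested null dropping exactly one coefficient:
  prior over posterior density at zero, the posterior density estimated by
  kernel density over the MCMC draws, with a between-chain Monte Carlo
  error. Appropriate for moderate evidence; at overwhelming evidence the
  KDE at zero underflows and the marginal route should be used.
* **Exact marginal likelihood** for everything else: with Gaussian
  likelihood and Gaussian priors, coefficients and random intercepts
  integrate analytically (Woodbury identity on the low-rank covariance);
  the remaining 1–2 dimensional integral over the half-normal SD priors is
  evaluated by trapezoid quadrature on the log scale around the Laplace
  mode (61/41 points per dimension, ±7–8 posterior SDs). This route is
  deterministic (mc_error 0), exactly reciprocal, and on conjugate
  problems equals the closed-form Bayes factor to machine precision.
  It replaces bridge sampling, which would only approximate the same
  quantity with Monte Carlo noise.

The sequential stopping rule monitors BF10 from 20 dyads per condition
onward and stops at BF > 5 (support for the full model) or BF < 0.20
(support for the null), otherwise declaring resources exhausted.

### Mediation

Dyad-level two-equation linear mediation,
$M = \alpha_0 + aT + \gamma C + e_1$,
$Y = \beta_0 + c'T + bM + \delta C + e_2$, with the social-context
indicator as co-predictor $C$ in both equations when the treatment is a
laughter variable. Both regressions are conjugate normal–inverse-gamma
problems, so the posterior is sampled *exactly* (i.i.d. draws, flat-ish
prior $v_0 = 10^6$); posterior means match OLS, which the tests assert.
Per draw ACME $= ab$, ADE $= c'$, total $= c' + ab$ — the linear identity
total = ADE + ACME holds exactly. Proportion mediated excludes draws with
$|{\rm total}| < 10^{-6}$ (excluded fraction reported) and is summarized by
its median, because the ratio is heavy-tailed when the total effect is near
zero. Intervals are 95% equal-tailed posterior quantiles (type-7).
The grid over treatments × mediators × outcomes reports uncorrected ETIs —
with ~200 cells, roughly 5% of null cells will exclude zero by chance, so
grid hits are screening leads, not confirmations.

## The synthetic-data generator

The generator is the package's test bed: dyadic recordings with a *known*
coupling level, laughter annotations with *known* expected totals, and
outcomes with *known* structural paths.

* **Coupling**: each channel carries
  $\kappa g + \sqrt{1-\kappa^2}\, h_{p,roi}$ where $g$ is one band-limited
  (8–75 s) Gaussian component shared by the whole dyad and $h$ is
  participant/ROI-specific; $\kappa$ tunes band coherence directly and
  monotonically (verified over $\kappa \in \{0, .3, .6, .9\}$).
* **Noise**: white channel noise (SD 0.5), 1/f background (SD 0.5),
  sinusoids at ~1.0 Hz (cardiac, amp 0.3), ~0.25 Hz (respiratory, 0.2) and
  ~0.1 Hz (Mayer, 0.3) with small frequency jitter — all below the 3.9 Hz
  Nyquist — plus optional boxcar motion artifacts (default rate 0, so the
  clean default cohort passes the quality gate).
* **Laughter**: Poisson bout onsets, log-normal durations (mean 2.5 s,
  σ_log 0.6). Rates are calibrated in closed form by inverting the
  Boolean-model coverage formula $p = 1-e^{-\lambda\mu}$ and the union
  coverage $1-(1-p)^2$, so the expected dyad-union total matches the
  per-cell targets (135 / 51.2 / 36.1 / 0.52 s in the manipulation window;
  ~50 s in free interaction). Only the mean totals are calibrated — the
  bout-level distribution is a modelling choice.
* **Defaults as study conditions**: cell couplings default to 0 (real
  dyads in this paradigm do not exceed chance synchrony) and the
  structural defaults are $a = b = 0$, $c' = 0.5$ (direct effects without
  a synchrony-mediated path). Tests that need positive coupling or a
  mediated path set those parameters explicitly.
* **Raw intensities** are synthesized by inverting the Beer–Lambert
  transform around a constant baseline, so the preprocessing chain can be
  exercised end-to-end and its recovery checked against the generating
  concentrations.
* **Reproducibility**: one master seed; every dyad/stream derives its
  substream via a documented 31-bit multiplicative hash
  (`substream_seed`), so cohorts are bitwise reproducible and
  order-independent.

What the generator does **not** emulate: hemodynamic response convolution
with events, optode–scalp coupling physics, laughter contagion between
partners (tracks are independent given the cell), serial dependence of
questionnaire items beyond a shared dyad effect, and gender/condition
structure in the surrogate pool. Passing tests therefore certify the
estimator and inference chain on signals with the *assumed* statistical
structure; they do not certify robustness to real-data pathologies such as
systemic physiology shared across a dyad, which would inflate both real and
pseudo-dyad coherence.

## Problem sizes used in the checks

The verification suite runs at sizes chosen to make the checks sharp but
cheap: coupling-recovery cohorts use a single-ROI, 4-channel montage and
one 300-s phase (20 dyads per κ level; 20 cohorts for the zero-coupling
surrogate check with 5 surrogate partners per participant); hierarchical
recovery uses 20 replicates of 200 dyads; mediation recovery uses n = 500;
the laughter calibration uses 1000 replicates. The surrogate plan's default
of 100 partners and the full 16-channel montage remain the analysis
defaults.

## Known limitations

* HbR is carried through the chain and selectable (`signal = "hbr"`), but
  the defaults and all checks use HbO.
* Savage–Dickey density estimation at zero fails (returns Inf) when the
  posterior has essentially no mass at zero; use the marginal route there.
* The mediation model is linear with no treatment×mediator interaction
  (a flag exists in the design but the default two-equation structure is
  the implemented one) and no sensitivity analysis for unmeasured
  confounding.
* ELAN's EAF XML is not parsed; the tab-delimited export is the interface.
* SNIRF (HDF5) containers are not read or written; per-channel CSV/TSV
  tables are the recording interface.
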