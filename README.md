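# dyadsync

Interbrain synchrony analysis for dyadic fNIRS hyperscanning experiments.

Hyperscanning studies record two interacting people's cortical hemodynamics
simultaneously and ask whether their brain signals align — and whether that
alignment carries social meaning. `dyadsync` implements the full analysis
chain for such a study, for researchers who want a tested, reproducible
alternative to one-off MATLAB/R scripts:

* a **simplified fNIRS preprocessing chain** — optical density, motion
  detection, spline correction, wavelet despiking, zero-phase band-pass,
  and the modified Beer–Lambert transform to ΔHbO/ΔHbR;
* **wavelet transform coherence** (WTC) between partners' region-of-interest
  signals with an adaptive period band and cone-of-influence exclusion;
* a **pseudo-dyad surrogate null** (each participant paired with random
  non-partners) to establish the chance level of synchrony;
* **laughter annotation algebra** — interval unions across the dyad, phase
  assignment with pre-onset windows, relative durations (LBMP/LBFI);
* **questionnaire outcome scoring** — liking composites, Cronbach's alpha,
  IOS bonding, prosociality ratios;
* **Bayesian hierarchical Gaussian models** with Bayes-factor model
  comparison (exact marginal likelihoods or Savage–Dickey) and a
  sequential BF stopping rule;
* **Bayesian mediation** (treatment → synchrony → outcome) with ACME, ADE,
  total effect, proportion mediated and 95% equal-tailed intervals;
* a **synthetic-cohort generator** with known cross-brain coupling and known
  structural paths, so every stage is testable without any real recording.

## The statistic at the core

Coherence between partners' signals $x, y$ is computed from smoothed Morlet
wavelet spectra,

$$R^2(s,t) = \frac{\left|S\left(s^{-1} W_{xy}(s,t)\right)\right|^2}
  {S\left(s^{-1}|W_x(s,t)|^2\right) \; S\left(s^{-1}|W_y(s,t)|^2\right)}
  \in [0,1],$$

with Gaussian-in-time (SD $s/\sqrt{2}$) and 0.6-octave boxcar-in-scale
smoothing $S$, analytic Morlet mother ($\omega_0 = 6$). Per segment the
analysed period band runs from 8 s to duration/4 (a 300-s segment gives
8–75 s ≈ 0.0133–0.125 Hz); cells inside the cone of influence
($\sqrt{2}\,s$ from an edge) are excluded, and the remaining cells are
averaged to one synchrony value per dyad × ROI pair × phase × interval.
Because smoothing biases coherence upward, values are interpreted against
the pseudo-dyad surrogate distribution, never against zero.

## Worked example

Simulate a small cohort in which the Laughter cells carry genuine
cross-brain coupling (κ = 0.8) and the control cells none, then recover the
difference:

```r
library(dyadsync)

cfg <- sim_config(n_dyads_per_condition = 2,
                  phase_plan = data.frame(phase = "manipulation",
                                          duration_s = 300, preonset_s = 60),
                  rois = c("IFGl", "TPJr"), channels_per_roi = 4,
                  coupling_strength = c(L_S = 0.8, L_NS = 0.8,
                                        NL_S = 0, NL_NS = 0),
                  seed = 42)
cohort <- generate_cohort(cfg)

syn <- do.call(rbind, lapply(cohort$recordings, dyad_synchrony))
merge(aggregate(wtc_value ~ dyad_id, syn, mean),
      cohort$ground_truth[, c("dyad_id", "laughter", "kappa")])
#>   dyad_id wtc_value laughter  kappa
#> 1 dyad001     0.653      yes 0.7620
#> 2 dyad002     0.571      yes 0.8339
#> 3 dyad003     0.585      yes 0.7789
#> 4 dyad004     0.724      yes 0.8740
#> 5 dyad005     0.410       no 0.0000
#> 6 dyad006     0.463       no 0.0000
#> 7 dyad007     0.467       no 0.0000
#> 8 dyad008     0.462       no 0.0626
```

Coupled dyads sit around 0.57–0.72 band-averaged coherence; uncoupled
dyads sit at the smoothing-induced chance level around 0.41–0.47 (which is
why the surrogate null matters). Laughter behaviour comes from the
annotation module:

```r
beh <- dyad_behavior(cohort$annotations, cfg$phase_plan,
                     dyad_ids = cohort$ground_truth$dyad_id)
head(beh, 3)
#>   dyad_id  lbmp total_manipulation_s
#> 1 dyad001 0.416                149.8
#> 2 dyad002 0.455                163.7
#> 3 dyad003 0.167                 60.1
```

`lbmp` is the proportion of the extended manipulation window (300 s task +
60 s pre-onset here) covered by the dyad's union laughter. From there,
`build_dyad_dataset()` assembles the one-row-per-dyad table,
`fit_hierarchical()` / `bayes_factor()` run the outcome models, and
`fit_mediation()` / `mediation_grid()` test whether synchrony mediates
treatment effects. `run_pipeline()` chains all stages and writes CSV/JSON
stage outputs plus a manifest.

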