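---
title: "Modelling accommodation under narrowband light with chromacc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling accommodation under narrowband light with chromacc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromacc)
```

## The problem

The eye's longitudinal chromatic aberration (LCA) makes short wavelengths
focus in front of the retina and long wavelengths behind it, a spread of
roughly a diopter between blue and red within the visible range. When a
display uses narrowband primaries, the accommodation system must decide how
far to refocus for each primary, and the finite spectral bandwidth of an LED
maps into a dioptric blur interval that is wider for blue than for red.
`chromacc` implements an analysis pipeline for experiments that measure this
behaviour with dynamic photorefraction: steady-state accommodation and pupil
diameter recorded at 50 Hz while observers view targets under narrowband
illuminants at varying dioptric demands, together with 4AFC Landolt-C acuity
measured by adaptive staircases through trial lenses.

## The chromatic eye model

Ocular refractive error as a function of wavelength is the hyperbola

$$D(\lambda) = p - \frac{q}{\lambda - c}, \qquad \lambda \text{ in } \mu m,$$

with defaults $p = 1.7312$, $q = 0.63346$, $c = 0.21410$, which place zero
defocus at 580 nm. The sign convention is that positive defocus requires
*more* accommodation (red), negative less (blue). Everything downstream uses
this model: the LCA-defocus regressor is the defocus of an illuminant's peak
wavelength relative to 527.5 nm (`relative_defocus()`), the demand of a
stimulus under an illuminant adds the peak's defocus to its dioptric
distance (`demand_for_illuminant()`), and the blur interval of a primary
with bandwidth $w$ is evaluated symmetrically at peak $\pm\, w/2$
(`fwhm_defocus_spread()`). Broadband illuminants are treated as focused at
the reference wavelength (zero LCA defocus); this convention only enters
error plots, never the LCA-compensation model, which is fit on narrowband
conditions.

Trial-lens conditions use the vertex-corrected effective demand
(`effective_demand()`) and the corresponding angular magnification
(`angular_magnification()`); a 1 m screen viewed through +2 ... -7 D lenses
at a 3 cm vertex spans demands from -1.0 to 6.5 D. Acuity gaps in degrees
convert to logMAR by `log10(60 * gap * magnification)`.

`spectral_summary()` reduces a measured radiance spectrum to the summaries
used to describe an illuminant: it weights the spectrum by the luminous
efficiency function V(lambda) (built-in CIE photopic table), reports the
weighted peak and its half-maximum width (linear interpolation between
samples), and integrates to luminance with $K_m = 683$ lm/W; the constant is
a package choice, as only "luminance" is conventionally reported.

## Trace cleaning

Photorefraction traces carry blinks (missing pupil), blink-related
refraction spikes, and an accommodation onset transient. The cleaning rules,
all constants exposed in `chromacc_config()`:

* samples with a missing pupil, plus 60 ms before and 120 ms after each
  missing run, are invalid (`mark_blinks()`); windows are rounded *outward*
  to whole samples, so 60/120 ms at 50 Hz is 3/6 samples;
* samples with |refraction| > 25 D are invalid (`apply_refraction_limit()`);
  the published rule says "greater than 25 D" without a sign — spikes occur
  in both directions, so the magnitude reading is the default and a signed
  variant is available;
* the first 1500 ms (physical-distance profiles) or 2000 ms (trial-lens
  profile) are invalid (`trim_onset()`);
* a per-subject multiplicative calibration gain is applied to refraction
  (`apply_calibration()`); the calibration *measurement* is out of scope —
  the gain is an input.

The cleaning operations only clear validity flags, so they commute. A trial
reduces to its median accommodation and pupil over valid post-onset samples
(`summarize_trial()`); the trial weight is the number of valid samples as a
proportion of the samples *possible in the post-onset window*, so onset
trimming itself does not down-weight a trial. Trials with less than
1000 ms (2000 ms for the trial-lens profile) of valid data are flagged
`kept = FALSE`. No interpolation is ever performed across blinks — samples
are excluded, not imputed.

## Stimulus-response structure

The response curve of a subject under one illuminant is the median response
per demand. Its per-point gradient uses central differences in the interior
and one-sided differences at the ends (a forward-difference variant is a
config switch); a point is *saturated* when its gradient is at or below half
the median gradient. The linear portion is then forced contiguous: the
maximal unsaturated run containing the point of maximum gradient (longer run
wins a tie). The original workflow inspected these flags visually and
occasionally corrected them; `apply_saturation_overrides()` is the hook for
such corrections, but the judgment itself is not reproduced.

Within-trial variability is the RMSE of refraction about an unconstrained
straight line in time, with $n$ in the denominator (the statistic is called
a root-*mean*-square error; an $n-2$ variant is a config flag). The RMSE is
invariant to adding any linear trend, so it measures fluctuation, not drift.
Staircase-length trials (> 20 s) are first divided into
`floor(duration / 5 s)` equal subsets — the floor reading guarantees every
subset lasts at least 5 s — while short trials pass through whole.

## Mixed-effects analyses

All models are fit by maximum likelihood through lme4, following a
fallback ladder for the random-effects structure: the maximal structure is
tried first and a rung is abandoned only on an optimizer convergence
failure; singular fits (variance components at zero) are retained, since
dropping them would silently change the model the evidence asked for. The
structure actually used is recorded in the result. Confidence intervals on
fixed effects are Wald intervals; the reporting convention for categorical
illuminants is contrasts against the shortest-wavelength baseline.

The four analyses:

1. **LCA compensation.** Responses are centered per subject x distance cell
   on the median green (527/528 nm) response; the centered response is
   modelled as `distance * lca_defocus` with subject random intercept and
   slopes. The interaction coefficient is the rate at which the
   compensation slope grows with proximity; the slope reaches unity at
   `(1 - a)/b` diopters (`slope_unity_distance()`), about 4.5 D for the
   published coefficients. The model is fit over the linear portion of each
   curve (`linear_portion_only()`): outside the accommodative range the
   response is pinned at the range boundary and carries no wavelength
   information, and leaving those points in biases the interaction toward
   zero.
2. **Variability.** `log(RMSE)` on mean accommodation plus illuminant; the
   accommodation coefficient back-transforms to percent growth per diopter,
   `100 (exp(beta) - 1)`.
3. **Pupil.** Median pupil on accommodation plus illuminant with random
   intercept and slope.
4. **Acuity.** Three models after the printed exclusions (pupil < 4 mm
   dropped everywhere; the positive-error stratum additionally drops error
   magnitudes > 5.5 D and thresholds > 1.2 logMAR, where acuity saturates):
   within the linear range, `error magnitude x error sign + illuminant`;
   outside it, separate positive- and negative-error models
   `error magnitude x pupil (centered at 4 mm) + illuminant`. Estimated
   marginal means per illuminant are computed through emmeans.

## The best-PEST staircase

Acuity is measured by a 24-trial maximum-likelihood staircase on a logMAR
grid from -0.3 to 1.3 in 0.02 steps. The procedure keeps an unnormalized
log posterior over candidate thresholds under a fixed logistic template
(slope 0.08 logMAR, guess 1/4, lapse 0.01 — the template constants are
config), places every trial at the current posterior mode, and reports the
mode after the last trial. Ties among posterior maxima resolve to the middle
of the tied set, rounding toward the harder level, so a flat prior starts at
the grid midpoint. The mode (not the mean) is the estimate, switchable by
config. Mode estimates from 24 trials carry a small negative bias that grows
with threshold level (about -0.01 to -0.015 logMAR in the simulations shipped
in the tests); this is a property of short ML staircases, shared by the
procedure being modelled, and is why staircase-derived contrasts recover
slightly below their generative values.

## The synthetic-data generator

`simulate_experiment()` emulates the statistical structure of the recordings
so the whole pipeline is testable without the deposited data. A synthetic
observer draws, independently and normally unless noted:

* a green-response line `g(d) = intercept + slope * d` with slope mean 0.9
  (a -0.5 D lag at 5 D) and intercept mean 0; the subject spreads (SD 0.19
  and 0.05) are the published random-effect SDs of the centered model's
  intercept and distance terms. The centered model's small, non-significant
  population means (0.05, -0.02) are folded to zero because green-centering
  cancels any population-level term exactly — they would be unidentifiable
  in recovery;
* LCA-compensation coefficients `a ~ N(-0.26, 1.14)` and
  `b ~ N(0.28, 0.45)`; the steady-state response to a narrowband illuminant
  is `g(d) + (a + b d) * dLCA`, clipped to the observer's accommodative
  range (far point U(0, 0.5) D, near point U(5, 9) D — free parameters, the
  printed example subject spans roughly 0.5-5.5 D);
* microfluctuation noise: AR(1) with a ~2 Hz cutoff whose about-trend RMSE
  is `0.14 * 1.1495^A` diopters at the shortest-wavelength illuminant,
  with multiplicative illuminant offsets (blue > green > red/broadband
  ordering; exact values free) and a lognormal subject scale (SD 0.2,
  free). Only the RMSE law is contractual — the spectrum of real
  microfluctuations is not modelled;
* pupil: `base + slope * A + offset(illuminant)` with slope means
  -0.75 / -0.16 / -0.18 mm/D by experiment profile and offsets spanning
  1.70 / 1.40 / 0.45 mm between the extreme illuminants, plus slow AR
  noise;
* blinks as Poisson missing bursts (0.25 /s, ~150 ms, free), occasionally
  followed by a > 25 D refraction spike so the cleaning rules are
  exercised;
* an onset transient (300 ms latency, 250 ms time constant) that settles
  *exactly* by 1.2 s — before the shortest onset-trim window — so the
  steady-state median is exact in the noise-free limit. The transient is
  cosmetic: it is discarded by trimming and carries no acceptance weight.

`simulate_acuity_experiment()` derives each cell's true threshold from the
generative acuity equation (0.04 logMAR at blue and zero error; illuminant
offsets -0.11 / -0.08 / -0.09; error slopes 0.10 and 0.12 per diopter in
range, `0.21 + 0.08 (pupil - 4)` and `0.06 + 0.04 (pupil - 4)` out of range;
saturation at 1.2 logMAR) and then observes it through a seeded 24-trial
staircase.

What the generator does *not* emulate: vergence and proximal cues,
higher-order aberrations, melanopsin dynamics behind the pupil-wavelength
offsets (they are injected directly), spectacle-wearing subjects, and any
curvature of the response line beyond range clipping. Passing recovery
tests therefore demonstrate that the pipeline estimates what the generator
encodes — parameter recovery under the model's own assumptions — not that
real traces satisfy those assumptions.

## Problem sizes and reproducibility

The recovery studies (`recover_lca_interaction()`,
`recover_variability_growth()`, `recover_pupil_slope()`,
`recover_acuity_contrast()`) each run 20 seeded replicates. Dataset shapes
are the package's choices: 17 subjects x 6 distances x 5 narrowband
illuminants x 4 repeats for the LCA recovery; the pooled 8-subject 8 s x 5
and 9-subject 3 s x 12 profiles for variability; the 9-subject
constant-angular-size profile for the pupil slope; and the full 10-subject
trial-lens acuity protocol (10 lenses x 4 illuminants x 3 staircases) for
the acuity contrast. Replicate seeds derive from one master seed, and every
stage is deterministic given it; identical seeds reproduce simulated CSVs
byte for byte.

Monte-Carlo uncertainty in these studies is dominated by subject draws: with
17 subjects per replicate and an interaction RE SD of 0.45, the mean
interaction estimate over 20 replicates has a standard error near 0.024, so
individual recovery runs can sit a few hundredths away from 0.28 without
indicating bias.

## Numerical choices and degenerate inputs

* Wavelengths are nm at every interface; conversion to um happens inside
  the defocus formula. Wavelengths at or below the model pole are errors.
* The 25 D refraction rule is a strict inequality on the magnitude.
* A curve whose median gradient is not positive is wholly unusable and is
  flagged rather than fit.
* Summaries with no valid samples carry `NA` medians and `kept = FALSE`;
  RMSE requires at least three valid samples.
* `fit_lmm()` returns an explicit non-converged result if every ladder rung
  errors; degenerate designs (green-only centering, single-illuminant
  factors) either drop the term or raise a named error.
* All thresholds are clamped to the staircase grid, so an extreme generative
  threshold cannot place trials outside the tested range.
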