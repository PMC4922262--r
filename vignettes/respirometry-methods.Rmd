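---
title: "Estimating fish metabolic rates from intermittent-flow respirometry: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fish metabolic rates from intermittent-flow respirometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimresp)
```

## The measurement chain

Intermittent-flow respirometry estimates a fish's oxygen uptake by sealing
it in a chamber, recording the decline of dissolved O2, and periodically
flushing the chamber back to full air saturation. `swimresp` implements the
whole chain from raw O2 traces to a statistical comparison of protocols:

1. **Trace model** — validated O2 time series sampled at 0.5 Hz, with
   measure/flush phase labels on an 8-min cycle (5 min sealed measurement,
   3 min flush).
2. **MO2 engine** — within each sealed window, mass-specific oxygen uptake
   is the slope of the ordinary-least-squares regression of concentration
   on time:
   \[
   \dot M_{O_2} = \frac{S \, V_{\mathrm{resp}}}{M},
   \]
   with \(S\) the decline slope (mg O2 L\(^{-1}\) s\(^{-1}\)),
   \(V_{\mathrm{resp}}\) the chamber volume minus the fish volume (L) and
   \(M\) the fish mass (kg); reported in mg O2 kg\(^{-1}\) h\(^{-1}\).
   Microbial background uptake, measured in the empty chamber before and
   after a trial and assumed linear in time, is interpolated to each
   window's midpoint and subtracted.
3. **Metrics** — protocol-specific estimators of maximal metabolic rate
   (MMR), standard metabolic rate (SMR), aerobic scope (MMR − SMR) and
   critical swimming speed (Ucrit).
4. **Comparison** — a repeated-measures linear mixed model of estimates on
   species and method with a fish-level random intercept, pairwise method
   contrasts, model-predicted percent differences, and a fixed-effects
   linear model with Tukey comparisons for Ucrit.

A trace simulator with known ground-truth physiology closes the loop: every
estimator can be validated end to end against the parameters that generated
the data.

## Protocols and their estimators

**Swim tunnel (Ucrit protocol).** After habituation at 0.5 BL s\(^{-1}\)
and a 4-min ramp, speed steps from 4.0 BL s\(^{-1}\) upward in
0.5 BL s\(^{-1}\) increments, three 8-min cycles (24 min) per speed, until
fatigue. MMR\(_{Swim}\) is the MO2 at the highest speed at which the fish
completed at least one full cycle; we take the *maximum* window value there
(the wording of the rule is singular; the mean is available by option).
Ucrit follows Brett's interpolation
\(U_{crit} = U + U_i \, (t / t_i)\) where \(U\) is the last fully completed
speed, \(U_i\) the increment, \(t\) the time swum into the failed increment
and \(t_i = 1440\) s. Nominal tunnel speeds receive a solid-blocking
correction \(\varepsilon = \tau_0 \lambda (A_{fish}/A_{tunnel})^{3/2}\)
(defaults \(\tau_0 = 0.8\), \(\lambda = 1\)); corrections above 5% flag the
fish as too large for the working section.

**Exhaustive chase.** Three minutes of chasing plus one minute of air
exposure, then resting respirometry beginning within 10 s. The first
minutes of measurement capture excess post-exercise oxygen consumption
(EPOC); MMR\(_{Chase}\) is the steepest 1-min slope within the first 5 min,
found by scanning every window position at the 2-s sample resolution
(exhaustive and reproducible; ties go to the earliest window). SMR is the
mean of the lowest 10% of window MO2 values recorded after a recovery
cutoff (default 6 h, the lower end of the conventional 6–12 h wait), with
\(k = \lceil 0.1 n \rceil \ge 1\) and at least 10 eligible windows required
so the rule cannot collapse onto a single noisy window.

**Circular chamber.** A stir-bar vortex forces swimming; measurement is
continuous during exercise because flushing is impossible until fatigue.
MMR\(_{Circle}\) is the steepest 1-min slope within the first 5 min
(configurable to 7 min); SMR\(_{Circle}\) follows the same lowest-10% rule
after recovery. Windows whose O2 minimum falls below 80% of air saturation
are flagged — never silently dropped — since hypoxia triggers stress
responses that contaminate MO2.

An indirect SMR estimator for swim trials extrapolates the MO2–speed
relationship \( \dot M_{O_2}(U) = a + b U^c \) (nonlinear least squares,
\(c \ge 1\)) to zero speed; an exponential form is available by option.
Neither functional form is canonical; the power form is the default for its
drag-power interpretation.

## The generative model behind the simulator

Each simulated fish carries a true SMR, MMR, Ucrit, a metabolic power
exponent \(c\) (default 2), an EPOC decay time constant \(\tau\), and
per-protocol *attenuation* fractions. During swimming,

\[ m(U) = \mathrm{SMR} + a_{p}\,(\mathrm{MMR}-\mathrm{SMR})
  \left(\frac{U - U_0}{U_{crit} - U_0}\right)^{c}, \]

capped at the method-expressed maximum; after exhaustive exercise,
\( m(t) = \mathrm{SMR} + A e^{-t/\tau} \) with
\(A = a_{p} (\mathrm{MMR}-\mathrm{SMR})\). The attenuations encode the
empirical finding that short protocols under-express the maximum: a fish
forced straight into burst swimming does not recruit all aerobic muscle.
Cohort defaults are calibrated so the generative method-level MMR ratios
are 1 : 1/1.2 : 1/1.25 (swim : chase : circle), i.e. swim-tunnel MMR
exceeds chase and circle by 20% and 25% at the cohort level.

Within a sealed window the generative rate is held constant (matching the
linear-regression estimator), and the O2 decline is computed from exact
closed-form integrals of the rate profile, so simulated traces satisfy mass
balance to machine precision. Flushing either restores saturation instantly
or approaches it exponentially.

Key default conditions, chosen once as realistic values for small tropical
reef fish and not revisited:

* **Sampling** 0.5 Hz; cycle 300 s measure + 180 s flush.
* **Chambers** 4.8 L swim tunnel (7 × 36 × 7 cm working section), 1.615 L
  resting chamber, 2.654 L circular chamber; fish volume defaults to
  1 L kg\(^{-1}\) of body mass (fish are near neutral buoyancy).
* **Saturation** 6.2 mg O2 L\(^{-1}\) at 28.5 °C seawater, a configuration
  constant rather than an internal solubility model.
* **Sensor noise** 0.005 mg O2 L\(^{-1}\) i.i.d. Gaussian per sample — the
  resolution scale of optical O2 meters; it yields within-window slope
  \(r^2 \approx 0.97\), matching practice.
* **Background** 0.05 mg O2 h\(^{-1}\) at trial start drifting by
  0.005 mg O2 h\(^{-2}\): under 5% of a small fish's SMR, the hygiene
  target of bleached, dried chambers.
* **EPOC decay** \(\tau = 1200\) s, a single-exponential recovery over
  1–2 h typical of small reef fish; a bi-exponential tail is a possible
  extension, not modelled.
* **Spontaneous activity** each measurement window adds a positive excess
  \(|N(0, 0.03 \cdot \mathrm{SMR})|\), so resting traces settle to SMR plus
  small activity, never below it.
* **Between-fish variation** log-normal (positivity), with SMR and MMR
  sharing one fish-level factor — exactly the random intercept the
  comparison model assumes on the log scale.
* **Simulated trial sizes**: habituation is shortened to 32 min and
  resting trials run 8 h (giving ≥ 15 windows after the 6 h cutoff); these
  sizes keep simulation studies cheap while preserving every structural
  feature the estimators rely on.

### What the simulator does and does not emulate

It reproduces the protocol structure, the speed–metabolism relationship,
EPOC kinetics, background drift, sensor noise, saturation floors and
missing trials. It does **not** model temperature dynamics, chamber mixing
kinetics during measurement, gait transitions, bi-exponential EPOC, diel
SMR rhythms, or the hydrodynamics of the circular vortex (whose true
swimming speed is unmeasurable — one reason that protocol resists
standardization). Passing recovery tests on simulated data therefore
demonstrates the *estimators* are faithful to their definitions under
realistic noise; it does not certify any field protocol.

## Statistical stage

The comparison model is
`response ~ species * method + (1 | fish_id)`, fitted by REML. The
interaction is tested first and removed when non-significant at
\(\alpha = 0.05\) (model simplification); omnibus F tests use Satterthwaite
denominator degrees of freedom — the convention this stack (lme4/lmerTest)
supports — and all-pairs method contrasts use a single-step multivariate
adjustment (`"mvt"`; its quasi-Monte-Carlo p-values are seeded internally
so results are reproducible). Fitting on the log scale makes contrasts
log-ratios, the natural scale for multiplicative method effects; the
identity scale (the default) mirrors conventional reporting, and percent
differences \(100 (\hat y_A - \hat y_B)/\hat y_B\) come from
population-level model predictions, overall and per species. Fish with
missing methods are retained by the mixed model; if almost no fish repeats,
the fit falls back to a fixed-effects model with a loud warning.

Ucrit uses a fixed-effects model with species nested in swimming mode and
Tukey-adjusted all-pairs species contrasts. Group letters are computed by
an insert-and-absorb pass over the non-significant-pair graph (two groups
share a letter exactly when they are statistically indistinguishable),
implemented in-package and cross-checked against hand-constructed cases.

## Numerical choices and degenerate inputs

* Time is 0-based seconds; all windows are half-open \([start, end)\); a
  sample on a boundary belongs to the next phase.
* Slope fits require ≥ 3 points and non-zero time variance; a perfectly
  flat window has slope 0 and undefined \(r^2\) (reported as `NA`).
* The steepest-window scan breaks ties toward the earliest window, with a
  relative tolerance of 10\(^{-9}\) so that exact ties are not scrambled by
  floating-point jitter.
* A background-corrected uptake at or below zero is floored at zero and
  flagged (`background_overcorrection`) rather than erroring: quiet
  night-time windows with a noisy background estimate can legitimately
  cross zero.
* \(r^2\) is reported per window but not used as a rejection filter by
  default; an optional `min_r2` flags poor fits.
* Partial trailing measurement windows are kept when ≥ 60 s, otherwise
  dropped.
* Fatigue time is read off the 2-s sampling grid, so recovered Ucrit is
  exact up to \(U_i \, \Delta t / t_i \approx 7 \times 10^{-4}\)
  BL s\(^{-1}\).

## Known limitations

Two estimator properties deserve emphasis, both *documented consequences of
the published estimation rules*, not implementation artifacts:

* **Steepest-window selection bias.** Taking the maximum-slope 1-min
  window among ~120 overlapping noisy candidates biases post-exercise MMR
  upward. The effect is largest for the circular chamber (largest
  chamber-volume-to-mass ratio, hence noisiest window slopes): under the
  default conditions the median inflation is roughly 6–8%, which also
  shrinks the recovered swim-vs-circle percent difference below its
  generative 25%. The chase protocol, with its smaller chamber, stays
  within ~2%.
* **Lowest-10% selection bias.** Averaging the smallest decile of noisy
  window values biases SMR downward as sensor noise grows; the test suite
  asserts this trend explicitly. At the default noise it is under 1%, but
  the same machinery quantifies it for any configuration.

Because the two resting protocols differ in chamber volume, these
sub-percent biases differ slightly between methods; with many paired
observations a mixed model can flag that difference as statistically
significant even though it is practically negligible — a useful reminder
that equivalence is a question of effect size, not p-values.

## Reproducing the validation studies

`estimator_recovery_study()` simulates ~50 fish under the default
conditions and returns estimate-vs-truth errors for every metric;
`method_recovery_study()` fits the comparison stage to 200 replicate
summary-level cohorts and reports contrast-CI coverage of the true
log-ratios and the frequency of correct method ordering. Both are invoked,
together with the slope oracles and a full four-species trace-level cohort
comparison, by `scripts/acceptance.R`.
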