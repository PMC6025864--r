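---
title: "Predicting VO2max from submaximal treadmill running: models and methods"
author: "vo2pipe maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting VO2max from submaximal treadmill running: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Maximal oxygen uptake (VO2max, ml·kg⁻¹·min⁻¹) is the standard measure of
cardiorespiratory fitness, but measuring it requires an exhaustive graded
exercise test with breath-by-breath gas analysis. `vo2pipe` implements a
pipeline that predicts VO2max from *submaximal* running — the warm-up and
first three stages of an incremental treadmill protocol — using only a
heart-rate monitor and body-worn accelerometers (tibia, lower back, upper
back). The pipeline covers raw-signal preprocessing, a 490-column candidate
feature catalogue, wrapper-based feature selection, a random-intercept
linear mixed model, nested leave-one-subject-out (LOSO) evaluation, and a
replication of the classic contact-time/heart-rate ratio model.

Because no raw cohort of this kind is publicly deposited, the package
includes a first-class synthetic session generator whose statistical
structure matches what the analysis assumes, so that every stage is
testable end to end.

## Protocol and preprocessing

The simulated incremental test mirrors the standard design: a 4-minute
warm-up at 8 km/h (women) or 9 km/h (men), then 4-minute stages separated
by 1 minute of rest, the first stage at warm-up speed and each later stage
+1.5 km/h, at a 1% gradient. Stage 0 denotes the warm-up.

Preprocessing follows the measurement conventions of this literature:

* **VO2max label** — the maximum over all time-based 30 s windows of the
  mean breath-by-breath VO2, windows advanced sample by sample. Windows
  are time-based because breath sampling is irregular (~4 s spacing).
* **Heart rate** — breath-by-breath samples averaged in consecutive 10 s
  bins anchored at the first breath, then smoothed with a 7-point running
  median \{x(t−3), …, x(t+3)\}. Edge bins use a shrunken window rather than
  padded data; an empty bin raises an error instead of being silently
  interpolated.
* **Acceleration** — 4th-order Butterworth low-pass at 50 Hz, applied
  forward–backward (zero phase), then tilt correction: the axes are
  rotated so the whole-trial mean acceleration vector maps onto the
  vertical, and the gravity magnitude is subtracted from the vertical
  channel. We estimate gravity by the *magnitude of the trial mean* rather
  than the literal constant 1 g; for calibrated sensors the two coincide,
  and the mean-based estimate guarantees an exactly zero-mean corrected
  vertical channel. The protocol has no dedicated standing window, so the
  stationary-mean assumption is applied to the whole trial (running
  segments are zero-mean per cycle, rests are quiet standing).

The filter order for the 50 Hz stage is not dictated by convention beyond
the cutoff; we use a 4th-order zero-phase Butterworth, matching the
explicitly specified 15 Hz contact-time filter and avoiding phase
distortion of the stage windows. No IIR filter design routine ships with
the pre-installed R stack, so the package implements the bilinear-transform
Butterworth design directly; its DC, passband, −3 dB and stopband behaviour
is pinned down in the test suite.

## The feature catalogue

For stages 0–3, with the first and last 10 s of each stage discarded
(treadmill acceleration/deceleration):

* 2 descriptive features: gender `G` (0 = male, 1 = female) and body mass
  `BM` (kg);
* 8 heart-rate features: the smoothed-HR average over the *last minute* of
  each stage (`HR_i`, rest periods depress earlier minutes) and its
  inverse `HR_i_inv`;
* 480 accelerometer features: {AVG, SD, VAR, RMS, P} × {tibia `t`, lower
  back `bl`, upper back `bu`} × {x = anterior–posterior, y = mediolateral,
  z = vertical, total = per-sample √(x²+y²+z²)} × stages 0–3, each with
  its inverse.

Numerical conventions: SD uses the n−1 denominator and VAR is computed as
SD² (exactly consistent); power P is defined as the mean squared signal and
computed as RMS², the standard signal-power definition (the source
literature does not define P; its redundancy with RMS is harmless because
selection admits at most a few columns). Inverses are guarded by
ε = 10⁻⁹: a near-zero base value flags the inverse as missing (`NA`)
rather than producing infinities, and selection skips flagged candidates.

## Prediction model

The regression is an unpenalized linear mixed model with a random intercept
for the test occasion (pre/post intervention):

$$\mathrm{VO_2max} \sim 1 + (1\,|\,\mathrm{Test}) + G + BM + \dots$$

Grouping is by the pre/post *test label* (two levels), not by subject —
this mirrors the source analysis and is flagged here because users may
expect subject-level grouping for repeated measures.

Estimation is REML, profiled to the single variance ratio
θ = σ²_b/σ²_e and optimized in one dimension; all linear algebra runs on
cross-products through the Woodbury identity. This custom fitter exists for
speed: nested selection needs on the order of 10⁵–10⁶ fits, three orders of
magnitude beyond what a general mixed-model package sustains. The test
suite verifies agreement of fixed effects, variance components, standard
errors and BLUPs with `lme4::lmer` on fixtures. When the variance estimate
hits the zero boundary the fit reduces exactly to OLS (σ²_b = 0, all BLUPs
zero). Inside cross-validation, predictions include the test-level BLUP
(both levels appear in every training fold); the shipped full-data
predictor functions are fixed-effects only, as published.

## Feature selection

Greedy forward selection starts from the descriptive base {G, BM} (not the
empty set). Each iteration scores every remaining candidate `f` by the
adjusted explained variance of base ∪ selected ∪ {f}, computed by an
*inner* LOSO loop over the training subjects:

$$R^2_{adj} = 1 - \frac{n-1}{n-p-1}\,(1 - R^2), \qquad
R^2 = 1 - \frac{\sum_i(\hat y_i - y_i)^2}{\sum_i(y_i - \bar y)^2}$$

with pooled predictions, \(\bar y\) the pooled observed mean (the formula's
mean is not fold-subscripted), `n` the number of training rows, and `p` the
feature count *including* the base but excluding the intercept (the
adjustment's purpose is comparing sets of different size, so all
non-intercept columns count). The best candidate is accepted iff its score
improves the current set's score — recomputed each iteration, not the
original base score — by at least 0.05; ties break by the canonical
registry column order; selection stops when no candidate clears the
threshold. The procedure is deterministic.

The candidate scorer evaluates the profiled REML criterion for all
candidates simultaneously: per inner fold, the bordered normal equations
[base | candidate] are solved through the Schur complement of the shared
base block, and θ is minimized on a log-spaced grid with local refinement.
This is numerically equivalent to fitting each candidate separately
(agreement ~10⁻⁴ in R²adj, asserted in tests) at a small fraction of the
cost. Columns are centred and scaled internally — a fixed affine
reparametrization absorbed by the intercept — because inverse features span
six orders of magnitude.

Feature-set combinations gate the candidate pool: F1 = base only (no
selection), F2 = +8 HR candidates, F3 = +480 accelerometer candidates,
F4 = +488 both.

## Evaluation

The outer loop is LOSO by subject: all of a subject's sessions (one or two
tests) are held out together; selection and model fitting see only the
remaining subjects, so the inner CV never touches held-out rows (a leakage
probe in the test suite corrupts a held-out subject's outcome and asserts
its predictions are unchanged). Pooled predictions over all N tests feed
five metrics: R², MAE, RMSE (ml·kg⁻¹·min⁻¹), MAPE and RMSRE (percent).
Metrics are pooled over predictions, not averaged over folds.

The sampling-rate robustness experiment freezes a model trained at the
native rate, decimates only the tibia signal to each target rate
(anti-alias zero-phase low-pass at 0.4× the target rate, then every k-th
sample; the decimation method is a package choice, not prescribed), and
recomputes only the warm-up inverse tibia-variance feature before
re-scoring.

## Contact time and the ratio model

The comparison model predicts VO2max from (1/t_c)/HR, where t_c is the
foot–ground contact time. Contact is detected on the tilt-corrected
vertical lower-back (≈ centre of mass) acceleration after 4th-order 15 Hz
zero-phase Butterworth smoothing: a contact starts at a negative→positive
zero crossing and ends at the next positive→negative crossing — stance is
the positive-acceleration phase, flight rests near −1 g. The crossing
direction is fixed by this physics; crossing times are linearly
interpolated between samples to de-bias durations at finite rate, and
events outside the physiological running range [0.1, 0.5] s are discarded
to reject double-crossings (whether the original method gated durations is
unstated; running contact times at 8–12 km/h sit comfortably inside).
Per stage, t_c is the mean duration of contacts *starting* inside the full
stage window; the ratio feature averages (1/t_c)/HR over stages 1–3
(the warm-up is omitted because the comparison protocol has none). Both
historical variants are evaluated with fixed-effects OLS: method 1 fits
separate per-gender models on the ratio alone, method 2 one model on
gender plus the ratio.

One caveat is documented in the tests: for waveforms with *discontinuous*
edges (a rectangular stance/flight pattern), the 15 Hz smoothing shifts
both zero crossings outward whenever the zero level is not the edge
midpoint, a deterministic bias of a few milliseconds. For band-limited
gait — including everything this generator produces — the filter is
transparent and recovery is exact to ~1 µs.

## The synthetic world

The generator states one world and the tests measure it; its defaults were
fixed before the acceptance suite was frozen and are not tuned per test.

**Truth model.** Following the design goal that the published best feature
set be the recoverable ground truth, the truth is *linear in the features*:
each subject draws two wearable latents — the inverse warm-up heart-rate
steady state `hr0inv` ~ N(1/165, 5.1·10⁻⁴) (≈ 165 ± 13 bpm) and the
inverse warm-up tibia total-acceleration variance `varinv` ~ N(2.7, 0.58)
g⁻² — and

$$\mathrm{VO_2max}_{true} = b_0 + c_G G + c_{BM}(BM - \mu_{BM,g})
  + c_H\,\mathrm{hr0inv} + c_V\,\mathrm{varinv} + \varepsilon$$

with coefficients defaulting to the published full-data predictor
(−8.861, −0.2538, 5546, 4.879). The intercept and sd(ε) ≈ 1.3 are derived
so the pooled marginal has exactly the configured mean 46.73 and SD 6.51;
the implied per-gender means (51.8/42.9) sit close to the published
cohort's (51.55/43.65). Each latent contributes ≈ 8 (ml·kg⁻¹·min⁻¹)² of
unique outcome variance, which puts the population R² of
{base}, {base+HR}, {full} near 0.56 / 0.74 / 0.92 before cross-validation
shrinkage — bracketing the published 0.494 / 0.692 / 0.781 column.

A direct consequence, worth knowing when reading the combination-ranking
test: in this world the accelerometer-only pool (F3) *contains* the true
tibia feature, so F3 performs comparably to F2 rather than below F1 as the
original cohort showed. The generator plants the published F4 structure;
it does not reproduce the original cohort's accelerometer-only failure
mode, which would require accelerometer features that correlate with the
outcome only through heart rate. The asserted ranking is therefore
F4 ≥ F2 ≥ F1.

**Sessions and signals.** 13/28 of subjects return for a post test, whose
fitness gain (+2 ml·kg⁻¹·min⁻¹ by default) flows through the two latents
(half each), keeping the truth exactly linear in session feature values; a
shared test-level intercept (sd 1.0) gives the (1|Test) term non-zero
variance. Day-to-day latent jitter is small (≈1.4 bpm, 0.06 g⁻²).
Breath timestamps are jittered 4 ± 1 s; VO2 and HR follow first-order
kinetics toward stage-specific steady states (τ = 25/30 s in stages,
slower in rests), VO2 plateauing at the session's true value in the final
two stages (so the plateau attainment criterion is exercised) and warm-up
HR approaching 1/hr0inv. Acceleration is a step-frequency-locked template
(f = 2.2 + 0.05·speed Hz, ≈2.6–3.0 Hz) per stage: the lower-back vertical
channel is the two-harmonic waveform sin θ + a₂·cos 2θ whose stance
fraction has a closed form (the contact-time ground truth); the tibia adds
a half-sine impact transient per step (width 80 ms, chosen band-limited so
decimation to ≥ 50 Hz preserves the variance feature) and is scaled so the
noiseless warm-up Var(total) equals 1/varinv exactly. Channels carry
Gaussian noise (0.05 g), a +1 g vertical gravity component, an optional
mounting tilt ≤ 5°, and ±16 g range clipping.

**Stage-level variability.** Per-stage HR steady-state noise
(sd 8/10/12 bpm, stages 1–3) and multiplicative tibia amplitude jitter
(log-sd 0.3, stages ≥ 1) make the warm-up the cleanest link, so selection
identifies the *warm-up* features rather than indistinguishable
cross-stage aliases. These magnitudes are free parameters of the stated
world: between-day variability of submaximal HR is largest near maximal
effort.

**Reproducibility.** All draws flow from one root seed: cohort-level
quantities consume the root stream in fixed order, then each session gets
a derived seed; session truth is drawn first under that seed, so
signal-free "stub" cohorts and full-signal cohorts share identical planted
truth. The gender split is deterministic (round(sex_ratio·n) males,
permuted), which pins the cohort ratio and keeps LOSO training folds
gender-mixed.

**What a green test does not establish.** The generator emulates the
statistical structure the analysis assumes — monotone links, gait-locked
periodicity, impact transients, plateauing VO2 — not biomechanics: no
musculoskeletal dynamics, no treadmill-belt physics, no HR artifacts
(the original study simply excluded faulty tests), no non-plateau
sessions. Green recovery tests establish that the pipeline finds structure
that is present as modeled; they say nothing about sensor-specific noise
the model omits.

## Degenerate inputs and numerical choices

* Breath series shorter than 30 s, empty HR bins, stages ≤ 20 s, mean
  acceleration below 0.5 g, fewer than 5 contacts per stage, fewer than 2
  subjects or 4 protocol stages, n − p − 1 ≤ 0 in the adjustment — all
  raise typed errors rather than returning values.
* Rank-deficient designs raise a collinearity error naming the offending
  columns; a perfectly constant candidate is unselectable by construction
  (its Schur complement is flagged).
* The REML boundary θ → 0 is compared explicitly against the interior
  optimum; boundary fits are exact OLS, never NaN.
* Zero-phase filtering uses odd-reflection padding sized from the slowest
  filter pole, so startup transients decay outside the returned segment.

## Scaled-down test sizes

The test suite runs the statistical criteria at the sizes stated in their
tests: recovery over 25 seeds at the full 28-subject cohort scale
(signal-free stubs carry the same planted truth as full signal cohorts);
combination ranking over 8 seeds at 20 subjects; signal-level fixtures at
128 Hz with shortened stages where only structure, not bandwidth, matters;
native 1024 Hz wherever a criterion states it (feature count, contact
time, downsampling). Statistical thresholds (≥80% of seeds, ≥90% of
seeds, 3 SE, 2 ms) are as specified, not relaxed for the smaller sizes.

## Known limitations

* The random effect groups by pre/post test label (2 levels), as
  published; with many repeated subjects a subject-level random effect
  would be the natural extension.
* The 50 Hz low-pass order/phase and the HR 10 s averaging scheme (bins
  vs sliding) are unstated in the source conventions; the package's
  choices (4th-order zero-phase; left-anchored bins) are documented above.
* Contact-time estimation from the lower back is known to be less accurate
  than foot-mounted sensing; the generator's gait is idealized and will
  understate that error.
* MAPE/RMSRE require strictly non-zero observed values (always true for
  VO2max).
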