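---
title: "popMDSA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{popMDSA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popMDSA analyzes blocked two-context audiovisual go/no-go sessions with
simultaneously recorded population spiking. This vignette is the package's
account of the underlying models, the parameters that matter, the numerical
conventions, and the choices we made where the design was genuinely open.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Task structure and behavioral models

Every multimodal trial presents a grating (45° → go, 135° → no-go) and a
tone (5 kHz → go, 10 kHz → no-go); the blocked, uncued context determines
the relevant modality. A trial is *congruent* when the two modalities
indicate the same action. `classifyTrials()` derives congruence, the
expected action and (given choices) the outcome deterministically from this
mapping.

**d′.** Performance is z(hit rate) − z(false-alarm rate) with both rates
clipped to [0.01, 0.99] before the inverse-normal transform, so |d′| is
capped at 2 z(0.99) ≈ 4.653 and degenerate sessions (0% or 100% rates)
remain finite. Chance responding gives d′ = 0; `dprimeNull()` provides the
Monte-Carlo null used both for the chance level and for the tail
probability of the d′ ≥ 1.7 expert criterion.

**Consistency blocks.** Binary choices prevent trial-resolved strategy
inference, so we assume across-trial constancy and compute moving-average
fraction-correct curves separately for the four congruence × action trial
types. A trial is *consistent* when all four curves are strictly above 0.5
("above chance" is strict: a window fraction of exactly 0.5 is
exploratory). Two open details are resolved as follows and exposed as
options: the window is **trailing** (the current trial and the 19 before
it) with a centered variant available, and windows missing one of the four
types mark the trial non-consistent; trials before the first complete
window are exploratory. The default width of 20 trials is the narrowest
window that in practice still contains all four types while remaining
sensitive to strategy switches. `consistencyNull()` calibrates the
consistent-trial count N and the longest run L against 100,000 random
sessions (70 trials, constant 75% lick rate by default — the typical
incongruent-trial lick rate of a weakly performing context).

**Choice models.** Five Bernoulli observation models are fitted by
maximizing the mean log-likelihood: correct-modality and opposite-modality
(parameter-free), context-unaware constant lick rate *p*, context-aware
bias *β* (lick certain in go trials, probability β in no-go trials) and
context-aware lapse *λ* (error probability λ in both). Predicted
probabilities are clipped to [0.001, 0.999], which makes the log-likelihood
finite at the boundaries; the single free parameter is found by Brent
search (`optimize`, golden-section plus parabolic interpolation) on [0, 1]
at tolerance 1e-6, with an explicit boundary check because the bracketing
search never lands exactly on 0 or 1. Models are compared by mean
log-likelihood over consistent incongruent trials (the trials that require
context inference); exact ties are broken toward fewer parameters, then by
name, so rankings are deterministic.

## Rate preprocessing

Spike counts in 10-ms bins are convolved with a unit-mass Gaussian kernel,
σ = 100 ms, truncated at ±4σ. Near trial edges the kernel is renormalized
over the available bins (no padding), so edge rates are unbiased at the
cost of exact count conservation within 4σ of the edges; in the interior
the integral of the smoothed rate equals the spike count to machine
precision. Because the kernel is symmetric, decoders see information from
up to ~200 ms in the future — visible as above-chance stimulus decoding
slightly before onset.

Z-scoring subtracts, per unit, the across-trial mean of the time-averaged
baseline activity (window −1500…0 ms) and divides by the standard deviation
of the unit's rates pooled over **all** trials and all timepoints of the
trial. The pooled denominator was chosen over a per-trial standard
deviation for stability at low rates; units with numerically zero pooled
variance are dropped and listed (`"degenerate_std"`) rather than imputed,
to avoid fabricating signal.

Per-unit sensitivity to a binary variable is |mean₁ − mean₀| divided by the
across-trial standard deviation at each timepoint, averaged within the pre-
(−1.5–0 s) and on-stimulus (0–3 s) epochs. The denominator includes the
signal variance, so a true effect of d standard (noise) deviations reads as
d/√(1 + d²/4) for balanced classes.

## Signal-variance decomposition

For a scalar signal y over conditions x, Var[y] = E_x[Var[y|x]] +
Var_x[E[y|x]] — noise plus signal variance. We use population moments
(denominator n) and weight conditions by their empirical frequency, so the
identity holds exactly (tested to 1e-10) and unbalanced designs are
handled. Population activity is concatenated over all timepoints of all
trials (samples = trial × timepoint, features = units) before PCA, so both
trial-to-trial and within-trial variance contribute. The cumulative
relative signal variance at K is the per-PC signal variance summed over the
first K PCs divided by the total variance those PCs capture; at K equal to
the unit count it is the full-space value and is invariant under any
orthonormal change of basis. The baseline replaces PCs by Haar-random
orthonormal bases (QR of Gaussian matrices, seeded), 20 projections by
default, reported as mean ± s.e.m.

## Linear decoding

Decoders are L2-regularized logistic regressions on 50-ms feature windows:
for each unit, 5 consecutive 10-ms samples of the z-scored smoothed rate,
concatenated unit-major. The window is aligned to start at the label time t
([t, t + 50 ms)). The penalty is fixed (glmnet, α = 0, λ = 1/n — the usual
C = 1 convention under 1/n loss scaling), with no feature standardization
beyond the baseline z-scoring. Cross-validation is class-stratified 10-fold
(per-fold class ratios match the global ratio to one trial); accuracies are
reported as fold means with the s.e.m. over the 10 held-out folds.

**Decision vectors.** Per timepoint, fold coefficient vectors are averaged,
the 5 bins of each unit are averaged to map feature space back to unit
space, and the result is normalized. DVs over a window (default the first
1.5 s after onset) average the raw fold-averaged vectors across timepoints
*before* normalizing.

**Effective chance.** 40 decoder runs with labels drawn Bernoulli(0.5);
each run contributes its time-averaged (fold mean + 1 s.e.m.), and the
threshold is the mean + 1 s.e.m. of the run values — a one-sided
point-threshold suitable for curve displays. For hypothesis-like checks
("is this single accuracy at chance?") the tests instead use the **chance
band**, mean ± 2 s.d. of the run values: the run-to-run spread measures
exactly the sampling noise of one decode at chance, whereas the
point-threshold converges to a point as runs accumulate and would
eventually reject any finite sample.

**Cross-temporal generalization** uses 2 repetitions of randomized
stratified 3:1 train/test splits (cheaper than 10-fold at matrix scale).
Statistics: decay rate = −slope of a linear fit of accuracy over the first
500 ms of forward test shifts, in accuracy loss per 100 ms; DV angle matrix
γ(t₁,t₂) = arccos **d**⁽ᵗ¹⁾·**d**⁽ᵗ²⁾ in degrees; block means over the
lower triangles of the pre- (−1.5–0 s) and on-stimulus (0–3 s) blocks and
the full pre × on rectangle, all excluding |t₁ − t₂| < 100 ms (inside the
smoothing kernel and feature window, accuracies are trivially inflated);
*blockiness* = mean(within-pre, within-on) − cross accuracy. Cross-time DVs
are averaged over splits before angles are computed (refitting per split
and averaging angles was the alternative; averaging first is less noisy and
is what the window-averaged DV definition already does).

**Equalized subset decoding** (consistent vs exploratory) equalizes trials
to the smallest count over trial type × context × subset, subsamples 20
times, and uses leave-one-out CV because the equalized counts are small; a
subset needs at least 10 trials per context to enter. Timepoints where both
subsets decode below a chance level recomputed at the reduced trial count
are excluded from the difference distribution.

**Population-size control.** Accuracies of two decoders across sessions are
each regressed on the number of units; the residuals are correlated
(two-sided test). This equals the partial correlation given unit count; a
constant unit count falls back to the plain correlation with a warning.

## Multidecoder subspace analysis

DVs of several decoders live in the same population space and span a
(generally skewed) task-relevant subspace S. The projector onto S is
**P** = D(DᵀD)⁻¹Dᵀ (1-D case: **d d**ᵀ/‖d‖²); display coordinates use the
Gram-Schmidt orthonormalization Q of D in the user's column order, with
each display axis oriented along its defining DV. Bases with condition
number above 1e6 are rejected — (DᵀD)⁻¹ is numerically meaningless for
near-collinear DVs. Angles are reported in [0°, 180°] without folding
(obtuse angles are information; folding to [0°, 90°] is an option).

The nullspace projector R comes from a QR factorization of the complement
of **d d**ᵀ: N−1 orthonormal rows, all orthogonal to **d**, so
‖a‖² = ‖R a‖² + (**d**ᵀa)². Decoding a variable from its *own* subspace
requires outer cross-validation: the DV is fitted on outer-training trials
only, outer-test activity is projected, and the inner stratified CV runs
on projected outer-test data (two outer folds). Without this, the
projection itself leaks label information; the test suite verifies that
with it, label-free data stays inside the chance band.

## Movement controls

Run speed is the magnitude of the treadmill displacement derivative,
low-pass filtered below 1 Hz with a single-pass first-order Butterworth
filter (first-order low-pass preserves nonnegativity; a zero-phase variant
would not add anything at 1 Hz and is off by default), then averaged in
50-ms windows. For distribution matching, per-trial speeds are pooled over
3 consecutive windows (150 ms) to tame histogram sampling noise, binned
0–100 cm/s at 5 cm/s, and the larger context is subsampled per bin to the
smaller (bins empty in either context are dropped). Matched decoding is
compared against random subsamplings of identical per-context sizes, 10
repetitions each; optional shifts displace the speed stream relative to
the neural data.

Video motion: the per-pixel background recursion is
b_t = 0.3 x_t + 0.7 b_{t−1} and the smoothed difference
d_t = 0.9 (x_t − b_t) + 0.1 d_{t−1}. (A sign variant of the background
recursion that subtracts the history diverges for a static scene; the
stable convention is used.) The two-stage PCA computes up to 200 chunk PCs
per 3000-frame chunk (memory-bounded outer stage), concatenates the chunk
scores, and reduces to 40 session PCs; both stages mean-center and both are
inverted on the reconstruction path, with a cumulative-sum option to undo
the differencing. Absolute motion is the mean over PCs of |score|, smoothed
by a 9-frame (4 back / 4 forward) moving average with renormalized edges;
RoI motion averages |difference| over mask pixels directly. Stationary
trials have at most a set proportion of frames above a motion threshold
(default sweep: thresholds 0.2–2.0, proportions 0.05–0.50).
Motion-level-equalized decoding bins (timepoint, motion level) cells, drops
cells with fewer than 5 trials in either context, equalizes by subsampling,
and compares against a motion-level-shuffled control.

## The synthetic-session generator

`generateSession()` emulates the study's data structure: two blocked
contexts, 3-s stimulus / 3-s intertrial trials on a 10-ms grid, trial types
i.i.d. uniform over the four congruence × action combinations (the
within-block schedule is not otherwise constrained; the uniform default is
exposed in the config), choices from a named strategy, and inhomogeneous
Poisson populations with rate

  r_i(t) = baseline_i + Σ_v amplitude_v · direction_v[i] · s_v(trial) · profile_v(t),

floored at 0 Hz (rectification is the standard convention; a warning fires
when more than 1% of bins clip). Directions are unit-norm and by default
mutually orthogonal; context is sustained, stimulus and choice components
switch on at onset. An onset rotation turns rotating components by a
configured angle inside the plane spanned by the direction and an
orthonormal partner — 0° gives a stable code, 90° an abrupt representation
change. Components may also be driven by the instantaneous run speed
(s_v = speed/10 cm/s), which is how speed-gain confound constructions are
built. Spike times are drawn per 10-ms bin (Poisson count, uniform
placement); all randomness derives from a single seed through fixed
substreams, so identical configs are bit-identical.

Default study conditions: 120 trials per context (a typical multimodal
block), 7 Hz baselines (typical V1 rates), 8 Hz modulation amplitudes for
sensory/context components and 5 Hz for choice (strong enough that
decoders saturate at these population sizes), a context-aware lapse
strategy with λ = 0.13 (a typical fitted lapse), speed base 10 cm/s with a
5 cm/s context offset at full coupling, AR(1) traces (ρ = 0.9, sd 4 cm/s),
and 128 × 64 video at 20 frames/s with an 8-px Gaussian dot whose
displacement integrates the run speed on a static noise background.

What the generator does **not** emulate: spike-train autocorrelations
beyond Poisson, slow drift and unit instability, eye position or pupil,
learning across sessions, realistic video statistics (posture, whiskers,
licking). Passing tests therefore demonstrate the correctness and
calibration of the analysis machinery on data with known ground truth, not
robustness to every pathology of real recordings.

## Constructions used by the acceptance tests, and their sizes

The simulation scales below were chosen as the smallest at which each
construction's effect is unambiguous; each is a package design choice.

- *Orthogonality recovery*: 24 units, 60 trials/context, 10 Hz amplitudes,
  20 seeds; decoders saturate (> 0.95) and context/visual DV angles
  concentrate near 90°. The shared-direction contrast drives both
  modalities along one direction and decodes them on congruent trials,
  where the two signals add coherently.
- *Purely 1-D context code*: equal-magnitude loadings (±1/√N). With unequal
  loadings, baseline z-scoring (which pools signal into the denominator)
  makes the class-conditional noise anisotropic, and the population-optimal
  logistic direction tilts away from the mean-difference axis — its
  nullspace then retains genuine signal no matter how many trials are used.
  Equal loadings keep the noise isotropic so the DV converges to the true
  axis; 150 trials/context, 16 units.
- *Two-population onset rotation*: a 6 Hz stable component plus a 10 Hz
  component rotating 90° at onset. The full space stays decodable across
  the border through the stable part (small blockiness); the nullspace of
  the on-stimulus DV removes the stable part and is blockier.
- *Speed confounds*: a 15 Hz/(10 cm/s) speed-gain component with full
  context-speed coupling, speed sd 6 cm/s so the two contexts' speed
  histograms overlap (matching needs common support); the
  speed-independent contrast uses a direct 10 Hz context component at zero
  coupling.
- Decoding grids in the tests use 0.25–0.5 s timepoint spacing rather than
  the full 10-ms grid; every operation accepts arbitrary grids and defaults
  to 10 ms.

## Known limitations

- Decoders are linear and binary; continuous variables and nonlinear
  readouts are out of scope.
- The chance band is estimated from 40 randomized runs; with very few
  timepoints its s.d. is itself noisy.
- `equalizedSubsetDecode()` requires every trial type × context × subset
  cell to be populated; heavily unbalanced sessions must be filtered first.
- Session I/O uses plain-text CSV/JSON plus multi-frame TIFF; spike times
  round-trip at 6 significant digits.
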