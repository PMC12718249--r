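---
title: "Methods: dyadic RSA and fNIRS synchrony, moderation, and the permutation control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic RSA and fNIRS synchrony, moderation, and the permutation control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures `dyadsync` implements, the
parameters that matter and why their defaults were chosen, what the
synthetic cohort generator does and does not emulate, and the numerical
decisions made where the methodology literature leaves the design open.

## The scientific setting

A mother and her 5–7-year-old child complete a short resting baseline
(2 min) followed by a 5-minute mildly stressful collaborative task while
two signals are recorded from each of them: ECG-derived interbeat intervals
(IBIs), and two-wavelength fNIRS over the left and right dorsolateral
prefrontal cortex (dlPFC; 4 channels per hemisphere per person, 7.81 Hz,
760/850 nm). Two dyad-level synchrony indices are derived — respiratory
sinus arrhythmia (RSA) coupling and dlPFC wavelet coherence — and used as
moderators of the association between maternal affect (PANAS positive and
negative scales) and child emotion dysregulation (an emotion-regulation
checklist lability score, mean near 1.8 on a 1–4 scale).

## Cardiac branch

**IBI artifact correction.** Manual beat editing is replaced by an
automated rule: each interval is compared with the running median of its 9
neighbours; intervals more than 30% below the median are merged with their
successor (spurious beat detection), intervals more than 30% above are
split into `round(IBI/median)` equal beats (missed beats). Elapsed time is
conserved exactly, the pass iterates to a fixed point (so the operation is
idempotent), and a series with more than 20% flagged beats is declared
unusable rather than repaired. The 30%/20% thresholds are conventional
heart-rate-variability editing heuristics; both are arguments.

**Continuous RSA.** The corrected IBI sequence is interpolated (cubic
spline against beat end time) to a uniform 4 Hz heart-period series,
band-passed with a zero-phase 4th-order Butterworth filter to the
respiratory range — 0.12–0.40 Hz for adults, 0.24–1.04 Hz for children,
the standard psychophysiology conventions, both configurable — and
converted to RSA(t) = ln Var over a centred 15-s sliding window, emitted
at 1 Hz. Edge windows are truncated rather than dropped so a 300-s task
yields a full 300-sample series, which the 29-sample epoching needs; a
variance floor of 1e-6 ms² keeps the logarithm finite on silent stretches.
Whether the original sliding window was centred or trailing is not
documented anywhere we could find; centred is the symmetric default.

**Epochs and baseline.** Task RSA is averaged over consecutive complete
29-sample blocks (10 epochs per 300-s task, the closest approximation to
30-s epochs at 1 Hz), and each person's baseline reference is the mean of
the final 29 baseline samples. We read "the last 29 timepoints" as 1 Hz
samples, not epochs — a 2-minute baseline only contains four 29-sample
epochs, so the epoch reading would leave the reference badly determined.

**Dyadic coupling model.** For child task epochs $C_t$, mother epochs
$M_t$ and baseline references $C_b, M_b$:

$$C_t - C_b = a_i\,(C_{t-1} - C_b) + s_i\,(M_t - M_b) + \varepsilon_t,
  \qquad t = 2,\dots,10 .$$

$s_i$ is the dyad's RSA synchrony. The original analysis fit a Bayesian
structural equation model in proprietary software whose priors and lag
structure are not recoverable from any published description; this package
keeps the three stated ingredients — baseline referencing, autoregression
control, and a concurrent cross-partner slope — in a transparent form.
Per-dyad OLS is available (`estimator = "per_dyad_ols"`), and the default
`hierarchical_map` estimator adds the Bayesian-flavoured pooling: slopes
are modelled as $s_i \sim N(\mu_s, \tau_s^2)$, $(\mu_s, \tau_s)$ are
estimated by maximising the marginal likelihood of the OLS slopes given
their standard errors, and the reported slopes are the posterior modes.
Shrinkage can only move a slope toward $\mu_s$, a property the tests
assert. Whether the mother term should be concurrent or lagged is equally
unrecoverable; both are options (`mother_term`), concurrent is the
default. Only the mother→child direction is modelled, matching the
moderation design in which synchrony moderates outcomes of the child;
the symmetric fit can be obtained by swapping the arguments.

With 10 epochs the per-dyad slope standard error is necessarily large
(roughly 0.3–0.6 in ln-variance units under the generator's defaults), so
individual-dyad slopes are noisy; the hierarchical estimator recovers the
group mean well, and rank recovery of individual couplings is demonstrated
in the tests at the generator's epoch-level measurement noise (~0.09, see
below) rather than through the full physiological cascade, where a
coupling spread of 0.05 across dyads is simply not identifiable from 9
regression points — an information limit, not an implementation one.

## fNIRS branch

The preprocessing chain is fixed and order-enforced (each operation logs
itself and refuses to run twice): optical density → channel pruning →
spline motion correction → wavelet motion correction → hemoglobin
conversion → band-pass → downsample → region aggregation.

- **Optical density**: $OD = -\ln(I/\bar I)$ per channel and wavelength,
  with the temporal mean as reference.
- **Channel pruning**: a channel is unusable if its raw-intensity
  coefficient of variation exceeds 15% or it is flat for more than 5% of
  samples; a region (hemisphere) with fewer than 2 usable channels is
  invalid; a dyad with any invalid region is excluded from neural
  analyses. The source methodology names pruning criteria only loosely
  ("signal integrity"), so these concrete defaults follow common fNIRS
  practice and are exposed as arguments. The <2-channels rule is this
  package's own operationalisation of dyad exclusion.
- **Spline motion correction**: segments where the 1-s moving SD exceeds
  5× its median are flagged; each flagged segment has its smoothing-spline
  trend removed and is re-anchored to the local trend of the preceding
  clean data; data after the segment is re-levelled so that local
  low-order trends extrapolated from both sides agree at the segment
  centre — this removes step baseline shifts while leaving spike-only
  events' surroundings untouched.
- **Wavelet motion correction**: a periodised Daubechies-4 discrete
  wavelet transform (reflection-padded to a power of two, up to 6 levels);
  detail coefficients outside `1.5 × IQR` beyond the quartiles are zeroed
  before reconstruction. The transform reconstructs to ~1e-15 when nothing
  is zeroed, which the tests assert.
- **Hemoglobin conversion**: the modified Beer–Lambert 2×2 system with
  extinction coefficients at 760/850 nm from the standard compiled
  tabulation (1486.59/3843.71 and 2526.39/1798.64 cm⁻¹ M⁻¹ for HbO/HbR)
  and an age- and wavelength-dependent differential pathlength factor
  (mother default age 36 → DPF ≈ 6.47 at 760 nm; child default age 6 →
  ≈ 5.54). Concentrations are in µM; HbT ≡ HbO + HbR holds exactly.
- **Filtering and downsampling**: a deliberately wide 0.01–0.5 Hz
  zero-phase band-pass (narrow frequency selection is done later by the
  coherence band average), then anti-alias low-pass at 0.4× the target
  rate and cubic interpolation onto an exact 1 Hz grid (the 7.81→1 ratio
  is non-integer).
- **Region aggregation**: mean over usable channels per hemisphere,
  separately per chromophore — aggregation happens *before* coherence, so
  one coherence value is computed per region rather than per channel,
  matching the aggregated-series description of the analysis.

## Wavelet-transform coherence

The Morlet CWT (ω₀ = 6, 12 scales per octave, smallest scale 2·dt) is
computed by FFT after linear detrending and variance normalisation
(coherence is amplitude-invariant, but detrending stabilises edge
behaviour). Squared coherence uses the standard smoothing operator: a
Gaussian in time whose width matches each scale, and a 0.6-octave boxcar
across scales. Without smoothing coherence is identically 1, so the
implementation refuses to compute it unsmoothed. Coherence is clipped to
[0, 1] against floating-point overshoot; self-coherence is 1 to 1e-6 and
coherence is exactly symmetric and scale-invariant (tested).

The frequency band of interest is 0.02–0.1 Hz — periods 10–50 s — below
Mayer waves (~0.1 Hz), respiration (~0.2–0.3 Hz) and cardiac pulsation
(~1 Hz). Averaging over the band and the 300 task samples yields one
coherence per dyad × region × chromophore.

**Cone of influence.** At a 50-s period in a 300-s record, a large part of
the time–scale plane is edge-contaminated, so whether COI cells enter the
band average is consequential. The default here *excludes* them
(`coi_policy = "exclude"`); `"include"` reproduces the convention of the
widely used R implementation that averages the full plane. The policy is
recorded in every output row.

An important calibration fact, measured by this package's own Monte-Carlo
tests: the band-averaged coherence of two *independent* 300-sample series
is ~0.35, not 0 — smoothing over a short record leaves that much spurious
coherence. Observed dyad coherences near 0.33–0.36 in this literature
should be read against that floor, which is exactly what the
random-pairing control quantifies.

## Moderation and Johnson–Neyman probing

Each of the ten models regresses child dysregulation on a mean-centered
focal affect scale, a mean-centered synchrony moderator, their product,
and three covariates (the other affect scale, child gender, income as an
ordered 1–4 band), after listwise deletion — six predictors, so the model
F has (6, n−7) degrees of freedom. Standardized betas use analyzed-sample
SDs (the original table does not say; this is documented rather than
guessed). No multiple-testing correction is applied across the ten models,
matching the analysis being reimplemented; a Benjamini–Hochberg flag is
available as an extension.

The Johnson–Neyman boundaries solve $\theta(m)^2 = t_{crit}^2
\mathrm{Var}[\theta(m)]$ for the simple slope $\theta(m) = B_{iv} +
B_{int} m$, with $\mathrm{Var}[\theta] = V_{11} + 2 m V_{13} + m^2 V_{33}$
and two-tailed $t_{crit}$ at α = .05 on n−7 df. Roots are reported on the
raw moderator scale, flagged when outside the observed range, and the
tests require agreement with a brute-force 1e-4-step grid of simple-slope
t-tests. Degenerate cases (no interaction variance) return a single global
region. Probing is exposed for any fitted model regardless of the
interaction's p-value; the fit's p-value is carried in the output so
exploratory probes are labelled as such.

## Random-pairing permutation control

Each mother is paired with a random *other* dyad's child; the default
scheme samples uniform derangements (no fixed points), which preserves
each child's appearance count per permutation. Independent per-mother
sampling is available (`method = "independent"`) since the looser reading
of "a random child from another dyad" is also defensible. With 100
permutations (default), each mother's pseudo-coherence is the mean over
permutations, and the moderation models are refit with pseudo values in
place of true ones. Genuine dyadic coupling should (a) make true-pair
coherence exceed pseudo-pair coherence, and (b) erase coherence-driven
interactions under random pairing — both are asserted by the acceptance
tests on synthetic cohorts.

## The synthetic cohort generator

The generator produces, per dyad: beat times for both partners, raw
two-wavelength intensities for 16 channels, and a behavioral record. Its
defaults *are* the study conditions: 120-s baseline + 300-s task, 7.81 Hz
optics, 4 channels per hemisphere, PANAS marginals 36.21 (6.78) and
19.54 (7.26), outcome mean/SD 1.79/0.37, RSA synchrony scale
−0.01 (0.03), 54% girls, four income bands at the reported proportions.

- **Cardiac coupling** is an amplitude-envelope construction: each
  partner's heart period is mean IBI + a respiratory sinusoid (mother
  0.25 Hz, child 0.5 Hz — distinct adult/child bands) whose slow
  (0.01–0.05 Hz) log-amplitude envelope is shared across partners with
  per-dyad weight $s_i$, plus white jitter. Because RSA is log windowed
  variance, the envelope passes through the cardiac branch almost
  linearly, giving epoch-scale RSA covariation proportional to $s_i$
  without simulating cardiorespiratory physiology. The generator refuses
  to produce IBIs below 200 ms.
- **Hemodynamics**: per region, underlying HbO/HbR are a
  $\sqrt{f}$-weighted mixture of a common band-limited (0.02–0.1 Hz)
  source and person-specific sources, so the shared fraction $f$ controls
  band coherence; channels add Mayer (0.1 Hz), respiratory, cardiac and
  white noise at amplitudes defaulting to 0.1/0.08/0.05/0.1 µM against a
  0.5 µM signal — chosen so that observed coherence SDs land near the
  0.05–0.06 reported for real dyads, since no physiological ground truth
  for these amplitudes exists. Intensities come from the *forward*
  Beer–Lambert model with the same extinction matrix the conversion
  inverts, so the optical round trip is exact by construction and is
  tested to 1e-6 µM. Per-dyad shared fractions are drawn around
  `shared_fraction` (SD 0.15, clipped to [0, 1]): a cohort in which every
  dyad had identical true coherence could not carry coherence-moderated
  behavioral effects.
- **Behavior**: dysregulation = b₀ + b_pa·PA + b_na·NA + b_sync·s +
  b_int·PA·s + b_gender·g + b_income·inc + ε with all predictors centered
  at sample means (so a noiseless cohort is recovered *exactly* by the
  mean-centering moderation fit — the tests assert machine-precision
  recovery). Default coefficients point in the directions of the reported
  models, with b_int = −0.47 at the reported magnitude and residual SD
  0.30 chosen so the outcome SD lands near 0.37.
- **Motion artifacts**: spikes (≥5 signal SDs, 0.5–2 s, exponential
  decay) and persistent step shifts at Poisson times, common-mode across
  channels, acting multiplicatively on intensity; the corruption mask is
  stored with the truths.
- **Seeding**: one global seed draws per-dyad substream seeds, so a
  cohort extended from n to n+k dyads leaves the first n bit-identical.

What the generator does **not** emulate: real respiratory dynamics (no
respiration signal, no peak-valley RSA), scalp/skull optics and partial
volume effects, systemic physiology shared across *both* partners (which
in real hyperscanning inflates pseudo-dyad coherence), non-stationary
task structure, or missingness mechanisms. Passing tests therefore show
that the pipeline's arithmetic and statistical calibration are right
under the assumed structure — not that the scientific conclusions
transfer to any real cohort.

## Numerical choices and problem sizes

Zero-phase filtering uses 4th-order Butterworth designs via
`signal::filtfilt`, applied around the series mean to avoid
initial-state edge transients. Interpolation is `stats::spline` (FMM end
conditions, exact on cubics). The hierarchical τ search maximises the
marginal likelihood on log-τ over [e⁻¹², e⁴] with `stats::optimize`.
Degenerate inputs have defined behaviour throughout: constant partner
series are excluded with a logged reason, zero-variance variables yield
NA correlations, empty frequency bands and sub-Nyquist violations raise
errors naming the offence.

The test suite runs its Monte-Carlo properties at sizes chosen to keep
the default run in tens of seconds (e.g. 30–60 seeds for coherence
monotonicity and baselines); the acceptance suite runs the calibration
studies at full scale — 1000 null cohorts of 80 dyads for the type-I
rate, 500 for interaction recovery, 200 seeds for the paired
true-versus-pseudo coherence comparison and 200 cohorts for the
pseudo-interaction nullification — in a few minutes. The acceptance
*script* reports the same quantities at reduced replicate counts
(400/300/60) chosen to keep a full from-scratch rerun under a minute;
with any fixed seed its output is bit-reproducible.

## Known limitations

Per-dyad RSA coupling is weakly identified from 10 epochs (see above);
group-level inference is the supported use. The wavelet coherence null
floor (~0.35 for 300 samples) means absolute coherence values are not
interpretable without the permutation control. The spline motion
correction assumes artifacts are sparse relative to the record; beyond
roughly one event per 10 s its re-levelling errors accumulate. The
moderation models are ordinary least squares on dyad-level scalars;
measurement error in the synchrony moderators attenuates interactions,
which is inherent to the two-stage design, not corrected here.
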