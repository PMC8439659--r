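---
title: "Methods: decoding locomotion from whole-brain calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding locomotion from whole-brain calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wormdecode` analyzes two-channel whole-brain calcium imaging of moving
*C. elegans*: it motion-corrects fluorescence, extracts behavior from
centerlines, quantifies single-neuron tuning, fits linear population
decoders, and compares correlation structure between moving and
immobilized epochs. This vignette is the package's account of the models
and of the choices made where the procedures left room for judgment, and
of what the synthetic validation does and does not establish.

## The measurement model and preprocessing

Each tracked neuron contributes a GCaMP trace $G_i(t)$ (calcium-sensitive)
and an RFP trace $R_i(t)$ (calcium-insensitive) on a common volume grid
(~6 volumes/s). Three corruptions are assumed: slow photobleaching,
sparse outliers/tracking gaps, and a motion artifact shared between the
channels of a neuron up to a scale factor, because both fluorophores
experience the same tissue deformation.

**Photobleaching.** Each trace is fit with $A e^{-t/\tau} + B$; traces
well described by the fit are divided by it and affinely rescaled to their
original mean and variance, others pass through untouched. Two numerical
choices matter here, both the package's own:

* The fit is *two-stage*: $\tau$ is estimated from the slow trend of the
  trace (30 s Gaussian smooth, edges trimmed to the kernel half-width so
  that an exponential's interior smooth is an exactly rescaled
  exponential), then $A$ and $B$ are refit linearly on the raw trace at
  that $\tau$. Fitting the raw trace directly lets calcium transients
  capture the fit; the trend restriction removes them. Levenberg–Marquardt
  runs from three $\tau$ starting points because the sum-of-squares
  surface has a near-linear ridge ($A,\tau \to \infty$) that can trap a
  single start.
* "Well fit" (unspecified in the underlying procedure) means trend
  $R^2 \ge 0.3$, $\tau \in [10\,\mathrm{s},\,4\times\mathrm{duration}]$,
  $A > 0$, and a strictly positive fitted curve. Decays slower than
  $4\times$ the recording are indistinguishable from linear trends and too
  mild to matter, so they are left uncorrected rather than divided by an
  ill-determined curve.

**Outliers.** A point is flagged when RFP leaves $[-2\sigma, +5\sigma]$,
GCaMP leaves $\pm 5\sigma$, RFP or the G/R ratio drop below absolute
floors (defaults: 10% of the neuron's median, configurable — the source
procedures name the floors but not their values), or the point is
sandwiched between missing/flagged points; volumes where most neurons are
bad are dropped entirely. Flagged and missing points are linearly
interpolated and every trace is smoothed with a Gaussian of
$\sigma = 0.83$ s (kernel truncated at $\pm 3\sigma$ and renormalized at
the edges, so constants are preserved to the boundary).

**Motion correction.** $F_{mc} = (G - \alpha R) - \langle G - \alpha R
\rangle$ with the per-neuron $\alpha = \sum GR / \sum R^2$, the closed
form of minimizing $\sum (G - \alpha R)^2$. The fit uses valid,
non-interpolated points of the bleach-corrected, smoothed traces — the
stage order (bleach → outliers → interpolate/smooth → motion-correct →
derivative) is fixed, and fitting $\alpha$ after bleach correction keeps
the two channels' artifact scaling consistent. Temporal derivatives use a
derivative-of-Gaussian kernel of width 2.3 s; the width is interpreted as
the Gaussian $\sigma$ (a FWHM flag is provided, since the convention is
not stated), and the kernel is moment-normalized so a ramp maps to its
exact slope, with odd-reflection padding so that holds at the edges too.

## Behavior from centerlines

Velocity is the motion of the point 15% of body length behind the head
tip projected on the unit head direction (the 10%→20% chord), after
Hampel filtering (window 11 samples, 3 scaled MADs — parameters are the
package's defaults, exposed in the interface), interpolation to a common
200 Hz axis, and differentiation by a Gaussian-derivative of
$\sigma = 0.5$ s. Curvature is the mean of $d\theta/ds$ over segments at
15–80% of arc length, from finite differences of unwrapped tangent angles
on the 100-point polyline. Both series are aligned to imaging volumes by
linear interpolation. Velocity is invariant to constant stage offsets and
curvature to rigid motions; both are verified as properties in the tests.

## Tuning and its significance

Tuning is the Pearson correlation of a neuron's $F_{mc}$ or $dF/dt$ with
velocity or curvature over valid, non-interpolated points. The null
preserves each neuron's autocorrelation: the activity is time-reversed and
circularly shifted by a uniform random lag, M replicates per neuron pooled
into an $M \times N$ sample. The implementation evaluates the full
circular cross-correlation once per neuron by FFT and samples lags from
it, which is exact for this null family and fast. Empirical p-values are
raw tail proportions (a zero count is reported as 0 with the resolution
$1/(MN)$ attached; no +1 correction, matching the literal description of
the procedure); significance requires $p < 0.05/(2N)$ — the $2N$ covers
testing both features per neuron — and $|\rho| \ge 0.4$, applied globally.

## Population decoding

The decoder is $\hat y(t) = \sum_i (W_{F,i} F_i + W_{dF/dt,i}\,
dF_i/dt) + \beta$ with all $2n$ features z-scored so weight magnitudes are
comparable. Scaling statistics come from training rows only; the sources
are silent here, and training-only scaling avoids leaking the held-out
window into the fit. The middle 40% of the recording is the test set
(indices $\lfloor 0.3T \rfloor$ to $\lfloor 0.7T \rfloor - 1$). Ridge
weights solve the normal equations in closed form; $\beta$ is unpenalized
and, with training-centered features, equals the training mean of the
target. $\lambda$ is selected on an inner split — the last contiguous
third of the training rows, contiguity preserving temporal structure —
over 30 log-spaced values in $[10^{-3}, 10^6]$, then the model is refit on
the full training set. Interpolated timepoints participate in the
population fit (excluding them is impractical at population scale);
majority-missing volumes do not. Performance is
$\mathrm{RMS}^2(y, \hat y) = R^2(y - \langle y \rangle, \hat y - \langle
\hat y \rangle)$ on the evaluation window, range $(-\infty, 1]$; a
constant prediction scores exactly 0.

The best-single-neuron baseline fits slope and intercept for every single
feature on the training rows and selects by training $\mathrm{RMS}^2$
(test-based selection would leak). The truncated-model analysis sorts
neurons by $\max(|W_F|, |W_{dF/dt}|)$ (ties by index), keeps the top $N$
weight pairs with relative weights frozen, and refits only a scalar gain
and offset on training rows; performance is evaluated on the entire
recording since the relative weights cannot overfit. Whether any scale is
refit when truncating is not specified by the sources; both a frozen mode
and the gain+offset refit are implemented, refit being the default, and
the full-model reference for N90 is the $N = n$ entry of the same curve,
which makes the identity truncation exact by construction. Variants: the
acceleration penalty $\mu\,(dy/dt - d\hat y/dt)^2$ ($\mu = 10$) enters the
normal equations through the same Gaussian-derivative filter applied to
the feature matrix; the elastic-net penalty $\lambda (r \|W\|_1 +
(1-r)\|W\|_2^2)$ ($r = 10^{-2}$) is solved by coordinate descent (glmnet)
with the response standardized explicitly and the penalty mapped exactly
onto glmnet's parameterization ($a = r/(r + 2s(1-r))$,
$\lambda_g = \lambda(1-r)/(n(1-a))$ with $s$ the population SD of the
training response); the mapping is verified in the tests against the
soft-threshold closed form on an orthogonal design.

## Correlation structure across states

Correlation matrices are Pearson correlations over valid points of a
window (≥ 60 s); the dissimilarity between epochs is the root mean square
of off-diagonal changes over unordered pairs. The defining texts disagree
on whether the root is taken — the formula is printed without it but the
procedure is described as root-mean-squared — and the root is applied
here, with a flag for the squared variant. Moving→immobilized recordings
exclude an annotated 1–2 min transition (the exclusion is a required
annotation, not inferred, since its length varies per recording);
moving-only controls compare the first 30% of a recording to the latter
60%, mimicking the treated timing, and groups are compared with Welch's
unequal-variance t-test. PCA state spaces are fit on one window only
(centering and loadings from the immobilized epoch by default; centering
only, variance scaling optional), the whole recording is projected with
those parameters, and each component's largest-magnitude loading is made
positive for deterministic output. Correlation shifts relative to a
reference pair (AVAL/AVAR) use a paired Wilcoxon signed-rank test over
(neuron, reference) pairs.

## What the synthetic generator emulates — and what it does not

The generator is the package's test bed: every recording carries its
ground truth (planted tunings, artifact traces and couplings, bleach
curves, event times, epoch loadings), and noise-free recordings
reconstruct exactly from those components.

* **Behavior**: velocity is a smoothed telegraph process (forward
  ~0.1 mm/s, reversals to ~−0.15 mm/s at Poisson times, transition
  bandwidth ~1 s so the true process lies inside the passband of the
  0.5 s differentiation filter used for measurement — the generator's own
  round-trip invariant requires it), modulated by a bounded multiplicative
  fluctuation so event-free runs stay strictly forward. Curvature is
  band-limited noise plus ventral-positive turn bumps, soft-saturated at
  6 mm⁻¹ (a worm cannot coil tighter without self-intersection).
* **Neural signals**: the tuning drive (the behavior itself, or bumps at a
  stored subset of events for partial-event tuning) passes through a
  zero-phase 1.5 s calcium kernel, so planted tuning is contemporaneous —
  the tuning statistic is zero-lag Pearson. Derivative-tuned neurons
  integrate the drive with a 45 s leak: long enough that the integral
  itself carries little instantaneous-behavior information and the tuning
  lives in $dF/dt$ where it was planted. Every neuron adds intrinsic
  behavior-independent variability (50% of drive SD by default): no single
  neuron is a clean readout, which is precisely why the population beats
  the best single neuron.
* **Artifact**: per-neuron traces dominated by fast undulatory bending
  (~0.45 Hz, neuron-specific phase) with a seconds-scale neuron-specific
  compression component, amplitude-gated by how much the animal moves
  (vanishing under paralysis), plus a small coupling to one shared
  "posture distortion" trace that carries the behavior-locked part. The
  sharing matters: residual artifact after correction then cannot be
  averaged away across the population, which is what keeps zero-gain
  (GFP-mode) recordings decodable only at control levels rather than
  approaching signal recordings. Channel couplings share a per-neuron
  susceptibility and scale with each channel's brightness — compression
  changes fluorophore density, hence fluorescence, proportionally — which
  is exactly the regime in which a single per-neuron $\alpha$ can cancel
  the artifact; a configurable jitter (10%) breaks the proportionality
  slightly, leaving the small behavior-locked residual real tissue shows.
  The artifact sits inside the bleaching envelope (it is a fluorophore-
  density modulation, so it bleaches with the fluorophore).
* **Degradations**: per-neuron exponential bleaching with
  $\tau \in [600, 2000]$ s — substantial but moderate relative to the
  recording, the regime in which a variance-preserving bleach rescale
  inflates both channels' fluctuations by similar factors and ratiometric
  correction stays consistent; contiguous 1–3 s tracking gaps at Poisson
  times; sparse large spikes present in the data (and recorded only in
  the ground truth, since finding them is the pipeline's job).
* **Immobilization**: before onset, neurons load on behavior-coupled
  latents (centered within the moving epoch, so no step at onset
  masquerades as a bleach trend); after onset, behavior freezes and a slow
  oscillator with new loadings takes over, a configurable fraction of
  neurons flipping sign relative to an AVA-like pair. The pair shares its
  latent with only a small independent component and carries twice the
  default gain (as the brightest, most dynamic neurons in real recordings
  do), which keeps its within-pair correlation above 0.9 in both epochs.

The generator does **not** emulate: nonlinear calcium indicator
saturation, multiplicative artifacts (a flag exists for robustness
probing, off by default — the correction is tested where its assumptions
hold), tracking identity swaps, optical sectioning, or correlated noise
across neurons beyond the planted latents. Passing tests therefore show
that the pipeline recovers what it assumes the data contain; they do not
certify behavior on violations of those assumptions.

## Problem sizes and test design

Unit and property tests run on 2–4 minute recordings of 10–30 neurons.
The end-to-end checks use 20 seeded recordings of 60 neurons × 8 minutes
for decoding comparisons, 20 moving→immobilized pairs of 40 neurons × 10
minutes for the correlation-structure effect, 100 stationary-null repeats
for the group-test false-positive rate, and 20 null recordings at M = 500
shuffles for tuning-test calibration — sizes chosen as the smallest at
which the directional effects and calibration bounds are stable across
seeds. Two constructions deserve a note: weight-sign recovery is asserted
on a design where each behavior is carried by one feature type, because
when both a fast (activity) and a slow (derivative) linear readout of the
same behavior exist, the optimal decoder uses the slower as a suppressor
and partial-weight signs are no longer the planted marginal signs — a
property of regression, not a defect of the fit; and the tuning-test null
uses exactly proportional channel couplings (jitter 0), since with the
default jitter the residual artifact is genuinely behavior-locked and
calls against it are not false positives.

## Known limitations

* Per-trace exponential bleach fits are confounded by slow signal
  components; the trend-restricted two-stage fit mitigates but cannot
  eliminate this, and misestimated bleach leaves slow residuals in
  $F_{mc}$.
* The variance-preserving bleach rescale folds trend variance into
  fluctuations; under very strong bleaching this inflates the two channels
  unequally and degrades artifact cancellation. Real recordings in that
  regime would need a different normalization.
* The $\alpha$ fit minimizes total squared difference, so its value is
  dominated by the channel baselines; artifact cancellation relies on the
  artifact-to-baseline proportionality the generator (and the underlying
  physics) provide.
* Decoding scores on synthetic data run higher than on real recordings —
  the generator's neurons are linear encoders of exactly the two modeled
  behaviors — so absolute $\mathrm{RMS}^2$ values should not be compared
  across worlds; directional comparisons (population vs BSN vs GFP) are
  the meaningful ones.
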