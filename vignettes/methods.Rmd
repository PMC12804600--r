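---
title: "Models and methods behind cortexnav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cortexnav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexnav)
```

cortexnav analyses freely moving Y-maze navigation recorded together with
miniscope calcium imaging: behavioral kinematics, per-neuron tuning
classification (position / path / acceleration), the location-matched
d′ dissociation of acceleration from position, a linear trajectory
encoding model, and population decoders of path and position. Because no
public dataset of this kind ships with the package, a synthetic session
generator with planted ground truth stands in for real recordings; every
downstream stage is validated by recovery against what was planted.

This vignette explains the models, the conventions, the open design
choices and what the synthetic validation does — and does not — establish
about real data.

## Data model and conventions

* Coordinates are in cm, origin at the maze/arena centroid, y up. Frames
  are 0-based; all frame intervals are half-open `[start, end)`.
* Behavior (19 frames/s Y-maze camera, 10 frames/s open field) and neural
  traces (ΔF/F at 10 Hz) are assumed to share absolute timestamps; the
  behavioral stream is linearly interpolated onto the neural clock, events
  snap to the nearest neural frame with ties toward the earlier frame.
  One clock for everything keeps every downstream statistic unambiguous.
* Missing coordinates: gaps of ≤ 3 frames are linearly interpolated at
  load time; longer gaps stay invalid and are excluded from every
  statistic.
* The default Y-maze has three 30-cm arms at 120°, arm width 6 cm, a
  hexagonal center of radius 5 cm, reward zones in the distal 5 cm of
  arms 1 and 2. The five-zone variant used by the zone decoder splits
  arms 1 and 2 into proximal/distal halves and pools center with arm 3
  into a middle zone — five stations along the reward-to-reward corridor.
  (The five-way division is a package choice; only its existence is given
  by the analysis it serves.)

## Behavioral kinematics

Speed is the frame-to-frame centroid displacement over the frame
interval. Acceleration is the *signed time derivative of speed*, not the
magnitude of the 2-D acceleration vector: the tuning analysis must be
able to exclude decelerations, which requires a sign.

Momentary tortuosity at frame $t$ uses a symmetric ±1.25 s window:
$T(t) = L(t)/D(t)$, with $L(t)$ the summed frame-to-frame displacement
across the window and $D(t)$ the Euclidean distance between the window
endpoint frames. $T = 1$ exactly on straight segments; on a circular arc
of radius $r$ spanning angle $\theta$ it equals the arc/chord ratio
$\theta r / (2 r \sin(\theta/2))$, which the test suite uses as a closed
form. Windows whose endpoints nearly coincide ($D < 0.1$ cm, e.g.
out-and-back turns) are undefined rather than capped — a capped value
would silently distort the running summary. The summary statistic is the
75th percentile of $T$ over frames faster than a running-speed threshold;
since the reference cohort that defines that threshold does not ship with
the package, the threshold is an explicit parameter and
`running_speed_threshold()` derives it from any set of sessions (mean of
per-session 75th-percentile speeds).

Turn angles use three consecutive frames: the unsigned angle between the
two displacement vectors, in [0°, 180°]. Steps below 0.05 cm are
excluded so centroid jitter does not dominate the histogram. Immobility
is speed < 2 cm/s sustained ≥ 1 s. Open-field metrics discard the first
30 s (adaptation) and use a central 20 × 20 cm zone for center entries
(half the linear dimension — a convention, since no definition is given
by the assay itself).

## Navigation trials

A navigation trial is one traversal between the two reward arms: from
movement initiation in the origin arm (speed ≥ 2 cm/s sustained 0.5 s
while still in that arm, after the previous water delivery) to arrival in
the destination reward zone, strictly before that traversal's delivery.
Trials that spend more than 20% of their frames in arm 3 or exceed 60 s
are kept but flagged unqualified; both thresholds are parameters because
the qualification rule is not pinned down by the task description. Path
phases are journey-relative: origin arm = `starting`, center = `central`,
destination arm = `terminal`, regardless of which arm the journey leaves.

## The synthetic session generator

The generator is kinematic, not agent-based: dwell-and-lick bouts at a
spout, a traversal along the arm centerlines with a piecewise-constant-
acceleration speed profile, occasional arm-3 detours and dry same-spout
revisits, repeated under the alternating-reward rule (water accompanies
licks only on alternation-valid visits). Three generator features matter
for the statistics downstream:

* **Speed is re-modulated repeatedly along each traversal** (new target
  speed and accelerations drawn every few hundred ms, peaks across
  5–45 cm/s²). Without this, acceleration episodes happen only at
  departure and arrival, making acceleration behaviorally confounded with
  position; with it, both analysis bins ([5, 25) and [25, 50] cm/s²) are
  populated in every maze region. Default sessions carry well over 100
  frames per bin, and the generator warns if they do not.
* **The mouse slows at the choice point** (speed cap 7 cm/s within the
  center). Choice-point hesitation is a well-described behavior, and it
  gives the small center region enough residence frames for center tuning
  to be a testable condition.
* **Calcium forward model**: each neuron emits Poisson events at rate
  `baseline_rate × (1 + gain × indicator)` (GCaMP6f-like exponential
  kernel, τ = 0.4 s, unit amplitude, plus white noise). Conjunctive
  neurons multiply two indicators and receive a higher default gain,
  because their conjunction is active in far fewer frames; their
  preferred conjunction is drawn only among combinations that actually
  occur in the session (≥ 50 frames). In the degenerate baseline-free
  limit the rate is `gain × indicator` events/s, so a purely conditional
  responder can be constructed for tests. Path-tuned neurons are planted
  on journey phases (`starting`/`terminal`), position-tuned neurons on
  absolute regions — the two are dissociable by design in
  direction-balanced sessions.

Defaults: 600-s sessions, 500 neurons (20 position, 20 path, 40
acceleration, 5 + 5 conjunctive, 410 untuned), gain 4, baseline 0.2
events/s, noise SD 0.1 ΔF/F. The per-session neuron count is a free
choice (recordings of this kind report only totals across animals) and
fully configurable.

What the generator does *not* emulate: imaging noise structure (shot
noise, motion artifacts, neuropil contamination), nonlinear indicator
dynamics, slow drift, inter-animal variability, or deliberative behaviors
(reorientation and turnaround events are treated as ground-truth labels,
not detected). Passing recovery tests therefore shows the *estimators*
are correct and calibrated under a realistic forward model — not that
real cortical data will be as clean.

## Tuning classification

For each neuron and each of the three tests, the statistic per condition
is a difference of mean ΔF/F between the condition's frames and a
*matched* comparison group:

* acceleration: high vs low bin (and vice versa), over all binned frames;
* position: arm 1 vs arm 2 (and vice versa) stratified by path phase,
  and center vs both arms;
* path: starting vs terminal (and vice versa), with equal weight on the
  two traversal directions; only frames inside qualified trials are used.

The matched contrasts are essential. Against a plain "condition vs all
other frames" statistic, every arm neuron is automatically
"path-tuned" (it never fires in the central phase) and every `starting`
neuron elevates arm means over center — the two factors are entangled by
construction, because phases are defined through regions. Balancing the
contrast over the other factor cancels that label-driven component
exactly, not just in expectation, which is what makes pure position and
pure path tuning separable in finite sessions. The `central` phase is not
tested as a path condition: it labels (almost) the same frames as center
position tuning, so the two are a single hypothesis, reported under
position(center). One-vs-rest contrasts remain available through the
`references` argument of `test_condition_tuning()`.

Two temporal guards protect against calcium dynamics masquerading as
tuning: the first 0.8 s (≈ 2τ) of every path-phase segment and of every
center visit are dropped from the labels, because the indicator decays
across region boundaries (activity from the origin arm bleeds into the
center crossing, and center activity into the terminal phase).

The null distribution comes from circular time-shifts of the trace
relative to the labels (uniform shift ≥ 5 s, 1000 draws by default),
which preserves the trace's autocorrelation while destroying behavioral
alignment. The per-condition one-sided p is
`(1 + #{null ≥ observed}) / (1 + n)`. A neuron is flagged for a test when
its combined p — the minimum over conditions, Šidák-adjusted for the
number of conditions tested — falls below α = 0.05. The adjustment keeps
the *neuron-level* false-positive rate at α, which is what the
calibration and recovery analyses measure; with no adjustment the
min-over-conditions rule would flag ~10–14% of untuned neurons. Raw
per-condition p-values are reported alongside. A frame-wise rank-sum
backend (`backend = "ranksum"`) is provided for comparison; it ignores
autocorrelation and is anticonservative on slow traces. Conjunctive flags
are simply the conjunction of component flags.

Implementation note: the shift statistics for *all* possible shifts are
obtained at once via FFT cross-correlation of the trace with each
condition indicator, so classifying thousands of neurons at 1000
permutations each costs seconds, and every neuron draws its own shift
set from its own seed.

## The d′ dissociation and the encoding model

Location-matched d′ asks whether a neuron discriminates acceleration
state with position held constant: within each matched region,
`d′ = (μ_high − μ_low) / sqrt(0.5 (σ²_high + σ²_low))` with unbiased
variances. The default response unit is the frame (maximising sample
size); a per-trial-mean backend (`unit = "trial"`) is available, since
the choice of unit is not dictated by the formula. Results are reported
per region (arms 1 and 2 by default) rather than pooled. Degenerate
groups follow explicit rules: equal means with zero variances give 0;
unequal means with zero variances give a signed infinite-separation
sentinel, flagged.

The encoding model is ordinary least squares for
`x(t) = β₀ + β₁·Position(t) + β₂·Acceleration(t) + ε`. The mapping from
neuron sets to the scalar regressors is a modelling choice (nothing in
the model pins it down): the package uses the z-scored mean trace of each
flagged class, recorded in the output metadata. Collinear designs
(condition number above 10⁶) are refused rather than silently fitted.

## Decoders

Four models, all trained from scratch in R on BLAS matrix operations with
hand-derived backpropagation (gradient-checked against central finite
differences in the test suite):

* **Path transformer** — trials are PCA-reduced over the neuron axis
  (basis fit on training trials only), projected frames padded to a fixed
  token length with an attention mask, linearly embedded, a learned class
  token prepended and learned position embeddings added; a post-norm
  transformer encoder feeds the class-token output to a small classifier.
  Defaults follow the published recipe (256 components, 196 tokens,
  128-dim embedding, AdamW 1e-4 / weight decay 1e-4, cosine annealing,
  dropout 0.3, 30 epochs, stratified 8:2 trial split). Encoder internals
  the recipe leaves open default to depth 2, 4 heads, feed-forward 256.
  Over-long trials are head-truncated (the trial onset carries the
  direction information).
* **Position classifier** — non-overlapping 2-s windows with step twice
  the window length (adjacent samples can never overlap), window label =
  region at the final frame, linear embedding + layer norm + 1-D
  convolution + bidirectional LSTM, Adam 1e-3 / weight decay 1e-5,
  plateau-halving, 50 epochs, batch 16, stratified 70/30 window split.
* **Trajectory regressor** — 15 input frames → the next 5 frames of
  (x, y), mean-squared error (the natural loss for a coordinate
  regression), 80/20 split, batch 64, lr 5e-4, 80 epochs. Targets are
  z-scored with training statistics and un-scaled for reporting, so the
  loss scale does not depend on arena coordinates.
* **Zone classifier** — 10-frame windows labeled with the modal five-zone
  label within the window (ties toward the zone listed first along the
  corridor); same recipe as the regressor.

Input traces for the LSTM-family models are z-scored per neuron with
training-window statistics; the PCA basis, normalisation statistics and
scheduler state depend on training data only. "Validation" and "test"
are one held-out split — no third split, as only one is ever reported
against. All randomness (initialisation, batch order, dropout, splits)
derives from `split_seed`/`train_seed`, so a fixed configuration is
bit-reproducible.

The evaluation suite and the acceptance script run desk-scale
architectures (32-dim embeddings, 96-token padding, lr 1e-3 and 45
epochs for the transformer) on sessions of 80–110 trials or 20–25
minutes; these sizes
were chosen as the smallest at which planted high-SNR signal is decoded
essentially perfectly, and are stated wherever used. Decoder evaluation
sessions use strong planted coding, slowed locomotion, longer dwells and
frequent arm-3 visits — the regime where window labels are least
ambiguous (a window whose final frame sits just after a region boundary
is genuinely undecidable at calcium timescales, since the indicator needs
a few hundred ms to reflect the new region).

## Ablation and lick-removal controls

Subset contribution is measured by *removal and retraining* — never by
zeroing inputs, which is ill-defined once PCA mixes neurons: the decoder
is retrained from scratch without the flagged class, and again without a
size-matched random subset, with identical seeds. The lick-removal
control drops all frames within ±0.5 s of any lick from training and
evaluation windows and retrains with identical seeds; on synthetic
sessions where position coding is planted independently of licking, the
paired accuracy change is a few points at most — the small residual
change reflects window-composition shift (lick-adjacent dwell windows are
the easiest), not reward-related signal.

## Known limitations

* The tuning test assumes (circular) stationarity of the trace under the
  null; strong slow drift would need detrending first.
* Center-position and central-path tuning are not separable hypotheses
  under this task geometry; the package reports them as one.
* The generator's behavioral repertoire is stylised; tortuosity and
  turn-angle distributions are narrower than in real open-field data.
* Decoder accuracies on synthetic high-SNR sessions are upper bounds of
  convenience for testing, not predictions for real recordings.
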