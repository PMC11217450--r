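---
title: "Models and methods behind scnca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scnca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`scnca` analyzes system-level calcium dynamics of the suprachiasmatic
nucleus (SCN): how time of day is encoded in, and decodable from, the
joint activity of thousands of GABAergic neurons recorded as hourly
5-minute imaging sessions. This vignette explains the generative model
behind the synthetic testbed, each analysis stage with its assumptions
and tunable parameters, the numerical choices, and what the synthetic
results do and do not establish about real recordings.

## The synthetic SCN generator

Real SCN recordings cannot ship with a package, so every analysis stage
is exercised on a generator (`synth_config()`, `generate_dataset()`)
whose planted structure is logged as ground truth. The generator is the
package's definition of the study conditions, not a fitted model of any
particular dataset.

**Geometry.** Neurons are placed uniformly in two ellipsoidal nuclei
(semi-axes 130 × 160 × 100 µm) mirrored about the midline, with 5 µm
Gaussian jitter on the mirrored copies so bilateral symmetry is realistic
rather than exact. Modules are concentric distance bands around a
ventrolateral anchor; `module_banding = "area"` uses equal-width bands
(populations follow band area), `"equal"` uses equal-count bands.

**Traces.** A session trace is the sum of

* a burst train: per-neuron Poisson rates drawn lognormal
  (5%/95% ≈ 0.001–0.011 Hz); five burst classes with calibrated mean
  FWHM durations (25, 55, 100, 130, 180 s — the pooled 5%/95% duration
  percentiles land near 17.4 and 129 s) and amplitudes
  (0.8–2.5 ΔF/F), realized as gamma ("spiky"), triangle, trapezoid
  ("echelon") and square kernels. Class mixtures rotate slowly with the
  hour;
* a slow baseline oscillation (random phase and period per session);
* a dynamical-state motif for the six archetypes (ring, three-lobed,
  plateau, hyperactive, inverted-spiking, irregular), drawn per
  neuron-session from `state_probs` (the irregular archetype dominates at
  ~95%);
* the 12-h activity-mode cycle: a sustained baseline elevation
  (`mode_dc`, default 0.25 ΔF/F) expressed in the high-activity window
  and scaled by `mode_ratio` (0.4) in the low window, with per-neuron
  boundary jitter. Without a sustained component the circadian
  session-mean rhythm would rest on roughly one burst per session and be
  unrecoverable at realistic rates;
* the hourly population signature: a smooth unit-SD waveform per hour
  (sums of 1–3 cycle sinusoids), shared across the population and scaled
  by `hourly_signature_strength`. A per-hour DC offset would be erased by
  the per-trace z-scoring used in decoding, so the signature must live in
  the within-session waveform; the hour-dependent class mixture is kept
  as a secondary cue;
* a module-shared Ornstein–Uhlenbeck drive (correlation time ≈ 15
  frames) mixed with weight `coupling_gradient[module]` — this is what
  makes the maximal information coefficient (MIC) rise in strongly
  coupled modules without prescribing a network topology;
* Gaussian frame noise (`noise_sd`, 0.1 ΔF/F).

Fluorescence is F = F₀(1 + ΔF/F) with per-neuron baselines, and the
optional traveling hyperactivity wave adds a session-level Gaussian bump
that crosses the nucleus at `pwha$speed` along `pwha$direction`.

**The two study configurations.** The default configuration is
*decoding-calibrated*: `hourly_signature_strength = 0.008` and weak
coupling (0.02 → 0.004) are set so that a single neuron decodes the hour
only slightly above the 1/24 chance level (measured ≈ 8%), which is the
regime in which cohort polling is interesting. `module_structured_config()`
is the *subtype/module* configuration: three equal-count concentric
modules with a strong coupling gradient (0.6 → 0.15) running opposite to
a steep amplitude gradient (1 → 4), a module-rotating burst-class
composition (`module_class_contrast = 3`), and a Gaussian-copula
correlation (0.98) between a neuron's burst-rate percentile and its
module position. The copula preserves the population-wide lognormal rate
marginal while making module membership decodable from single-neuron
dynamics — a precondition for any subtype discovery method; with rates
assigned independently of module, per-neuron rate variability (a factor
of ~10 across the population) swamps a 2× amplitude gradient and even a
supervised classifier cannot recover module identity reliably.

## Burst detection and classification

`detect_bursts()` is a transparent stand-in for model-based spike
inference: peaks are found on a 5-frame moving average and filtered by
topographic prominence (default 0.3 ΔF/F); amplitude (peak ΔF/F above
the local base) and FWHM duration (interpolated half-maximum crossings)
are then measured on the raw trace, so the attribute definitions are
exact on clean pulses. Negative deflections are detected on the flipped
trace and flagged by polarity, not classed. Raising the prominence
threshold can only remove events.

`cluster_bursts()` z-scores (duration, amplitude) — the two axes have
incommensurate units — and runs K-means (20 restarts) for each candidate
K; K is selected by the gap statistic with B = 50 uniform reference
draws over the bounding box and the standard one-standard-error rule.
Degenerate inputs return K = 1. Class-switching matrices count
consecutive same-neuron transitions and are row-normalized; the mean
signed duration change per transition summarizes drift toward shorter or
longer classes.

## States, modes and their classifiers

Traces are z-scored and delay-embedded in three dimensions; the delay is
the first local minimum of a 16-bin histogram mutual information over
delays 1..T/4 (fallbacks: MI half-maximum, then global minimum — a pure
sinusoid of period P yields τ ≈ P/4). Consecutive embedded points form a
directed path graph; the node count is exactly T − (m−1)τ.

The state classifier is a three-layer graph convolution (width 32,
leaky-rectifier slope 0.2) on that graph, with the three layer outputs
concatenated, max-pooled over nodes, and classified by a two-layer head
under cross-entropy (Adam, learning rate 0.001, 160 epochs). Labeled
training material comes from `archetype_trace()`, and
`augment_labeled_manifolds()` expands it exactly four-fold (magnitude
perturbation with mean 1/variance 0.5, half-swapping, both). For
batching, node sequences are linearly resampled to a common length
(default 100); the graph propagation averages each node with its
predecessor, the simplest reading of directed temporal edges.

Mode assignment takes each neuron's session-mean ΔF/F profile and calls
the contiguous 12-session circular window with maximal mean the H mode.
Because that window is *selected* to be maximal, a naive two-sample test
on the split is anti-conservative (≈20% false positives at α = 0.05 in
null simulations); `assign_modes()` therefore reports a selection-aware
permutation p-value (the max-window statistic recomputed under session
permutations, 200 by default, measured ≈3% type-I) alongside the
conventional Wilcoxon rank-sum p for the chosen split.

## Cohort time decoding

Hour decoding treats a cohort of neurons as one sample: each member's
session trace is z-scored and the predictor must output the hour label
(24 classes, chance 1/24). Neurons — not time points — are split 6:1:3
into train/validation/test pools (floor arithmetic, remainder to test),
and cohorts are always drawn within one pool, so no trace is shared
between training and evaluation.

The network is one convolutional layer (kernel 7), a residual block of
32 channels, and a fully connected head under cross-entropy. Two design
choices matter:

* *Neuron pooling placement.* The first convolution is linear, so
  averaging its outputs over cohort members equals convolving the
  cohort-mean trace. Pooling is therefore applied right after that layer,
  which keeps the predictor permutation-invariant in the neurons and
  makes training cost independent of cohort size.
* *A positional head.* The hour signatures are locked to the session
  clock, so the head uses strided average pooling over time (stride 4)
  followed by a flattening FC layer rather than global pooling; a fully
  time-invariant head cannot distinguish phase-shifted signatures and
  plateaus far below ceiling.

Training draws fresh labeled cohorts every epoch, with two
regularizers against the neuron-resampling shift between pools: cohorts
are drawn at a mixture of sizes (the target size and 1/4, 1/2, 2/3 of
it), which emulates the structured sampling noise that separates the
pools, and decoupled weight decay (1e-4). Early stopping monitors
validation-pool cohorts. Default optimization: Adam at 1e-3, batch 128,
20 fresh cohorts per hour and epoch, up to 60 epochs.

`accuracy_curve()` reports accuracy versus cohort size with SEM across
seeds and a one-sided trend test; `embed_feature_space()` shows the
time-pooled second-convolution features in 2-D via the package's exact
t-SNE, with the mean silhouette of the hour labels.

**Contribution coefficients.** For per-neuron attribution the dataset is
reshaped into 24 all-neuron samples and a slimmed network (2-channel
convolutions, per-neuron paths pooled after the nonlinear stack) is
trained until the 24 samples are classified perfectly — attribution of a
misclassifying network is refused. Integrated gradients from a zero
baseline (midpoint rule, M = 64, completeness within 1%) are aggregated
to one coefficient per neuron and hour (mean absolute attribution over
time), min-max normalized within each hour, fitted per hour by a
moment-based Gaussian, and averaged over the cycle; the 5%–95% spread of
the 24-h average quantifies how uniformly neurons contribute.

## Contrastive subtype discovery

Each neuron's sessions are concatenated as raw ΔF/F (per-session
z-scoring would erase the amplitude attributes that distinguish
subtypes). Two overlapping random crops per neuron form a view pair;
augmentations are binomial timestamp masks (keep probability 0.5),
Gaussian noise at 0.1 of the trace SD, and a wavelet view that keeps only
detail coefficients (periodized Daubechies-4, 3 levels) — the
high-frequency content that carries bursts. Negatives are other
timestamps or other neurons, sampled in an exact 1:1 ratio with the
positives.

The encoder is an input projection, timestamp masking (training only),
and ten dilated residual convolution blocks (kernel 3, dilations
2⁰..2⁹; receptive field > 2¹⁰ − 1 frames), with a per-timestep output
projection to D = 64 (initialized at low gain so the contrastive softmax
starts unsaturated). The loss contrasts aligned overlap latents at every
level of a max-pool-by-2 temporal pyramid: a temporal term (same neuron,
same timestamp across views vs other timestamps) and an instance term
(vs other neurons at the same timestamp), dot-product similarity at
temperature 1, averaged over levels; only the temporal axis forms a
pyramid. Training stops when the relative loss change drops below 1e-3
(after a minimum of 8 iterations — the loss is noisy early) or at the
iteration cap; typical runs converge in about ten iterations. The
per-neuron representation is the time-axis max pooling of the unmasked
encoding of the full series.

Max-pooled activations are heavy-tailed (they track the largest burst),
so `cluster_subtypes()` rank-normalizes features before K-means; raw
K-means isolates a handful of extreme neurons instead of splitting the
population. Robustness checks re-run the pipeline under farthest-point
spatial subsampling (50%), temporal decimation (every other frame),
single-sided analysis with mirrored-pair comparison, and three 8-h
segments, reporting adjusted Rand indices against the full-data labels.

## Module-level statistics

`module_stats()` aggregates per-neuron amplitude (session-mean ΔF/F
averaged over sessions) into module means and across-neuron variances,
with a Spearman trend test along the ventrolateral→dorsomedial band
order. `module_mic()` estimates within-module coupling as the average
MIC over randomly sampled neuron pairs (capped at 500 per module) on
per-session z-scored, concatenated and evenly subsampled series. The MIC
itself is a grid search over equal-frequency partitions with
kx·ky ≤ n^0.6 and at most 15 bins per axis, normalized by log₂ min(kx,
ky) — 1 for noiseless functional relations, near 0 for independence.
`cross_module_eval()` trains one cohort predictor per module (6:1:3
split within the module, cohorts shrunk with a warning if a module is
small) and evaluates every predictor on every module's test cohorts.

## Wave detection

Hourly intensity maps (neuron positions binned on a pixel grid, session
means averaged per cell) are Gaussian-smoothed (σ = 3.5 px), normalized
by their mean pixel value — which also makes the result invariant to
global intensity scaling — and differentiated twice in time with central
differences. Pixels above a threshold (default: the 97.5th percentile of
the second-derivative distribution; the percentile is a package default,
chosen to flag only the sharpest accelerations) are "excited". The
wavefront is the per-frame excited-pixel centroid with boundary
contours; speed and direction come from a robust (Huber) regression of
the centroid trajectory, because the excitation forms lobes leading and
trailing the crest and frames where only one lobe crosses threshold are
off-track. Estimates bias low when the wave enters or leaves the imaged
field, as truncated lobes drag the centroid; the recovery tests
therefore plant waves that stay interior.

## Problem sizes and determinism

The test suite and the acceptance script regenerate everything from
seeds; all stochastic stages take explicit seed arguments and fixed
seeds give bit-identical datasets. The canonical decoding study uses
N = 3000 neurons × 24 sessions × 200 frames with cohort size 900 and
500 evaluation cohorts; the module-specific predictor study uses
3 × 1200 neurons with cohort 600; subtype-recovery replicates run five
seeds of the module-structured configuration at N = 48–60 neurons with a
16-channel encoder, and the remaining unit tests use smaller instances
of the same generators. These sizes are the package's chosen study
scale: large enough that the population-level effects are unambiguous,
small enough that the whole suite reruns from scratch routinely.

## Limitations

The generator is a phenomenological surrogate: it plants the multiscale
structure the analyses are meant to recover, but it does not model
photon noise, optical sectioning, neuropil contamination, motion, or the
molecular clockwork, and its hour signatures are stationary waveforms
rather than emergent network dynamics. Passing tests therefore certify
that each method recovers the structure it targets when that structure
is present at the planted strength — not that real SCN recordings
contain that structure. The burst detector is a transparent stand-in for
model-based deconvolution and will merge heavily overlapping events.
Time decoding here is within-recording: train and test cohorts come from
different neurons but the same 24 sessions, which is the paired design
for "how many neurons carry the time code", not a test of
generalization across days or slices.
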