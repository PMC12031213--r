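---
title: "Methods: simulating and classifying medication-taking gestures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying medication-taking gestures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(medgest)
```

## The problem

Adherence to medications for opioid use disorder (oral liquid methadone,
sublingual buprenorphine film) is usually monitored by supervised dosing
or self-report. Both medications are taken with short, stereotyped wrist
movements — raising a small bottle and drinking; tearing a packet and
placing a film under the tongue — that a wrist-worn accelerometer sees as
a few seconds of characteristic 100 Hz tri-axial signal. `medgest`
implements the full recognition pipeline: generate (or ingest) raw
recordings, recover labeled gesture bouts, window them, split without
leakage, train a 1D residual network, and report precision/recall/F1
across three scenarios of increasing practical abstraction
(drug-vs-drug, drugs-vs-daily-living, any-medication-vs-daily-living).

Because no public recording corpus exists for this task, the simulator is
a first-class component: it reproduces the *protocol* of a supervised
collection study and provides exact ground truth, so every downstream
stage is testable against known answers.

## The synthetic cohort generator

**Signal model.** A gesture is an ordered list of kinematic phases. Each
phase carries a start and end wrist orientation (a unit gravity direction
in the sensor frame), a smooth movement-acceleration bump
(`peak * sin(pi*u)^2` along a fixed direction), and optionally an
oscillatory component (tremor-like jitter for packet-tearing and typing,
rhythmic swing for waving). The rendered trace is

    a(t) = 9.81 * g(t) + movement(t) + N(0, noise_sd^2)

with `g(t)` the orientation slerped through the phase endpoints under a
smoothstep time-warp. Units are m/s² with gravity 9.81, the Android
sensor convention. Rendering a template at duration `d` and rate `r`
yields exactly `round(d*r)` samples per channel. A left-wrist rendering
negates the x and z channels of the right-wrist rendering — a fixed,
involutive mirroring; the exact sensor frame is arbitrary, but the
transform is documented and testable.

**The two medication templates** share a five-phase skeleton
(reach → prepare → raise → ingest → lower) with identical duration
fractions, differing in orientations, bump amplitudes, and the prepare
phase: cap-unscrewing for methadone is near-static on the watch hand,
while packet-tearing for buprenorphine adds 8 Hz jitter. Sharing the
skeleton lets the two templates be blended phase-wise toward their common
mean: `class_separability = 1` renders them fully distinct,
`0` collapses them onto identical class-mean traces. This dial, together
with `noise_sd`, sets task difficulty continuously.

**Durations** are drawn as `2.5 + 8.5 * Beta(2, b)` seconds — support
exactly [2.5, 11] s — with per-class `b` (25.33 methadone, 23.95
buprenorphine) calibrated once so that a 4-s window retains 96% of
methadone and 95% of buprenorphine bouts; the class medians (3.03 s,
3.06 s) follow from that calibration and are recorded in the
configuration for reference.

**Protocol assembly.** Each session plants
`gestures_per_session_per_class` bouts per medication class (default
10 + 10) with a 5 left / 5 right wrist split, each bout immediately
bracketed by a vigorous wrist shake — a 1 s, 4 Hz sinusoidal burst at
15 m/s² peak with a flat-top (Tukey, 10% ramp) envelope, separated from
the gesture only by a 0.05–0.15 s grip pause. The flat top makes the
shake's extent sharply delimited, which is what makes it a useful
labeling delimiter; its amplitude is several times any gesture movement,
so it is unambiguous in band-passed RMS. Daily-living bouts (default 20
per session) fill the gaps between shake pairs, drawn from a weighted
taxonomy: `typing`, `reaching`, `waving`, `rest`, and `drinking` — the
last of which deliberately *clones the methadone template* (drinking
water from a small bottle is the same motion), making it the designated
confounder for the medication-vs-daily scenarios. Sessions in the first
half of a participant's schedule are tagged `nMTE` (natural), the rest
`sMTE` (scripted). Timestamps lie on a 10 ms grid from a configurable
session start; raw CSVs use the dialect
`hour,minute,second,millisecond,day,month,year,ax,ay,az` with
acceleration printed to 6 decimals (round-trip error below 1e-6 m/s²).

**Determinism.** Every session's randomness derives from a per-session
seed computed from the master seed and the participant/session indices;
identical configurations produce byte-identical CSVs.

**What the simulator does not emulate**: inter-participant biomechanical
idiosyncrasy beyond RNG variation, sensor drift and temperature bias,
clock jitter, wear-position variation, and the long ambient stretches of
real free-living data. Passing tests therefore demonstrate pipeline
correctness and capacity on protocol-shaped data, not field performance
on real wearables.

## Segmentation

Shake markers are detected by high-pass filtering each axis (4th-order
zero-phase Butterworth, 3 Hz corner), taking a 0.25 s moving RMS of the
filtered vector magnitude, and keeping maximal intervals above 5 m/s²
lasting at least 0.4 s. Filtering per axis (rather than filtering the
magnitude) matters: gravity dominates the norm, which would halve and
frequency-double the burst energy. Consecutive marker pairs delimit
candidate gestures; each candidate needs an external annotation (class,
wrist) or is discarded and counted, mirroring a labeling workflow in
which low-confidence gestures are excluded. On simulated sessions at
default noise, all planted markers are recovered with no false positives
and boundary errors at or below 0.2 s, and segmentation recovers every
planted bout (the test suite asserts this over 50 seeded sessions).

Sample coordinates are 0-based, half-open everywhere. Timestamp gaps
larger than 3 sample periods split a recording into segments rather than
interpolating — sensor data are never fabricated.

## Windowing and standardization

Every bout becomes one 4 s × 3 channel window (400 samples at 100 Hz)
centered on the bout midpoint. Bouts shorter than the window take real
surrounding recording context (preserving realistic signal statistics)
and are zero-padded only at recording edges, with a flag; bouts longer
than the window are center-cropped. The crop-not-discard default follows
from maximizing data retention — only ~4–5% of bouts exceed 4 s under the
duration model, and their central span carries the ingest phase.
Sliding-window augmentation is deliberately absent: one window per bout
keeps window counts equal to gesture counts.

Standardization is per-channel global z-scoring with statistics fitted on
the training split only; the fitted object records `fitted_on` and is
never refit downstream, which is the leakage-safety contract (asserted in
tests). The transform is exactly invertible.

## Splitting

Three independence levels are selectable:

- **gesture** (default): stratified per class; no bout contributes
  windows to more than one of train/val/test, though participants and
  recordings may span sets;
- **recording** / **participant**: whole groups are assigned to one
  side; stratification happens at group level on the group's majority
  class.

The test share is `round(0.2 * n)` per class (gesture level). Validation
is always carved from the training side, 10% by default — a declared
choice where the protocol literature says only "a small proportion".
Splits are deterministic per seed, with ties broken by stable bout order.

## The classifier

A RegNet-style 1D residual network: the design space is deliberately
regular — a stem convolution (kernel 7, stride 2), `n` stages of
identical residual blocks (two conv–BN–ReLU layers with an identity
skip; a strided 1×1 projection at stage entry), non-decreasing stage
widths, global average pooling, and a linear head. Defaults are stem 32;
depths [2, 2, 2]; widths [32, 64, 128]; kernel 3 — the smallest
RegNet-flavored configuration that trains comfortably on a CPU; all of
it is configuration-exposed, and the embedding hook returns the pooled
pre-head features (length = last stage width) for t-SNE inspection.
Input is accelerometer-only (3 × 400); He-normal initialization is
deterministic under the model seed.

The forward and backward passes are implemented in the package
(convolutions as im2col gathers plus BLAS matrix multiplies; batch
normalization with running statistics for evaluation mode) and the
backward pass is verified against central finite differences for every
parameter tensor in the test suite.

**Optimization** is AdamW (decoupled weight decay; batch-norm parameters
and biases exempt) with cross-entropy loss. Defaults: learning rate
1e-3, weight decay 1e-2, batch 64, at most 50 epochs, early stopping on
validation loss with patience 10; the best-epoch weights are returned,
never the last. Optional inverse-frequency class weighting supports
imbalanced daily-living volumes. Training reads train windows only and
selects on validation only; test windows are never touched before final
evaluation (a test corrupts the test windows with NaN and shows training
is unaffected). Runs are deterministic given the seeds on a fixed BLAS.

## Evaluation

Confusion matrices use rows = true, columns = predicted. Per-class
precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, and F1 — the harmonic mean
`2PR/(P+R)`, defined as 0 when `P + R = 0`; macro values are unweighted
means over classes. Vanishing denominators yield 0 with an explicit
flag, a conservative and test-stable convention. Report rendering rounds
half-up to two decimals; zero-support classes print `NA`. Precision-
recall curves sweep every distinct score threshold; t-SNE is an exact
(dense) implementation with perplexity-calibrated affinities, PCA
initialization, early exaggeration, and momentum descent — deterministic
per seed and adequate for the few-hundred-window embedding sets this
pipeline produces. All metric code is cross-checked against brute-force
recomputation from raw label pairs.

The three scenarios relabel bouts before windowing: scenario 1 drops
daily-living bouts; scenario 2 maps every `daily:*` activity to `daily`;
scenario 3 additionally merges the two drugs into `medication`. One
model is trained per scenario from scratch. Relabeling commutes with
metric computation (tested).

## Benchmark sizes and numerical choices

The packaged benchmark (`benchmark_config()`) uses a 4 × 2 cohort
(~320 bouts, 160 medication), a reduced model (stem 16, depths
[1, 1, 1], widths [16, 32, 64]), 30-epoch budget — sizes chosen so the
full three-scenario run completes in about a minute on a single CPU
while still exercising every pipeline stage. It fixes
`class_separability = 1`, `noise_sd = 0.02`, and zero weight on the
`drinking` confounder: the easy-separability regime in which held-out
macro F1 is expected near 1.0 (asserted ≥ 0.95 for scenario 3 and
≥ 0.85 for scenario 1). With permuted labels the same setup collapses to
chance-level macro F1, the standard sanity check against leakage.

Other numerical details: batch-norm epsilon 1e-5 and momentum 0.1;
cross-entropy clamps probabilities at 1e-12; `round(d*r)` sample counts
make window and phase lengths exact integers with totals preserved;
degenerate inputs (zero-variance channels, empty validation sets,
single-class PR truth, identical embeddings, infeasible stratification)
are rejected with named errors rather than silently propagated.

## Limitations

Synthetic kinematics are phase-level caricatures, not biomechanics; the
perfect benchmark scores say nothing about real-world F1. The drinking
confounder makes medication-vs-daily arbitrarily hard, but real
confounders are broader (eating, smoking, face-touching). Only the
accelerometer is modeled; gyroscope fusion and physiological channels
are out of scope. Early stopping uses a single holdout, not
cross-validation. Exact t-SNE is quadratic in the number of points and
meant for a few hundred embeddings.
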