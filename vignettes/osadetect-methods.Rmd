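---
title: "Detecting sleep-apnea events and estimating the AHI from four 1-Hz channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep-apnea events and estimating the AHI from four 1-Hz channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osadetect)
```

## The problem

Obstructive sleep apnea (OSA) is diagnosed from the apnea–hypopnea index
(AHI): the number of respiratory events — complete airflow cessations
(apneas, ≥ 90% reduction) or partial reductions with a ≥ 3% oxygen
desaturation or arousal (hypopneas) — per hour, each lasting at least 10 s.
Full polysomnography measures dozens of channels in a lab; portable monitors
(PMs) must work from a handful of comfortable sensors. `osadetect`
implements a PM-oriented pipeline over four channels sampled or downsampled
to 1 Hz: oxygen saturation (SpO2, %), heart rate (HR, bpm), and thoracic and
abdominal respiratory effort. Recordings are cut into non-overlapping 60-s
windows; a 1-D convolutional network classifies each window as containing an
apnea/hypopnea event or not; positive windows are counted and divided by the
total recording time (TRT, fixed at 8 h for full records) to estimate the
AHI and the clinical severity class (AHI < 5 none, 5–15 mild, 15–30
moderate, ≥ 30 severe). Because the denominator is recording rather than
sleep time, severity can be slightly understated — a deliberate PM
convention that we inherit rather than correct.

## Labeling and preprocessing

A window is labeled positive when the union of overlapping respiratory
events covers **at least 10 s** of it, regardless of how many events
contribute; two 6-s events in one window therefore count (12 s of union
coverage), while a 9-s event never does. Central/mixed/other event types are
excluded by default (`include_central = FALSE`); annotation sources are
trusted on hypopnea validity rather than re-scored from SpO2.

Two optional preprocessing stages define the four dataset variants
(numbered 1-4) used to study their effect on the classifier:

* **Artifact interpolation** — SpO2 samples outside [80, 100]% and HR
  samples outside [40, 200] bpm are treated as heavy sensor artifacts
  (dropouts read as zeros, out-of-range spikes) and replaced by linear
  interpolation between the nearest valid neighbours (nearest-value fill at
  the record edges). The operation is idempotent and leaves effort channels
  untouched; a channel that is flagged in its entirety rejects the record.
* **Per-window standardization** — each 60 × 4 window is z-scored per
  channel, `z = (X - mu) / sigma`, with the within-window, within-channel
  mean and *population* (divide-by-n) standard deviation; a constant channel
  maps to zeros. The population/sample distinction is immaterial at n = 60
  but is fixed so tests can assert exact values. Standardizing per window —
  rather than per recording — makes every window self-referential, which
  suits streaming PM inference. A min–max variant rescaling each channel to
  [0, 1] is available behind `method = "minmax"` but is off by default; the
  z-score is the definition used everywhere else.

Variant 1 applies neither stage, 2 only interpolation, 3 only
standardization, 4 both. Labels are computed before any value transform, so
all variants share identical label vectors. Training sets are balanced to
exactly 50/50 by keeping every minority-class window and down-sampling the
majority uniformly at random with a fixed seed, preserving window order.

## The classifier

The window classifier is a 1-D CNN whose reference architecture
(`reference_config()`) has six hidden blocks — feature maps 128, 192, 224, 96,
256, 96; kernel sizes 7, 5, 3, 7, 9, 9; dropouts 0.3, 0.3, 0.4, 0.2, 0.3,
0.5 — each block being a length-preserving convolution (stride 1, zero
"same" padding), batch normalization, ReLU, and element-wise dropout. There
is **no pooling or striding inside blocks**: the only temporal reduction is
a global average pool (GAP) before a single sigmoid unit, so the last
convolutional layer stays aligned 1:1 with the 60 seconds of the window —
the property that makes CAM-style localization clean. Training minimizes
binary cross-entropy with Adam (learning rate 0.001) at batch size 1,024
for at most 50 epochs, with early stopping that monitors validation loss
with patience 5 and restores the best epoch's weights (including the
batch-norm running statistics). Within each block we place batch-norm
before the activation and dropout after it, and use element-wise rather
than channel-wise dropout — the common Keras idiom; neither ordering nor
dropout style carries a field-wide convention, so these are package
choices.

The engine is written in R: convolutions are evaluated as an im2col gather
followed by one BLAS matrix multiplication per layer, and all gradients
(conv, batch-norm, GAP, dense) are analytic, verified in the test suite
against central finite differences to ~1e-7 relative error. At inference
the batch normalization folds into a single affine map per feature. Window
probabilities are thresholded at 0.5 by default with ties predicted
positive.

Because a six-block network at batch 1,024 is a GPU-scale job, the package
also names a CPU-scale profile, `scaled_down_config()`: two blocks of 32
maps (kernels 7 and 5, dropout 0.1), batch 128, learning rate 0.003, at
most 20 epochs. All desk-scale experiments, the test suite and the
acceptance script use this profile; the six-block configuration remains the
reference and is built and audited layer-by-layer in the tests.

Hyperparameter search (`tune()`) samples depth (2–6) and per-layer feature
maps {64…256}, kernels {3, 5, 7, 9, 11} and dropouts {0.1…0.5} uniformly,
then applies successive halving: every candidate trains for a first short
rung, the top `keep_fraction` survive to a rung with `1/keep_fraction`
times the epochs, and so on. The default budget (90 candidates, 3 rungs,
keep 1/3) matches the scale of a Hyperband search over the same space while
replacing Hyperband's bracket accounting — whose trial-count formulas differ
between published descriptions — with this single documented schedule.
With one rung and `keep_fraction = 1` it degenerates to plain random
search, which the tests exploit.

## Patient-grouped evaluation

Windows from one patient are strongly correlated, so window-level random
splits leak. Every split in the package is **by patient**: the 70/20/10
train/validation/test split, the training-time leakage check (shared
patient ids between train and validation are a hard error), and the
incremental cross-validation plan, where fold *i* of *k* uses the first
`ceiling(i * n / k)` patients of one fixed shuffle, split patient-wise into
train and validation (default inner validation fraction 0.2). We interpret
the incremental scheme in patient units because patients, not windows, are
the independence unit the scheme exists to protect.

Window metrics are the standard confusion-derived rates plus the
Mann–Whitney AUC (computed by ranks, hence exactly equal to pairwise
counting) and the positive likelihood ratio LR+ = sensitivity / (1 −
specificity), the screening statistic with the cited ≥ 5 usability bar for
portable monitors. Patient-level agreement reports R² (1 − SS~res~/SS~tot~),
the 4 × 4 severity confusion matrix, linearly weighted Cohen's kappa
(weights `1 - |i - j| / 3`), and binary screening metrics at AHI cutoffs
{5, 15, 30} (exposed as configuration because screening studies vary in
which cutoffs they report). Severity bins are the clinical half-open
intervals, boundary values going up (5 → mild, 15 → moderate, 30 →
severe).

## Explainability

`grad_cam()` computes the gradient of the class score with respect to the
last convolutional block's activations `A_k(t)`, averages it over time into
channel weights `alpha_k`, and returns `ReLU(sum_k alpha_k A_k(t))`
normalized by its maximum. With a GAP + single-logit head the gradient has
the closed form `w_k / T`; the class-0 score is the negated logit, the
standard binary adaptation of the multi-class formulation. One shared
temporal map shades all four channel traces — the input channels are mixed
by the first convolution and cannot be separated at the last layer — which
also matches how such overlays are drawn in practice. An all-zero raw map
(e.g. a zeroed head) is returned as all-zeros with a `null_saliency` flag
rather than divided by zero. Maps default to the *predicted* class and are
normalized per window, not per batch.

Grad-CAM is validated against an independent occlusion oracle
(`occlusion_relevance()`): each 10-s span of the window is replaced by the
per-channel window mean and the drop in class probability recorded; a
second's relevance is the mean drop over spans covering it. Across
correctly detected apnea windows from held-out patients, the acceptance
suite requires a mean Spearman correlation above 0.3 between the two maps
and higher mean relevance inside the event-response span (event interval
plus a 20-s tail covering the lagged desaturation and heart-rate rebound)
than outside it.

## The synthetic cohort generator

NSRR polysomnography is access-restricted, so the package ships a generator
that emulates the statistical structure the detector relies on, making the
whole pipeline testable end to end:

* 8-h (28,800-sample) 1-Hz records; a target AHI drawn per patient (default
  Uniform(0, 45), spanning all four severity classes) determines
  `round(AHI × hours)` events of 10–40 s, placed by rejection sampling with
  ≥ 10-s gaps (at most 10,000 attempts before a placement error).
* Respiratory effort is an amplitude-modulated sinusoid (4-s breath
  period); events scale the envelope by ≥ 90% (apneas) or 50% by default
  (hypopneas, ≥ 30% enforced).
* SpO2 rides a 96% baseline; each event triggers a piecewise-linear
  fall/plateau/recovery desaturation of 3–8%, lagged 10–20 s after onset —
  the peri/post-event pattern seen in real recordings.
* HR (65 bpm baseline) shows a half-sine bradycardia dip (−10 bpm) during
  the event and a tachycardia surge (+12 bpm over 15 s) after it. The
  magnitudes are module parameters: the dip/surge shape is well described
  in the sleep literature, its size much less so.
* Per-channel Gaussian noise (0.3% SpO2, 1.5 bpm HR, 0.15 a.u. effort) and,
  optionally, Poisson-distributed heavy artifacts: 3–30-s spans of SpO2/HR
  replaced by zeros or out-of-physiologic-range values, mimicking the
  sensor dropouts that motivate the artifact-interpolation stage.

Records can be written as EDF plus NSRR-style `ScoredEvent` XML so the
real-data readers are exercised by synthetic fixtures. Everything is
deterministic given the seed, with per-patient substreams so cohorts are
reproducible patient by patient.

What the generator does *not* emulate: sleep stages and arousals, body
position, central/mixed apnea morphology, SpO2 drift, inter-patient
baseline variability, or scorer disagreement. Passing tests on this cohort
therefore demonstrate that the implementation is correct and that the
pipeline recovers planted structure under realistic noise and artifacts —
not that the reported clinical accuracies transfer to real polysomnography,
which requires the access-restricted datasets.

## Numerical choices and degenerate inputs

* Downsampling to 1 Hz is the non-overlapping block mean (anti-aliasing by
  averaging), not every-Nth decimation; it preserves event-scale envelopes
  and the overall mean exactly.
* Records shorter than the 8-h target are zero-padded at the tail (windows
  from the pad are dropped, not labeled); longer records are truncated.
  Both adjustments warn.
* All times are 0-based seconds; intervals are half-open
  `[start, start + duration)`.
* Binary cross-entropy clips probabilities at 1e-7; batch-norm uses eps
  1e-5 and momentum 0.9; σ = 0 channels standardize to zeros; AUC and
  weighted kappa are undefined (NA) for single-class inputs and
  zero-variance references respectively; LR+ is +Inf at specificity 1.
* Training history reports train metrics as running means over the epoch's
  mini-batches (dropout and batch statistics active, the Keras convention)
  and validation metrics from a full inference pass.

## Problem sizes used by the tests and the acceptance script

The acceptance experiments train the scaled-down profile on a 20-patient
synthetic training cohort (14 train / 6 validation patients, ≈ 5,400
balanced training windows) for at most 20 epochs, then evaluate AHI
recovery on an independent 30-patient cohort — sizes chosen so the full
suite runs comfortably on a single CPU while still exercising every stage
at realistic record lengths (full 8-h records throughout). Unit tests use
1–2-h records. Expected figures at these sizes: validation accuracy ≈ 0.99,
AUC ≈ 0.999, Grad-CAM/occlusion rank correlation ≈ 0.85, AHI R² ≈ 0.99 —
comfortably above the acceptance floors (0.90, 0.95, 0.3, 0.8), as the
synthetic cohort is cleaner than clinical data by construction.

## Known limitations

* The AHI counts positive windows, so one long event spanning two windows
  counts twice and an event split 6 s / 6 s across a boundary may count
  zero times; with 60-s windows these mostly cancel, and the window-counting
  convention is what makes the AHI computable from a window classifier at
  all.
* Only a binary obstructive/hypopnea-vs-normal distinction is made; central
  and mixed events are not modelled or discriminated.
* The R engine trains the scaled-down profile in minutes but is not meant
  for GPU-scale replication of the full six-block search.
* TRT-based AHI understates severity when actual sleep time is much shorter
  than the recording.
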