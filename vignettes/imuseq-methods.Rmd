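---
title: "Counting functional motion primitives from wearable IMU data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting functional motion primitives from wearable IMU data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Upper-extremity (UE) rehabilitation after stroke is dosed in *functional
primitives* — the elemental goal-directed motions that activities decompose
into: **reach** (motion to contact a target object), **reposition** (motion
near an object without conveying it), **transport** (motion conveying an
object), **stabilization** (minimal motion holding an object still) and
**idle** (minimal motion at the ready). Counting primitives by video coding
is accurate but takes thousands of seconds of coder time per minute of
recording, which makes dose quantification impractical in the clinic.

`imuseq` implements a wearable-sensor alternative: a nine-sensor IMU array
yields a 77-channel kinematic time series at 100 Hz (27 accelerations, 27
sensor-orientation quaternion components, 22 joint angles, and a constant
paretic-side flag), and a sequence-to-sequence recurrent model decomposes it
into the ordered primitive sequence, which a deduplicating counter turns
into per-class tallies.

## Pipeline and model

The pipeline has three stages.

**Preprocessing.** Each sensor's orientation stream is re-expressed relative
to a reference pose (`sensor_centric_transform()`, Hamilton product
`ref^-1 ⊗ q(t)`), so quaternions describe rotation of the sensor about its
own axes; all 76 continuous channels are z-scored with statistics estimated
on the training split only (`channel_stats()`, `zscore_normalize()`). The
quaternion channels store the vector part of a unit quaternion with the
scalar part implied non-negative (9 sensors × 3 components = 27 channels).

**Sequence prediction.** The recording is tiled into 6-s windows whose
middle 4-s *core* is predicted; the flanking 1 s on each side is context
(`make_windows()`). During training the windows slide by 0.5 s, which
multiplies the training set and exposes primitive boundaries at many
offsets; at test time the slide is 4 s so the cores partition the recording.
The model (`train_seq2seq()`) is an encoder–decoder: a 3-layer bidirectional
GRU encodes the window into a feature vector — the concatenation of the
final forward and backward top-layer states, so a per-direction width $H$
gives a $2H$ feature — and a single-layer GRU of width $2H$ autoregressively
emits primitive tokens from a start-of-sequence token until end-of-sequence.
The feature vector both initializes the decoder hidden state and is
concatenated with the previous-token input at every decode step: with
initial-state conditioning alone the feature's influence decays across
steps, which measurably inflated late-sequence errors at desk scale.
Training minimizes teacher-forced token cross-entropy (PAD masked, EOS
appended) with Adam.
Four models trained on rotating subject-level folds form an ensemble
(`cross_validated_train()`): at each decode step the four per-class
probability vectors are averaged, the argmax token is emitted (ties broken
in fixed class order) and fed back to all four decoders
(`decode_greedy()`).

**Counting.** Per-window sequences are concatenated in core order; when the
last token of one window equals the first of the next, the two are merged
into one counted instance (`dedup_and_count()`). With non-overlapping 4-s
cores and primitives of at most 5 s, at most one primitive straddles each
boundary; a primitive spanning three cores merges pairwise and is counted
once. Two genuinely distinct same-class primitives meeting exactly at a core
boundary are merged incorrectly — an inherent limit of timing-free
sequences, shared by the original design.

## Evaluation

Predicted and ground-truth sequences are compared per trial with a unit-cost
Levenshtein alignment (`align_sequences()`). The backtrace prefers match ≻
substitution ≻ deletion ≻ insertion; among equal-cost alignments the
taxonomy tallies can differ, so the tie rule is fixed for determinism. The
alignment operations map onto a four-way error taxonomy
(`classify_outcomes()`): a *deletion* is a missed primitive, a
*substitution* is simultaneously a *swap-out* of the true class and a
*swap-in* of the predicted class, an *insertion* is an invented primitive.
Hence FN = deletions + swap-outs and FP = insertions + swap-ins — identities
the test suite checks on every random alignment. From the tallies:

- sensitivity $= TP/(TP+FN)$,
- FDR $= FP/(TP+FP)$ (the overcount measure),
- $F_1 = 2\,s\,(1-f)/(s + (1-f)) = 2TP/(2TP+FN+FP)$,
- AER (Action Error Rate) $=$ edit distance / ground-truth length (may
  exceed 1).

`confusion_matrix()` normalizes by ground-truth class counts, so the
diagonal is per-class sensitivity and each row (diagonal + swap-outs +
deletion margin) sums to 1; the insertion margin is an extra row outside the
identity. `bootstrap_compare()` subsamples trials with replacement (default
81 of the available trials, 250 replicates — the same draws fed to every
model), aggregates tallies per replicate, and compares models with unpaired
two-tailed equal-variance t-tests (df $= 2 \times 250 - 2 = 498$) under
Bonferroni correction over the number of rivals.

Model selection during training follows the dosing logic of rehabilitation:
overcounting mistrains patients, so among epoch checkpoints with validation
FDR < 20% the maximum-sensitivity epoch is kept; if none qualifies, the
minimum-AER epoch. Training stops after `patience` epochs without
improvement of the selected checkpoint.

## The synthetic data generator

Real labeled patient recordings cannot ship with the package, so
`generate_dataset()` emulates them with class-distinct kinematic phenotypes
under a first-order Markov grammar (`default_grammar()`): rows sum to one,
the diagonal defaults to zero so ground truth never contains back-to-back
same-class segments (a timing-free sequence could not represent the
boundary), and two default "activities" differ in how object-bound their
transition structure is. Durations are log-normal truncated to [0.3, 5] s.
Motion primitives render minimum-jerk velocity bells
($v(\tau) \propto \tau^2(1-\tau)^2$, the standard smooth reaching profile)
on class-specific sensor signatures — reach hand/forearm-dominant at 1 g,
reposition forearm-dominant at 0.65 g, transport hand/arm-dominant at
0.85 g with trunk involvement — with matching joint-angle and orientation
excursions; 70% of the amplitude is on the paretic side and 30%
contralateral. Stabilization and idle render noise only, except that
object-carrying classes (stabilization, transport) add a constant 0.12-g
offset on the paretic-hand acceleration channels as a grasp surrogate: the
sensor array has no finger channels, which is exactly why stabilization and
idle are the confusable pair, and the offset magnitude is the knob that
studies that confusion. Gaussian noise: 0.05 g on accelerations (5% of the
largest burst), 1° on angles, 5 mrad on orientation angles.

The defaults define the study conditions used by the tests: 10 subjects
(8 train, 2 held-out test), 5 trials each (40 training trials), 20-s trials
at 100 Hz, balanced paretic sides. A fixed seed fully determines the
dataset.

What the generator does **not** emulate: whole-body biomechanics, object- or
impairment-specific kinematics, sensor drift dynamics (only an optional
linear angle drift), coder disagreement, and the heavy-tailed variety of
real activities. Passing the end-to-end checks therefore demonstrates that
the pipeline machinery is correct and that the architecture can learn
sequence decomposition from multichannel kinematics — not that the reported
real-data accuracy transfers.

## Numerical and design choices

- **Desk scale.** The reference full-scale configuration (encoder width
  3072, decoder 6144, learning rate 5e-4, 100-Hz input) targets GPU
  training on tens of thousands of primitives. The package defaults are a
  desk-scale operating point chosen, as in the original protocol, by
  validation AER: width $H = 64$, learning rate 5e-3 decaying by 0.93 per
  epoch, batch 32, at most 20 epochs with patience 6, a 2-s validation
  slide (denser validation cores make per-epoch checkpoint selection less
  noisy), and an encoder time stride of 5 (20-Hz effective input;
  primitives last ≥ 0.3 s, so the kinematic content is preserved while
  backpropagation-through-time is 5× shorter). All of these are
  `seq2seq_config()` fields; the full-scale values remain valid settings.
- **Teacher forcing ratio 1.0** and **greedy decoding** (no beam search):
  the simplest well-defined choices; ties break by fixed class order.
- **Feature vector = concatenated final bidirectional states**; it both
  initializes the decoder and conditions every decode step. Token feedback
  (not probability feedback) carries the ensembled decision to the next
  step.
- **Training-target slivers.** A label run overlapping a core by < 0.15 s
  belongs substantially to the neighbouring core (a primitive lasts at
  least 0.3 s, so it always overlaps some core by ≥ 0.15 s); including the
  sliver makes the target depend on sub-tenth-second boundary placement and
  teaches the decoder to emit unstable boundary tokens (insertion errors).
  Such runs are dropped from training and validation targets
  (`target_min_overlap_s`, default 0.15 s in the model config;
  `make_windows()` itself defaults to the exact collapse). Evaluation
  ground truth and the oracle counting path always use the exact collapse.
- **Windows are zero-padded** (after normalization) where they extend past
  the recording, so every time step belongs to exactly one test core and
  edge cores keep their 1-s context window shape; the final test core may be
  shorter than 4 s.
- **Adjacent same-class ground-truth segments merge** in decoder targets
  (run-length collapse): the timing-free decoder cannot distinguish them.
  The generator's zero self-transition default sidesteps the ambiguity.
- **sd floor** 1e-8 replaces zero standard deviations (constant channels
  normalize to zero). **Gradient clipping** at global norm 5 stabilizes
  recurrent training.
- Two optional training regularizers are available and off by default:
  Gaussian **input-noise augmentation** on the normalized channels
  (`input_noise_sd`) and clipped inverse-frequency **class weighting** in
  the loss (`class_weighting`). With the per-step-conditioned decoder
  neither improved held-out metrics on the default synthetic conditions —
  and augmentation noise partially masks the small constant grasp offset
  that separates stabilization from idle — but both are useful dials on
  noisier data. **Kaiser smoothing** uses reflection padding and
  renormalizes probability vectors; the shape parameter comes from the
  stated sidelobe attenuation by the standard window-design relation.
- **Random-forest baseline**: 5 statistics per channel (mean, max, min,
  population sd, RMS) on 1-s sub-windows at 0.1-s stride (the original's
  input window is unstated), probability forest, then Kaiser smoothing with
  parameters grid-searched on validation F1 (ties to the smallest window).
  It is evaluated through exactly the same core-partition, deduplication
  and alignment machinery as the sequence model.

## Problem sizes used by the shipped checks

The test suite trains the default 4-fold ensemble once (H = 64, ~990
training windows per fold from 30 trials, 20-s trials) and reuses it for the
end-to-end recovery and baseline-ordering checks; the Levenshtein oracle
suite is exhaustive for sequence lengths ≤ 4 and samples 10,000 pairs of
lengths 5–6; taxonomy conservation uses 1,000 random alignments; counting
exactness uses all 50 default recordings. These sizes were chosen so the
full suite runs on a single CPU in well under half an hour.

## Known limitations

- On the default synthetic conditions the pointwise random-forest baseline
  with tuned Kaiser smoothing *matches or exceeds* the sequence model: the
  generator gives each class a distinct, stationary sensor signature, so
  the task is nearly pointwise-separable and a per-step classifier with
  1-s feature context approaches the oracle. The benchmark ordering
  reported on real patients (sequence model clearly ahead of the random
  forest) rests on inter-subject kinematic variability and overlapping
  class signatures that the generator deliberately does not emulate; the
  synthetic benchmark therefore exercises the comparison machinery, not
  the real-data ranking.

- Timing-free output: no durations, onsets or kinematic quality per
  primitive; boundary-coincident same-class primitives undercount by one.
- The stabilization/idle distinction rests on a grasp surrogate; with the
  offset at 0, the two classes are indistinguishable by construction.
- Checkpoints are R serializations; they are version-tagged but not a
  cross-language exchange format.
- The bootstrap treats trials as exchangeable units; it ignores subject
  clustering, as does the original analysis.
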