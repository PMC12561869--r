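---
title: "Automatic sleep staging with a multimodal multi-scale attention network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic sleep staging with a multimodal multi-scale attention network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sleepnet)
```

## The problem

Clinical sleep scoring divides an overnight polysomnography (PSG) recording
into 30-second epochs and assigns each epoch one of five stages — W (wake),
N1, N2, N3 and REM. Manual scoring is slow and inter-scorer agreement is
imperfect, which motivates automatic scoring from the raw signals. The
stages differ in well-understood electrophysiological signatures: relaxed
wake carries an 8–12 Hz alpha rhythm and high chin-muscle tone; N2 carries
12–14 Hz spindle bursts and K-complexes; N3 is dominated by high-amplitude
0.5–2 Hz slow waves; REM shows rapid eye-movement deflections on the EOG
with near-complete muscle atonia on the EMG. A single EEG channel cannot
carry all of these cues — the REM/N1 distinction in particular lives largely
in the EOG and EMG — which is why this package consumes a four-channel
montage: EEG Fpz–Cz, EEG Pz–Oz, horizontal EOG, and submental EMG, all at a
common 100 Hz.

## The model

Each 30 s epoch enters the network as a (4, 3000) array. The architecture
has three parts.

**Multi-scale convolutional front end.** Each modality (the two EEG
derivations share one branch with input width 2; EOG and EMG have width-1
branches) is processed by two parallel 1-d convolutional blocks: a small
kernel of 50 samples (0.5 s, stride 6, max-pool 8) that resolves sub-second
transients such as spindles, and a large kernel of 400 samples (4 s, stride
50, max-pool 4) that resolves slow-wave trends. Each block is ordered
convolution → batch normalization → LeakyReLU (slope 0.01) → max pooling →
dropout (p = 0.5), with 64 filters per branch. The two branch outputs (61
and 13 time steps) are concatenated along the time axis into a 74-step
sequence per modality.

**Channel attention and fusion.** A squeeze-and-excitation (SE) gate is
applied per modality: the 64 feature channels are average-pooled over time
(`z_c = mean_t X[c,t]`), passed through a bottleneck of two fully connected
layers (`s = sigmoid(W2 relu(W1 z))`, reduction ratio r = 4, no biases),
and each channel is rescaled by its gate `s_c` in (0, 1). This lets the
network emphasize, say, eye-movement channels during REM-like epochs. The
three gated modality maps are then concatenated along the feature axis into
a (74, 192) sequence.

**Temporal encoder and classifier.** A single-layer bidirectional LSTM (128
hidden units per direction) encodes the 74-step sequence; each step's
forward and backward states are concatenated into a 256-dimensional state.
Attention pooling scores each step with `e_t = v' tanh(Wh h_t + bh)`
(width 128), softmaxes the scores over time, and forms the convex
combination `c = sum_t alpha_t h_t`. After dropout (p = 0.5), a fully
connected softmax layer maps `c` to the five stage probabilities. Training
minimizes the cross-entropy between the predicted distribution and the
one-hot label, computed from logits via log-sum-exp so a vanishing
probability never produces `log(0)`. Optional inverse-frequency class
weights (`w_k = N/(K N_k)`) are available against the strong N1 imbalance
but are off by default, matching the plain cross-entropy objective.

### Ablation variants

`buildVariant()` constructs five reduced architectures alongside the full
model: `no_msconv` (small-kernel branch only, 61 steps), `eeg_only` (EOG and
EMG paths removed; feature width 64), `no_se` (gates replaced by identity),
`no_lstm` (attention pooling applied directly over the convolutional
sequence), and `no_attn` (the context vector is the last bidirectional
state). All six share the training protocol and interface.

### Design choices the architecture leaves open

Several hyperparameters are not dictated by the architecture sketch and were
fixed once as package defaults: one convolutional block per branch; 64
filters in both branches (equal filter counts are required for the time-axis
concatenation); strides and pools (6/8 small, 50/4 large) chosen so the two
branch lengths are the same order of magnitude; small-branch features first
in the concatenation; SE reduction r = 4; SE placed after branch
concatenation and before cross-modal fusion; LSTM width 128 with a single
layer per direction; LeakyReLU slope 0.01; uniform fan-in initialization
with a configurable seed. The conv-branch dropout rate is shared between
the two branches (0.5). All of these are exposed in `sleepNetConfig()` as
configuration, not claims.

## Implementation

No deep-learning framework is used: the forward and backward passes are
implemented directly, with the dense kernels (im2col convolution, fused
batch-norm + LeakyReLU, max pooling, the LSTM recursion, SE broadcasts) in
C++ (RcppArmadillo) and the remaining matrix algebra on R's BLAS. The
backward pass of every variant is verified against central finite
differences in the test suite at a relative tolerance of 1e-4 on sampled
parameters. Optimization is Adam (learning rate 0.001, beta1 = 0.9,
beta2 = 0.999, batch size 64); batches are reshuffled every optimizer epoch
with a derived seed and the last partial batch is kept. Batch normalization
uses biased batch variance and running statistics with momentum 0.1.

## Data pipeline

`readPSG()` reads EDF/EDF+ (16-bit) files, applies the digital-to-physical
calibration from the signal headers, matches channels by case-insensitive
substring patterns, and resamples every retained channel to 100 Hz by
linear interpolation — in the public sleep-cassette archives the submental
EMG is stored at 1 Hz, and upsampling it keeps the (4, 3000) epoch geometry
uniform. `readHypnogram()` parses EDF+ time-stamped annotation lists.
`mapStageLabels()` applies the scoring table: the older 4-stage deep-sleep
scoring merges into N3 (the universal convention when reporting five AASM
stages from such archives), and movement/unscored slots are excluded.

`epochAndTrim()` drops excluded slots and trims wake: W epochs more than 30
minutes before sleep onset or after final sleep offset are removed. This
margin is exposed as a flag because archival preprocessing descriptions are
ambiguous on the point; 30 minutes is the common convention and the
default. `normalizeEpochs()` z-scores each channel per recording (epsilon
guard 1e-8 maps constant channels to zero): raw EDF channels differ in
physical scale by orders of magnitude and unnormalized fusion destabilizes
training.

Training evaluation is subject-disjoint: `makeSubjectFolds()` partitions
subjects (not epochs) into k = 5 test folds differing in size by at most
one, all recordings of a subject traveling together; `leakageCount()`
audits the plan. Within each fold's training epochs a stratified 10%
holdout drives early stopping (patience 5, at most 100 optimizer epochs,
best-validation parameters kept). Stratification is used because N1
scarcity makes small unstratified holdouts unstable; the holdout is taken
at the epoch level (a literal reading of holding out training samples).

## The synthetic generator

`makeSyntheticDataset()` exists so the whole pipeline — including learning —
is testable without any data download. Hypnograms are Markov chains whose
default transition matrix is `P = a I + (1-a) 1 pi'` with persistence
a = 0.86, giving strong self-transitions (diagonal 0.87–0.92) and exactly
`pi` as stationary distribution; `pi` defaults to the count-derived class
balance of a public sleep-cassette archive (W/N1/N2/N3/REM =
19.6/6.6/42.1/13.5/18.2 %), so N1 is the rarest stage. Signals are sums of
narrowband random-phase oscillations with amplitude envelopes, stage
transients (spindle bursts, K-complex-like pulses, EOG deflections,
blinks), a white-noise EMG whose RMS encodes muscle tone with REM atonia,
and 1/f Gaussian background. The generator reproduces exactly the cues the
architecture targets — band powers, transients, EMG tone — and nothing
else: no realistic artifacts, no inter-subject physiology, no slow
overnight nonstationarity. Passing tests on these data therefore
demonstrate that the implementation can learn the advertised cues, not
that it attains benchmark accuracy on real PSG; benchmark-scale evaluation
requires the public archives and the full training protocol.

Two built-in checks keep the generator honest: a multinomial logistic
regression on hand-crafted band-power features must reach at least 80%
five-class accuracy (the classes are linearly separable, so any failure of
the network is a model bug, not a data bug), and a variant of the generator
(`stageSignalModel(remEEGDistinct = FALSE)`) makes wake and REM identical
on the EEG channels so that only EOG/EMG separate them — the EEG-only
ablation must then score strictly worse than the full model, demonstrating
that the multimodal path is actually used.

## Numerical and procedural details

* Epoching is exact: retained epochs reproduce source samples bit-for-bit
  before normalization.
* EDF writing digitizes against the physical range exactly as serialized in
  the header (symmetric digital range ±32767), so a write/read round trip
  is identity on labels, rates and annotation triples, and signal error is
  bounded by half a quantization step; constant-zero signals round-trip
  exactly.
* Division-by-zero cases in per-class metrics (a stage absent from truth
  and prediction) report 0 with a warning so pooled cross-fold reports
  never fail; Cohen's kappa of a degenerate single-class prediction is 0.
* Softmax and cross-entropy are computed with max-shifts / log-sum-exp.
* All randomness (initialization, shuffling, dropout, holdouts, the
  generator) flows from explicit seeds through one derivation function;
  evaluation-mode forward passes are deterministic, and repeated runs with
  one master seed are bit-identical on one platform.

## Problem sizes used by the tests and the acceptance script

Mechanical properties (layer algebra, early stopping, checkpointing,
determinism) are tested on a scaled-down geometry: 3 s epochs and a small
configuration (8 filters, LSTM width 8), where the logic is identical and
the runtime negligible. End-to-end learning properties use the full default
architecture at the study geometry: an overfit run on 100 epochs (20 per
stage) that must reach 100% training accuracy within 300 optimizer steps,
and a 5-fold subject-disjoint cross-validation on the default synthetic
dataset of 10 subjects × 200 epochs that must exceed 90% accuracy against a
20% chance level. The synthetic classes separate quickly, so the
cross-validation runs are capped at 2 optimizer epochs per fold — the
100-epoch/patience-5 protocol itself is exercised separately on the small
geometry. The acceptance script repeats these computations from scratch
under a caller-supplied seed.

## Known limitations

* The benchmark numbers reported for this architecture on the public
  sleep-cassette archives are not reproduced here; they require the
  download and hours of training, and several architecture hyperparameters
  (filter counts, strides, LSTM width) are open choices, so exact
  replication is not guaranteed by design.
* The model classifies one 30 s epoch at a time; there is no multi-epoch
  sequence input and no pretraining or fine-tuning scheme.
* EDF support covers continuous EDF/EDF+ 16-bit recordings; discontinuous
  (EDF-D), BDF and proprietary formats are out of scope, as are artifact
  rejection and filtering (the pipeline feeds the raw time series to the
  network).
* The Markov hypnogram model has no overnight cycle structure (no
  NREM/REM cycling); it reproduces stage persistence and class balance
  only.
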