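# sleepnet

Automatic five-stage sleep scoring (W, N1, N2, N3, REM) from multi-channel
polysomnography, for sleep researchers and methods developers who want an
end-to-end, dependency-light R implementation: EDF/EDF+ ingestion, epoching
and label mapping, a neural classifier built from first principles, a
subject-disjoint cross-validation protocol, a complete metric suite, and a
synthetic PSG generator so everything is testable without downloading a
benchmark archive.

## The model

Each 30 s epoch of the four-channel montage (EEG Fpz–Cz, EEG Pz–Oz, EOG,
submental EMG; 100 Hz) enters as a (4, 3000) array and passes through:

1. **Per-modality dual-branch multi-scale 1-d convolution** — a small
   kernel (50 samples, stride 6, pool 8) for sub-second transients such as
   sleep spindles, and a large kernel (400 samples ≈ 4 s, stride 50,
   pool 4) for slow-wave trends; each branch is conv → batch norm →
   LeakyReLU → max pool → dropout with F = 64 filters, and the branch
   outputs are concatenated along time (61 + 13 = 74 steps).
2. **Squeeze-and-excitation channel attention** per modality:
   z = (1/T) Σₜ X[:, t], s = σ(W₂ δ(W₁ z)), X̂꜀ = X꜀ · s꜀, with reduction
   r = 4, then feature-axis fusion of the three modalities (3 × 64 = 192).
3. **BiLSTM + attention pooling**: hₜ = [h⃗ₜ; h⃖ₜ] (128 hidden units per
   direction), αₜ = softmaxₜ(vᵀ tanh(W_h hₜ + b_h)), c = Σₜ αₜ hₜ.
4. **Softmax classifier**: y = softmax(W_fc c′ + b_fc) after dropout
   (p = 0.5), trained with cross-entropy L(ŷ, y) = −Σₖ ŷₖ log yₖ
   (optional inverse-frequency class weights).

Five ablation variants (`no_msconv`, `eeg_only`, `no_se`, `no_lstm`,
`no_attn`) share the interface and training protocol. Evaluation reports
overall accuracy, macro-F1, Cohen's kappa κ = (P₀ − Pₑ)/(1 − Pₑ), and
per-class/macro sensitivity, specificity and precision, all derived from a
5×5 confusion matrix.

The forward and backward passes are implemented in the package itself
(RcppArmadillo kernels + BLAS); no deep-learning framework is required.

## Worked example

```r
library(sleepnet)

# synthetic study: 10 subjects x 200 labeled 30 s epochs
dataset <- normalizeEpochs(makeSyntheticDataset(10, 200, seed = 11))
dataset
#> SleepEpochSet: 2000 epochs x 4 channels x 3000 samples (normalized)
#>   subjects: 10
#>   stages:  W=296 N1=179 N2=852 N3=360 REM=313

# subject-disjoint 5-fold cross-validation of the full model
cv <- runCrossValidation(dataset, variant = "full", k = 5, seed = 12,
                         maxEpochs = 2)
round(100 * unlist(cv$metrics[c("ACC", "F1_Macro", "Kappa")]), 2)
#>      ACC F1_Macro    Kappa
#>      100      100      100

cv$pooled
#> ConfusionMatrix (rows = truth, cols = predicted)
#>      predicted
#> truth   W  N1  N2  N3 REM
#>   W   296   0   0   0   0
#>   N1    0 179   0   0   0
#>   N2    0   0 852   0   0
#>   N3    0   0   0 360   0
#>   REM   0   0   0   0 313
```

The synthetic stages carry the textbook cues (alpha-dominant wake,
spindling N2, delta-dominant N3, EOG deflections plus muscle atonia in
REM) and are deliberately clean — a perfect score here says the
implementation learns those cues end to end, not that it matches benchmark
accuracy on real recordings. Real EDF data flow through the same pipeline:

```r
cmdPrepare("cache/", inputDir = "edf/")   # *-PSG.edf + *-Hypnogram.edf pairs
cmdTrain("cache/", "run1/", config = list(variant = "full", seed = 1))
cmdAblate("cache/", "ablation/")          # all six variants, one fold plan
```

A thin shell wrapper for these commands is installed at
`inst/scripts/sleepnet`. See the vignette
(`vignettes/sleepnet-methods.Rmd`) for the model, its assumptions and every
tunable parameter.

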