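# fgcnn — feature-guided convolutional networks for knee-angle estimation from single-channel surface EMG

Wearable robots and assistive devices need an estimate of the user's
*intended* joint movement. Surface electromyography (sEMG) leads the motion
it drives and carries neuromuscular control information, but practical
systems cannot always afford electrodes on every relevant muscle. This
package implements continuous **knee-joint angle estimation from a single
sEMG channel** during level walking, for researchers in biomedical signal
processing, rehabilitation robotics and human–robot interfaces.

## The method

A single channel (one of VL, VM, BF, ST, LG, MG) is band-pass filtered
(Butterworth 10–500 Hz, zero phase) and segmented into overlapping 50 ms
windows advanced by 20 ms. Each window **x** ∈ ℝ²⁵⁰ yields two feature
vectors:

- **p** ∈ ℝ¹⁴ — the handcrafted time-domain bank: IEMG, MAV, mean, RMS,
  VAR, kurtosis, skewness, ZC, SSC, WL and four Yule–Walker AR
  coefficients;
- **l** ∈ ℝ¹⁴ — learned by a 1-D CNN: five stages of
  conv('same') → batch-norm → LeakyReLU (learnable slope) → pairwise max
  pooling, with 2/4/8/16/32 filters of lengths 5/4/3/2/1
  (250 → 125 → 62 → 31 → 15 → 7), then fully connected layers of 192 and
  14 units.

A **fusion layer** ŷ = tanh(**w**ₚ·**p** + **w**ₗ·**l**) is trained against
the measured angle scaled to [−1, 1], minimising
MSE = (1/N) Σᵢ (yᵢ − ŷᵢ)² with bias-corrected Adam (α = 0.001, β₁ = 0.9,
β₂ = 0.999, ε = 10⁻⁸) for 50 epochs; the fusion weights receive the
analytic gradients ∂MSE/∂**w**ₚ = −(2/N) Σᵢ **p**ᵢ(yᵢ − ŷᵢ)(1 − ŷᵢ²)
(likewise for **w**ₗ). Guidance by **p** shapes what the CNN learns; the
final angle estimate in degrees comes from a conventional regressor
(random forest by default; gradient boosting, MLP, SVR and KNN are
available) fit on the fused 28-vector [**p**, **l**]. Accuracy is reported
as NRMSE = RMS error / (y_max − y_min) in percent and CC (Pearson
correlation), under 5-fold trial-level cross-validation, with
Kruskal–Wallis rank tests for method comparisons.

Because no public recordings accompany the protocol, the package includes a
**synthetic gait generator** (phase-locked activation envelopes modulating
band-limited noise, a Fourier knee-angle template, cadence jitter, sensor
noise) that reproduces the statistical structure the method assumes, making
every stage testable end-to-end.

## Worked example

```r
library(fgcnn)

# a synthetic subject: 5 treadmill trials of 10 s (use defaults for 11 x 60 s)
cfg <- defaultGaitConfig(nTrials = 5L, trialDurationS = 10, seed = 42L)
rec <- generateTrial(cfg, 1)
rec
#> EMGRecording: subject SYN1, trial T01
#>   sEMG: 50000 samples x 6 channels @ 5000 Hz (VL, VM, BF, ST, LG, MG)
#>   angle: 1000 samples @ 100 Hz, range [1.1, 59.7] deg, ground-truth phase attached

ds <- windowRecording(rec, "LG")   # filter, window, align angle targets
ds
#> WindowedDataset: 498 windows x 250 samples (LG @ 5000 Hz)
#>   targets: [1.1, 59.7] deg

round(handcraftedFeatures(windowsMatrix(ds))[1, ], 4)
#>     iemg      mav     mean      rms      var kurtosis skewness       zc
#>   4.2051   0.0168   0.0000   0.0208   0.0004   2.4575  -0.2354  29.0000
#>      ssc       wl      ar1      ar2      ar3      ar4
#>  39.0000   1.3444   1.8601  -0.7780  -0.4811   0.3432

# the three-way comparison: handcrafted vs unguided CNN vs feature-guided CNN
res <- runExperiment(list(
  sim = list(nTrials = 5L, trialDurationS = 10, seed = 42L),
  muscle = "LG", featureSets = "all", regressors = "RF",
  fgcnn = list(epochs = 10L), seed = 42L))
aggregate(cbind(cc, nrmse) ~ feature_set, res$results, function(v) round(mean(v), 3))
#>   feature_set    cc nrmse
#> 1         CNN 0.956 8.780
#> 2       FGCNN 0.959 8.574
#> 3          HF 0.949 9.519
res$stats$cc$p    # Kruskal-Wallis comparison of the CC scores
#> [1] 0.0437
```

Mean CC is the correlation between measured and estimated knee angles on
held-out trials (1 is perfect tracking); NRMSE is the error as a percentage
of the angle range. The fused FG-CNN features beat both the handcrafted
bank and the unguided CNN here, and the Kruskal–Wallis p-value (< 0.05)
marks the feature-set effect as significant even on this small benchmark.

A thin command-line wrapper covers the same pipeline
(`simulate`, `run`, `features` subcommands):

```sh
Rscript inst/cli/fgcnn.R simulate --out data/ --trials 11 --seed 0
Rscript inst/cli/fgcnn.R run --config experiment.yaml --seed 0 --out results/
```

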