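# edadecomp

Tonic/phasic decomposition of electrodermal activity (EDA) for in-the-wild
wearable recordings, with a synthetic-ground-truth test bench.

## The problem

Skin conductance (microsiemens, sampled at 8 Hz by research wearables) is
modeled as the sum of two physiologically distinct signals:

* the **tonic** component (skin conductance level, SCL): a slow baseline
  tracking general sympathetic arousal over minutes;
* the **phasic** component: a train of skin conductance responses (SCRs),
  each a steep onset and slow recovery well described by the Bateman
  biexponential `exp(-t/τ_d) − exp(-t/τ_r)`, elicited by discrete stimuli.

Every downstream biomarker — direction of SCL change, SCR frequency, SCR
amplitude — presupposes this decomposition, yet no ground truth exists for
field data. The package is aimed at researchers processing wearable EDA who
need decomposers, a simulator with known ground truth to validate them, and
distribution-level comparison machinery.

## What is inside

* **Preprocessing** — CSV I/O (`time_s,eda_us`), zero-phase 4th-order
  Butterworth low-pass at 3 Hz, non-overlapping 180 s frames (1440
  samples), linear resampling.
* **Simulator** — frames built as `tonic + driver ∗ Bateman + noise`:
  Poisson SCR events (4/min) with log-normal amplitudes (median 0.1 µS),
  a smoothed random-walk baseline with occasional abrupt motion-artifact
  steps, white measurement noise; full ground truth retained, everything
  seeded.
* **Decomposers**
  * Theil–Sen detrending: tonic = robust line (slope = median of pairwise
    slopes), phasic = residual;
  * a transformer decomposer: an unsupervised, non-autoregressive
    encoder–decoder with autocorrelation attention and series-decomposition
    sublayers that reconstructs each frame as
    `pool(frame) + network(frame)` — the SCL branch is a weight-free 1-D
    average pooling (kernel `8·g + 1` samples for SCL granularity `g` ∈
    {60, 30, 1} s) and the deep branch learns the SCR component by
    minimizing reconstruction MSE (Adam, lr 0.001, weight decay 0.1);
  * adapters to cvxEDA/sparsEDA via a Python `neurokit2` installation when
    one is available.
* **Evaluation** — a shared prominence-based peak detector, tonic slope
  binning (falling / stable / rising at ±0.001 µS/s), fixed histogram
  families for peak counts, peak amplitudes and phasic ranges,
  Kullback–Leibler divergence against the uniform histogram, pairwise
  Jensen–Shannon distances, and ground-truth event recall on synthetic
  frames.

See `vignettes/eda-decomposition.Rmd` for the model details and design
rationale.

## Worked example

```r
library(edadecomp)

# 40 synthetic 3-min frames with known ground truth
sfs    <- synthesize_frames(40, sim_config(seed = 42))
frames <- lapply(sfs, `[[`, "frame")

# compare Theil detrending against plain 60 s average pooling
pool60 <- function(fr) {
  tn <- scl_branch(fr, pool_kernel_for(60, fr$rate))
  eda_decomposition(tn, fr$samples - tn, method = "pool60")
}
rep <- compare_methods(frames,
                       list(theil = detrend_decompose, pool60 = pool60),
                       min_amplitude = 0.05)
print(rep)
#> <feature_report>
#>   theil      slope 15%/52%/32% entropy 1.10e-01 | mean peaks 11.8 | mean ampl 0.113
#>   pool60     slope 12%/57%/30% entropy 1.59e-01 | mean peaks 12.1 | mean ampl 0.105
round(rep$js_peak_count["theil", "pool60"], 3)
#> 0.073
```

Reading: both methods see ~12 SCR peaks per frame with mean amplitude
≈ 0.11 µS (the simulator plants 12 events/frame at median 0.1 µS, so both
are close to truth); their slope histograms lean "stable" because the
simulated baseline drifts gently; the Jensen–Shannon distance 0.073 says
their peak-count distributions are nearly identical. A single frame:

```r
dec <- detrend_decompose(frames[[1]])
tonic_slope(dec$tonic)           # 0.0012 uS/s
bin_slope(tonic_slope(dec$tonic))# rising
detect_peaks(dec$phasic, rate = 8, min_amplitude = 0.05)
#> <peak_set> 10 peaks, mean amplitude 0.1060 uS
```

Training the transformer decomposer (minutes on one CPU core):

```r
fit <- ft_train(feel_transformer(model_config(standardize = TRUE), seed = 1),
                sfs, train_config(max_epochs = 10, seed = 1))
dec <- predict(fit$model, frames[[1]])   # tonic + phasic == reconstruction
```

A thin command-line front end with `simulate` / `decompose` / `train` /
`evaluate` subcommands is installed at `inst/cli/edadecomp.R`.

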