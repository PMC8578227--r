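# ecggan

Generative adversarial synthesis and evaluation of 10-second 12-lead
electrocardiograms, in R.

Sharing clinical ECG collections is hard: even "anonymised" waveform data
can identify individuals, so population-scale ECG datasets rarely leave
their home institutions. One answer is to train a generative adversarial
network on a screened cohort of normal ECGs and release *synthetic* records
that carry the population's distribution of intervals and amplitudes but
belong to no real person. `ecggan` implements that whole stack for
researchers who want to study, reproduce or extend the approach on a single
CPU: the network architectures, the adversarial training objective, the
lead algebra, a simulator that stands in for a real normal cohort, a
transparent normality screener standing in for a commercial ECG
interpreter, and the cohort-level evaluation surfaces.

## The model

An ECG record is stored as its 8 independent channels (leads I, II, V1–V6;
5000 samples = 10 s at 500 Hz, amplitudes in µV). The four remaining
clinical leads are fixed linear combinations (Einthoven/Goldberger):

    III = II − I,  aVR = −(I + II)/2,  aVL = I − II/2,  aVF = II − I/2

Two generator architectures are provided:

* **`wavegan_spec()`** — a deconvolution generator: a 100-point latent
  vector drawn from U(−√3, √3) (mean 0, sd 1) is projected to a coarse
  feature map and refined through six blocks of up-sampling → constant
  padding → 1D convolution → ReLU into an 8 × 5000 record.
* **`pulse2pulse_spec()`** — a 1D U-net: an 8 × 5000 noise field passes
  through six down-sampling blocks (strided convolution + Leaky ReLU) and
  six mirrored up-sampling blocks whose inputs are concatenated with the
  matching down-path features (six skip links, doubling each up block's
  input width).

Both feed a shared **critic** (`critic_spec()`): seven 1D convolution
layers with Leaky ReLU and a phase-shuffle layer (random ±2-sample time
shifts with reflection fill) after layers 1–6, flattened into one unbounded
realness score per record.

Training (`train_gan()`) minimises the Wasserstein objective with gradient
penalty,

    L_D = E[D(G(z))] − E[D(x)] + λ E[(‖∇_x̂ D(x̂)‖₂ − 1)²],   x̂ = εx + (1−ε)G(z)
    L_G = −E[D(G(z))]

with λ = 10, Adam (learning rate 1e-4, β₁ = 0.5, β₂ = 0.9), batch size 32,
and exactly five critic updates per generator update. The networks run on a
small reverse-mode differentiation engine built into the package (BLAS-backed
im2col convolutions; pullbacks are themselves differentiable, which is what
lets the gradient penalty be backpropagated to the critic weights), so no
external deep-learning framework is needed.

Around the GAN:

* **`sample_cohort()` / `population_spec()`** — a dynamical PQRST
  simulator: each beat is a sum of Gaussian waves plus a tapered ST
  plateau; per-record parameters are drawn from truncated normals whose
  *truncated* moments are calibrated to a normal-population target (heart
  rate 70 ± 8 bpm on [60, 90], QT 395 ± 21 ms, PR 156 ± 19 ms, QRS
  90 ± 9 ms, P duration 105 ± 12 ms, …) with a QT–RR coupling
  QT ∝ √RR.
* **`extract_features()` / `screen_normality()`** — R-peak detection,
  threshold delineation of P/QRS/T fiducials, the eight standard
  interval/amplitude features (amplitudes read from lead V5), and a
  rule-based Normal / bradycardia / tachycardia / other-abnormal verdict
  with the conventional hard boundaries (HR normal on [60, 100) bpm,
  PR ∈ [120, 220] ms, QRS < 120 ms, QT ∈ [350, 460] ms). This screener is
  a transparent stand-in for commercial interpretation software, not a
  replication of any product.
* **`fraction_normal()` / `summarize_cohort()` / `checkpoint_compare()`** —
  the cohort metrics: fraction of records classified Normal (the
  checkpoint-selection metric), per-feature mean/sd/2.5%/97.5% tables, the
  QT/RR r², and ranked checkpoint comparisons.

## Worked example

```r
library(ecggan)
set.seed(7)
cohort   <- sample_cohort(population_spec(), 100)  # 100 synthetic normals
features <- extract_features(cohort)               # Table-style features
verdicts <- screen_normality(features)
summary  <- summarize_cohort(features, verdicts)
summary
#> <cohort_summary> n = 100 | fraction normal = 1.000 | QT/RR r^2 = 0.808
#> # A tibble: 8 × 7
#>   feature             mean     sd pct_2_5 pct_97_5 n_missing flagged
#>   <chr>              <dbl>  <dbl>   <dbl>    <dbl>     <int> <lgl>
#> 1 heart_rate         70.3    7.97    60.9     88.7         0 FALSE
#> 2 p_duration        107.    10.5     88      128.         12 FALSE
#> 3 qt_interval       397.    22.1    357.     433.          0 FALSE
#> 4 qrs_duration       95.1    8.42    80      110           0 FALSE
#> 5 pr_interval       157.    18.2    124      190.          0 FALSE
#> 6 stj_amplitude_v5   -2.42  28.1    -41.1     50.6         0 FALSE
#> 7 r_amplitude_v5   1320.   407.     674.    2115.          0 FALSE
#> 8 t_amplitude_v5    345.   146.     147.     628.          0 FALSE
```

The cohort of 100 simulated records reproduces the population targets: mean
heart rate 70.3 bpm with the 2.5%/97.5% span [60.9, 88.7], QT 397 ± 22 ms,
and a strong positive QT/RR association (r² = 0.81); every record passes
the normality screen. `tidy(summary)` and `glance(summary)` return the same
numbers as tibbles, `plot_hr_distribution(features)` draws the heart-rate
histogram with the 60/100 bpm bands, and `plot_qt_rr(features)` the QT/RR
scatter.

Training at reduced scale (the full-size networks need GPU-days):

```r
prof <- smoke_profile(seed = 1)           # 512-sample signals, widths / 8
set.seed(1)
data <- cohort_to_array(sample_cohort(population_spec(), 80),
                        length = 512, offset = 1001)
gen  <- build_model(prof$generator_spec)
cri  <- build_model(prof$critic_spec)
st   <- train_gan(gen, cri, data, prof$config)   # 200 generator updates
autoplot(st)                                     # loss curves
```

Command-line wrappers for the simulator and the screener live in
`inst/cli/` (`simulate.R`, `evaluate.R`).

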