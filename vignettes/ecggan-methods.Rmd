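---
title: "Models and methods behind ecggan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ecggan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ecggan` synthesises and evaluates 10-second 12-lead electrocardiograms
with 1D generative adversarial networks. This vignette is the package's
account of its modelling choices: the signal representation, the network
architectures and the training objective, the simulator that stands in for
a real normal-population cohort, the feature extractor and screener, and
the numerical decisions behind all of them. It states no empirical claim
that the test suite and `scripts/acceptance.R` do not themselves compute.

## Signal representation and lead algebra

A 12-lead ECG carries only 8 independent channels: leads III, aVR, aVL and
aVF are fixed linear combinations of I and II. The package therefore
stores records as 8 × 5000 matrices (leads I, II, V1–V6; 10 s at 500 Hz)
in microvolts, and derives the 12-lead view on demand:

$$\mathrm{III} = \mathrm{II} - \mathrm{I},\quad
  \mathrm{aVR} = -\tfrac{1}{2}(\mathrm{I} + \mathrm{II}),\quad
  \mathrm{aVL} = \mathrm{I} - \tfrac{1}{2}\mathrm{II},\quad
  \mathrm{aVF} = \mathrm{II} - \tfrac{1}{2}\mathrm{I}.$$

These are the universally used Einthoven/Goldberger closed forms; the
12 × 8 derivation matrix has rank 8, and `derive_12_from_8()` /
`reduce_8_from_12()` round trip bitwise on integer-microvolt input. The
amplitude unit (µV), the 500 Hz rate and the storage order (I, II, V1–V6)
are fixed conventions of the package; a record whose derived leads violate
their identities is reduced with a warning naming the worst lead and its
maximum residual.

## Architectures

Three networks are specified declaratively (`wavegan_spec()`,
`pulse2pulse_spec()`, `critic_spec()`) and instantiated by
`build_model()`.

**Deconvolution generator.** A 100-point latent vector is projected
linearly to a 512-channel × 5-sample map and refined by six deconvolution
blocks — nearest-neighbour up-sampling, constant (zero) padding, a 1D
convolution (kernel 25), ReLU — with up-sampling factors (5, 5, 5, 2, 2, 2)
reaching 5000 samples. Channel widths halve toward the 8-channel output
(512 → 256 → … → 8); the final block is linear (no output activation).
Because 5000 = 5³·2³·5, a six-stage integer up-sampling schedule is forced
up to permutation; the chosen order refines coarse structure first. The
latent law "uniform with mean 0, sd 1" is taken literally as
U(−√3, √3); a Gaussian N(0, 1) alternative is a spec switch.

**U-net generator.** An 8 × 5000 noise field passes through six
down-sampling blocks (1D convolution with strides (2, 2, 2, 5, 5, 5) +
Leaky ReLU, slope 0.2) and six mirrored up-sampling blocks built like the
deconvolution blocks. Each up block consumes the concatenation of its
upstream features with the mirror-level down-block features; the sixth
skip is the noise input itself, so there are exactly six skip links and
every up block's input width is double the skip-free width. Down-path
widths grow 64 → 128 → 256 → 512 (capped); the final up block emits 8
channels, linear. The down path uses Leaky ReLU to match the critic's
down-sampling behaviour; the up path uses ReLU.

**Critic.** Seven 1D convolution layers (kernel 25, strides
(5, 5, 5, 2, 2, 2, 1), widths 64 → … → 512), each followed by Leaky ReLU
(slope 0.2) and — after layers 1–6 — a phase-shuffle layer, then a single
linear score over the flattened features. Phase shuffle shifts every
channel of every record by an integer drawn uniformly from ±n (default
n = 2), filling edges by reflection; it prevents the critic from keying on
the absolute phase of periodic waveforms. We do not shuffle after the last
convolution, since its output feeds the score head directly.

Training data are divided by a fixed amplitude constant (6000 µV, bringing
normal ECGs into roughly the unit interval) and generated signals are
multiplied back. Kernel size, Leaky slope and shuffle width follow the
conventions of 1D audio GANs that this family of architectures descends
from. Weights use fan-in-scaled Gaussian initialisation from the seeded
RNG stream.

## Training objective and loop

The critic is trained under the Wasserstein objective with gradient
penalty:

$$L_D = \mathbb{E}[D(G(z))] - \mathbb{E}[D(x)]
      + \lambda\,\mathbb{E}_{\hat x}\big(\lVert\nabla_{\hat x} D(\hat x)\rVert_2 - 1\big)^2,
  \qquad \hat x = \varepsilon x + (1 - \varepsilon) G(z),$$

with $\varepsilon \sim U(0,1)$ drawn per record (not per element) and
$\lambda = 10$, the standard penalty weight. "Gradient clipping" belongs
to the original weight-clipped Wasserstein GAN and is deliberately *not*
used; the penalty formulation is strictly what the loop implements. The
generator minimises $-\mathbb{E}[D(G(z))]$. Both networks use Adam with
learning rate 1e-4, β₁ = 0.5, β₂ = 0.9, batch size 32, and the loop
performs exactly five critic updates per generator update; the trailing
batches of an epoch that cannot fill a complete 5 + 1 cycle are dropped so
the ratio stays exact. Checkpoints (`ckpt_epoch{N}/`) store both parameter
sets, both Adam states and the RNG state, so a resumed run reproduces the
uninterrupted one bitwise.

### The differentiation engine

No deep-learning framework is assumed: the package carries a small
reverse-mode automatic-differentiation engine (`R/autodiff.R`) on dense
arrays. Convolutions are im2col gathers followed by BLAS matrix products;
their adjoints (col2im) are implemented as the exact adjoint linear maps,
and every pullback is written in terms of the engine's own primitives, so
requesting a differentiable gradient graph (`higher = TRUE`) makes
second-order terms — the derivative of the gradient-penalty norm with
respect to the critic weights — exact rather than approximated. The test
suite checks first- and second-order gradients against central finite
differences and the penalty against closed forms (a unit-norm linear
critic gives exactly 0; a zero critic gives exactly λ).

### Reduced-scale profile

Full-scale training is a GPU-scale undertaking (the reference setting
trains for thousands of epochs over days). For CPU-scale, end-to-end
verification the package fixes one reduced profile (`smoke_profile()`):
512-sample signals, channel widths one eighth of full scale, batch size 8,
80 simulator records, 200 generator updates (= 1000 critic updates). All
optimisation hyperparameters are the full-scale ones. At this scale the
adversarial game shows the textbook early phase: the critic's Wasserstein
estimate rises from near zero and reaches a plateau once the
penalty-constrained critic saturates, while the generator — moving at
learning rate 1e-4 under a 5:1 update handicap — closes the gap only over
horizons far beyond 200 updates. A *declining* estimate, the signature of
generator catch-up, should therefore not be expected from the reduced
profile; the suite's convergence-trend check documents this honestly
rather than masking it.

## The synthetic normal cohort

The simulator exists so that every other module is testable without any
real recordings; it emulates a screened normal adult population at the
level of per-record interval/amplitude statistics.

**Beat morphology.** Each beat is a sum of Gaussian waves placed on the
time axis relative to the R peak, plus a tapered ST plateau:
QRS onset/offset sit at ∓ QRS/2; the R wave has sd QRS/5; small Q and S
deflections (−0.10 and −0.20 of the R amplitude, sd QRS/18) sit at
∓0.35 QRS; the P wave has sd = P-duration/5 centred so the PR interval is
honoured; the T wave has a fixed 32 ms sd with its offset (2.5 sd past the
centre) at QRS-onset + QT; the STJ offset enters as a plateau equal to the
STJ amplitude on [J, J + 60 ms] with 20 ms half-cosine tapers. A Gaussian
wave's nominal duration is its ±2.5 sd span — the convention that makes
onsets and offsets well-defined, and that the delineator mirrors. The
single-channel template is projected onto the 8 leads by fixed scale
factors with the largest R in V5 (the amplitude-reporting lead) and an
inverted V1.

**Population law.** Each parameter follows a truncated normal. The target
table gives *cohort* statistics — mean, sd and the 2.5%/97.5% percentiles
of the screened population (heart rate 70 ± 8 bpm on [60, 90], P duration
105 ± 12 ms on [82, 130], QT 395 ± 21 ms on [352, 436], QRS 90 ± 9 ms on
[74, 110], PR 156 ± 19 ms on [120, 198], STJ 2 ± 27 µV on [−44, 58], R
amplitude 1287 ± 402 µV, T amplitude 343 ± 137 µV) — so the *underlying*
normal of each parameter is solved numerically so that its truncation to
the printed percentile bounds reproduces the printed mean and sd. For
heart rate the target sd (8) is close to the maximum any distribution on
[60, 90] can have, so the calibrated law is nearly flat with more mass at
low rates — exactly the shape screening at a hard 60 bpm boundary
produces. P amplitude (not tabulated) defaults to 100 ± 25 µV on
[50, 150], a typical adult limb-lead P height.

QT is not drawn independently: QT = a·(RR/1000)^b + ε with b = 0.5 (a
Bazett-like exponent — a modelling choice, not a population value),
ε ~ N(0, 10 ms) rejected into the QT bounds, and a fixed so the mean-RR
record hits the target mean QT. This induces the strong positive QT–RR
association normal cohorts show. Joint draws violating the P-inside-PR
constraint (about 3% of records) re-draw the P duration with a 10 ms
margin, shifting its marginal mean by well under a millisecond.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: beat-to-beat variability (all beats in a record
are identical), respiratory baseline wander and noise (optional white
noise only, default off), inter-lead morphology differences beyond a scale
factor, pathological rhythms, and any covariance between parameters other
than QT–RR. Results on simulator cohorts bound the pipeline's behaviour on
clean, regular sinus rhythm; they say nothing about its robustness to
artefact-laden recordings.

## Feature extraction and screening

R peaks are picked on lead II after subtracting a 62 ms moving average
(which attenuates the broad P/T waves far more than the narrow QRS), with
polarity auto-detection, a 60%-of-maximum threshold and a 200 ms
refractory window. Per beat, fiducials come from threshold crossings at
4.39% of the local wave peak — the ±2.5 sd point of a Gaussian wave, so on
noise-free simulator output the crossings recover the generating
parameters up to sampling quantisation. Two non-obvious choices: the QRS
offset requires a sustained (24 ms) sub-threshold run at a lowered (60%)
threshold, because the brief dip between the S wave and the J point would
otherwise merge with the ST segment; and the ST level is estimated from
the 24–54 ms post-J window (where the simulator's plateau is flat) and
subtracted before offset detection, so an elevated or depressed STJ does
not bias the QRS offset. Heart rate is 60000 / mean(RR in ms); all other
features are medians across beats, which makes them insensitive to
dropped partial beats at the record edges. Amplitudes (R, T, STJ) are read
from lead V5. On a 200-record noise-free cohort the suite requires ≥90% of
records within ±0.5 bpm (HR), ±15 ms (QT, PR) and ±10 ms (QRS) of ground
truth; the observed rates are at or near 100%, with a small (+5 ms) QRS
bias from the threshold convention.

The screener applies hard boundaries exactly as printed in clinical
convention: normal heart rate on [60, 100) bpm with bradycardia strictly
below 60 and tachycardia at or above 100; PR within [120, 220] ms; QRS
strictly below 120 ms; QT within [350, 460] ms (the QT band is a package
default — flagged as such — since no reference value was available).
Missing features fail their rules explicitly, a heart-rate failure decides
the label, and a record is Normal exactly when no rule fails. The rule set
is deliberately transparent and YAML-configurable: it is a functional
stand-in for commercial interpretation software, not a replication of any
product, and its rule identifiers cannot be mapped onto any vendor's
statement taxonomy.

## Evaluation

`fraction_normal()` is the checkpoint-selection metric: the proportion of
generated records the screener labels Normal. `summarize_cohort()`
tabulates each feature's mean, sd (n − 1 denominator) and 2.5%/97.5%
percentiles (linear interpolation between order statistics — the method is
fixed because the reference tables do not state theirs), plus the squared
Pearson correlation of per-record QT and RR (one point per record).
`checkpoint_compare()` generates a fixed-size batch per checkpoint
(default 100 at desk scale; full-scale work would use 10⁴), screens it and
ranks checkpoints by fraction normal, marking the argmax best; unloadable
checkpoints become failed rows rather than errors. Two controls bound the
metric: replaying real (simulator) records through the screener must score
at least 0.95, and an untrained random-weight generator at most 0.2 — in
practice it scores ~0 because random conv outputs have no detectable
rhythm or absurd features.

## Numerical choices and degenerate inputs

Sampling is 0-based in time (sample k at k/500 s); thresholds and windows
are rounded to samples at 2 ms resolution, so a ±1-sample quantisation
(±2 ms on intervals, ±0.1 bpm on HR from a 10 s record) is the noise floor
of all interval estimates. The gradient-penalty norm adds 1e-12 under the
square root to keep the derivative finite at zero gradient. Truncated
normals are drawn by inverse-CDF, exact for sd = 0 (degenerate cohorts are
supported and produce identical records). Empty cohorts, flat signals,
fewer than two beats, infeasible truncations (low ≥ high) and latent-shape
mismatches raise explicit errors; in multi-record extraction a failed
record yields an all-NA row so cohort screening can count it as
non-normal instead of aborting. Problem sizes used by the suite and the
acceptance script — 200-record recovery cohorts, 100-record evaluation
batches, 10⁴ parameter-only draws for percentile checks, and the
reduced-scale training profile above — are the package's fixed desk-scale
conditions.

## Known limitations

The per-layer widths and kernels of the reference architectures are not
public in full detail; the schedules here are a documented reconstruction
constrained by the stated block counts and the 5000-sample factorisation.
Desk-scale training runs demonstrate the loop's mechanics, determinism and
bookkeeping, not generation quality — producing screener-passing synthetic
ECGs requires the full-scale, long-horizon training this package
deliberately leaves out of its test conditions. The screener is far
simpler than commercial interpreters (no axis, ST/T-morphology or rhythm
statements beyond rate), so its fraction-normal values are not comparable
in absolute terms to numbers produced by such systems.
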