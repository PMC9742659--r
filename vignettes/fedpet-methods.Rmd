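---
title: "Federated attenuation/scatter correction of PET images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated attenuation/scatter correction of PET images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative PET requires correcting the raw emission image for photon
attenuation (events lost to absorption along the line of response) and
Compton scatter (spurious low-frequency counts); scattered events account for
roughly 30-35% of detections in 3D brain imaging and can exceed 50-60% in
whole-body imaging. On PET/CT systems the CT scan supplies the 511 keV
attenuation map, but CT-less systems (PET/MRI, standalone PET) must estimate
the correction another way. A convolutional network can learn the mapping
from non-attenuation/scatter-corrected (NAC) images directly to
attenuation/scatter-corrected (ASC) images, but a generalizable model needs
multi-centre training data, and patient-level data usually cannot leave the
hospital. Federated learning (FL) trains a shared model while only model
parameters cross institutional boundaries.

`fedpet` implements this entire experimental apparatus at desk scale: a
multi-centre phantom simulator, the preprocessing and normalization pipeline,
a nested residual U-block regression network, four training strategies, and
the evaluation and statistical-comparison protocol. Everything runs on a
single CPU in minutes, so the behaviour of the four strategies can be studied
end to end.

## Four training strategies

With $K$ centres, centre $k$ holding $N_k$ paired slices and local objective
$F_k(\theta) = \frac{1}{N_k}\sum_i \mathcal{L}(\theta; (X_i, Y_i))$, the
global objective is the sample-weighted mixture
$F(\theta) = \sum_k \frac{N_k}{N} F_k(\theta)$, $N = \sum_k N_k$.

* **CB (centre-based)** — each centre minimises only its own $F_k$.
* **CZ (centralized)** — all data pooled; plain mini-batch training on $F$.
* **FL-PL (parallel federated)** — per round, the server broadcasts
  $\theta_t$, every centre trains locally, and the server aggregates. Two
  aggregation modes are implemented: `parameter_average` (FedAvg,
  $\theta_{t+1} = \sum_k \frac{N_k}{N}\theta_k$) and `gradient`
  ($\theta_{t+1} = \theta_t - \eta \sum_k \frac{N_k}{N}\nabla F_k(\theta_t)$,
  restricted to one full-batch local step so that the identity is exact;
  the two coincide when each centre takes a single full-batch SGD step).
* **FL-SQ (sequential federated)** — the parameters travel
  centre-after-centre, each training for a fixed number of local epochs, for
  a fixed number of rounds; there is no aggregation step.

All strategies share one optimizer recipe: Adam, learning rate 0.001, weight
decay 0.0001 implemented as an L2 penalty added to the loss gradient, and an
L2 (sum of squared error) image loss. In FL-PL, optimizer moments are
centre-local state and are never exchanged or aggregated — only parameter
vectors (or exact gradients) cross the "network". In FL-SQ the moments
travel with the parameters by default (`sq_carry_optimizer`), making the
chain one continuous optimisation run through changing data; the
alternative — centre-local moments that sit idle while the parameters visit
every other silo — leaves each centre applying stale second-moment estimates
to a model that has moved on, which measurably destabilises short schedules.
Centres are simulated as in-process workers.

Two schedule choices were genuinely open and are worth recording:

* **Local epochs per FL-PL round.** One averaged local excursion per round
  advances the global model much more slowly than the sequential schedule,
  which accumulates every centre's epoch within a round. At a fixed budget of
  20 rounds the package therefore defaults FL-PL to 2 local epochs per round
  (`strategy_overrides` in `experiment_config()`), which brings its
  optimisation depth close to CZ and FL-SQ without dominating the total
  compute; larger values continue to help and can be configured.
* **Model selection.** No early stopping inside the FL loop; the round with
  the lowest pooled validation loss supplies the evaluated parameters.

## The network

The model is a two-level nested U-structure: an outer U-Net whose
convolutional stages are themselves small symmetric encoder-decoders —
ReSidual U-blocks (RSU) — giving intra-stage multi-scale features without
sacrificing full-resolution detail. Each RSU computes `U(x) + skip(x)` where
`skip` is the identity (equal channel counts) or a 1x1 projection; `depth`
controls the number of internal resolution levels, and the coarsest stages
use dilated variants that widen the receptive field without further
downsampling. Deep supervision attaches a linear 3x3 side head to every
decoder stage and to the bottom encoder stage; a 1x1 fusion convolution
combines the side outputs. The training loss is the equally weighted sum of
the mean-squared errors of the fused output and every side output, so
gradients reach all scales directly.

Choices the architecture description leaves open, resolved here:

* **Stage counts and widths.** The `"full"` preset mirrors the published
  U2-Net topology (6 stages, RSU depths 7-6-5-4, two dilated bottom stages).
  The `"desk"` preset — 4 encoder stages over 3 resolution levels, base
  width 8, mid width 4, depths 2-2-1-2 — is the package's own CPU-scale
  choice: it trains in milliseconds per slice while keeping every
  architectural ingredient (nesting, dilation, deep supervision, skip
  projections) exercised. It is deliberately not claimed to match any
  clinical configuration.
* **Regression head.** Hidden convolutions use ReLU; side and fusion heads
  are linear, because the target is a continuous 0-5 intensity range, not a
  0-1 saliency map. Outputs are clipped to be non-negative only at inference
  export.
* **No batch normalisation.** BN running statistics are awkward in FL (they
  are data statistics, not parameters, and averaging them across non-IID
  silos is its own research topic); plain conv+ReLU keeps the exchanged
  state exactly equal to the parameter vector.
* **Resampling.** 2x2 max pooling down, bilinear interpolation up (and
  bilinear side-output upsampling); bilinear avoids checkerboard artifacts
  in image regression. Inputs are zero-padded to the required divisibility
  and cropped back.
* **Initialisation.** He-normal hidden weights and zero biases. The linear
  side heads start near zero and the fusion conv starts as the exact mean of
  the side outputs, so the network begins from a consistent "predict ~0"
  state rather than a random mixture of untrained heads. On short schedules
  this matters a great deal: with conventionally scaled random heads the
  first rounds are spent unlearning the head mixture, and how long that
  takes varies strongly with the seed. All initialisation is deterministic
  given the seed.

The backward pass is hand-derived and verified against central differences
to ~1e-7 relative error in the test suite (`test-nn.R`), so the training
engine does not depend on any external autodiff framework.

## The phantom simulator

The study design needs paired NAC/ASC data from silos with deliberately
different scanners. Anatomy is a randomized 2D ellipse phantom (one
transaxial slice per "patient", matching 2D training): a body ellipse with
soft-tissue attenuation (0.0096/mm at 511 keV), 2-4 elliptical organs that
override uptake (0.3-4 SUV-like) and attenuation (0.002-0.013/mm, lung to
bone), and 0-3 circular hot lesions (radius 4-12 mm, uptake 3-8). Overlaps
resolve by draw order (later wins). Bodies span 90-160 mm so that every
centre's field of view contains them.

The physics is a deliberate desk-scale surrogate — not sinogram-domain
simulation, which is out of scope:

* **Attenuation** enters as a per-pixel *angular-mean survival factor*:
  the mean over 32 directions of $\exp(-\int \mu\, dl)$ along the full chord
  through the pixel, with line integrals ray-marched at half-pixel steps.
  This preserves the two properties that matter for the learning problem —
  attenuation removes signal multiplicatively, and deeper/denser geometry
  attenuates more — and is validated against the closed-form uniform-disc
  factor $\exp(-2\mu r)$ to <1% in the tests.
* **Scatter** is a broad Gaussian convolution of the primary (attenuated)
  signal — scatter is low-frequency — with kernel FWHM fixed at 0.4 x body
  diameter (the exact width is not identifiability-critical) and rescaled so
  that `sum(scatter) / (sum(scatter) + sum(primary))` equals the profile's
  scatter fraction *exactly*; the rescaling identity is asserted to 1e-9.
* **Resolution and noise.** The reference ASC image is the activity map
  blurred by the scanner PSF (Gaussian, per-centre FWHM 4.5-7 mm). Noise is
  mean-zero pseudo-Gaussian with variance proportional to local intensity
  (a pseudo-Poisson surrogate, appropriate for continuous activity units),
  scaled per centre; negative pixels are clamped at zero and counted.
* **Heterogeneity.** The six default centres differ in PSF, noise scale,
  scatter fraction (0.30-0.55, the whole-body range), matrix size and pixel
  size — non-IID by construction. Phantom anatomy derives only from the
  centre id and master seed, so two profiles differing in scanner parameters
  can be compared on identical anatomy.

Because each study is generated directly on its centre's native grid, no
internal resampling disturbs the exact scatter-fraction calibration; grid
harmonisation is the preprocessing module's job, as in a real pipeline.

What the simulator does *not* emulate: sinogram/reconstruction artifacts,
correlated (structured) noise, randoms, out-of-plane scatter, organ motion,
truncation, metal artifacts, and real anatomical variability. Passing tests
on these phantoms therefore demonstrate that the *framework* behaves
correctly (physics identities, aggregation algebra, strategy orderings), not
that the trained desk model would transfer to clinical images.

## Preprocessing

Studies are converted to SUV
(`image x body_weight x decay_factor / injected_activity`; the simulator
calibrates its activity units so this recovers SUV-like values, and the
decay factor defaults to 1 because synthetic data need none), resampled to a
common grid by bilinear interpolation (zero outside the source extent), and
normalized by the fixed empirical divisors 3 (NAC) and 9 (ASC). The stated
0-5 intensity range is enforced as a hard clip after division — the
clipped-voxel count is attached to the result so the decision is auditable —
and `denormalize()` inverts the map exactly for unclipped voxels. The common
grid default is 3 mm in-plane (the 2D analogue of the 3 x 3 x 4 mm
convention; slice thickness travels in the metadata), 64 x 64 pixels.

## Evaluation and statistics

Per study, against the reference ASC image over a body mask
(`reference > 0.01` normalized units — the relative-error metrics divide by
the reference, so a mask is required for them to be finite; the same mask is
applied to all error metrics for consistency, and the threshold is a
reported, configurable parameter):

* ME, MAE (SUV units), RE%, ARE% (voxel-wise relative errors x100),
* PSNR with `Peak` = per-study masked reference maximum (a fixed Peak is
  available by configuration, since "Peak" is conventionally ambiguous),
* SSIM with the standard 11x11 Gaussian window (sigma 1.5), stabilizers
  `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, and dynamic range `L = 5` for
  normalized images; computed on the normalized pair.

Pooled voxel-wise agreement is summarised by a joint 2D histogram (128x128
bins over [0,5]^2) and the coefficient of determination of the ordinary
least-squares fit of predicted on reference values (one of several possible
"R^2" conventions; this one is documented precisely because conventions
differ).

Strategies are compared pairwise per metric with the two-sided two-sample
Wilcoxon rank-sum (Mann-Whitney) test — exact for small tie-free samples,
midranks/normal approximation under ties — with Benjamini-Hochberg
adjustment across the family of comparisons within each grouping (overall,
or per centre) and significance declared at q < 0.05. Summary tables report
mean, SD and normal-theory 95% confidence intervals.

## The four-way comparison experiment

`run_experiment()` ties everything together: simulate the configured
centres, preprocess, split each centre 60/20/20 (a 50-study centre gives the
canonical 30/10/10; the desk default of 16 studies gives 10/3/3), train the
requested strategies from a shared initialisation, and evaluate on the
shared pooled test studies. CB models are evaluated both on their own
centre's test studies (the standard CB protocol) and — clearly labelled
`CB_cross` — on every centre's test studies, to quantify the
generalizability loss that motivates federation. The qualitative signature
to look for, and the one the acceptance suite asserts across master seeds,
is `CZ <= FL-PL, FL-SQ < CB_cross` in mean test ARE%.

### Problem sizes used by the tests

The test and acceptance runs use: 6 centres x 16 studies (10/3/3) on 64x64
grids, the desk network (~13k parameters), 20 rounds, batch size 2, and
three master seeds for the ordering check; the identity-task trainability
check uses 64 slices at 32x32. These sizes were chosen so a complete
four-way comparison runs in a few minutes on one CPU while keeping every
centre's test set large enough for rank-based statistics.

## Known limitations

* The desk model and phantom data are a study of the *training strategies*,
  not a clinically meaningful AC/SC model; absolute error levels are much
  higher than a converged full-scale model would reach.
* ARE% is dominated by low-uptake voxels just above the mask threshold;
  comparisons are therefore made strategy-to-strategy under the identical
  mask, never against external absolute values.
* FL rounds are synchronous and failure-free; no privacy mechanisms
  (secure aggregation, differential privacy) or robustness to adversarial
  updates are modelled.
* 3D volumes are supported only as stacks of independent slices, matching
  the 2D training regime.
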