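---
title: "Classification by per-class edge-conditioned GAN reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification by per-class edge-conditioned GAN reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ganrecon)
```

## The model

`ganrecon` classifies histology tiles with one generative model per class
rather than one discriminative model over all classes. For each tissue
class c, a conditional GAN is trained on tiles of that class only. The
condition y is the **channel-wise Canny edge map** of the tile: a 3-channel
binary mask whose channel i contains the edges of color channel i. The
generator G_c learns to reconstruct the full-color tile from its edges; the
discriminator D_c judges (condition, image) pairs. Training minimises, for
the discriminator,

$$\ell_D = -\log D(x \mid y) - \log\bigl(1 - D(G(y) \mid y)\bigr)$$

and for the generator the weighted sum

$$\ell_G = \lambda_{adv}\,\bigl(-\log D(G(y)\mid y)\bigr) + \lambda_{mse}\,\mathrm{MSE}\bigl(G(y), x\bigr).$$

We use the non-saturating adversarial term $-\log D(G(y))$ rather than the
saturating $\log(1-D(G(y)))$ of the minimax formulation: the two share
fixed points, but the non-saturating form keeps gradients alive when the
discriminator is winning early in training. The saturating form remains
available via `training_config(saturating = TRUE)`.

At inference a tile is passed through **every** class generator, each using
the edge parameters it was trained with, and the winner rule applies:

$$\hat c(x) = \arg\min_c d\bigl(x, G_c(y)\bigr)$$

with dissimilarity d = MSE on the 0–255 scale by default. SSIM and PSNR are
available as alternatives; both are converted to dissimilarities (1−SSIM
and 200−PSNR dB) so the arg-min semantics hold for every metric. Since any
strictly increasing transform of the per-class errors leaves the arg-min
unchanged, metric choice mostly matters when reconstructions are close.

Key assumptions: (1) class identity is expressed in *structure* that
survives edge detection — nuclear density, gland shapes, fiber geometry —
so that a generator can only reconstruct well what it was trained on;
(2) reconstruction error under the right generator is smaller than under a
wrong-class generator, which holds when classes differ in edge statistics
and/or palette; (3) tiles presented for classification are predominantly
single-class (mixed-content windows are classified anyway, and filtering is
left to the evaluator).

## Why edges, and the edge parameters

The 3-channel binary condition removes all color and intensity variation
from the generator's input, which makes the classifier robust to staining
variability: the model must repaint its class's colors from structure
alone. `sigma` (Gaussian smoothing SD, px) controls how much detail
survives: the shipped presets are `sigma_2` and `sigma_5`. Below ~2 the
detector picks up noise; above ~5 too few edges survive for a faithful
reconstruction. The hysteresis thresholds (`low_fraction = 0.02`,
`high_fraction = 0.04` of the 8-bit intensity range, applied to
Sobel-gain-normalised gradient magnitudes) are a package decision — only
sigma is a study condition — chosen so that fine fiber edges survive at
sigma = 2, pure sensor-style noise (SD ≈ 6) never seeds an edge, and edge
counts decrease monotonically in sigma. All edge parameters are stored in
each trained model and reused verbatim at classification time, so a saved
model always sees the conditioning it was trained with.

The detector itself (separable Gaussian smoothing with reflective borders,
Sobel gradients, interpolated non-maximum suppression, two-threshold
8-connected hysteresis) is implemented in the package; interpolated NMS
matters here because heavily smoothed contours otherwise yield thick
ridges that break the monotone-in-sigma property.

## Architecture and training defaults

The generator is a U-Net: `depth` stride-2 4×4 encoder convolutions
(widths `min(base·2^(i-1), 8·base)`), a 3×3 bottleneck, and a decoder that
doubles resolution by nearest-neighbour upsampling + 3×3 convolution, with
skip connections concatenating the mirrored encoder stage and, at full
resolution, the input condition itself. The output is tanh-bounded; images
live on [−1, 1] inside the model and are mapped back to 0–255 for I/O. The
discriminator is a plain stride-2 convolutional stack with a global average
pool and a two-way softmax head, matching the "standard convolutional
network with softmax" reading; per-sample output is a probability pair.

The GAN noise term z is realised as dropout (rate 0.5) in the innermost
decoder stages during training (`noise_mode = "dropout"`); at inference
dropout is disabled so reconstruction — and therefore classification — is
deterministic. An explicit noise input channel (`noise_mode = "input"`,
zeros at inference) is available for fidelity experiments.

Defaults follow the pix2pix convention where the study is silent:
`lambda_mse = 100`, `lambda_adv = 1`, Adam with `learning_rate = 2e-4` and
`beta1 = 0.5`. Weights are initialised N(0, 0.02²). Training alternates one
discriminator and one generator update per mini-batch over shuffled
single-class batches; given a seed, the run is bit-reproducible, and the
fingerprint (md5 over the serialised weights) certifies it.

Each network's update is clipped to a global gradient norm of 5
(`clip_norm`). These small models carry no normalisation layers, so once
the discriminator becomes confident its input gradients can spike and
push the generator's tanh output into permanent saturation (a constant
image); a norm cap is the standard, architecture-neutral stabiliser and
leaves well-behaved runs untouched.

## The synthetic data generator

The generator emulates the two tissue populations at small-tile scale:

* **tumorlike** — hematoxylin-dark elliptical nuclei at 1.6 per 1000 px²
  (≈ 6–7 per 64² tile), semi-axes 3–6 px, 40% drawn as rings to mimic gland
  cross-sections, on a pale pink background;
* **stromalike** — wavy eosin-hued fiber strokes (two per 64×64 px of
  area, half-width ≈ 2 px, length ≈ 100 px, sinusoidal waviness) with rare
  small nuclei, on a near-white background. Stroke counts scale with
  raster area, so a large high-power field carries the same local fiber
  statistics as a training tile.

Both classes carry additive Gaussian intensity noise (SD 6) and are drawn
with anti-aliased primitives. Two design constraints were imposed a priori:
the classes' mean edge-pixel densities at sigma = 2 differ by well over a
factor of 1.5 (stromalike is the edge-denser class: two fiber flanks per
stroke outweigh nucleus perimeters), so the condition demonstrably carries
class signal; and the foreground coverage of the two classes is
approximately matched (~8–10%), so that when palettes are deliberately
equalised (`default_texture_specs(palette_drained = TRUE)`) a trivial
pixel-mean classifier drops to near chance while edge statistics still
separate the classes. That second property is what certifies that the test
fixture exercises structure-based, not color-based, classification.

What the fixture does **not** emulate: real chromatin texture, stain
variation between slides, scanner artifacts, focus blur, or mixed-tissue
transitions. Passing tests therefore demonstrate the machinery —
conditioning, training, the winner rule, modularity — not clinical-grade
accuracy on real slides.

Every generation call derives one sub-seed per tile from the spec's seed,
so generation is a pure function of (spec, n, tile_size) and tile i does
not depend on how many tiles were requested.

## Scaled-down study conditions

The tests and the acceptance script exercise the full pipeline at desk
scale: 64×64 tiles, 200 training and 60 held-out tiles per class, U-Net
depth 3 with 16 base filters (~0.3 M parameters), 5 epochs at batch size 1
with learning rate 2e-3, sigma = 2 conditioning, and 10 homogeneous 160×160
synthetic HPFs classified by majority vote over 50 windows of 64 px. Batch
size 1 and the raised learning rate compensate for the small step budget
(1000 optimiser steps) relative to full-scale GAN training; with the
MSE-dominated objective this is stable and reaches tile-level F1 ≈ 96% on
the synthetic classes. Smaller "tiny" models (32 px, depth 2, 8 filters)
back the contract tests where classification quality is irrelevant.

## Numerical choices and degenerate inputs

* Probabilities entering logs are clipped at 1e-12; loss terms are finite
  by construction and `g_total` equals its weighted decomposition to
  machine precision.
* MSE for classification is computed on the 0–255 scale so errors are
  comparable across configurations; the training-time `g_mse` lives on the
  model's [−1, 1] scale.
* Exact per-class error ties break to the lexicographically smaller label
  (C-locale ordering everywhere), flagged via `tie_broken`. HPF vote ties
  break by the smaller summed dissimilarity over the winning windows, then
  lexicographically.
* A constant tile has zero gradient everywhere and yields an empty edge
  condition; the generator then reconstructs its learned class prior.
* `precision`/`sensitivity` guard zero denominators by returning 0 with a
  `degenerate` attribute; the fold-level SD is the sample SD (n−1).
* Stereology squares are half-open `[r, r+T) × [c, c+T)` anchored at the
  top-left grid point, 0-based; "strictly inside" is read literally as
  100% containment (`containment = 1`), with a fraction knob for relaxed
  sampling. Grid spacing defaults to the tile size (non-overlapping).
* HPF windows are sampled uniformly **with replacement** over valid
  corners, seeded; on a homogeneous field the vote is invariant to the
  number of windows.

## Open design points, resolved

* **Discriminator granularity** — a single global two-way head (not
  patch-wise), the literal reading of a softmax classification layer.
* **Positive class for metrics** — any label starting with "tumor", else
  the lexicographically first label, reported one-vs-rest.
* **Mixed-content HPF windows** — classified like any window; no filtering.
* **Imbalance protocol** — `resample_imbalance` draws
  `floor(ratio · majority_count)` minority tiles without replacement,
  seeded; because training never sees other classes, the resampled model
  equals the directly trained model on the surviving tiles, fingerprint
  for fingerprint.

## Limitations

Reconstruction-error classification produces no calibrated confidence; the
arg-min is a hard call. Mixed tiles at class borders are assigned to a
single class by whichever generator wins. Training at full slide scale
(256×256 tiles, tens of thousands of tiles) is supported by the code paths
but far slower in base R than in a GPU framework; the package is sized for
method development, teaching, and the synthetic validation shipped with it.
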