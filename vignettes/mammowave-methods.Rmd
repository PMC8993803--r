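---
title: "Methods: wavelet-activated convolutional networks for mammogram classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-activated convolutional networks for mammogram classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammowave)
```

# Scope

`mammowave` implements a complete desk-scale pipeline for multiclass
abnormality classification in digital mammograms: contrast enhancement
(CLAHE), content-aware reduction (seam carving), orthonormal 2D Haar wavelet
decomposition feeding the low-pass band to a classifier, a convolutional
network whose activations are a cosine-Gaussian wavelet rather than ReLU, a
DCGAN-style synthesizer for under-represented abnormality classes, and a
confusion-matrix metric suite. A seeded synthetic mammogram generator makes
every stage testable end to end without clinical data.

This vignette records the models, the tunable parameters, and the design
choices that were genuinely open, including the numerical ones. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

# The preprocessing chain

## CLAHE

Tile-wise histogram equalization with a clip limit redistributes histogram
mass so local contrast grows without amplifying noise unboundedly.
Parameters: `clip_limit` (normalized fraction of a tile histogram a bin may
hold, default 0.01) and `tile_grid` (default 8 x 8). The computation is
delegated to `EBImage::clahe()`; the wrapper returns a constant image
unchanged, since a constant tile has no histogram to spread (the underlying
routine rejects that case). Output is equalized over the full dynamic range
and clamped to [0, 1].

## Gradient energy and seam carving

The energy at a pixel is `|dI/dx| + |dI/dy|`, discretized as central
differences with replicated edges (the border gradient uses the clamped
neighbor, so border energies are half-weighted one-sided differences). Total
image energy is the sum of the map. A *seam* is an 8-connected path — one
column index per row (vertical) or one row index per column (horizontal) —
and carving removes the seam of minimal cumulative energy, recomputing the
energy map after every removal. Removal count defaults to 5% of each
dimension in `preprocess_image()`.

Design choices:

* The minimal seam is found by the classic dynamic-programming recurrence
  over steps {-1, 0, +1}. Ties are broken toward the smallest starting
  index and then the smallest index at each step, so the result is the
  lexicographically smallest optimal seam and all tests are deterministic.
* Vertical seams are removed first, then horizontal — a fixed order chosen
  for reproducibility.
* The DP result is validated against exhaustive enumeration of all
  8-connected seams on small maps (up to 6 x 6, both orientations) in the
  test suite.

## 2D Haar decomposition

One level splits an image into four subbands by separable filtering with
the orthonormal Haar pair — scaling `(1, 1)/sqrt(2)`, wavelet
`(1, -1)/sqrt(2)` — along x then y, downsampling by two:

* `LL` scaling in both directions (approximation / low pass),
* `LH` wavelet in x (horizontal detail),
* `HL` wavelet in y (vertical detail),
* `HH` wavelet in both (diagonal detail).

The orthonormal normalization (rather than the averaging 1/2 convention)
makes the transform an isometry: round trips reconstruct exactly and
energy (squared norm) is conserved across any pyramid depth, which the test
suite asserts to 1e-8. A constant image `c` maps to `LL = 2c` with all
details zero. Odd dimensions are replicate-padded on the right/bottom
(recorded in `pad_info`, stripped on synthesis); replication avoids boundary
ringing. `wavedec2()` builds the Mallat pyramid (recursing on LL);
`packet = TRUE` recurses on all four children instead. The deepest LL,
min/max normalized, is the network input (`extract_ll()`,
`wavelet_features()`). The default depth is 2 — a 299 x 299 input yields a
75 x 75 LL, small enough to matter and large enough to train on; the
maximum admissible depth for an `m x n` image is `floor(log2(min(m, n)))`.

# The wavelet activation

The classifier's distinguishing element is the elementwise activation

$$\psi(x) = \cos(\beta x)\, e^{-x^2/2},$$

a real Morlet-type wavelet: a cosine under a Gaussian envelope, with
analytic derivative

$$\psi'(x) = -\beta \sin(\beta x) e^{-x^2/2} - x \cos(\beta x) e^{-x^2/2}$$

used for backpropagation. `beta` defaults to 0.5 and is a global
hyperparameter, not learned. Numerically, `|psi(x)| <= exp(-x^2/2)`
everywhere, `|psi(x)| < 1e-8` for `|x| >= 6.5`, and inputs with `|x| > 40`
return exactly 0 (the envelope underflows long before). The analytic
derivative is validated against central finite differences to 1e-6 before
use.

## Trainability at small scale

Two properties of psi matter for optimization and drove design choices that
are defaults in this package:

1. psi is even with `psi'(0) = 0`: near the origin
   `psi(x) ~ 1 - (1 + beta^2) x^2 / 2`. Raw [0, 1] images have pixel
   standard deviation around 0.15, so first-layer preactivations under a
   fan-in-scaled init sit in this flat region and the signal is attenuated
   quadratically. The builders therefore insert a parameter-free per-image
   standardization layer (`standardize_input = TRUE`, exact Jacobian in the
   backward pass), which places preactivations on the O(1) scale where psi
   responds. This was verified directly: without it a small wavelet network
   stays at chance accuracy on a linearly separable task that the matched
   ReLU network solves.
2. psi attains its maximum at 0, so max pooling over psi outputs tends to
   select near-peak (constant ~1) responses and erases spatial contrast in
   small networks. `network_spec(pooling = "avg")` is therefore recommended
   (and used by the package's own scaled experiments) for wavelet networks;
   max pooling remains the default for the full-size
   architecture.

# Network architectures

`network_spec()` defaults encode the full-scale design: 299 x 299 single
channel input, an explicit zero-padding of the input, six blocks of three
same-padded 3 x 3 convolutions followed by one 2 x 2 pooling, filter
schedule `32, 64, 128, 256, 512, 512` (powers of two capped at 512, cap
repeated for the sixth block), L2 penalty 2e-4 on every convolution and the
dense head, flatten -> dropout 0.5 -> dense softmax over the class set.
`build_cnn()` uses ReLU; `build_wcnn()` is topologically identical with
every convolutional activation replaced by psi — the two have equal
parameter counts by construction, which the tests audit.

Training (`train_model()`) is mini-batch categorical cross-entropy plus the
L2 penalty, with Adam (default) or SGD; the full-scale defaults are
learning rate 1e-5, batch 64, 10 epochs. All randomness —
initialization, shuffling, dropout — flows through R's RNG, so seeded runs
are bit-reproducible on CPU. Loss choice (cross-entropy with the softmax
head), He-style fan-in init, and 2 x 2 max pooling are the conventional
pairings adopted where the design was open. Class probabilities are
softmax rows; predicted labels take the smallest index on ties.

The network input size follows the preprocessed sample's actual shape
(e.g. 75 for the depth-2 LL of a 299 image) rather than upsampling the LL
back — interpolation would smear the wavelet features.

# GAN synthesizer

`gan_spec()` describes a DCGAN pair. The generator projects a
100-dimensional Gaussian noise vector to a 4 x 4 x 1024 block and climbs
stride-2 fractionally strided 5 x 5 convolutions (batch-norm + ReLU;
final layer tanh, no batch-norm) to the configured power-of-two output
size; the discriminator mirrors the ladder downward (batch-norm + leaky
ReLU 0.2) into a single sigmoid unit. Weights draw from normal(0, 0.02).
Training alternates discriminator and generator Adam updates
(rates 1e-4 / 1e-5, beta1 0.5, beta2 0.999, minibatch 32) on the standard
non-saturating adversarial objective; images cross the module boundary in
[0, 1] and live in [-1, 1] inside. One GAN is trained per abnormality
class (`train_gan()` takes a single-class dataset), matching per-class
synthesis without conditional machinery. The geometry is the canonical
consistent ladder — 4 x 4 projection, stride-2 steps, one output channel —
with every filter count configurable.

The compute engine behind both classifiers and the GAN is the package's own
compact CPU implementation: im2col/col2im convolution and transposed
convolution kernels in C++ (BLAS matrix products), max/average pooling,
batch normalization, dropout, dense layers and optimizers in R. Gradient
correctness for every layer type is pinned by numeric-vs-analytic checks in
the test suite.

# Metrics

Per-class one-vs-rest confusion counts feed the six metrics: accuracy,
specificity TN/(TN+FP), sensitivity (= recall) TP/(TP+FN), precision
TP/(TP+FP), and F1 = 2PR/(P+R). The averaging policy is explicit: *micro*
(default) pools counts over classes before applying a formula, *macro*
averages per-class values. For single-label multiclass data, micro
precision = recall = F1 = plain accuracy (correct / n) — a mathematical
identity the tests verify on random prediction vectors; micro accuracy is
computed as the pooled TP share of samples because summing one-vs-rest TNs
would count each sample K - 1 extra times. Pooled one-vs-rest specificity
inflates with class count for the same reason; this is documented rather
than hidden. Zero denominators yield 0 with a warning, never a silent NaN.

# Synthetic data generator

The generator emulates the statistical shape of mammographic ROIs, not
anatomy: a smooth low-contrast background (baseline 0.3 plus two or three
low-frequency cosine gratings of amplitude 0.02–0.035) with Gaussian pixel
noise (default sd 0.02), and per-class structure added on top:

* `N` background only;
* `BM` / `M` one to three Gaussian blobs (mass), `M` brighter (peak 0.5 by
  default) and 1.3 x larger than `BM` (0.6 x peak);
* `BC` / `CALC` clusters of 1–3 px bright speckles, `CALC` denser;
* `AD` radial bright line segments converging on a focus (architectural
  distortion);
* `ASYM` a monotone lateral intensity ramp (asymmetry).

The background amplitudes guarantee that a mass peak clears the background
maximum by at least half the lesion intensity, so N-vs-M is linearly
separable on a single feature — the tests verify a max-intensity threshold
reaches 95% on 200 samples. Every sample derives its own seed from
(global seed, index) by an exact-integer Lehmer hash, making whole-dataset
generation a pure function of the spec. What the generator does *not*
emulate: pectoral muscle, labels and film artifacts, tissue texture
correlations, scanner noise. Passing tests on these fixtures demonstrate
the pipeline's mechanics and trainability, not clinical performance.

# Study sizes used by the package's own experiments

Chosen once as desk-scale conditions and fixed:

* Learnability: a compact wavelet network (2 blocks x 1 convolution,
  filters 16/32, average pooling, Adam 3e-4, batch 8, 5 epochs) on the
  two-class N/M task with 200 training and 100 validation images at
  64 x 64, noise sd 0.02. This configuration reaches >= 0.9 validation
  accuracy with strictly decreasing training loss across seeds.
* GAN smoke: 64 x 64 ladder (generator filters 64/32/16/8), 64 real
  images, 50 adversarial steps.
* Pipeline determinism: five classes x 50 images at 64 x 64, CLAHE, 5%
  carving, depth-2 LL (16 x 16), compact network, 3 epochs, run twice and
  compared bit for bit.

A known limitation follows from the working size: at 64 x 64, the depth-2
LL reduces a ~5 px mass to about one pixel, so the five-class task at the
determinism conditions sits near chance accuracy — the determinism check is
about reproducibility, not skill. The two-class protocol above is the
learnability demonstration. At the full 299 x 299 scale the same depth
leaves a 75 x 75 LL where lesions remain several pixels wide.

# Reproducibility

A single global seed fans out to per-stage seeds through the Lehmer hash;
`run_pipeline()` writes a JSON manifest capturing the resolved
configuration and metrics, per-epoch history and the metric report as CSV.
Two runs from the same configuration produce bit-identical numeric
artifacts on CPU. `scripts/acceptance.R` recomputes the package's headline
quantities from scratch under any seed.
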