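---
title: "Image-text guided vessel segmentation: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-text guided vessel segmentation: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Retinal vessel segmentation assigns every pixel of a fundus photograph
(color fundus, CF) or an OCTA en-face image a binary vessel/background
label. Convolutional U-shaped networks do well on coarse vessels but lose
fine ones, and pixel-level annotation is expensive. `vesselvit` implements a
dual-branch image-text model that augments a U-shaped CNN with a
transformer branch fed by a free-text description of each image ("vessel
density is high, the vessels form a fine reticular mesh ..."), so that
coarse semantic priors from text can guide the dense prediction.

The architecture combines four ideas:

* **Squeeze-and-Excitation (SE) channel attention** in the CNN branch. For
  a feature map $U \in \mathbb{R}^{C\times H\times W}$, the squeeze step
  pools each channel to $z_c = \frac{1}{HW}\sum_{i,j} u_{ijc}$, the
  excitation step computes $s = \sigma(W_2\,\mathrm{ReLU}(W_1 z))$ with a
  bottleneck of width $\max(1,\lfloor C/r\rfloor)$, and recalibration
  rescales channel $c$ by $s_c \in (0,1)$. Placement is configurable:
  after encoder stages (`down`), decoder stages (`up`), both (`all`), or
  absent (`none`); the reference experiments favour `down`.
* **Pixel-level attention (PLAM)** at each skip connection: a CBAM-style
  sequential channel-then-spatial attention (global average and max
  descriptors through a shared two-layer perceptron; per-pixel mean/max
  maps through a 7x7 convolution), merged back by a 1x1 projection with a
  residual add.
* **Gated residual transformer layers** in the ViT branch. Each residual
  connection is modulated by a learned sigmoid gate computed from the
  sub-layer input: $y' = \mathrm{Gate}_{attn}(x)\odot\mathrm{Attn}(x) + x$,
  then $y = \mathrm{Gate}_{mlp}(y')\odot\mathrm{MLP}(y') + y'$. Gates are
  one scalar per token by default (per-feature optional). The gate-0 limit
  collapses a layer to the identity; the gate-1 limit recovers the plain
  pre-norm transformer layer — both limits are asserted exactly in the
  tests.
* **Text conditioning**: captions are embedded (768-dimensional tokens),
  mean-pooled, linearly projected to the token dimension and added to every
  image token at the entry of the transformer branch. A zero text embedding
  is exactly a no-op, which makes the with/without-text comparison a clean
  ablation.

Training minimizes equally weighted binary cross-entropy and soft Dice on
the sigmoid output. The reference recipe (Adam, learning rate 0.001, batch
size 2, 300 epochs) is the package default; tests use shorter schedules.

## Why pure R, and what that implies

No deep-learning framework ships with the target environment, so the
package carries a small reverse-mode automatic differentiation engine
(`R/autograd.R`): dense tensors, a dynamic tape, and the ~25 operators the
architecture needs (im2col convolution, pooling, attention, layer norm,
losses). Every operator's gradient is validated against central finite
differences in the test suite, and each architectural block against
independent loop-level oracles. The engine is adequate for the test profile
(64x64 images, 8 base channels) but a few orders of magnitude slower than a
GPU framework; reproducing the reference scale is a non-goal.

## The synthetic corpus: what it emulates, and what it does not

The package generates its own training surface because the reference
datasets are external downloads. Two modalities are emulated as recursive
binary vessel trees grown from peripheral seed points toward the image
centre, rasterized with per-generation width decay:

* `cf`: few (6) thick trunks, radial layout, a bright optic-disc blob;
* `octa`: many (18) fine trunks forming a dense mesh, with a central
  avascular disc (emulating the foveal avascular zone) that is guaranteed
  vessel-free by construction.

The image is the blurred (Gaussian, sigma 0.7 px), contrast-modulated mask
plus Gaussian background noise (sd 0.08) — values chosen once as a
plausible mild-speckle regime for downsampled angiography-like images, not
tuned to any test outcome. Captions are derived from descriptors measured
on the mask (density class from the vessel-pixel fraction with cut points
0.05/0.15; distribution class from the modality; abnormal-area clauses from
injected blobs), so text and pixels are consistent by construction.

What a green learnability test establishes: the assembled model, its
gradients, and its optimizer can jointly fit a nontrivial thin-structure
segmentation task from tens of images on a CPU. What it does not establish:
performance on real fundus images, where illumination, pathology, contrast
and annotation noise are far richer than this generator produces.

## Committed choices where the design was open

* **SE hyperparameters**: reduction ratio defaults to 16 with the hidden
  width clamped to at least 1; no biases on the two bottleneck layers.
  Both are the original SE conventions; the source describes only the
  three equations.
* **PLAM wiring**: the figure-level description does not pin the branch
  topology, so the package commits to sequential channel-then-spatial
  attention with a zero-initialized 1x1 merge projection plus residual —
  the module starts as an exact identity and the tests pin this declared
  wiring, not a figure.
* **Gate placement and granularity**: pre-normalization layout, gates
  computed from the sub-layer input and applied to the sub-layer output
  before the residual add; one scalar gate per token by default. Gate
  weights start at zero and biases at zero, so training starts at gate
  0.5 — midway between identity and full residual.
* **Text fusion**: additive, after a learned projection of the pooled
  embedding (zero-initialized so that no text is exactly a no-op). The
  text encoder is frozen; only the projection trains. A pretrained
  transformer encoder can be registered at run time, but the default stub
  embedder is a seeded hash-per-token scheme: fully offline, deterministic,
  order-independent — the pipeline never depends on downloaded weights.
* **ViT/decoder interface**: the transformer branch runs on the bottleneck
  token grid with 2x2 token merging between its two U levels; its output
  map re-enters the CNN decoder by concatenation followed by a 1x1
  projection.
* **Loss**: BCE + Dice (equal weights). The source does not state its
  loss; this pairing is standard for thin structures and makes the
  overfit-sanity oracle attainable.
* **Metrics aggregation**: pooled (micro-average) confusion counts are the
  headline numbers since the four formulas are written directly in counts;
  a per-image macro average is attached for transparency.
* **Binarization**: threshold 0.5 with ties mapping to vessel.
* **Preprocessing order**: grayscale, then min-max normalization, then
  CLAHE (clip limit 2.0, 8x8 tiles), then gamma 1.2 — the listed order of
  the source, with parameter defaults from common fundus practice since
  none are given. With z-score normalization the image is affinely mapped
  back to [0,1] before CLAHE, which is defined on that range.
* **Label storage**: CSV is canonical (diffable, no binary dependency);
  xlsx is supported for fidelity to the described workflow via `readxl`
  (reading) and a minimal built-in writer (stored-entry zip with inline
  strings).

## Numerical and degenerate-input conventions

Constant images cannot be min-max normalized and return zeros with a
warning. Undefined metric ratios (zero denominators) are reported as
flagged `NA`, never silently zero. Max-pooling and per-channel max
operations break ties by first index, deterministically. Training aborts
with a diagnostic on a non-finite loss. All randomness flows through R's
RNG: a fixed seed fixes weights, data order, the synthetic corpus and the
stub embeddings, which is what makes the bitwise determinism tests
possible; the stub embedder saves and restores the global RNG state so that
embedding never perturbs the training stream.

## Known limitations

* CPU-scale only; the reference benchmark numbers on DRIVE/ROSE-1 are out
  of scope by design (external data, pretrained weights, GPU training).
* TIFF input is not supported (no offline reader in the environment).
* The ablation at toy scale is machinery validation: recovering the
  reference ordering of SE placements (SE-DOWN best) is not guaranteed or
  asserted at 64x64 with minutes of training.
* The caption grammar covers three descriptor axes only; it does not
  attempt clinical richness.
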