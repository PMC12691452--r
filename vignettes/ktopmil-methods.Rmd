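---
title: "Top-K attention MIL for whole-slide images: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Top-K attention MIL for whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktopmil)
```

## The problem

Ovarian carcinoma is subtyped from H&E-stained whole-slide images (WSIs)
into five histotypes — clear cell (CC), mucinous (MC), low-grade serous
(LGSC), high-grade serous (HGSC), and endometrioid (EC) carcinoma — whose
treatment and prognosis differ. WSIs are gigapixel images with only a
slide-level diagnosis attached: no pathologist marks which regions carry
the tumor. Two properties dominate the computational problem:

1. **Scale.** A slide cannot be fed to a classifier whole; it is tiled,
   and most tiles are background or non-diagnostic tissue.
2. **Weak supervision.** The label belongs to the slide, not to any tile.

Multiple-instance learning (MIL) is the standard formalization: a slide
becomes a *bag* of N tile *instances* sharing one label, a backbone maps
each tile to a feature vector, a permutation-invariant *aggregator* maps
the n x d instance-feature matrix to a single bag representation, and a
linear classifier with a softmax produces the subtype probabilities. The
cross-entropy between the bag prediction and the slide label is the
training objective.

This package implements that pipeline end to end — tiling, brightness
filtering, Lanczos downscaling, bag construction, four aggregators,
training, a full metric suite, temperature calibration, and a
leave-one-domain-out generalization protocol — together with a synthetic
multi-center WSI generator that makes every stage testable without any
pathology dataset.

## Preprocessing: from slide to bag

A W x H slide is covered by non-overlapping `tile x tile` windows
(default 512): `floor(W/512) * floor(H/512)` full tiles, partial edge
strips discarded. A 16,000 x 16,000 slide therefore yields at most
31 x 31 = 961 tiles. An overlapping dialect is available (`overlap = 50`
steps by 462 px with the last origin clamped to the image edge) for
tissue-continuity studies; non-overlapping is the default because it is
the only mode consistent with the 961-tile accounting above.

Tiles whose grayscale mean intensity falls strictly below 25 (on the
0–255 scale) are discarded: glass-edge shadows, scanner artifacts and pen
marks are near-black, while tissue and background are bright. The mean is
the unweighted channel mean; a tile at exactly 25 is kept. No
high-intensity (white background) filter is applied by default — bright
background tiles are legitimate instances that the aggregator must learn
to ignore, which is precisely the behavior the planted-signal experiment
probes.

Kept tiles are reduced 512 -> 256 px with separable Lanczos-3
resampling (the kernel stretched by the scale factor so it anti-aliases),
an exact 4x pixel and memory reduction at equal bit depth. The resampling
weights are normalized per output pixel, so constant tiles are preserved
exactly and resizing to the source size is the identity — both properties
are asserted in the tests.

From each slide's kept tiles, `N` (default 50) are drawn uniformly at
random without replacement. The brightness filter is the only quantified
tissue-selection rule in the protocol, so filter-then-uniform-sample is
the faithful composition. Slides with fewer than `N` kept tiles are
sampled with replacement and flagged; slides with none are excluded and
reported. Training-time augmentation (rotation up to ±90°, flips, color
jitter, random crop at 0.8–1.0 area scale, Gaussian blur with sigma in
0.1–2 px, then resize to 224) is available with per-transform
probabilities; setting all probabilities to zero reduces training mode to
the deterministic evaluation resize.

## Aggregators

Let `F` be the n x d instance-feature matrix of one bag.

* **Mean pooling** `B = colMeans(F)`: every tile votes equally; sparse
  diagnostic signal is diluted by background.
* **Max pooling** `B[k] = max_j F[j,k]` element-wise: dominated by single
  extreme tiles.
* **Attention pooling** `B = sum_j alpha_j F[j,]` with
  `alpha = softmax(s / tau_a)` and the gated-tanh scorer
  `s_j = w' tanh(V f_j + b1) + b2` (hidden width `m`). The scorer is the
  two-layer Linear–Tanh–Linear form; with the biases at zero it is exactly
  the bias-free `w' tanh(V f)` form, so the two presentations of the
  scorer coincide at initialization.
* **Top-K attention pooling** ranks instances by the raw score `s_j`
  (ties to the lower index) and aggregates the top `K` (default 5), either
  with the softmax weights renormalized over the selected set (default) or
  as their plain mean. At `K = n` the two modes reduce exactly to
  attention pooling and mean pooling respectively — identities the test
  suite asserts on random matrices.
* **Prediction-level max** (`score_max`): the no-attention baseline that
  computes per-instance class logits first and takes the per-class maximum
  as the bag logits.

Class probabilities come from the temperature-scaled softmax
`p_i = exp(z_i/tau) / sum_j exp(z_j/tau)` (max-subtracted for stability).
`tau` defaults to 1; the calibration sweep re-evaluates a trained model at
`tau` in {0.1, 0.3, 0.5, 1, 2, 5}. Rescaling logits never changes the
argmax, so accuracy is invariant in `tau` — asserted exactly — while
entropy is non-decreasing in `tau`. The temperature applies to the
classifier softmax only; applying it additionally to the attention softmax
is exposed (`attention_temperature`) but off by default, because the
calibration ablation modifies the classifier's softmax and gives no
indication the attention softmax is touched.

## Backbone and training

The bundled backbone (`tiny_cnn`) is a frozen three-block convolutional
texture encoder — 3x3 convolutions with fixed, seeded filter banks (8, 16,
32 channels), ReLU, 2x2 max-pooling, then global mean- and max-pooling per
channel, giving d = 64 features from a 64 x 64 input. It is deterministic,
needs no weight download, and is *not* trained: this package operates in
the frozen-extractor / linear-probe regime, in which the trainable
parameters are the scorer (V, b1, w, b2) and the classifier (W, b).
Configurations naming resnet18/resnet50/vit are accepted as pass-through
metadata (recording the standard penultimate width) for users who extract
features with their own weights; backbone fine-tuning is out of scope
here, which is the main respect in which this package is a scaled-down
account of the full method.

Training uses analytic gradients, AdamW (beta1 = 0.9, beta2 = 0.999,
decoupled weight decay 1e-4 on weight matrices), cross-entropy loss, and a
one-cycle learning-rate schedule with peak 2e-4 over 25 epochs by default,
with early stopping on validation accuracy (patience 10). Instance
features are standardized with training-set statistics
(`standardize_bags()`), the usual normalization for a linear probe.

Two initialization choices matter and are deliberate:

* the scorer head `w` starts near zero, so the initial attention
  distribution is effectively uniform and every attention-family
  aggregator starts out as mean pooling, sharpening only as the loss
  demands;
* the classifier starts at zero, the standard linear-probe init.

**The top-K cold-start pathology.** Hard top-K selection makes the loss
locally independent of the non-selected instances: with renormalized
weights, the full-softmax denominator cancels, so score gradients reach
only the selected set. A scorer that happens to rank the informative
instances low therefore never receives a signal to promote them, and
training can settle on a background-only selection. We observed exactly
this on synthetic cohorts: full attention pooling concentrates ~0.9 of its
weight mass on the planted instances, while a cold-started top-K model can
select zero informative instances indefinitely. The package's remedy is
`train_config(warmup_epochs = k)`: the first `k` epochs of a top-K model
are trained through the full-bag attention softmax (whose gradient reaches
every instance), after which hard selection is switched on. This changes
only the optimization path; the top-K operator itself, its two weighting
modes, and the K = n reduction identities are untouched.

## The synthetic multi-center generator

`generate_wsi()` emulates the features of a multi-institution WSI cohort
that the pipeline actually consumes, and nothing more:

* near-white background (mean intensity > 200) with slight per-slide tint
  variation;
* an informative region of class-specific procedural texture — each
  histotype gets a distinct base chromatin-like color, stripe frequency
  and orientation, and dot-lattice spacing — covering a configurable
  fraction of the image (planted on an alignment-cell grid, so the
  achieved fraction is within the cell granularity of the request, well
  inside ±5 percentage points absolute);
* near-black artifact regions (mean < 25) planted on tile-aligned cells,
  so they exercise the brightness filter tile-for-tile;
* a per-domain stain perturbation — hue rotation plus saturation scaling
  in HSV space, applied to tissue pixels only — as the simplest
  controllable analogue of inter-center staining variation.

Every image is a pure function of its spec (bitwise-identical
regeneration). Default conditions: 2048 x 2048 px slides (the tiling math
is scale-free, so tests need not handle gigapixels), informative fraction
0.3, artifact fraction 0.05, 512-px alignment cells.

What the generator does **not** emulate: nuclei, glandular architecture,
compression artifacts, TMA core geometry, magnification pyramids, or any
photorealistic H&E property. Tests passing on these cohorts demonstrate
that the pipeline's mechanics and the aggregators' selective behavior are
correct, not that the model reaches any particular accuracy on real
pathology data.

## The planted-signal experiment

`planted_signal_experiment()` is the package's headline property check,
a desk-scale analogue of the aggregator-comparison ablation: 100 slides
(20 per class) of 1024 x 1024 px across 4 stain-shifted domains, tiled at
256 px, downscaled to 128, 16 instances per bag. Informative texture is
planted tile-aligned at fraction 0.15, so each bag holds about 2 wholly
informative tiles among 14 background tiles — the sparse-instance MIL
regime in which averaging dilutes the signal roughly eightfold. Frozen
`tiny_cnn` features feed 5-epoch linear probes (learning rate 0.02,
batch 2, constant schedule, 3 warm-up epochs for the top-K model, K = 3)
under 3 evaluation seeds that redraw the 70/30 stratified split and the
initialization. The asserted property is the ordering — the median top-K
test accuracy is at least the median mean-pooling test accuracy — not any
absolute number; in typical runs top-K reaches ~0.9 and mean pooling
~0.8. Tile-level augmentation is skipped here (evaluation-mode resizing
only): with a frozen backbone the features are extracted once, and the
ordering claim does not hinge on augmentation.

These problem sizes (1024-px slides, 64-px backbone inputs, 5 epochs,
3 seeds) are the package's chosen desk-scale study conditions; the
whole experiment completes in about a minute and a half on one CPU.

## Dataset and domain splits

`make_split()` supports ratio and explicit-count splits with per-class
stratification by capacity-constrained largest-remainder allocation:
classes are processed sequentially against the remaining pool capacities,
which meets the requested cardinalities exactly while keeping every
class within one slide of its proportional share per pool.

`make_domain_splits()` builds the leave-one-domain-out protocol for a
cohort of size N over `d` domains: the test pool is
`ceiling((1 - train_frac) * N)` slides, each pool is divided as
`floor(pool/d)` per domain with the last domain absorbing the remainder,
and slides are assigned to domains class-stratified. For a 513-slide
cohort at 80/20 over 4 domains this yields train 102/102/102/104, test
25/25/25/28, domain totals 127/127/127/132 — the accounting
410 + 103 = 513.

`run_cross_domain()` trains one model per held-out domain (on all bags of
the other domains) and evaluates on the held-out domain, producing the
per-domain accuracy / balanced accuracy / AUROC / F1 quadruple.
`domain_gaps()` measures each domain's accuracy shortfall from the
best-performing domain in percentage points (the reference row prints
"-"); "relative difference" is implemented as absolute difference in
percentage points, the only reading under which the published example
columns (e.g. a 10.52-point delta from a 95.72% reference against an
85.2% domain) are reproducible. `delta_table()` reports Delta1 (distance
from a source domain) and Delta2 (distance from an externally supplied
best reference accuracy) with consistency labels: a delta in [0, 9]
percentage points is labelled `high`, above 9 `medium`; the boundary
value 9 itself is high. `summarize_domains()` uses the sample (n-1)
standard deviation.

## Metrics

All confusion-matrix metrics are computed one-vs-rest per class and then
averaged. Precision, recall, specificity and F1 are support-weighted by
default — the only scheme under which the averaged recall is *identically*
the overall accuracy, an algebraic identity the tests assert on random
matrices and which published result tables exhibit as equal accuracy and
recall columns. Balanced accuracy is the unweighted mean of per-class
recalls (binary case: (TPR + TNR)/2 exactly). Cohen's kappa is
(Po - Pe)/(1 - Pe) from the marginals, with the degenerate Pe = 1 case
defined as 1 if Po = 1 and 0 otherwise. AUROC is the macro-averaged
one-vs-rest Mann–Whitney statistic with half credit for ties (identical
to trapezoidal ROC integration); AUPRC is step-wise average precision
with tie groups collapsed. Zero-denominator cells contribute 0; classes
absent from the truth are skipped with a warning; AUROC with fewer than
two observed classes is an explicit error, not NaN.

## Numerical and degenerate-input choices

* Tile coordinates are 0-based, half-open, row-major by (y, x); an image
  smaller than one tile gives an empty grid, not an error.
* Top-K ties break to the lower instance index; permutation invariance is
  asserted for the no-tie case.
* Softmaxes are max-subtracted; cross-entropy is computed in log-space
  from logits during training and clamps probabilities at 1e-300 when
  computed from a probability matrix.
* Lanczos output is clamped to [0, 255] (the kernel overshoots at sharp
  edges).
* Non-finite training loss aborts with a diagnostic naming the epoch and
  bag rather than continuing with poisoned optimizer state.
* All randomness is scoped: generators and training restore the caller's
  RNG state, and every stochastic function takes an explicit seed.

## Known limitations

* The backbone is a fixed texture encoder; no fine-tuning, no pretrained
  deep features. Absolute accuracies on real WSIs are out of reach by
  design, and all assertions are structural (identities, contracts,
  orderings).
* The synthetic cohorts are far easier than real pathology: class
  textures are globally consistent and stain shifts are clean hue/
  saturation transforms. Domain gaps measured on them are small almost by
  construction.
* The attention warm-up mitigates, but does not eliminate, the
  sensitivity of hard top-K training to its optimization
  hyperparameters; very high learning rates can still collapse the
  scorer.
* One-vs-one multiclass AUROC, significance testing, and explainability
  heatmaps are not implemented.
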