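---
title: "Tile-based whole-slide classification of NSCLC subtypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-based whole-slide classification of NSCLC subtypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Distinguishing squamous (S) from non-squamous (NS) non-small cell lung
cancer on routine haematoxylin-eosin(-saffron) biopsy slides is the first
branching point of lung-cancer therapy. `histotile` implements a complete
patch-based classification pipeline for this task:

1. **Tiling.** The slide raster is partitioned into non-overlapping
   220 x 220 px tiles at 0.5 um/px (20x), anchored at the image origin;
   trailing partial strips are discarded. A tile is removed when strictly
   more than 2/3 of its pixels are white background.
2. **Colour normalization.** Reinhard moment matching in the l-alpha-beta
   opponent colour space: per channel, `out = (in - mu_src) * sd_tgt/sd_src
   + mu_tgt`, computed over tissue pixels and applied per slide.
3. **Classification.** A convolutional network scores every kept tile with
   a probability pair (p_NS, p_S). Training follows the reference schedule:
   100 epochs, Adam (beta1 0.9, epsilon 1e-7), lr 0.001 decaying by 0.9
   every 5 epochs, batches of 100, flip/right-angle-rotation augmentation,
   and cross-entropy multiplied by 1.5 for currently misclassified tiles.
4. **Patient inference.** Two post-processing routes: per-class confidence
   thresholds tuned by exhaustive grid search on the validation split over
   {0.5, 0.55, ..., 0.95}^2, or spatial re-estimation of each tile from its
   8-neighbourhood by a logistic-regression "filter kernel". Slide calls
   come from majority vote or max pooling, on whole-slide tiles (WSI) or on
   tiles gated to virtual tissue-microarray cores (500 um radius circles
   around annotation centroids).
5. **Evaluation.** Overall and per-class (recall) accuracy at tile and
   slide level for the full 2 x 2 x 2 strategy cross-product, ROC/AUC with
   squamous as the positive class, and red/green/grey probability heatmaps.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `tile_px` | 220 | px | reference tile size at 20x |
| `max_white` | 2/3 | fraction | background-removal rule ("more than 2/3") |
| `white_level` | 0.94 | unit scale | white is undefined upstream; 0.94 tolerates mild stain shift yet never matches stained tissue |
| `fractions` | 0.6/0.2/0.2 | slides | slide-grouped split; per class `floor(0.6n)` / `floor(0.2n)` / remainder reproduces the 39/13/14-per-class learning-cohort split |
| `lr0`, `lr_decay`, `decay_every` | 0.001, 0.9, 5 | — | reference schedule |
| `loss_weight` | 1.5 | — | penalty on misclassified tiles, both error directions |
| `grid_step` | 0.05 | probability | search grid containing both published operating points (0.5 and 0.9) |
| `tma_radius_um` | 500 | um | virtual-TMA core radius (1000 px at 0.5 um/px) |

Interpretation choices where the upstream description is ambiguous, each
fixed and documented:

* **"0.5 mm/pixel"** is read as 0.5 um/pixel — 0.5 mm/px contradicts 20x
  magnification, while 0.5 um/px is the standard 20x value.
* **Weighted loss.** "False negatives and false positives equally penalized
  with a 1.5 factor" is implemented as: multiply the per-example
  cross-entropy by 1.5 whenever the example's argmax is currently wrong,
  identically for both error directions.
* **Threshold objective.** Tile-level correct-classification rate among
  retained tiles on the validation split, subject to at least 5% of tiles
  retained; ties break toward lower thresholds (retain more tiles).
* **Kernel filter.** Fitted on training-split tiles against the slide's
  class; features are the tile's own p_S, the fraction of its existing
  8-neighbours labelled S, and the fraction of the 8 positions missing.
  Applied in a single simultaneous pass (no iterative relaxation). A
  collinear (constant) feature is dropped with weight zero.
* **Ties.** Argmax ties at p = 0.5 call NS; majority-vote count ties go to
  the more confident side, then NS; max-pooling confidence ties go to NS.
* **TMA cores.** One core per annotation, center-in-circle tile rule,
  union over cores, intersected with the background-filter kept set.
* **Colour reference.** Statistics of the first manifest slide. The
  reference is an arbitrary colour anchor carrying no label information,
  so a split-independent choice keeps preprocessing reusable across
  training seeds.

## The backbone

The reference architecture (InceptionV3) needs a GPU-scale deep-learning
framework; none exists in this R environment and full-scale training is
out of scope. The backbone is therefore pluggable and the default
`tiny_cnn` is a small native network: a fixed 4 x 4 average-pooling stem
(220 -> 55 px), three 3 x 3 convolution blocks (8, 16, 32 filters) with
ReLU and 2 x 2 max pooling, global average pooling and a softmax pair.
Convolutions run as im2col + BLAS products; everything is deterministic
given the seed and single-threaded BLAS. `backbone = "inception_v3"` is
accepted in configuration but raises a clear error. All schedule
parameters, the loss, augmentation and the post-processing path are
identical to the full-scale description — the architecture is
configuration, not code structure.

## What the synthetic generator emulates — and what it does not

A synthetic slide is a white canvas (channel values >= 0.94 of full scale)
carrying wobbly-ring biopsy fragments. Each fragment contains stroma
texture common to both classes (light pink, smooth fibrous modulation) and
a tumour subregion whose texture identifies the class: coarse 8 px speckle
for squamous (keratinizing, high local-variance), smooth gland/ring
sinusoids (wavelength 64 px) around seeded centres for non-squamous. The
tumour polygon is the fragment ring scaled by `sqrt(tumour_fraction)` —
so the tumour/tissue area ratio is exact by construction — and shifted
off-centre, as in a biopsy whose tumour sits to one side of the core.
Per-slide stain shifts (uniform within a per-channel range) exercise
Reinhard normalization; per-pixel Gaussian noise models sensor noise.

Defaults, chosen once: 2640 px square slides (a 12 x 12 tile grid — large
enough that a 1000 px TMA core is a proper subset of the tissue), one
fragment, `tumour_fraction = 0.3` (biopsies carry little tumour relative
to tissue; the reference cohort's median tumour area of well under a square
millimetre motivates a small fraction), `noise_sd = 0.02`, stain-shift
range 0.12 per channel. Texture parameters live in one place
(`.texture_params`) and were chosen for learnability by a small CNN, not
biological realism: the two classes differ by more than 5 within-class
standard deviations in a fixed local-texture statistic, which is what
makes a green end-to-end test meaningful.

What a green test does **not** establish: performance on real HES scans.
The generator has no nuclear morphology, no pen marks, folds or blur, no
scanner-specific colour response, and its class textures are far cleaner
than real tumour morphology. Green means the pipeline's machinery —
tiling arithmetic, normalization contract, training loop, threshold
search, spatial re-estimation, gating and aggregation — behaves as
specified on a world with known ground truth.

## Numerical choices and degenerate inputs

* LMS values are floored at 1e-4 before the log in the colour transform,
  keeping pure black finite; RGB output is clipped to [0, 1].
* Images quantize to 8 bits on write (`round(x * 255) / 255`), making
  generation byte-deterministic under a seed.
* `weighted_loss` floors p at 1e-12; zero-variance channels and
  single-class training sets raise errors rather than degrade silently.
* An isolated tile's neighbour-label fraction falls back to its own label
  indicator; a slide with zero retained tiles falls back to unthresholded
  predictions and is flagged (`fallback_used`).
* Max-pool gradient ties route to the first of the four pooled positions;
  augmentation rotations are multiples of 90 degrees so the pixel multiset
  is preserved exactly.

## Training stability at desk scale

With ~1,000 weakly labelled tiles (every kept tile carries its slide's
class, so most stroma tiles are label noise) and ten epochs, last-epoch
weights oscillate: a run can sit near its accuracy ceiling at epoch 9 and
collapse to a one-class predictor within epoch 10. `train_classifier`
therefore keeps the weights of the epoch with the best validation
accuracy whenever a validation set is supplied — the standard checkpoint
rule on the validation curve that the full-scale schedule also records.
Without a validation set the final weights are returned unchanged.

## Scaled-down testing

The acceptance suite trains the tiny backbone for 10 epochs on a 40-slide
cohort with batches of 25 tiles — the update count per epoch then stands
in the same proportion to the ~1,100-tile training set as the reference
batch of 100 does to its ~140,000 tiles — reusing one preprocessing pass
across three training seeds; the three-seed median of held-out
majority-vote accuracy and the TMA-versus-WSI comparison are the
end-to-end checks. Published numbers from the full-scale study (tile
accuracies 0.99/0.87/0.85, slide accuracies 0.73-0.82, AUC 0.81-0.94) are
not reproducible at this scale and are not asserted anywhere.

## Known limitations

* No pyramidal/ndpi reading; rasters are plain PPM/arrays in memory.
* Two classes only; no multi-class support.
* The kernel filter is a single pass; no CRF-style iteration.
* `tiny_cnn` is CPU-sized; no transfer learning or pretrained weights.
* Physical TMA registration and interactive annotation are out of scope.
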