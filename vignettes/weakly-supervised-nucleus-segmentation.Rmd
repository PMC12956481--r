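---
title: "Weakly supervised nucleus segmentation from point annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised nucleus segmentation from point annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dense pixel-level annotation of cell nuclei in H&E histology is expensive:
nuclei are small, numerous, frequently overlapping, and outlining them
requires a pathologist. A single *point* per nucleus, by contrast, is cheap
to collect. `pointseg` trains a binary nucleus segmentation model from
nothing but one point per nucleus, in two stages:

1. **Stage 1 — noise-robust training on pseudo-labels.** The points are
   expanded into two complementary pseudo-labels. The *Voronoi label*
   $y_v$ partitions the image by nearest annotation point; small discs
   around the points are positives, the inter-cell ridges negatives, and
   everything else stays unlabeled. It encodes global topology (one
   nucleus per cell) but nothing about shape. The *superpixel label*
   $y_s$ marks as foreground the union of SLIC superpixels containing a
   point; it hugs local colour boundaries but inherits SLIC's over- and
   under-segmentation errors. Three networks are trained jointly on these
   noisy labels:
   - **seg**: a residual encoder–decoder with feature aggregation
     (decoder outputs pass through CBAM attention blocks, are summed and
     upsampled) producing the foreground probability map $f(I)$;
   - **att**: the same design with a smaller encoder, fed the RGB image
     concatenated with the $y_s$ plane, producing an attention map
     $f_\mathrm{att}$ that marks *confident* regions;
   - **cons**: a shallow constraint network preserving low-level texture,
     whose intermediate feature map $f_\mathrm{cons}$ is added to the
     first encoder stage of **seg** and whose N-channel output $h$ is
     pulled towards $f(I)$ by an L1 loss.

   The objective is
   $L_\mathrm{total} = \beta L_\mathrm{seg} + \gamma L_\mathrm{att} + \delta L_\mathrm{cons}$
   with
   $L_\mathrm{seg} = \mathrm{BCE}(f(I)\odot f_\mathrm{att},\, y_s)$,
   $L_\mathrm{att} = \tfrac{1}{|y_v^+|}\sum_{y_v^+}|1-f_\mathrm{att}| + \alpha\,\tfrac{1}{|y_v^-|}\sum_{y_v^-}|1-f_\mathrm{att}|$, and
   $L_\mathrm{cons} = \tfrac{1}{N}\sum_n \mathrm{mean}\,|f(I)-h_n|$.

2. **Stage 2 — confident-learning label refinement.** The trained model's
   probabilities are compared with the given labels: per class $j$, the
   threshold $t_j$ is the mean predicted probability of $j$ over pixels
   labeled $j$; a counting matrix $C_{ij}$ tallies pixels labeled $i$ but
   confidently predicted $j$; row-calibrating $C$ to the label frequencies
   and normalising gives the joint distribution $Q$. For each off-diagonal
   cell, the $\mathrm{round}(n\,Q_{ij})$ pixels with the largest margin
   $\hat p(j)-\hat p(i)$ are flipped. The model is then retrained from
   scratch on the refined label $y_{re}$.

## Worked example

```{r}
library(pointseg)
res <- run_full(run_config(), out_dir = "run")
print(res)
```

The default configuration generates 16 synthetic 96 x 96 histology-like
tiles, builds pseudo-labels, trains both stages (5 epochs each, tiny
network preset) and evaluates against the exact synthetic ground truth.

## The synthetic generator

Every other module is tested against scenes with exact ground truth:
rotated ellipses (semi-axes 2–6 px at a 96 px reference frame, scaled
linearly with image size) with per-nucleus colour jitter (SD 15/255)
around a dark purple mode (110, 70, 140), on a lighter pink background
(230, 200, 220), both overlaid with additive Gaussian pixel noise
(SD 8/255). Pairwise overlap is allowed up to 30% IoU, mimicking touching
nuclei, which is exactly the case where the Voronoi prior earns its keep.
The colour separation is chosen so SLIC boundaries are informative but
imperfect — the superpixel label is deliberately noisy supervision.
Centroids are recomputed from the rendered (possibly clipped) masks, never
taken from the analytic ellipse centre.

What the generator does *not* emulate: stain variation across slides,
out-of-focus blur, tissue architecture (stroma, glands), nucleoli and
chromatin texture, or imaging artefacts. Passing tests therefore
demonstrate that the pipeline's machinery is correct and that its
improvement directions hold on controlled data; they are not evidence of
clinical-grade accuracy on real slides.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| $\alpha,\beta,\gamma,\delta$ | 0.4, 0.8, 1, 0.4 | reference setting of the loss combination |
| optimiser | Adam, lr 0.001, weight decay 0.0005 | reference training recipe |
| schedule | halve lr after 4 epochs without val improvement | reference training recipe |
| epochs | 60 (desk profile: 5 + 5) | reference recipe; the desk profile shrinks only epochs and widths |
| batch size | 1 | reference setting (larger batches accumulate gradients) |
| `r_pt` | 2 px | point positives must be discs, not single pixels, to give the attention loss spatial support; 2 px keeps discs inside even the smallest nuclei |
| `ridge_width` | 1 px | the thinnest neighbourhood that marks every inter-cell boundary pixel |
| SLIC `n_segments` | $HW/150$ | superpixels comparable in area to a nucleus |
| SLIC `compactness` | 10 | standard trade-off for Lab-space SLIC |
| CL scope | `per_image` | thresholds and $Q$ estimated within each image bound memory and match per-image label refinement; `pooled` available for ablation |
| CL rounds | 1 | two or more rounds degrade the attention features |
| eval threshold | 0.5 on $f(I)$ | binary task, calibrated output |
| validation split | 20% per seed | training uses validation loss for scheduling, so a held-out fraction is required even though none is prescribed |

## Design choices where the design was open

- **Gradient isolation.** The attention map is treated as a fixed
  weighting inside $L_\mathrm{seg}$, and $f(I)$ as a fixed target inside
  $L_\mathrm{cons}$; each branch is trained only by its own objective.
  Without this, the degenerate solution $f_\mathrm{att}\to 0$ on the
  background short-circuits the masked BCE. `train_config(detach = FALSE)`
  restores fully joint gradients for ablation.
- **Negative target of the attention loss.** The formula puts
  $|1 - f_\mathrm{att}|$ on the ridge pixels as well, so both confident
  nucleus *and* confident background target 1 and the map reads
  "confident region", blanking only the unsupervised boundary band. The
  implementation follows that reading; `att_loss(neg_target = 0)` gives
  the alternative in which ridges target 0.
- **Point displacement.** Noisy annotations are emulated by displacing
  each point by *exactly* r pixels in a uniform random direction (r = 3
  and r = 5 are separate settings, not a 3–5 range; the CLI offers
  `--shift-mode range` for the other reading). The integer displacement is
  chosen from the lattice points whose norm is within 0.5 of r, because
  naive coordinate rounding can err in norm by up to $\sqrt 2/2$.
- **Constraint network shape.** Only the existence of an upsampling
  operation is prescribed, implying an earlier downsample: conv2 runs at
  stride 2 and a 2 x 2 average pool brings the branch to stride 4, where
  conv3 matches the first encoder stage's channels. N (conv5 channels)
  defaults to 3. `h` is squashed with a sigmoid so the L1 comparison with
  a probability map is scale-consistent.
- **Encoder tap for the merge.** "encoder 1" is read as the first
  residual stage (stride 4); conv3 of the constraint network handles
  channel/stride matching.
- **Deformable convolution** is implemented as an offset-predicting
  convolution plus bilinear sampling, switchable per config (off in the
  desk profiles — it is expensive on CPU). Offsets are zero-initialised,
  and with zero offsets the op reproduces the standard convolution
  exactly, which is asserted in the tests.
- **Colour normalisation** uses the Reinhard mean/variance matching in
  CIELab: it is parameter-free and deterministic.
- **Voronoi negatives** are the ridge pixels only; no additional
  background sampling (e.g. colour clustering) is added beyond them.

## Numerical choices

- BCE probabilities are clamped to $[10^{-7}, 1-10^{-7}]$.
- Voronoi ties (equidistant pixels) go to the lowest point index,
  deterministically.
- CL thresholds use strict `>` as specified, relaxed to `>=` only in the
  degenerate $t_j = 1$ case so perfectly confident predictions are not
  all discarded; $\mathrm{round}(nQ)$ rounds half away from zero.
- The networks run one image per forward pass; BatchNorm statistics are
  per-image spatial moments with running averages (momentum 0.1) for
  eval mode. Images whose sides are not multiples of 16 are padded by
  edge replication and cropped back.
- All randomness (weights, splits, shuffling, augmentation, generator)
  derives from explicit integer seeds; two runs with the same seed are
  bit-identical on CPU.

## Desk-scale profile and what it shows

The bundled profile (16 synthetic images, 96 x 96, `net_config("tiny")`,
5 + 5 epochs, flip augmentation) trains in a few minutes on one CPU. At
this scale the pipeline reproduces directions that matter: training loss
decreases, the confident-learning pass raises the *mean* pseudo-label
accuracy, and a fully supervised baseline trained on the true masks
outperforms the weakly supervised result. Absolute IoU/Dice values at
desk scale are not comparable to GPU-scale training on real datasets and
are not meant to be.

One desk-scale caveat deserves emphasis. On these small tiles the
superpixel label's noise is one-directional (SLIC blocks over-cover
nuclei, they essentially never miss one), while the briefly trained
model carries a thin confident-foreground halo around each nucleus —
its output is bilinearly upsampled from half resolution, so a ~1 px
blur is unavoidable. Confident learning therefore combines many large,
correct foreground-removal flips with a scatter of small, incorrect
foreground-addition flips. The net effect improves mean label accuracy,
but on images whose labels were already near-clean the spurious
additions can outweigh the corrections, so the per-image majority of
improvements is not guaranteed at this scale. On full-size tiles
(the regime the method targets) the halo is proportionally negligible.

## Known limitations

- The engine is pure R and single-image; it is deliberately compact and
  fully gradient-checked, but two to three orders of magnitude slower
  than a GPU framework. The `"full"` width preset exists for
  completeness, not for routine use.
- Binary (nucleus vs background) only; no instance separation or
  multi-class heads.
- SLIC is the only superpixel algorithm; whole-slide pyramidal formats
  are out of scope.
- With very few training epochs the model partially memorises the
  superpixel-label noise, which weakens confident learning — visible as
  occasional images whose refined labels are marginally worse.
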