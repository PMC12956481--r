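# pointseg

Weakly supervised segmentation of cell nuclei in H&E histology images
from **one point annotation per nucleus** — no dense masks required.

Dense pixel-level nucleus annotation needs a pathologist and does not
scale; a single click per nucleus does. `pointseg` is for researchers in
computational pathology and biological image analysis who want to train
a binary nucleus segmenter from such point annotations, and for anyone
studying label-noise-robust training: every stage of the pipeline is
exposed as a plain R function and the whole thing runs on a bundled
synthetic-histology generator with exact ground truth.

## Method

Two stages:

**Stage 1 — train on complementary pseudo-labels.** Points are expanded
into a tri-state **Voronoi label** y_v (discs around points = positive,
nearest-point-partition ridges = negative, rest unlabeled; global
topology, one nucleus per cell) and a binary **superpixel label** y_s
(union of SLIC superpixels containing a point; boundary-adhering but
noisy). Three networks train jointly:

- *seg* — residual encoder–decoder (last encoder block dilated, output
  stride 1/16, optional deformable convolutions) with a
  feature-aggregation head: decoder outputs pass through CBAM attention
  blocks, are summed, upsampled bilinearly and squashed to a foreground
  probability map f(I);
- *att* — the same design, smaller encoder, on the 4-channel input
  [RGB, y_s], producing a confidence mask f_att;
- *cons* — a shallow constraint network whose intermediate feature map
  f_cons is added into *seg*'s first encoder stage and whose N-channel
  output h is pulled towards f(I).

with the objective

    L_total = beta * L_seg + gamma * L_att + delta * L_cons
    L_seg  = BCE( f(I) .* f_att , y_s )
    L_att  = sum_{y_v+} |1 - f_att| / |y_v+|  +  alpha * sum_{y_v-} |1 - f_att| / |y_v-|
    L_cons = (1/N) sum_n mean | f(I) - h_n |

(defaults alpha, beta, gamma, delta = 0.4, 0.8, 1, 0.4; Adam, lr 0.001,
weight decay 0.0005, lr halved after 4 epochs without validation
improvement).

**Stage 2 — confident-learning label refinement.** Per class j the
threshold t_j is the mean predicted probability of j over pixels labeled
j; the counting matrix C_ij tallies pixels labeled i but confidently
predicted j; row-calibrating C to the label frequencies and normalising
gives the joint distribution Q between given and latent true labels. For
each off-diagonal (i, j), the round(n * Q_ij) pixels with the largest
margin p(j) - p(i) are flipped, and the model is retrained on the
refined label y_re.

## Worked example

```r
library(pointseg)
res <- run_full(run_config())   # 16 synthetic 96x96 tiles, tiny nets, 5+5 epochs
print(res)
#> Two-stage weakly supervised run: /tmp/.../run-...
#>   stage 1: mean IoU 0.6796, mean Dice 0.8066
#>   stage 2: mean IoU 0.6247, mean Dice 0.7670
#>   label refinement improved or tied 56% of images (flip fraction 0.0158)
```

The run directory contains the generated dataset, both pseudo-labels per
image, both stage checkpoints with per-epoch loss records, the
confident-learning summary (t, C, Q, flip counts), refined labels and
flip masks, IoU/Dice metrics for both stages and a label-quality report.
In this run the refinement raised mean pseudo-label pixel accuracy from
0.9703 to 0.9750; the per-image improvement fraction at this miniature
scale is limited by a ~1 px confident halo in the briefly-trained
model's predictions (see the methods vignette for the analysis).

Individual stages are plain functions: `generate_dataset()`,
`make_pseudolabels()`, `train_stage1()`, `refine_labels()`,
`train_stage2()`, `evaluate_model()`, plus `train_supervised()` for the
fully supervised reference ceiling. A thin CLI with the same stages as
subcommands lives at `inst/cli/pointseg.R`.

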