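# convatt

Screening for mild cognitive impairment (MCI) from the three classic
pen-drawing tasks — clock drawing, cube copying, and trail making — with a
multi-input convolutional network whose feature maps are aggregated by
CLS-token self-attention instead of global pooling.  The package is aimed
at researchers in computational neuropsychology and medical-imaging ML who
want a fully inspectable, dependency-light implementation of the complete
pipeline: data plumbing, soft-label training, attention-rollout and
Grad-CAM explanations, and ROI-based interpretability scoring — plus a
synthetic cohort generator with ground-truth anomaly masks so everything
can be exercised end to end without clinical data.

## The model

Each task image (resized to 256×256, replicated to three channels) is
processed by its own convolutional backbone (VGG16 architecture by
default, a small toy backbone for desk-scale work).  The final
H×L×C feature map is projected by a 1×1 convolution to hidden width D,
its HL pixels become tokens, and a learned CLS token is prepended.  A
stack of single-head self-attention layers

    Attn(Q, K, V) = softmax(QKᵀ / √D) V

mixes the tokens; the final CLS vector of each pathway is the image
representation.  The three vectors are concatenated and mapped through a
two-node softmax layer, giving the MCI probability p.

Training minimizes binary cross-entropy against either hard labels
(1{MoCA < 25}) or soft labels

    y = 1 − σ(m − 24.5),

which encode the diagnostic uncertainty near the cutoff (a score of 24
maps to 0.622, 25 to 0.378).  Heat maps for the attention model come from
attention rollout: per layer A = 0.5 W_att + 0.5 I, chained across layers
by left multiplication; the CLS row, reshaped back onto the feature grid
and upsampled, is the pixel-importance map.  The pooling baseline is
explained by Grad-CAM.  Heat maps are scored by IoU against two ROI
types: a dilated minimal enclosing shape around all drawn ink
(whole-drawing) and anomaly/expert masks.

## Worked example

A fully synthetic experiment: 300 subjects with severity drawn uniformly,
scored with noise, trained at 64×64 with the toy backbone and soft labels
(about four minutes on one CPU):

```r
library(convatt)

dir <- file.path(tempdir(), "demo_cohort")
man <- generate_cohort(300, stats::runif, dir, rng_seed = 101,
                       canvas_size = 128, noise_sd = 1)
table(hard_label(man$moca_score))
#>   0   1
#> 137 163

records <- load_manifest(file.path(dir, "manifest.csv"))
split <- stratified_split(records, seed = 11)
fit <- conv_att(records, split,
                conv_att_config(backbone = "toy", input_size = 64,
                                hidden_dim = 32, ffn_dim = 64, seed = 13),
                train_config(learning_rate = 1e-3, epochs = 30,
                             batch_size = 32, label_mode = "soft",
                             augment_shift = 4, seed = 17))
fit
#> Multi-input drawing classifier (conv_att)
#>   inputs   : clock, cube, trail
#>   backbone : toy, input 64x64
#>   attention: 2 layer(s), D = 32 , ffn = 64
#>   labels   : soft (cutoff 25 )
#>   trained  : 30 epoch(s); final val loss 0.4301, val AUC 0.952

idx <- which(split$partition == "test")
p <- predict_proba(fit, records[idx])
labs <- hard_label(vapply(records[idx], `[[`, 0, "moca_score"))
round(classification_metrics(p, labs), 3)
#> accuracy       f1      auc
#>    0.800    0.830    0.895
```

The model separates healthy from MCI-like subjects on held-out data (AUC
0.895 here) purely from the rendered drawings.  The interpretability side
compares each test image's top-20% rollout heat map with the generator's
anomaly mask, against a spatially permuted copy of the same map:

```r
cmp <- rollout_permutation_iou(fit, records[idx], k_percent = 20, seed = 23)
round(c(n_images = nrow(cmp), mean_iou = mean(cmp$iou_own),
        mean_iou_permuted = mean(cmp$iou_permuted),
        win_fraction = mean(cmp$iou_own > cmp$iou_permuted)), 3)
#>          n_images          mean_iou mean_iou_permuted      win_fraction
#>           109.000             0.023             0.013             0.541
```

On average the trained attention overlaps the planted anomalies well
above the permutation baseline (0.023 vs 0.013), though per-image wins
are far from universal — omission-type defects (a missing digit, an
erased connection) leave no ink for attention to land on; see the methods
vignette for the full discussion.

`run_experiment(run_config(...), out_dir)` drives the same cycle end to
end (generate → split → train → evaluate → explain → IoU curves) and
writes every artifact with a config hash and seed;
`inst/cli/convatt.R` exposes the stages as shell commands, and
`run_ablation()` reproduces the nine-row model-comparison grid with
`report_ablation()` computing absolute and relative deltas against a
named baseline.

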