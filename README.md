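# spineloc

Prompt-guided 2D/3D vertebra localization from calibrated biplanar
radiographs, in pure R (with Rcpp kernels).

## The problem

Minimally invasive spine surgery needs the 3D positions of vertebral body
centroids during the intervention, but the intraoperative modality is 2D
X-ray fluoroscopy. A calibrated biplanar acquisition — one lateral (LAT)
and one anteroposterior (AP) view, each with a known 3×4 projection matrix
P mapping world millimetres to pixels — constrains each landmark to the
intersection of two back-projected rays, yet two hard ambiguities remain:
*depth* (superimposed anatomy, low bone/soft-tissue contrast) and
*semantics* (a chain of nearly identical vertebrae, so level n in one view
must be matched to level n in the other).

`spineloc` implements a context-aware localization network that resolves
both with a user-supplied **point prompt**: a click near the center of the
top-most vertebral body in each view. The pipeline is

1. **Visual feature extraction** — a shared four-level U-Net with a
   spatial-pyramid bottleneck produces d-channel features `f_i` per view;
   images taller than the training window are processed by sliding windows.
2. **Prompt-guided enhancement** — a binary window mask `M_p` (half-width
   `r`) crops reference-vertebra features `f_p`; a cross-attention stack in
   which `f_p` serves as key and value enhances the repeated vertebral
   pattern in `f_i`, giving `f_e`.
3. **Masked features** — the unidirectional squared-distance mask
   `M_d(x, y) = (y − y0)²` is combined as
   `f_m = f_e · 1[M_d > 0] + M_d`, injecting each pixel's vertical distance
   from the prompt (the cue that aligns levels across views).
4. **Sparse dual-attention context module** — N learnable per-vertebra
   embedding grids (d×16×16) run a *coarse* attention over max-pooled
   (stride α) features, the top-k cells are expanded to their α×α blocks,
   and a *fine* attention runs only over those sparse foreground features;
   a linear+logistic head emits one 16×16 heatmap per vertebra slot and
   view. The attention cost drops from `O(L·wh·M·d)` to
   `(L/2)·O((wh/α²)·M·d + k·α²·M·d)`.
5. **Multi-view 3D fusion** — heatmaps are rescaled to image size,
   concatenated with `f_e`, unprojected into a pseudo-3D voxel grid (each
   voxel samples each view bilinearly at its projected pixel; views are
   averaged), refined by a small 3D convolution head, and read out per slot
   by a voxel softmax + **soft-argmax**: `l̃_n = Σ_v p_v · center_v`.
6. **Presence rule** — slot n is reported only if the maximum heatmap
   probability exceeds 0.5 in both views.

Training minimizes `Loss = MSE_2D + Dice_2D + MSE_3D` end to end (AdamW,
weight decay 0.05, batch 2, ground-truth prompts, random vertical crops).

Evaluation uses the standard landmark metrics: PCL@τ (fraction of
landmarks with error strictly below τ), MPE (mean Euclidean error), and
the normalized AUC of the PCL curve between 10 and 50 px/mm.

Because real calibrated biplanar data is scarce, the package ships a
**synthetic phantom generator**: procedural vertebra-chain attenuation
volumes (ellipsoidal bodies on a smooth curve, optional implants and
deformities), ray-integral radiograph rendering on a virtual detector,
rigid pose perturbation (±15° axial, ±5° coronal/sagittal), and exact
projected 2D annotations. Every stage of the pipeline is trainable and
testable on a laptop CPU with no external data.

## Worked example

```r
library(spineloc)

cfg  <- model_config("desk")              # 128 px, d = 16, N = 5 slots
pcfg <- phantom_config()                  # ~19 cm FOV, 3-5 vertebrae
s    <- simulate_biplanar_sample(pcfg, seed = 2005)

train <- lapply(1:50, function(i) simulate_biplanar_sample(pcfg, seed = 1000 + i))
fit   <- train_model(train, cfg, train_config(epochs = 14, seed = 7))

fw <- model_forward(fit$pars, s, cfg)
print(fw$result)
#> <localization_result: 5 slots, 5 valid>
#>   slot  x_mm  y_mm   z_mm pmax_lat pmax_ap valid
#> 1    0  0.98  0.77  30.71    0.508   0.508  TRUE
#> 2    1  0.84  0.39  13.71    0.508   0.508  TRUE
#> 3    2  1.66  3.57 -11.89    0.508   0.508  TRUE
#> 4    3 -2.32 -0.76 -26.50    0.508   0.508  TRUE
#> 5    4 -3.49 -2.00 -25.99    0.508   0.508  TRUE
```

Slots are ordered superior→inferior starting at the prompted vertebra;
coordinates are world millimetres; `pmax_*` are each slot's maximum 2D
heatmap probabilities and drive the validity flag. This unseen phantom
contains four vertebrae at z ≈ {32.6, 11.6, −9.9, −30.8} mm: slots 0-3
recover them with errors of 2-5 mm, while slot 4 is a borderline false
positive (pmax just over the 0.5 presence threshold) sitting on top of the
last true vertebra — the kind of residual error the evaluation metrics
quantify.

Held-out accuracy of the desk profile is measured (and printed) by
`tests/testthat/test-acceptance.R`: after training on 50 phantoms for 12
epochs on one CPU, every prediction on 10 unseen phantoms lands within 20
mm of its vertebra and the prompt-displacement sweep changes MPE3D by well
under a voxel; the mean position error plateaus around 7 mm, short of the
6 mm / 1.5-voxel desk targets that the acceptance criteria assert (those
two expectations are left honestly failing; see the methods vignette on
what bounds desk-scale precision).

Evaluation and robustness helpers:

```r
ev <- evaluate_model(fit$pars, cfg, test_samples, taus = c(10, 20))
ev$pcl; ev$mpe; ev$auc
sweep_prompt_displacement(fit$pars, cfg, test_samples,
                          view = "lat", axis = "x", offsets = -4:4)
```

## Command line

```sh
Rscript inst/scripts/spineloc generate --n 60 --seed 1 --out data/
Rscript inst/scripts/spineloc train    --data data/ --out runs/ckpt.rds
Rscript inst/scripts/spineloc infer    --checkpoint runs/ckpt.rds \
    --image-lat s/lat.pgm --image-ap s/ap.pgm --cameras s/cameras.json \
    --prompt-lat 63,52 --prompt-ap 62,52 --out preds.json
Rscript inst/scripts/spineloc evaluate --checkpoint runs/ckpt.rds --data data/
Rscript inst/scripts/spineloc flops    --preset bispinex
```

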