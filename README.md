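# strokeshape

Shape-space prediction of ischemic stroke lesion growth from CT perfusion.

## What it does

After an acute ischemic stroke, CT-perfusion maps show the already
infarcted **core** (depressed CBV) and the hypoperfused **penumbra**
(elevated TTD). Under successful treatment, the final lesion lies between
the core and the core+penumbra envelope — where exactly depends on how
long the tissue stayed hypoperfused. `strokeshape` predicts the follow-up
lesion from an admission CTP scan and two clinical times:

1. a 3D U-Net segments soft core (`S_c`) and core+penumbra (`S_cp`) maps
   from the CBV and TTD channels;
2. a convolutional auto-encoder embeds each segmentation independently
   into a learned low-dimensional shape space (`y = E(S)`);
3. the follow-up lesion is decoded from the time-normalized linear
   interpolation between the two codes:

   ```
   eta   = t_imaging_to_treatment / (T - t_onset_to_imaging),  T = 10 h
   y_i   = y_c + eta * (y_cp - y_c)
   S_l^  = D(y_i)
   ```

   with a monotone-growth constraint `L_mono(A, B) = sum(max(A_i - B_i, 0))`
   keeping decoded shapes nested along the trajectory.

Training uses the SoftDice overlap
`(2*sum(AB) + eps) / (sum(A^2) + sum(B^2) + eps)` in three phases:
U-Net segmentation, shape-space learning (encoder `E1` + decoder `D`),
and a second encoder `E2` that maps the U-Net's noisy estimates into the
frozen shape space. All network layers and reverse-mode differentiation
are implemented in the package on top of BLAS, so everything runs on CPU.

Clinical CTP cohorts with expert annotations are private, so the package
includes a synthetic generator (`synth_config()`, `generate_dataset()`)
producing nested core/lesion/core+penumbra shapes whose extent grows with
normalized time, with CBV/TTD-like contrast — every stage is trainable
and testable without any download.

## Worked example

```r
library(strokeshape)

# a small synthetic cohort on a 64x64x16 grid
cases <- generate_cases(synth_config(grid = c(64, 64, 16), n_cases = 12,
                                     seed = 1))
names(cases) <- sapply(cases, `[[`, "case_id")

cfgs <- desk_configs(c(64L, 64L, 16L), seed = 1)
unet <- train_unet(cases[1:8], cases[9:10], cfgs$unet, cfgs$train)
cae  <- train_shape_space(cases[1:8], cases[9:10], cfgs$cae, cfgs$train,
                          cfgs$loss)
cae  <- train_prediction_encoder(cases[1:8], cases[9:10], unet, cae,
                                 cfgs$train, cfgs$loss)

case <- cases[[11]]
pred <- predict_followup(case, list(unet = unet, cae = cae), horizon = 10)
pred
#> <prediction_result> method=shape_space eta=0.232 volume=914 voxels
hard_dice(pred$mask, case$lesion_mask)
#> [1] 0.68
```

The printed result says the case sits about a quarter of the way along
its core-to-penumbra trajectory (`eta = 0.232`) and the decoded prediction
covers 914 voxels; the Dice score compares it against the simulated
follow-up lesion. (Numbers come from this 12-case toy run; the reference
experiment below trains on 60 cases and reaches a mean shape-space lesion
Dice of about 0.81 on its 20 held-out cases.)

A command-line interface wraps the same functions:

```sh
inst/cli/strokeshape simulate --out data/ --n-cases 20 --seed 7
inst/cli/strokeshape train --manifest data/manifest.csv --out ckpt/
inst/cli/strokeshape predict --manifest data/manifest.csv \
    --checkpoints ckpt/ --out pred/ --mode auto
```

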