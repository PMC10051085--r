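# lesionseg

Semantic segmentation of gastrointestinal lesions — polyps in
colonoscopy frames, bleeding lesions in wireless capsule endoscopy —
with an **attention residual U-Net** implemented natively in R.

Automatic pixelwise delineation of lesions supports screening at the
scale WCE produces images (tens of thousands of frames per patient).
The package is aimed at researchers who want a self-contained,
inspectable implementation of this architecture family: every layer,
gradient and training step is in the package (convolution primitives in
C++ via RcppArmadillo, everything else vectorized R), with no
deep-learning framework dependency, and a synthetic lesion-scene
generator makes the whole pipeline runnable and testable without
downloading any clinical dataset.

## The model

The network is a U-Net encoder–decoder with two modifications:

* **Residual encoder units.** Each encoder stage computes
  `y = F(x) + x` (Eq.: residual learning), where `F` is two stages of
  3×3 convolution → batch normalization → ReLU, and the shortcut is a
  1×1 projection when channel counts differ. Channel width doubles per
  stage; 2×2 max pooling halves resolution. The decoder uses plain
  convolution blocks (no residual structure) with 2× upsampling.
* **Attention-gated skip connections.** Each skip connection is
  rescaled by coefficients `α ∈ [0,1]` computed by an additive
  attention gate: the encoder map `x_l` (strided 1×1 convolution) and
  the deeper gating signal `g` (1×1 convolution) are summed, passed
  through ReLU, a 1×1 convolution to one channel, and a sigmoid; `α` is
  upsampled bilinearly and multiplied into `x_l` before concatenation.

A final 1×1 convolution + sigmoid yields a per-pixel foreground
probability; thresholding (default 0.5) gives the binary mask. Three
architectures share one builder: `unet` (plain blocks, plain skips),
`attunet` (+gates), `attresunet` (+gates, residual encoder).

Training follows the protocol of the method: Adam (β₁ = 0.9,
β₂ = 0.99) with binary cross-entropy, batch training, paired
flip/rotation/zoom augmentation of training data only, and early
stopping on validation loss with best-weight restoration. Evaluation
reports pixel accuracy `(TP+TN)/(TP+FP+FN+TN)`, Dice coefficient
`2|A∩B|/(|A|+|B|)` and Jaccard index `|A∩B|/|A∪B|`.

## Worked example

```r
library(lesionseg)

# 200 synthetic 64x64 endoscopy-like scenes with ground-truth masks
scenes <- generate_dataset(scene_spec(), 200, seed = 11)
parts  <- split_dataset(scenes, dataset_split(0.6, 0.2, 0.2, seed = 11))

fit <- segnet(parts$train, parts$validation,
              architecture = "attresunet", depth = 3, base_filters = 8,
              config = train_config(batch_size = 10, epochs = 15, seed = 11),
              verbose = TRUE)
#> epoch   1  train loss 0.7768 acc 0.5459 | val loss 1.8587 acc 0.2622 dice 0.2081
#> epoch   2  train loss 0.5352 acc 0.9155 | val loss 0.5225 acc 0.9607 dice 0.7817
#> ...
#> epoch  15  train loss 0.3374 acc 0.9939 | val loss 0.3387 acc 0.9958 dice 0.9773

evaluate_dataset(fit$model, parts$test)
#> <metrics_report> n = 40 images
#>   per-image mean: accuracy 0.9955  dice 0.9761  jaccard 0.9540
#>   pooled pixels:  accuracy 0.9955  dice 0.9798  jaccard 0.9604
```

The per-epoch lines show the training loss falling as the network
learns, validation accuracy and Dice rising; the final report says the
model recovers ~98% of lesion overlap (Dice) on held-out scenes.
(Numbers above are from this exact script; the loss curve mirrors the
method's published behaviour — steadily decreasing loss, accuracy
saturating in the high 90s.)

`predict(fit, image)` returns probability maps, `predict(fit, image,
type = "mask")` binary masks; `plot(fit)` draws the loss curves;
`checkpoint_save()/checkpoint_load()` round-trip trained models.

## Command line

```sh
inst/exec/lesionseg synth    --out data --n 200 --seed 11
inst/exec/lesionseg train    --data data --out run --arch attresunet
inst/exec/lesionseg evaluate --checkpoint run/checkpoint.rds --data data --out eval
inst/exec/lesionseg predict  --checkpoint run/checkpoint.rds --image data/images/scene00001.png --out mask.png
```

Each command writes a `manifest.json` (resolved config, seed, package
version, paths, timestamp) sufficient to re-run it.

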