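# lcanet

Segmentation of low-contrast nodules in ultrasound images with a local and
context-attention network, in pure R (Rcpp kernels, no external
deep-learning framework).

Thyroid nodules in B-mode ultrasound are hard to delineate: the lesions are
low-contrast, their boundaries are weak (blurred), the image is covered in
multiplicative speckle, and nodules vary in size and are often clipped by
the image border. `lcanet` implements an encoder–decoder network built from
three blocks designed for exactly these difficulties, together with its
class-imbalance training loss, the standard segmentation metric suite, a
reproducible training loop, an ablation driver, and a synthetic
ultrasound-phantom generator so the whole pipeline runs end-to-end without
clinical data.

## The model

A U-shaped encoder–decoder whose stages are built from:

* **Context-attention block** — 8×8 query windows attend to overlapping
  10×10 key-value windows (stride *s*, default 1) with a learned relative
  position bias φ:

  `Attn(Q̂, K̂, V̂) = softmax((Q̂ K̂ᵀ + φ) / √C′) V̂`

  In the decoder, queries come from the same-level encoder skip and
  key-value from the deeper decoder stream, fusing fine localization with
  coarse semantics.

* **Backbone block** — a residual local-feature block whose 7×7 receptive
  field is factorized into consecutive 7×1 and 1×7 convolutions
  (14C² instead of 49C² weights, a ≈72% reduction), followed by batch
  normalization, 1×1 convolutions and the Mish activation
  `x·tanh(softplus(x))`.

* **Nodule-adaptive convolution (NAC)** — four parallel branches with
  receptive fields 1, 5, 7, 11 (a 1×1 convolution and 3×3 convolutions with
  dilations 2, 3, 5), mixed by input-conditioned softmax weights
  (0 ≤ αₖ ≤ 1, Σαₖ = 1), so the effective receptive field adapts to the
  nodule scale.

Training minimizes the class-imbalance pixel loss

`L = −(1/HW) Σ R·log( p(1−p)² + p²/2 )`

whose `(1−p)²` factor up-weights misclassified pixels, using AdaBound with
cosine-annealed learning rate and stochastic rotation/flip augmentation.
Evaluation reports Dice, pixel accuracy and Jaccard (percent) plus
precision, recall, FPR and FNR (fractions).

## Worked example

Generate phantoms, fit a small model, and score it:

```r
library(lcanet)

spec  <- phantom_spec(image_size = 64)
train <- generate_dataset(120, spec, seed = 1)
val   <- generate_dataset(30, spec, seed = 500)

cfg <- lca_net_config(depth = 4, widths = c(8, 16, 32, 64),
                      input_size = 64, attn_max_hw = 16)
ctl <- lca_train_control(epochs = 10, batch_size = 1, seed = 42)

fit <- lca_fit(train, val, net = cfg, control = ctl)
print(fit)
#> LCA-Net fit: depth 4, widths 8/16/32/64, 278,249 parameters
#>   blocks: backbone=TRUE attention=TRUE nac=TRUE
#>   trained 10 epochs on 120 samples (loss lca, optimizer adabound)
#>   best validation Dice 62.73% at epoch 9

ev <- evaluate(fit, generate_dataset(30, spec, seed = 900))
print(ev$summary)
#> Dice 57.50%  PA 96.37%  Jaccard 46.70%
#> precision 0.6493  recall 0.5957  FPR 0.0113  FNR 0.4043
```

Ten epochs on 120 images is a quick demonstration, far from converged: the
Dice score is the mean over all nodule sizes (small 20-80 px nodules pull
it down), and pixel accuracy is high because background dominates. The
30-epoch desk-scale study in the test suite reaches a held-out mean Dice
of about 80%. The block arithmetic is available directly:

```r
param_reduction_percent(7)        # 71.43: the ~72% factorization saving
effective_kernel_extent(3, 5)     # 11: the widest NAC branch
split_811(7288)$train |> length() # 5830
```

The mask/metric primitives work on plain matrices:

```r
m <- compute_metrics(confusion_counts(pred, truth))
m$dice
```

A thin command-line front end is installed at `inst/cli/lcanet`
(`simulate`, `train`, `eval`, `ablate` subcommands over PNG datasets).

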