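# MetaFuse

Metadata-conditioned feature fusion for skin lesion image
classification in R.

Image-only convolutional classifiers ignore what a clinician always
has at hand: the patient's sex, age band, the anatomical site of the
lesion, whether it bleeds or itches.  MetaFuse is for researchers who
want those categorical clinical attributes to *condition* the image
representation rather than merely sit next to it.  It implements, with
full training and evaluation machinery and no external data or model
downloads, three fusion blocks acting on the feature map
`X_img ∈ R^(h×w×k_img)` of a convolutional backbone given a one-hot
metadata vector `x_meta ∈ {0,1}^d_meta`:

- **MetaBlock** — gated modulation through two affine maps of the
  metadata,

      f_b(x_meta) = W_f' x_meta + w_0f        (per-channel scale)
      g_b(x_meta) = W_g' x_meta + w_0g        (per-channel shift)
      X = σ( tanh( f_b ⊙ X_img ) + g_b )

  with `W_f, W_g ∈ R^(d_meta × k_img)`; the tanh gate confines values
  to (−1, 1), the sigmoid gate to (0, 1), and the output keeps the
  input's shape.

- **MetaNet** — multiplicative channel reweighting: a two-layer
  subnetwork (affine → ReLU → affine → sigmoid) maps `x_meta` to one
  scale in (0, 1) per channel, which multiplies that channel
  everywhere.

- **MD-Net** — both blocks side by side; each output is globally
  average-pooled, projected to a common dimension `d_fuse`, and the
  two projections are concatenated before the softmax classifier.

Concatenation (pooled features ++ metadata) and image-only baselines
are included so the value of conditioning can be measured.  Around the
blocks: a reproducible one-hot metadata encoder with schema
serialization, a densely connected reference backbone
(`X_L = H_L([X_0, …, X_{L−1}])`), the full training protocol (batch
30, cross-entropy, 3:1 stratified split, flip/colour-jitter
augmentation, LR halving after 10 non-improving epochs, early stop
after 15, cap 150), and an evaluation suite in which balanced accuracy

    BACC = (sensitivity + specificity) / 2     (macro one-vs-rest)

is the primary index.  A synthetic image+metadata generator with a
closed-form Bayes limit makes every claim testable at desk scale; see
`vignettes/metadata-fusion.Rmd` for the methods account.

## Worked example

Four lesion classes whose image template is fully confounded by a
binary metadata field (`metaEffect = 1`): the image alone narrows a
sample to a pair of classes, so no image-only classifier can exceed
BACC 2/3, while image+metadata determines the class exactly.

```r
library(MetaFuse)

cfg <- synthConfig(nSamples = 600, nClasses = 4, metaEffect = 1, seed = 7)
dataset <- generateDataset(cfg)
bayesRates(cfg)
#> imageOnly  withMeta
#> 0.6666667 1.0000000

split    <- splitDataset(dataset, ratio = 0.75, seed = 7)   # 3:1
schema   <- buildSchema(datasetMeta(split$train))
backbone <- tinyDenseBackbone(kImg = 16, seed = 7)
model    <- metaFuseModel(backbone, mdnetParams(dMeta(schema), 16, seed = 7),
                          classes = levels(datasetLabels(dataset)),
                          schema = schema, seed = 7)
fit <- fitModel(model, split$train, trainConfig(seed = 7))
evaluateModel(fit$model, split$test)
#> MetricsReport
#>   accuracy     1.0000
#>   sensitivity  1.0000 (macro)
#>   specificity  1.0000 (macro)
#>   BACC         1.0000  [primary index]
#>   macro recall 1.0000
#>   AUC          1.0000 (macro)
#>   confusion (rows = truth):
#>          predicted
#> truth     class_1 class_2 class_3 class_4
#>   class_1      37       0       0       0
#>   class_2       0      37       0       0
#>   class_3       0       0      38       0
#>   class_4       0       0       0      38
```

The trained MD-Net assembly reaches test BACC 1.0 — above the 2/3
image-only Bayes limit — because the gates learn to route each image
pattern to a different class depending on the metadata value.
Swapping `mdnetParams(...)` for `noneFusion()` (and `schema = NULL`)
caps the same pipeline at the image-only limit.

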