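---
title: "Metadata-conditioned feature fusion: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metadata-conditioned feature fusion: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaFuse)
```

## The problem

Convolutional classifiers for dermoscopy images usually see pixels and
nothing else, while a clinician weighing a lesion also knows the
patient's sex, age, the anatomical site, whether the lesion bleeds or
itches.  Those clinical attributes are categorical, low-dimensional
and — crucially — can change what an image pattern *means*: the same
visual texture can be benign at one site and suspicious at another.
MetaFuse implements a family of *metadata-conditioned fusion blocks*
that let a small vector of encoded clinical attributes modulate the
channels of a convolutional feature map, together with everything
needed to train and evaluate such models end to end: a reproducible
one-hot encoder, a densely connected reference backbone, a training
harness, balanced-accuracy-centred metrics, and a synthetic benchmark
whose optimal achievable performance is computable in closed form.

## The fusion blocks

Let $X_{img} \in \mathbb{R}^{h \times w \times k_{img}}$ be the
feature map of the backbone's last convolutional stage and
$x_{meta} \in \{0,1\}^{d_{meta}}$ the one-hot encoded metadata vector.

**MetaBlock** (gated modulation).  Two affine maps of the metadata
produce per-channel modifiers,

$$f_b(x_{meta}) = W_f^\top x_{meta} + w_{0f}, \qquad
  g_b(x_{meta}) = W_g^\top x_{meta} + w_{0g},$$

with $W_f, W_g \in \mathbb{R}^{d_{meta} \times k_{img}}$.  The block
output is

$$X = \sigma\!\left[\tanh\!\big(f_b(x_{meta}) \odot X_{img}\big)
      + g_b(x_{meta})\right],$$

where $\odot$ multiplies each channel by its modifier, broadcast over
the spatial grid.  The tanh gate confines every value to $(-1,1)$, the
sigmoid gate to $(0,1)$; the output has exactly the shape of
$X_{img}$.  Two readings of the composition are possible (the gated
map as the output, or a second multiplication by $X_{img}$); MetaFuse
takes the gated map itself as the output, because the two gates
decompose exactly that expression and the block's contract is that
output and input shapes agree.

**MetaNet** (channel reweighting).  A two-layer subnetwork
(affine → ReLU → affine → sigmoid) maps $x_{meta}$ to one scale
$s_c \in (0,1)$ per channel and the output is $s \odot X_{img}$.  The
original formulation phrases the layers as one-dimensional
convolutions; on a length-one metadata sequence a kernel-size-1
convolution *is* an affine map, which is how they are implemented
here.  The hidden width is not specified by the source formulation;
it defaults to $d_{meta}$ and is an argument of `metaNetParams()`.
Because $s \in (0,1)$, MetaNet can only attenuate: signs are preserved
and magnitudes never grow, a property the test suite asserts.

**MD-Net** (combination).  Both blocks run on the same feature map;
each output is globally average-pooled to a $k_{img}$-vector,
projected by its own affine map to a common dimension $d_{fuse}$, and
the two projections are *concatenated* (fused length $2 d_{fuse}$).
Where the source material says only that the streams are "shrunk and
extended to the same dimension", two design points were open:

* pooling — global average pooling, the standard reduction for dense
  backbones;
* combination — concatenation rather than summation, so the classifier
  sees both streams unmixed (summation would let one stream cancel
  the other before the classifier ever sees them);
* $d_{fuse}$ — defaults to $\lceil k_{img}/2 \rceil$, keeping the
  fused length close to $k_{img}$.

**Baselines.**  `concatFusion()` appends the raw metadata vector to the
pooled image features; `noneFusion()` uses pooled image features
alone.  Both exist so that the value of *conditioning* (rather than
merely *providing*) metadata can be measured.

There is a genuine ambiguity in the source notation for $k_{img}$
(once the modifier count, once "the number of feature maps"); MetaFuse
adopts the feature-map-count reading throughout, which is the only one
that makes the stated weight shapes
$\mathbb{R}^{d_{meta} \times k_{img}}$ conformable.

## Metadata encoding

`buildSchema()` fixes field order and category order once
(lexicographic in the C locale unless an explicit order is supplied)
so the encoding is bit-for-bit reproducible across machines; the
conventional male-first sex encoding `(1,0)`/`(0,1)` is obtained by
supplying `sex = c("male","female")` explicitly.  Missing values
encode as an all-zero block: it keeps $d_{meta}$ fixed and is the
least-informative neutral code, and it makes the L1 norm of an encoded
record equal its number of non-missing fields.  Continuous age is
binned into quantile bands (`binNumeric()`, deciles by default, edges
exposed so a schema built on one cohort applies to another).  Which
clinical fields feed the model is deliberately a configuration choice,
not a package constant.

```{r}
sch <- metadataSchema(list(sex = c("male", "female")))
encodeRecord(list(sex = "male"), sch)
```

## Backbone contract

A backbone maps `H x W x 3 x N` image arrays to an
`h x w x kImg x N` feature map — always the pre-pooling map, because
the fusion blocks attach to the last convolutional stage, never to a
pooled vector.  Two architectures are registered:

* `tiny-dense-test` — a stride-2 stem convolution, a 2x2 average pool
  and a two-layer dense block (`kImg` channels, 8x8 grid from 32x32
  input).  All tests and the synthetic experiments use it; nothing
  ever needs downloading.
* `densenet169` — a structural adapter with the 169-layer dense
  architecture's exact channel bookkeeping (stem 64; blocks of
  6/12/32/32 layers at growth 32; 0.5-compression transitions;
  `kImg = 1664`).  It uses plain ReLU convolutions without batch
  normalisation and average pooling in the stem, and exists to
  exercise the weight-loading contract and channel arithmetic — it is
  not a trained ImageNet model, and training one is out of scope.

Dense connectivity follows
$X_L = H_L([X_0, X_1, \ldots, X_{L-1}])$: layer $L$ consumes the
channel-concatenation of everything before it, so a block adds
$L \cdot growth$ channels to its input.  Fine-tuning unfreezes the
whole backbone by default; `trainConfig(freezeBackbone = TRUE)` trains
only fusion and classifier.

## Metrics

All metrics generalise the binary definitions one-vs-rest and
macro-average over classes: sensitivity $TP/(TP+FN)$, specificity
$TN/(FP+TN)$, and the primary index

$$\mathrm{BACC} = \tfrac12(\mathrm{sensitivity} + \mathrm{specificity}).$$

The binary form of BACC does not determine its multiclass extension:
macro recall and $(\text{macro sens}+\text{macro spec})/2$ both reduce
to it at $C = 2$.  `MetricsReport` therefore carries both — `bacc` is
the sensitivity/specificity mean (matching the printed definition),
`baccRecall` is macro recall.  A related subtlety: invariance of BACC
to per-class duplication of samples holds exactly for two classes
(where each class's specificity is the other's recall) and for macro
recall at any $C$, but macro specificity at $C > 2$ depends on the
relative prevalence of the negative classes; the tests assert exactly
the invariances that hold.  Classes with no true samples (or no
negatives) are excluded from the corresponding average with a
warning.  AUC is the rank-based (Mann–Whitney) one-vs-rest area, ties
counting one half, macro-averaged; the test suite cross-checks it
against an independent ROC implementation.

## Training protocol

`trainConfig()` defaults encode the reference protocol: batch size 30,
at most 150 epochs, cross-entropy loss, a 3:1 train:test split
(`splitDataset(ratio = 0.75)`, stratified), augmentation on training
samples only (horizontal/vertical flips and brightness, contrast and
saturation jitter of ±0.2), learning-rate halving after 10 epochs
without validation improvement, and early stopping after 15.  Points
the protocol leaves open, decided here once:

* **Validation signal.**  Both schedulers watch validation *balanced
  accuracy* — the primary index — on a stratified fifth of the
  training portion split off inside `fitModel()` when no validation
  set is supplied (the protocol names a train:test ratio but no
  validation set).
* **Optimizer.**  Unstated in the source; MetaFuse uses Adam with the
  configured initial rate 0.001 — the standard stochastic-gradient
  choice for this model family — recorded in every checkpoint
  manifest.
* **Dropout.**  "Used" but not placed; here rate 0.5 on the fused
  feature vector, immediately before the linear classifier, active
  during training only.
* **Class imbalance.**  None beyond reporting BACC; an
  inverse-frequency loss-weight flag exists (`classWeights`) and is
  off by default.
* **Plateau semantics.**  A reduction requires both `lrPatience`
  epochs without improvement *and* `lrPatience` epochs at the current
  rate, so one plateau yields exactly one halving and $n$ reductions
  give $lr_0/2^n$ exactly.  "Improvement" means exceeding the best
  validation BACC by more than `minDelta` (default $10^{-8}$).
* **Best-epoch restoration.**  The parameters of the best validation
  epoch are restored when training ends, however it ends.

With a fixed `config$seed` and single-threaded execution the whole of
training — shuffling, augmentation draws, dropout masks, updates — is
bitwise reproducible; the test suite asserts identical histories
across repeated runs.

## The synthetic benchmark and its Bayes limits

`generateDataset()` draws balanced classes, renders each class as an
oriented sinusoidal stripe texture with a class-specific hue (texture
and colour being the feature families a convolutional extractor
plausibly learns at 32x32), adds Gaussian pixel noise, and draws
categorical metadata uniformly.  One designated field *confounds* the
class-to-template assignment: with probability `metaEffect` (λ) the
rendered template index is the class index rotated by the confounder's
category index.  At λ = 0 metadata is uninformative given the image;
at λ = 1 with a binary confounder, every template is shared by two
classes and only the (image, metadata) pair identifies the class.
Confounding-by-rotation was chosen precisely because it makes the
generative table enumerable: `bayesRates()` computes the optimal
balanced accuracy with and without metadata exactly (assuming the
template is recoverable from the image, comfortably true below a noise
standard deviation of about 0.15 given the well-separated hues; ties
in the posterior break toward the smallest class index, and the
reported rates are those of the accuracy-optimal rule).  For the λ = 1,
C = 4, binary-confounder configuration used in the acceptance
experiment the limits are $2/3$ image-only and $1$ with metadata.

What the generator does *not* emulate: photorealistic lesions, the
class imbalance of real collections, correlated or missing metadata,
label noise, resolution above desk scale.  Passing the benchmark shows
the machinery can learn a genuine image-metadata interaction that
image-only and naive-concatenation models provably cannot; it says
nothing about clinical performance on real dermoscopy data, whose
headline numbers require GPU-scale fine-tuning of pretrained backbones
and are deliberately outside this package's test surface.

Problem sizes used by the experiment (the package's own choice of a
desk-scale operating point): 2,000 samples of 32x32 at $C = 4$, tiny
backbone with $k_{img} = 16$, three seeds per assembly, full training
protocol; unit tests use images of 16x16 or smaller.

## Numerical notes

* Parameters initialize uniformly in $\pm 1/\sqrt{\text{fan-in}}$ from
  a caller-supplied seed; initializers restore the caller's RNG state.
* `tanh`/sigmoid outputs lie in open intervals mathematically;
  in double precision `tanh` saturates to exactly 1 once
  $|z| \gtrsim 18$.  Tests therefore probe the open-interval property
  with draws bounded away from saturation.
* Argmax predictions break ties toward the first class in the model's
  class order; `which.max` semantics apply throughout.
* The compiled convolution kernels (forward, and gradients w.r.t.
  input, weights and bias) are validated against scalar loop oracles
  and central finite differences; the assembled model's gradients were
  additionally verified end to end by finite differences during
  development.
* Training aborts with a diagnostic on a non-finite loss rather than
  silently continuing.

## Limitations

Single-threaded CPU training only; no spatial or cross-attention
fusion; no learned metadata embeddings or imputation; the densenet169
adapter is structural, not pretrained.  These follow the package's
scope: the contribution is the fusion blocks, their training protocol
and their verifiable evaluation, at a scale where every claim the
tests make can be checked exactly.
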