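---
title: "FAR-Net: label-relation learning for multilabel defect images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FAR-Net: label-relation learning for multilabel defect images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surface-defect inspection of agricultural products (here, dried jujubes) is
naturally a *multilabel* problem: one fruit frequently carries several
defects at once, and some defects co-occur systematically — rot and bird
pecking tend to appear together with cracking, and peeling accompanies most
other defects. A plain CNN classifier treats the image as a single instance
and ignores these semantic dependencies. FAR-Net (feature-wise
attention-based relation network) addresses this with four modules stacked
on a convolutional backbone:

1. **Feature extraction (FE).** A backbone `f` maps an input image `H` to a
   feature map `X` of shape h x w x D. The Inception-v3 configuration
   produces 8 x 8 x 2048 from a 299 x 299 x 3 input; this package also
   provides a four-stage "tiny" backbone (8 x 8 x 64 from 64 x 64 inputs)
   so the full pipeline trains on one CPU in minutes.
2. **Label-wise feature aggregation (LFA).** A three-layer convolutional
   block (1x1 -> 1024, 3x3 -> 1024, 1x1 -> C, each with batch
   normalisation, learnable scale, and ReLU) maps `X` to one channel per
   label, and each channel is normalised with a *spatial softmax*:
   `A_l(i,j) = exp(S_l(i,j)) / sum_ij exp(S_l(i,j))`. Channel `l` becomes a
   spatial distribution of evidence for label `l`.
3. **Activation/deactivation (ADA).** A squeeze-excitation gate: channel
   means `z` (squeeze), two C-dimensional fully connected layers with ReLU
   inner and sigmoid outer activation (excitation), and per-channel
   rescaling `A~_l = s_l * A_l` (reweight). The gate suppresses channels of
   absent labels and keeps present ones.
4. **Attention-based relation learning (ARL).** Each gated channel is
   flattened to an h*w vector. For a query label `l`, scaled dot-product
   attention over the other labels gives
   `wS_ml = (W_K fA_m) . (W_Q fA_l) / sqrt(d_K)` and
   `w_ml = softmax_{m != l}(wS_ml)`; the correlation feature is
   `fR_l = sum_{m != l} w_ml (W_V fA_m)`. The fused map `fM = A~ + fR`
   goes through global average pooling and a sigmoid to per-label
   confidences.

Training minimises the sum over labels of binary cross-entropy between the
multi-hot target and the per-label sigmoid confidence (the standard
multilabel reduction to C binary problems), averaged over the batch.

## Design choices on points the architecture leaves open

Several details are under-determined by the verbal description of the
architecture; the package resolves them as follows.

* **Which feature map feeds LFA.** The backbone output is taken as the last
  *convolutional* grid (8 x 8 x 2048 in the Inception layout) rather than a
  fully connected output, since LFA's first layer is a 1x1 convolution over
  a spatial grid. Auxiliary classifiers are not wired into the assembly.
* **Excitation activations.** Both excitation layers are C-dimensional, with
  ReLU on the inner layer and sigmoid on the outer — the standard
  squeeze-excitation design. No bottleneck/reduction ratio is used because
  both layers are explicitly C-dimensional here.
* **Attention scaling.** The score denominator defaults to `sqrt(d_K)`
  (the scaled dot-product attention convention, `d_K = 64`); dividing by
  `d_K` itself is available via `scale = "dk"` in `build_farnet()`.
* **Shared vs per-label relation parameters.** `W_Q`, `W_K`, `W_V` are
  shared across the C query labels by default (the standard attention
  reading, parameters O(1) in C); `per_label_params = TRUE` instantiates
  one set per query label for inference-time experimentation.
* **Domain of the attention maps.** Channels are flattened to h*w = 64
  vectors; `W_Q`/`W_K` map 64 -> d_K and `W_V` maps 64 -> 64.
* **Activation between fusion and pooling.** None.
* **Ablation semantics.** `ablate = "arl"` sets `fR = 0`; `"ada"` passes the
  aggregated map through ungated; removing LFA removes the label-channel
  representation entirely, so it requires removing ADA and ARL as well and
  yields the plain backbone + global-average-pool + C-way linear + sigmoid
  baseline.

### A structural property worth knowing

Because every aggregated channel is softmax-normalised, it sums to exactly 1
over the grid, two consequences follow. First, the squeeze vector is
constant (`z_l = 1/(h*w)`), so the learned gate is a *static* per-channel
scalar rather than an input-conditional one. Second, the pooled logit of the
direct path is bounded by `s_l/(h*w)`; unbounded logits enter only through
the relation features (via `W_V`). Gradients flowing into the LFA/ADA/ARL
stages are therefore smaller than those of the backbone stage by a factor of
order `(h*w)^2`. The staged protocol makes this manageable: per-stage
learning-rate multipliers (`stage_lr_mult` in `train_config()`) let the
label-channel stages take usefully sized steps while the backbone stage
keeps the base rate. Rank-based metrics (AP, mAP) are unaffected by the
squashed logit scale; threshold-based F1 at 0.5 is not meaningful for this
architecture's raw confidences, which cluster just above 0.5, so F1 numbers
are mainly useful for comparing models evaluated the same way.

## The staged training protocol

Training is divided into four stages (SGD with momentum 0.9, weight decay
0.0005, batch size 16, base learning rate 0.001, exponential decay — one
decay step per epoch, factor 0.95 by default):

1. the backbone is trained through its own pooled C-way linear + sigmoid
   head (from pretrained weights when a checkpoint is supplied; from random
   initialisation otherwise, with a logged note);
2. the backbone is frozen and LFA + ADA are trained; ARL remains in the
   forward pass, frozen at its initialisation, so LFA receives gradients
   (through the frozen random value projection) from the start;
3. everything but ARL is frozen and ARL is trained;
4. the whole model is fine-tuned jointly.

Frozen modules are bit-identical before and after a stage — this is tested
via parameter checksums. Stage learning rates, iteration counts, and the
decay factor are configuration; the published hyperparameter table fixes
momentum, weight decay, base rate, policy, and batch size, and is silent on
the rest. Within each stage the best-validation-mAP parameters are kept.

## The synthetic-data generator

No public dataset accompanies the architecture ("data sharing not
applicable"), so the package generates one. The generator reproduces the
published dataset census *literally*: 18 label combinations (8 single, 6
double, 4 triple) with exact counts summing to 1930 samples — 660
single-label, 1200 double-label, 70 triple-label, hence a 65.8% multilabel
fraction and a 48.4% peeling frequency. Co-occurrence therefore follows the
census rather than sampled conditional probabilities, which makes the
printed census statistics exactly recomputable; the co-occurrence prior
(rot/pecking with cracking, peeling with most defects) is embodied in which
combinations exist.

Each sample is a disc-shaped "fruit" on a dark background with one
geometrically distinct, locally confined motif per label: a speckle patch
(russeting), a medium dark blob (mild rot), a large dark blob (severe rot),
a thin curved line (cracking), parallel ridges (shriveled), a bright
irregular patch (peeling), and a small puncture cluster (bird pecking); the
"normal" label renders background only and never co-occurs with defects
(the census shows it only alone). Motif positions are uniform inside the
disc; contrast jitter (mixing weight 0.55-1.0) and Gaussian pixel noise
(sd 0.04) keep per-label evidence imperfect, so co-occurrence structure
carries usable signal. Rendering is a pure function of
(combination, motif parameters, seed).

What the generator does **not** emulate: photographic texture, lighting and
pose variation, occlusion between defects, class-conditional shape of real
jujubes, and annotation noise. Tests passing on this data demonstrate that
the architecture, gradients, training protocol and metrics are implemented
correctly and that the relation mechanism can exploit co-occurrence — they
do not demonstrate real-world defect-classification accuracy, and the
published accuracy tables on the real dataset are out of reproduction scope.

The default image side is 64 px (desk scale); 299 px matches the Inception
configuration. The 3:1:1 train/validation/test split is stratified by label
combination with largest-remainder rounding — every census count is
divisible by 5, so the census split is exactly 1158/386/386.

## Numerical choices

* Spatial softmax and the relation softmax subtract the per-slice maximum
  before exponentiation; the loss uses the log-sum-exp form of
  BCE-with-logits. Batch normalisation uses batch statistics during
  training, running averages (momentum 0.1) at inference, epsilon 1e-5.
* Binarisation for counting metrics is strict (`confidence > threshold`,
  default 0.5); ties at the threshold count as negative.
* AP is the every-point average precision: the mean of running precision at
  each positive in descending-score order, with stable tie-breaking. 0/0
  precision or recall is reported as 0 with an explicit `undefined` flag.
* Convolutions are evaluated as im2col gathers plus one BLAS multiply;
  backward passes are hand-derived and verified against finite differences
  and nested-loop oracles in the test suite.
* Weight init: He-uniform for convs; `W_V` is initialised at a reduced
  scale (0.3/sqrt(h*w)) so the untrained relation path starts as a small
  perturbation of the gated features.

## The desk-scale relation experiment

`run_relation_experiment()` is the package's headline experiment: for each
seed it generates the census dataset at 64 x 64, trains the full tiny
FAR-Net and its without-ARL ablation under the identical staged protocol
(the ARL-only stage has nothing to train in the ablation and is skipped),
and reports test mAP for both plus the attention contrast — the mean
symmetrised relation weight over label pairs that ever co-occur in the
census versus pairs that never do. The expected direction mirrors the
published module-occlusion result: relation learning should not hurt mAP,
and learned attention should be larger within co-occurring pairs.

Problem sizes are chosen for a single CPU: 1930 images at 64 x 64, the
tiny backbone, scaled-down per-stage iteration counts (defaults in the
function signature), base learning rate 0.03 with stage multipliers for the
label-channel stages (see above), three seeds. These are the package's
desk-scale study conditions; they were fixed from pilot loss/learning-curve
behaviour of the two training paths, not tuned against any expected
outcome. Two measurement details matter: the two arms share the (identical)
stage-1 training, and test rows are scored in a seeded shuffled order,
because the ablated architecture produces tied confidences and a tied
ranking must not inherit the generator's combination-blocked record order.

What should one expect? The mAP direction (full model at least as good as
the ablation) follows directly from the structural property above: the
ablated model's pooled logits are constant across images, so any learned
ranking beats it. The attention half of the story is weaker by
construction: the spatially pooled relation feature of query `l` reduces to
`sum_m w_ml <fA_m, c>` with a single learned spatial profile
`c = rowMeans(W_V)/(h*w)`, so the value a source channel contributes is a
positional readout of where that channel focuses — with motif positions
uniform in the disc, it carries little information about whether the
source's label is present. Without a presence-coding value path, gradient
descent has no sustained pressure to align attention with label
co-occurrence; the learned weights are free to route instead toward a few
globally informative channels (a large, salient motif such as severe rot is
the case where a presence-correlated value readout can still emerge). The
co-occurrence contrast statistic is therefore reported by
the experiment and asserted by the acceptance suite, but the literal
architecture gives it no mechanism to become positive at this scale; see
the test suite for the measured outcome.

## Known limitations

* Training the per-label-parameters ARL variant is not implemented (it is
  available for inference); the shared-parameter form is the default
  reading and the one trained.
* The Inception-v3 configuration reproduces the published stage *output
  shapes* with one conv(+pool) stack per stage; parallel inception branches
  and per-cell parameter counts are out of scope, and no pretrained weights
  ship with the package (loading a checkpoint is supported).
* The squashed-logit property above means absolute confidence calibration
  is poor by construction; comparisons should use rank metrics or a
  calibrated threshold.
* Everything runs on CPU in plain R; wall-clock scale is minutes for the
  desk-scale experiment, not suitable for 299 px training.
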