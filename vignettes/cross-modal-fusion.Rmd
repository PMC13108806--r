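---
title: "Cross-modal fusion of medical images and laboratory time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal fusion of medical images and laboratory time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmfusion)
```

## The problem

Clinical classification tasks increasingly pair an imaging study (a chest
radiograph, a dermoscopic photograph) with a short panel of laboratory time
series: `K` indicators (blood counts, inflammatory markers) measured at `T`
successive draws. The two modalities are structurally heterogeneous — one is
spatial, one is temporal-tabular — and naive concatenation of features is
both redundant and poorly aligned semantically. `cmfusion` implements a
framework that (i) encodes both modalities into a shared `d`-dimensional
space, (ii) prunes the concatenated feature with a learned, dynamically
thresholded gate, (iii) fuses the surviving branches with cross-modal
attention, and (iv) trains the whole pipeline with a three-term objective
balancing classification, alignment and sparsity.

## Model

**Image encoder.** The image is cut into non-overlapping $P \times P$
patches, each flattened and linearly embedded into $\mathbb{R}^d$; a
learnable class token is prepended and a learnable position embedding added.
The sequence passes through `depth` pre-norm transformer blocks (multi-head
self-attention plus a GELU feed-forward with expansion `mlp_ratio`, both
residual), and the final class-token state is the image feature
$F_I \in \mathbb{R}^d$.

**Laboratory encoder.** Each time step $x_t \in \mathbb{R}^K$ passes through
$\mathrm{ReLU}(W_2\,\mathrm{ReLU}(W_1 x_t + b_1) + b_2)$ with
$W_1 \in \mathbb{R}^{K \times d/2}$, $W_2 \in \mathbb{R}^{d/2 \times d}$,
and the `T` outputs are mean-pooled into $F_L \in \mathbb{R}^d$. The printed
weight shapes act on single time steps, so pooling over `T` is the natural
way to reduce the matrix input to one vector; flattening the whole $T \times
K$ matrix would contradict those shapes. The outer ReLU makes $F_L$
elementwise nonnegative — and therefore gives the concatenated feature a
*natural* population of exact zeros wherever a unit is inactive for a whole
series, which matters when interpreting feature sparsity (below).

**SmartTrim gate.** The concatenation $F_{cat} = [F_I; F_L] \in
\mathbb{R}^{2d}$ is scored by a dimension-preserving sigmoid layer, $S =
\sigma(W_s F_{cat} + b_s) \in (0,1)^{2d}$, and thresholded at
$$\tau = \mathrm{mean}(S) + \lambda \cdot \mathrm{std}(S),$$
with the *population* standard deviation (the definition is frozen so
independent recomputations agree bit-exactly). The binary mask $M_j =
\mathbf{1}[S_j \ge \tau]$ (inclusive, so a constant score vector keeps
everything) gates the feature elementwise: $F_{prune} = F_{cat} \odot M$.
Because the rule is a percentile cut, a score distribution with
$(\max - \mathrm{mean})/\mathrm{std} < \lambda$ would retain nothing; a
guard then keeps the single highest-scoring entry (lowest index on ties) so
fusion never receives the zero vector. Scores, threshold and mask are
per-sample quantities. $\lambda$ defaults to 0.3; larger values prune more
aggressively (feature retention is non-increasing in $\lambda$, which the
sweep protocol checks empirically on trained models).

**Fusion and head.** The gated vector splits back into branches
$F'_I, F'_L$. Queries come from the image branch and keys/values from the
laboratory branch: $Q = W_Q F'_I$, $K = W_K F'_L$, $V = W_V F'_L$, and
$\mathrm{Attn} = \mathrm{softmax}(QK^\top/\sqrt{d})\,V$. Applied literally to
single vectors the softmax is over one key and equals 1, so
$\mathrm{Attn} = W_V F'_L$ exactly; this degenerate vector mode is the
default and is asserted, not hidden, by the test suite. Setting
`tokens = m > 1` reshapes each projected vector into `m` tokens of dimension
`d/m` and runs standard scaled dot-product attention across tokens, making
the attention genuinely non-trivial; both modes share one code path (vector
mode is `m = 1`). The fused feature is
$F_{fusion} = \mathrm{LayerNorm}(\mathrm{Attn} + F'_I)$ (one block, one
head; the source describes no stacking), followed by a bottleneck head:
$F_{refine} = \mathrm{ReLU}(W_b F_{fusion} + b_b)$ of width $d/2$ (floored
at 4 for very small `d`) and a softmax classifier over `C` classes.

**Objective.**
$$\mathcal{L} = \mathcal{L}_{cls} + \alpha\,(1 - \cos(F_I, F_L)) +
\beta\,\overline{M},$$
with cross-entropy $\mathcal{L}_{cls}$ (probabilities clamped at $10^{-12}$
before the log), $\alpha = 0.1$, $\beta = 0.05$. Taken literally the
sparsity term rewards masking everything; $\beta$ is therefore the
pruning-pressure knob, counterbalanced by the classification gradient
through the gate. A zero-norm embedding would make the cosine undefined;
the exported metric raises an error, while the training loss counts such a
sample as fully misaligned (contribution 1) with zero gradient.

## Training through a hard mask

The hard mask is piecewise constant, so its true gradient is zero almost
everywhere. Training uses a straight-through convention: the forward pass
applies the hard mask; the backward pass sends the gating-path gradient to
$F_{cat}$ through the *hard* mask (the true gradient of the computation
actually performed) and the mask-generation gradient to the scores through
the sigmoid relaxation $\sigma((S - \tau)/t)$ with temperature $t = 0.1$ and
$\tau$ treated as a constant. The sparsity loss is computed on the relaxed
mask during training and on the hard mask in evaluation reports. All other
gradients (transformer blocks, attention, layer norms, both encoders, the
convolutional substitute) are exact; the test suite verifies every parameter
array against central finite differences on jittered weights (jittering
moves the check off ReLU kinks, where a subgradient and a finite difference
legitimately disagree).

## Initialization

Custom modules are Xavier-uniform; biases are zero; class token and position
embeddings are $N(0, 0.02^2)$. Three deliberate departures from plain
Xavier, all config fields:

* `residual_scale = 0.01`: each block's attention output projection and
  second feed-forward weight are scaled down at initialization, so blocks
  start near identity. The reference recipe fine-tunes a pretrained
  backbone; training the same architecture *from scratch* on a small cohort
  with full-scale residual branches floods the concatenation with
  high-variance random image features that the optimizer memorizes before
  the informative laboratory stream is heard (empirically: validation
  accuracy stalls near chance-plus on data both of whose modalities are
  linearly separable). Near-identity blocks remove that pathology while
  leaving the image pathway trainable.
* `scorer_init_scale = 0`: the gate's scorer starts at exactly zero, so
  every importance score begins at 0.5, the inclusive threshold rule keeps
  the gate fully open, and any score differentiation is learned rather than
  inherited from a random dense layer — the usual zero-init convention for
  gating layers. With a randomly initialized scorer the per-dimension mean
  scores start with a spread (~±0.2) that hundreds of optimizer steps
  cannot overcome, and the gate destroys information at random.
* `lab_init_gain = 2`: laboratory inputs are min–max scaled to $[0,1]$,
  which under plain Xavier leaves $F_L$ an order of magnitude smaller than
  $F_I$; the gain rebalances the streams.

## Optimization recipe

AdamW (moments 0.9/0.999, decoupled weight decay $10^{-5}$ applied to
weight matrices only), batch 32, peak learning rate $10^{-4}$ reached by a
5-epoch linear warmup and annealed cosinely to $10^{-6}$ at the final
epoch, early stopping on validation macro F1 with patience 10 and
restoration of the best weights. The desk-scale default is 30 epochs (the
full-scale recipe uses 100). Divergence (non-finite loss) aborts with a
diagnostic. All randomness (initialization, epoch shuffles, augmentation,
perturbation draws) derives deterministically from the run seed, so a rerun
with the same seed reproduces histories and reports bit-identically.

## Synthetic data: what it emulates and what it does not

Public image archives for this task exist, but their paired laboratory
series are partly simulated and not distributed, so the package ships a
generator whose structure mirrors the reported data: `T` in 8–12, `K` in
8–15, 4–14 classes. Each class plants (i) an image motif — a Gaussian bump
at a class-specific location, amplitude `signal_strength` in units of the
unit pixel noise — and (ii) a laboratory temporal template (class-specific
sinusoid plus offset) on the signal-carrying dimensions. A per-sample latent
$z \sim N(0,1)$ enters both modalities with weight `cross_modal_coupling`
(image: a smooth horizontal gradient; laboratory: a constant shift on signal
dimensions), creating genuine cross-modal correlation beyond the label.
Exactly `round(redundant_fraction * K)` dimensions are pure noise. A small
fraction of entries (2% by default) is set missing to exercise the
imputation path.

The reference study condition (`preset_strong_signal()`) is 600 samples, 4
classes, 32×32×3 images, `T = 10`, `K = 8`, half the dimensions redundant,
amplitude 3, coupling 0.8 — chosen so a nearest-class-mean classifier on raw
laboratory features exceeds 90% accuracy, the sanity floor the training
tests build on.

What the generator does *not* emulate: anatomical structure and acquisition
artifacts in the images, heavy-tailed or unit-heterogeneous laboratory
distributions, label noise, class imbalance, and missingness that is
informative rather than random. Passing tests therefore demonstrate that
the machinery optimizes what it claims to optimize under controllable
conditions — not clinical performance.

## Preprocessing

Images: bilinear resize to the configured size (default 224×224; the toy
preset uses the native 32×32), then per-image, per-channel z-score (the
source does not fix the scope; per-image is self-contained and leaks
nothing). A zero-variance channel maps to all zeros. Training-split
augmentation order is fixed as flip (p = 0.5) → area-ratio crop in
[0.8, 1] with resize back → Gaussian blur with sd uniform in [0, 0.1]
pixels. Laboratory series: per-feature statistics are computed on the
training split only and frozen; values outside mean ± 3·sd are marked
missing (removal would change `T`, so mark-and-impute is used instead),
missing values take the training median, min–max scaling maps to [0, 1]
(a constant feature maps to 0.5), then linear interpolation along time to
the target length. Robustness perturbations re-use these pieces: Gaussian
image noise with variance `intensity · v_max`, and uniform random masking
of exactly `round(fraction · T · K)` entries re-imputed with the training
median.

## Experiment protocols and problem sizes

The package runs its protocols at sizes chosen to keep a full desk run in
minutes: the end-to-end check trains the toy full model (d = 64, depth 2,
4 heads) on the 600-sample preset for up to 30 epochs, three seeds; the
λ sweep trains 8-epoch models at λ ∈ {0.1, …, 0.5} over three seeds (short
training keeps the comparison close to the mask rule itself); the ablation
grid runs its seven rows on a 400-sample dataset for 8 epochs, three seeds;
gate-selectivity training uses a narrower model (d = 32, depth 1) for 100
epochs with early stopping disabled, because the scorer — deliberately
starting from zero — accumulates its differentiation signal slowly.

The `-ViT` ablation replaces the transformer with a 3-block convolutional
encoder (3×3 convolutions, ReLU, 2×2 mean pooling, channels 8/16/32, global
average pooling, linear projection to `d`); the source names no substitute,
so one is defined here and held fixed. `-SmartTrim` passes `F_cat` through
unchanged; `-CMT` feeds the gated concatenation to the head through a
linear 2d → d adapter.

**Interpreting feature sparsity.** Sparsity is the percentage of exactly
zero entries in the gated feature. Because the laboratory encoder ends in a
ReLU, `F_cat` has a natural zero rate (~15–20% at desk scale) even with the
gate disabled; gate-off ablation rows therefore show that floor rather than
0%, and gated rows sit far above it.

**Gate selectivity.** Importance scores live on the 2d embedding, not on
the raw `K` laboratory dimensions, so "does the gate prefer signal-carrying
dimensions?" needs an attribution. `lab_dim_importance()` reports, for each
raw dimension `k`, the mean over samples of
$\sum_j S_{d+j}\,|\partial F_{L,j} / \partial x_{t,k}|$ using the exact
piecewise-linear Jacobian of the laboratory MLP averaged over time steps —
the score mass the gate allocates to pathways fed by dimension `k`.

**Cross-validation** runs `n_repeats` independent stratified shuffles of
`k` folds each, refits per fold, and carves a stratified 15% of the
training folds as the early-stopping monitor (the held-out fold is never
used for stopping).

## Numerical conventions

* Population standard deviation in the threshold rule; inclusive ≥ in the
  mask rule; empty-mask guard keeps the top score, lowest index on ties.
* Layer-norm ε = 1e-5, affine initialized to identity.
* Argmax ties in prediction break toward the lowest class index.
* F1 and AUC are macro-averaged for more than two classes; AUC is the
  pairwise rank statistic (ties one half), one-vs-rest per class; F1 of an
  absent class is 0.
* Cohen's kappa returns 1 in the degenerate all-mass-in-one-cell case.
* FLOPs count 2 per multiply-accumulate plus bias adds, matmuls only
  (norms, activations and softmaxes excluded); parameters count trainable
  arrays only. Vector-mode fusion counts only the value projection, since
  queries and keys are not computed in that mode.
* Largest-remainder allocation in the stratified split, remainder ties
  broken by a per-class rotating preference so the rounding surplus spreads
  across splits.
* 8-bit PNG on disk behind a recorded per-dataset affine transform;
  downstream per-image standardization is invariant to the affine part.

## Known limitations

* Vector-mode attention is degenerate by construction; token mode exists
  but the literal equations remain the default.
* The gate masks features, not parameters: no structural parameter removal
  happens, and parameter counts are unaffected by λ (they are reported, not
  targeted).
* The from-scratch initialization choices above are load-bearing at desk
  scale; fine-tuning a pretrained backbone would likely relax them, but no
  pretrained weights ship with the package (a weight map can be loaded into
  `cmf_model()`'s parameter list by name).
* Training is plain R; the desk-scale presets train in seconds to a few
  minutes on one CPU core, but the full-scale configuration (d = 768,
  depth 12, 224×224), while constructible and correct, is not practical to
  train here.
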