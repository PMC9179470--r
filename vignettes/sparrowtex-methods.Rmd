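---
title: "Methods: Gabor preprocessing, MDConv features, stacked GRUs and chaotic sparrow search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gabor preprocessing, MDConv features, stacked GRUs and chaotic sparrow search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sparrowtex` is a desk-scale pipeline for multi-class texture image
classification: Gabor filter-bank denoising, a mixed-depthwise-convolution
feature extractor, a stacked GRU classification head, and a chaotic sparrow
search optimizer that tunes the classifier's hyperparameters by minimizing
validation error rate. This vignette documents the models, their
assumptions, the numerical choices behind each module, and what the tests
do and do not establish.

## Gabor preprocessing

The preprocessing stage convolves each grayscale plane with the real part
of a 2-D Gabor kernel

$$G(a, b) = \exp\!\Big(-\frac{a'^2 + \gamma^2 b'^2}{2\sigma^2}\Big)\,
\exp\!\big(i\,(2\pi a'/\delta + \psi)\big), \qquad
a' = a\cos\theta + b\sin\theta,\;\; b' = -a\sin\theta + b\cos\theta,$$

a band-pass, orientation-selective operator. Parameters, with units and
defaults:

* `delta` — carrier wavelength in pixels (default 4 in the pipeline
  stage). Texture within roughly one octave of this wavelength passes.
* `theta` — orientation in radians, normalized into $[0, \pi)$; the
  half-turn range suffices because $\theta + \pi$ duplicates the response
  up to sign.
* `psi` — phase offset; 0 and $\pi/2$ select the even and odd components.
  The pipeline uses the even ($\psi = 0$) filter.
* `gamma` — aspect ratio (default 0.5, mildly elongated along the carrier).
* `bw` — spatial-frequency bandwidth in octaves (default 1). When given,
  the envelope width is derived as
  $\sigma = (\delta/\pi)\sqrt{\ln 2 / 2}\,(2^{bw}+1)/(2^{bw}-1)$, which is
  linear in $\delta$ and strictly decreasing in `bw`; `bw = 0` is a pole
  and is rejected.

Design choices where convention had to be fixed:

* **Kernel support.** Truncated at `half_extent = ceiling(3σ)`, the usual
  three-standard-deviation envelope coverage; configurable.
* **Borders.** Reflect padding with same-size output, avoiding the edge
  ringing zero padding produces on small tiles. A `"zero"` border is
  available and is what the brute-force convolution oracle in the test
  suite uses.
* **Convolution orientation.** True convolution (kernel flipped), so an
  impulse reproduces the flipped kernel — the property the tests pin.
* **Bank.** Four orientations $\{0, \pi/4, \pi/2, 3\pi/4\}$ averaged into
  one plane. Averaging even-phase responses acts as an
  orientation-agnostic band-pass smoother; it is a denoising stage, not a
  feature code.
* **Color.** Channels are collapsed by an unweighted mean before
  filtering; the discriminative signal in this pipeline is texture, not
  color, and the unweighted rule is the simplest reproducible one.
* **Naming.** The pipeline stage is exposed both as `gabor_denoise()` and
  under its conventional stage alias `gf_preprocess()`; the kernels are
  Gabor filters (the "Gaussian" in the stage name refers to the envelope).

## MDConv feature extraction

A mixed depthwise convolution partitions `M` input channels into `C`
contiguous groups and filters each group depthwise with its own odd kernel
size, giving one layer several receptive-field scales at depthwise cost.
The extractor is deliberately the smallest structure that exercises every
mechanism: three blocks of [MDConv → pointwise 1×1 → ReLU], widths
(16, 32, 64), kernel sizes (3, 5) in two near-equal groups, stride 1,
same padding, global average pooling at the end. The feature length
therefore equals the last width (64) regardless of input resolution.
A one-channel input degenerates to a single group with the smallest
kernel. Weights are He-initialized from the extractor seed; the package
supports warm-starting from a previous fit's weights but ships no
pretrained parameters, and the extractor is used with fixed random
weights in the shipped pipeline — the classifier, not the extractor, is
trained. Random convolutional features followed by pooling are a standard
cheap featurizer and are sufficient for the synthetic textures; users with
more compute can train the extractor externally and inject weights.

The module also carries the cost-accounting identities for
depthwise-separable convolution: parameters $D_k^2 M + MN$ against
$D_k^2 M N$, multiplies $D_k^2 M D_F^2 + M N D_F^2$ against
$D_k^2 M N D_F^2$, ratio exactly $1/N + 1/D_k^2$ — independent of $M$ and
$D_F$, below 1 exactly when separable wins (always for $D_k \ge 3$,
$N \ge 2$; the direction flips at the degenerate $1{\times}1$,
single-output case, where the ratio is 2).

## Stacked GRU classifier

Each length-64 feature vector is chunked, in index order, into 4 time
steps of 16 values (`featuremap_to_sequence()`); a feature vector has no
intrinsic temporal order, so the chunking is simply a fixed deterministic
partition that lets the recurrent stack mix feature blocks sequentially.
The cell is the standard GRU,

$$u = \sigma(W_u h + U_u x + b_u),\quad r = \sigma(W_r h + U_r x + b_r),$$
$$\tilde c = \tanh(W_c (r \odot h) + U_c x + b_c),\quad
h' = u \odot \tilde c + (1 - u) \odot h,$$

stacked so that layer $i \ge 2$ consumes layer $i-1$'s hidden state at the
same step; all $h_0 = 0$. The top layer's final state feeds an affine
softmax head. Defaults: 2 layers, hidden size 16, learning rate 0.01,
dropout 0.5, batch size 5, 50 epochs, plain SGD on cross-entropy —
the conventional settings for this architecture at this scale, and the
first four are exactly the dials the optimizer tunes.

Numerical and design details:

* **Standardization.** Features are z-scored with training-set mean and
  standard deviation (stored in the fit, applied at prediction). Without
  it, pooled ReLU features have heterogeneous scales and SGD at the
  default rate collapses to the majority class.
* **Dropout placement.** Inverted dropout on inter-layer hidden states
  only, disabled at inference; with one layer there is nothing to drop.
* **Determinism.** Initialization, shuffling and dropout masks all derive
  from the fit seed; two same-seed runs produce identical parameters.
* **Softmax stability.** Logits are max-shifted before exponentiation;
  per-sample loss clamps probabilities at $10^{-12}$.
* **Gradients.** Backpropagation through the stack is implemented
  analytically and verified against central finite differences (worst
  coordinate error below $10^{-6}$ at $\varepsilon = 10^{-6}$) and the
  forward pass against an independent scalar-loop oracle.

## Chaotic sparrow search

The optimizer maintains $N$ positions in a box $[a_d, b_d]^D$. Each
iteration, sorted by fitness (minimization):

* **Discoverers** — the best `pd_frac · N` (default 0.2). One alarm value
  $R_2 \sim U(0,1)$ is drawn per iteration; if $R_2 < ST$ (safety
  threshold, default 0.8) each discoverer contracts,
  $x \leftarrow x\,e^{-i/(\alpha T)}$ with rank $i$ and
  $\alpha \sim U(0,1]$ (zero is remapped to 1 since $\alpha$ divides);
  otherwise each takes a shared normal step $x \leftarrow x + Q$,
  $Q \sim N(0,1)$ per sparrow, on every coordinate.
* **Joiners** — the rest, with global rank $i$. If $i > N/2$ (a "hungry"
  joiner): $x_d \leftarrow Q\,e^{(x_{worst,d} - x_d)/i^2}$. Otherwise the
  joiner forages around the best discoverer position after its move:
  every coordinate of that position is offset by the mean over dimensions
  of $\mathrm{rand}(-1,1)\,|x_d - x_{best,d}|$ with a fresh uniform draw
  per dimension. The update formula's sum over dimensions is read
  literally — a scalar offset shared by all coordinates; this keeps a
  joiner sitting exactly at the best position fixed.
* **Vigilantes** — a random `sd_frac · N` subset (default 0.1). A sparrow
  whose fitness differs from the global best jumps relative to the worst
  position, $x_d \leftarrow x_{worst,d} + \beta\,|x_d - x_{worst,d}|$,
  $\beta \sim N(0,1)$; the sparrow at the global best steps by
  $K\,|x_d - x_{worst,d}| / ((f_i - f_w) + e)$ with $K \sim U(-1,1)$ and
  stabilizer $e = 10^{-8}$ guarding the degenerate $f_i = f_w$ case
  (a warning is raised if the denominator is below $e/2$).
* **Chaotic local search.** A logistic-map value
  $\rho_{k+1} = 4\rho_k(1 - \rho_k)$ (seed $\rho_1 = 0.123$ by default;
  the rational fixed/periodic points 0.25, 0.5, 0.75 and the endpoints
  are rejected) is mapped into the box as $P_d = a_d + \rho\,(b_d - a_d)$
  and blended with the incumbent best as
  $CL = (1 - SC)\,TP + SC\,P$, $SC = (T - t + 1)/T$ — pure chaotic
  exploration at $t = 1$, shrinking toward the incumbent as $t \to T$.
  The mapping uses the box's lower corner as offset so the candidate is a
  convex combination of two feasible points and stays in bounds by
  construction.

Remaining conventions: positions are clipped (projected) to the box after
every phase; the chaotic candidate is accepted only on strict improvement
of the global best (greedy elitism, which makes the recorded best-fitness
history non-increasing by construction) and then replaces the worst
population member; all fitness values are re-evaluated once per sparrow
per iteration, plus one candidate evaluation, for a logged budget of
$N + T(N + 1)$ evaluations; population splits round to at least one
sparrow per role. The population seed fixes everything; same-seed runs
are bit-identical.

For hyperparameter tuning (`cssa_tune()`), each search dimension declares
bounds and a type: continuous, integer (positions round and clamp), or
log-scale (the optimizer walks log-space — appropriate for learning
rates). The default space is learning rate $[10^{-3}, 10^{-1}]$ (log),
dropout $[0, 0.8]$, batch size $[2, 16]$, hidden size $[4, 32]$
(integers). The objective is the validation error rate in percent —
identical, by construction, to $100 -$ overall accuracy.

## Metrics

From a $K \times K$ confusion matrix (rows = truth), each class is
binarized one-vs-rest and seven metrics are computed on unrounded counts,
reported in percent: accuracy, precision, recall, specificity, F-score,
MCC and G-mean ($\sqrt{\text{recall} \times \text{specificity}}$). The
macro row is the unweighted mean over classes, computed on unrounded
per-class values; rounding (half away from zero, 2 decimals) happens only
at report time. A zero denominator (e.g. a class never predicted in a
small run) reports 0 for that metric and raises a `degenerate` flag
rather than erroring. `confusion_from_diagonal()` reconstructs a matrix
from published per-class correct counts and totals — recall and macro
recall depend only on those, so the proportional allocation of the
off-diagonal mass is immaterial for them.

## The synthetic generator

`dataset_spec()` defaults to an 8-class collection with the class
proportions of a benign/malignant histopathology dataset: A 106, F 237,
PT 115, TA 130 (benign, 588), DC 788, LC 137, MC 169, PC 138 (malignant,
1232), 1820 images of side 64. Each class is a parametric texture family:
an oriented sinusoidal grating at a class-specific orientation
($(k-1)\pi/8$) and frequency ($3 + k$ cycles per side) plus a Gaussian
blob field of class-specific density ($2k$ blobs), with additive Gaussian
pixel noise ($\sigma = 0.05$ on the unit intensity scale) and random
phase/blob placement per image. Every image is a pure function of the
spec seed.

The generator emulates the *statistical shape* of the classification
problem — many classes, strong imbalance (the largest class is 7.4 times
the smallest), oriented band-limited texture, nuisance noise — with
tunable difficulty. It does **not** emulate stain variation, tissue
morphology, scanner artifacts, intra-class heterogeneity or inter-image
correlation. Passing tests therefore demonstrate that the pipeline's
machinery is correct and can learn an 8-class oriented-texture signal
under class imbalance; they say nothing about accuracy on real
histopathology images.

## Problem sizes and budgets

All shipped checks run on one CPU core. The test suite and the
reproduction script use: 12×12 images against the brute-force convolution
oracles; hidden sizes 2–8 for the GRU oracles; the 5-D sphere with
$N = 20$, $T = 100$ over 20 seeds for the optimizer benchmark (plus
25-iteration runs on sphere, Rosenbrock and Rastrigin for the invariant
sweeps); and 0.1-scale fixtures (177 images, per-class floor 8, images
downscaled 2× after filtering) with 50 training epochs for the end-to-end
run. The tuned-versus-default comparison trains at a matched 8-epoch
budget with a small search ($N = 6$, $T = 3$) over several split seeds
and compares median validation error. These sizes were chosen as the
smallest that exercise every code path and give stable medians.

## Known limitations

* The feature extractor is used with random (untrained) weights; training
  it end-to-end is out of scope, so feature quality bounds achievable
  accuracy.
* Plain SGD with a fixed learning rate; no momentum or schedules.
* The optimizer handles box constraints only, by projection; no integer-
  aware search beyond decode-time rounding.
* Joiner and vigilante updates can concentrate mass at the box corners in
  pathological landscapes (a known trait of this algorithm family);
  the chaotic candidate mitigates but does not remove it.
* Metrics assume single-label classification; no ROC/PR curves are
  computed (the probability columns returned by `predict()` allow users
  to add them).
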