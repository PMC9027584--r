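---
title: "Discriminative fine-tuning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative fine-tuning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transfer learning on small medical-image collections — the motivating case is
BI-RADS classification of mammograms, where a few hundred labeled images must
retrain a network pretrained on natural images — faces two coupled
difficulties: overfitting, and the cost of training every layer at a rate
appropriate for the classifier head. Discriminative fine-tuning (DFT)
addresses both by giving every layer group its own learning rate and
momentum: early groups, which already hold generic features, move slowly;
the freshly initialized head moves fast.

`dftune` implements that training method end to end: the per-layer
triangular schedule, the momentum-velocity update it drives, the
learning-rate range test that selects the schedule's bounds, a
mammogram-style augmentation pipeline with minority oversampling, the
multiclass sensitivity/specificity metrics used to read the resulting
confusion matrices, an emulated mixed-precision path, and a synthetic image
generator so everything is testable on one CPU with no downloads.

## The schedule

Given rate bounds $[\alpha_{\min}, \alpha_{\max}]$ and momentum bounds
$[m_{\min}, m_{\max}]$, layer group $l \in \{0, \dots, l_{\max}-1\}$ receives
the base rate

$$\alpha(l) = \alpha_{\min} + (\alpha_{\max} - \alpha_{\min})
  \frac{l}{l_{\max} - 1},$$

so the earliest group sits exactly at $\alpha_{\min}$ and the head at
$\alpha_{\max}$. Over iterations $t \in \{0, \dots, t_{\max}-1\}$ a
triangular factor $f(t)$ rises linearly from 0 to 1 over the first
$\kappa$ fraction of the run and falls back linearly over the remainder
($\kappa = 0.5$ by default); the effective rate is

$$\alpha(t, l) = \alpha_{\min} + f(t)\,(\alpha(l) - \alpha_{\min}).$$

The factor scales the *spread* above $\alpha_{\min}$, not the base, so no
layer is ever frozen mid-run. Momentum interpolates $m_{\min} \to m_{\max}$
across layers during the rising phase and mirrors to $m_{\max} \to m_{\min}$
during the falling phase; `invert_momentum = TRUE` swaps the two for the
common practice of cycling momentum opposite to the rate. The update applied
to each group is classical heavy-ball momentum,

$$v' = m\,v - \alpha\,g, \qquad \theta' = \theta + v',$$

which reduces to plain SGD at $m = 0$; the regularized objective is
$J(\theta) = \bar{\mathcal{L}} + \lambda\,\Omega(\theta)$ with $\Omega$ the
squared norm of the weight matrices (biases excluded) and default
$\lambda = 10^{-4}$ (the weight-decay value is a free
parameter of the method; $10^{-4}$ is the conventional order for
fine-tuning).

Two details of the method's original formulation required interpretation,
and both decisions are deliberate. First, the per-layer rate formula as
circulated divides the rate spread by $\alpha_{\max}$ and multiplies by the
raw layer index, which escapes the stated bounds for any realistic depth;
the linear interpolation above is the only reading consistent with its
stated endpoints (lowest rate to the earliest layer, highest to the
latest). Second, the original formulation draws $\kappa$ at random, which
would make schedules irreproducible; `dftune` exposes
$\kappa$ as a configuration knob with default 0.5 and supports one cycle
per run (default) or per epoch (`cycle = "epoch"`). A whole-run cycle
matches the narrated behavior of a single warm-up and anneal inside a short
epoch budget.

## Selecting the bounds: the range test

`run_sweep()` performs the single-epoch trial: one momentum-SGD step per
iteration with the rate growing geometrically from `lr_start` to `lr_end`
(geometric spacing is the default; linear is available), recording the
raw batch loss and its bias-corrected exponential moving average
(weight 0.98). The sweep aborts once the smoothed loss exceeds 4x its
running minimum, so the exploding tail never contaminates the curve, and
the model's weights are restored afterwards. The sweep steps use momentum
(default 0.9, the midpoint of the default momentum band) deliberately:
momentum inflates the effective step size by roughly $1/(1-m)$, so a
momentum-free sweep probes the wrong dynamics and would select rates up to
an order of magnitude too hot for the momentum training they will drive.

`select_bounds()` automates what is a visual read-off of the loss-vs-rate
plot in practice: it takes the most negative finite difference of smoothed
loss with respect to log rate, sets $\alpha_{\max}$ to the rate there
(strictly below any divergence point) and $\alpha_{\min} =
\alpha_{\max}/10$. Two guards make the automation robust where a human eye
would not be fooled: the first 10% of points (at least 2) are excluded,
because the moving average is still converging there and its ramp-in looks
like a steep drop; and on curves of 20+ points the finite difference spans
5% of the curve rather than one noisy consecutive pair. Minibatches fed to
the sweep should mix classes — `dataset_batches()` shuffles before cutting,
since datasets are stored class-sorted and class-homogeneous batches make
single-batch losses meaninglessly noisy.

## Augmentation and imbalance

The augmentation registry holds the four distortions that mammogram
acquisition realistically varies — Gaussian blur (kernel
$\propto e^{-(x^2+y^2)/2v}$, reflect padding), gamma intensity shift
$I' = \mathrm{clip}(c\,I^{\gamma})$, small rotation (bilinear, zero fill),
and mild white noise — plus an explicit `identity`. One transform is drawn
per emitted image by default (`chain = TRUE` composes all of them instead).
The method itself does not prescribe parameter ranges; the defaults were
fixed once at visually mild values: $v \in [0.25, 4]$ px², $c \in [0.8, 1.2]$,
$\gamma \in [0.7, 1.5]$, $|\varphi| \in [2^\circ, 15^\circ]$ (either sign),
$\sigma \in [0.005, 0.02]$. Horizontal mirroring is deliberately absent:
breast anatomy chirality must be preserved, and the test suite verifies via
an embedded chirality marker that no registry transform flips an image.

Manual visual curation of generated images — the usual practice in this
setting — is not automatable; `dftune` replaces it with a deterministic
filter: exact duplicates (identical 8-bit content) are rejected and
redrawn. No particular kept-image count is therefore a reproduction
target.
Class imbalance is handled by random minority oversampling
(`oversample_minority()`), applied to the *training partition only, after
splitting*: oversampling before splitting would leak duplicated minority
images into validation, so the safe order is fixed here.

## Metrics

`confusion_matrix()` fixes rows = actual, columns = predicted; that
orientation is forced by the one-vs-rest count definitions (row sum minus
diagonal = false negatives). Per-class sensitivity
$\mathrm{MSN}_i = TP_i/(TP_i+FN_i)$ and specificity
$\mathrm{MSP}_i = TN_i/(TN_i+FP_i)$ are reported as flagged-undefined
(`NA`) when a denominator is zero — silently coercing an absent class to 0
would distort macro averages. Summary precision/recall are unweighted
macro averages over defined classes (macro was chosen because it treats
rare BI-RADS classes on equal footing).

## The synthetic world

`generate_synthetic()` emits seeded grayscale images: a smooth random
background plus a class pattern (Gaussian blobs whose count and radius vary
with class, plus an oriented sinusoid whose angle and frequency encode the
class) scaled by `signal_strength`, plus Gaussian noise scaled by
`1 - signal_strength`. At `signal_strength = 0` every class is
distributionally identical by construction; at the default 0.9 a small CNN
separates three classes within a few epochs on a CPU. Class counts follow
the requested proportions exactly under largest-remainder rounding.

What the generator does *not* emulate: radiological texture, breast
contours, DICOM intensity calibration, view (CC/MLO) structure, or
inter-reader label noise. A green convergence test therefore establishes
that the training machinery behaves as specified — schedules, updates,
splits, metrics — not that any accuracy transfers to real mammograms.

The built-in backbone (`small_cnn()`) is three same-padded 3x3 conv blocks
with ReLU and 2x2 max-pooling plus a linear head — four parameter groups,
which is the granularity DFT operates at. It exists so that training is
testable without pretrained weights; real backbones can be plugged in by
supplying the same `params`/`loss_grad`/`predict` interface. Training
defaults mirror the reference conventions (batch 64, epoch cap 50, 80:15:5
stratified split) except the image side, which defaults to 64 px because
400x400 CPU training is not a desk-scale operation; `image_side = 400`
restores the original geometry.

## Mixed precision

The mixed-precision contract is emulated in software (no FP16 hardware path
exists here): weights are rounded to IEEE binary16 (round-to-nearest-even,
subnormals below $2^{-14}$, overflow to $\infty$ beyond 65504), the loss —
hence every gradient — is multiplied by `loss_scale` (default 1024) before
the backward pass so small gradients survive quantization, scaled gradients
are rounded to binary16, then unscaled in full precision and applied to
full-precision master weights. Non-finite scaled gradients skip the step,
leave parameters untouched, and halve the scale. With `emulate_fp16 =
FALSE` and scale 1 the path is bit-identical to the plain step, which is
how the contract is tested on CPU.

## Numerical choices and degenerate inputs

* Max-pooling ties route the gradient to the first maximal position in scan
  order — deterministic, so fixed seeds give identical training histories.
* Argmax prediction ties resolve to the lowest class index.
* Best-checkpoint selection is by validation accuracy with ties to the
  earlier epoch.
* The divergence guard in the sweep (4x running minimum) and the softmax
  `log(pmax(p, 1e-12))` floor bound the quantities fed to slope estimation
  and loss reporting.
* Blur kernels are normalized to sum exactly 1, so constant images are
  exact fixed points and interior mean intensity is conserved to < 1e-3.
* All randomness flows through per-purpose seeds derived deterministically
  from one user seed, so partial pipelines (e.g. re-running only `train`)
  are reproducible.

## Known limitations

* Pure-R training: practical for the desk-scale geometry (64 px, tens of
  epochs); 400x400 fine-tuning of deep backbones is out of scope.
* The range-test selector presumes a sweep wide enough to show a descending
  region; on a flat curve it refuses (with instructions) rather than guess,
  and `alpha_min = alpha_max/10` can fall below `lr_start` if the sweep
  starts barely a decade under the steepest drop.
* Per-parameter adaptive optimizers (Adam family), warm restarts, and
  per-layer sweeps are non-goals.
* Image I/O is ASCII PGM + CSV manifest; PNG/DICOM conversion is assumed
  upstream (any standard tool can emit 8-bit grayscale PGM).
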