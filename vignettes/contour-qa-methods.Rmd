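---
title: "Methods: uncertainty-aware contour quality assurance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-aware contour quality assurance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In online adaptive radiotherapy, organ-at-risk and target contours are
re-generated while the patient is on the couch, and a human must decide —
under minutes of time pressure — whether each automatic contour is
clinically acceptable. `contourqa` implements a slice-level QA classifier
for this decision, together with the machinery that makes such a classifier
deployable: a calibrated measure of how much each individual decision can
be trusted.

The QA unit is one 2D slice of one structure: a grayscale image, the binary
mask under review, and a code identifying which structure the mask claims
to be. The model outputs $p \in [0,1]$, the probability that the contour
*requires revision*; $p \ge 0.5$ flags the contour, $p < 0.5$ accepts it.

## Model

The classifier is a residual CNN over a two-channel input — the image slice
and the binary mask stacked — so the convolutional trunk can detect local
disagreement between mask boundaries and image edges. After global average
pooling, a one-hot *structure code* of length $K$ is concatenated to the
pooled features, and a fully connected head produces a single sigmoid
logit. One multi-structure model therefore serves every structure; the code
tells the head which anatomy's error statistics apply.

Two backbones are configured: `small_resnet` (stem convolution plus two
stages of one residual block, widths 8/16, roughly 6k weights) for
CPU-scale work, and `resnet34_style` (four stages of 3/4/6/3 blocks,
widths 64/128/256/512). All convolutions are 3x3 with identity or 1x1
projection skips; each stage ends in 2x2 max-pooling. The network,
backpropagation, binary cross-entropy loss and the Adam optimiser are
implemented in compiled code (`src/nn.cpp`); a finite-difference gradient
check in the test suite pins the backward pass to ~1e-10 of the numerical
gradient.

Training defaults follow the reference protocol: Adam at $10^{-4}$, the
rate multiplied by 0.2 every 100 epochs (`lr_at_epoch()` uses 0-based
epoch indices), batch size 64, binary cross-entropy. Each epoch is
balanced per structure: every acceptable sample is paired with a freshly
perturbed revision-required counterpart, so the class ratio is exactly 1:1
for every organ and the negatives never repeat across epochs. The
best-validation-accuracy weights are kept; model selection at threshold
0.5 is the package's own rule.

## Uncertainty

Dropout (rate 0.1) precedes every fully connected layer and is kept active
at inference. A prediction consists of $T$ stochastic passes (default
$T = 30$), averaged into

$$\hat p = \frac{1}{T}\sum_{t=1}^{T} p_t ,$$

and the uncertainty score is the normalized Shannon entropy of that mean,

$$H = -\frac{1}{\log 2}\left[\hat p \log \hat p +
  (1-\hat p)\log(1-\hat p)\right] \in [0, 1],$$

with $0\log 0 := 0$ (each term is evaluated with its explicit limit, so
$H(0)$ and $H(1)$ are exactly zero). Entropy of the mean
— predictive entropy — is used, not the mean of per-pass entropies.
Per-pass dropout masks derive from one seed by pass index, so a prediction
is reproducible and independent of how samples are batched.

## Calibration and the decision policy

On validation predictions, sorted by ascending entropy (stable ties), the
*cumulative recall* of the revision-required class within the accepted
prefix is computed; before the first revision-required sample enters the
prefix, recall is vacuously 1. The per-structure threshold $\tau$ is the
entropy of the first point whose cumulative recall drops below the target
(default 98%); if it never drops, $\tau = 1$ and everything is
auto-accepted. Deployment is strict: a prediction is auto-accepted only
when its entropy is strictly below $\tau$, otherwise it is routed to a
human. By construction the accepted prefix meets the recall target on the
calibration set; transfer to test data is an empirical property that the
package's end-to-end experiment measures. Per-structure targets can be
overridden — e.g. 1.0 for a treatment target, which places $\tau$ at the
entropy of the first missed revision-required validation sample.

Two diagnostic views are provided: `binned_performance()` partitions
$[0,1]$ into 80 uniform entropy bins (empty bins are absent, bins without
positives report no recall) and `autoplot()` methods draw the calibration
curve and the accuracy-vs-uncertainty trend.

## Synthetic errors

Revision-required masks are manufactured from clean masks by one of four
error families, drawn uniformly:

* **dilation / erosion** — rectangular structuring elements of 1x5, 5x1 or
  5x5 pixels ("approximately two pixels along x, y or both"); the element
  shape realizes exactly 2 px per selected direction and is configurable.
  The axis mode is drawn uniformly from {x, y, both}.
* **shift** — integer translation with $dx, dy \in [-2, 2]$, $(0,0)$
  excluded by construction (the sampler draws from the 24 non-zero pairs).
* **boundary noise** — up to 15 boundary vertices (uniform on
  1..min(15, boundary length), chosen without replacement along the traced
  contour) are displaced by integer offsets within $\pm 2$ px per axis;
  the displaced vertex sequence is refilled as a closed polygon. If the
  refill splits the region, the largest component is kept.

Exactly one family is applied per revision-required sample. Degenerate
outcomes — erosion emptying a small mask, a shift pushing everything
off-frame, an identity refill — raise a typed condition and the sampler
retries with fresh family and parameters (budget 20), preserving the rule
that every labelled error differs from its source in at least one pixel.
Coordinates follow (row, col) = (y, x), 0-based, with "x" meaning image
columns, stated once and used everywhere.

## The phantom

Clinical images cannot ship with the package, so a generator emulates the
essential statistics of resampled pelvic MR at desk scale: square
grayscale slices (default 64 px) containing one elliptical blob per
structure on a noisy background. Three size archetypes — a large
bladder-like, a medium prostate-like and a small urethra-like class —
ensure the fixed +-2 px perturbations span a range of relative severities,
because small organs are proportionally harder. Per patient, base shape
parameters are drawn once and jittered per slice; images are rendered as
background mean 0.25, foreground means 0.85/0.65/0.95, Gaussian pixel
noise (sd 0.06), blur (sigma 0.7), then clamped to [0, 1]. Masks are the
exact pre-noise ellipse rasterizations. A validity check requires
foreground/background separation of at least two noise standard
deviations, and all shapes to fit within half the frame.

What the phantom does *not* emulate: MR physics (bias fields, coil
profiles), inter-observer ambiguity in "acceptable", 3D anatomical
continuity, and organs with weak image contrast. Passing the end-to-end
experiment therefore demonstrates that the pipeline's machinery — balanced
dynamic training, MC-dropout uncertainty, recall-targeted calibration —
works as specified, not that clinical-grade accuracy would transfer to
patient data.

## The reference desk-scale experiment

`reference_run_config()` fixes the package's standard experiment: 100/20/20
patients (train/validation/test), 3 structures, the `small_resnet`
backbone, 20 epochs at batch 64, T = 10 passes, target recall 0.98.
Training runs for ~800 Adam steps, so the initial learning rate is set to
1e-3 — the reference schedule (1e-4, decaying every 100 epochs) is sized
for runs hundreds of epochs long and would barely leave its plateau here.
The experiment completes in minutes on one CPU; `scripts/acceptance.R`
reruns it from scratch and reports pooled test metrics, the Spearman
correlation between per-bin uncertainty and accuracy, and the auto-accept
operating point.

```{r, eval = FALSE}
library(contourqa)
res <- run_pipeline(reference_run_config(seed = 1), verbose = TRUE)
res$metrics |> dplyr::filter(structure == "overall")
autoplot(build_calibration_curve(res$val_predictions))
```

## Numerical and design notes

* Pooled "overall" metrics aggregate slices across structures (not an
  average of per-structure metrics); per-structure rows are reported
  alongside.
* AUC is the rank-based Mann-Whitney estimator with midrank tie
  correction.
* Epoch-level balancing (rather than per-mini-batch) plus a uniform
  shuffle is used; with batch 64 this yields approximately balanced
  batches.
* Entropy ties during calibration sort are broken by input order (stable
  sort), making curves reproducible.
* The decision rule at exactly $\tau$ is *flag*: acceptance is a strict
  inequality.
* All seeds derive from one master seed by label hashing
  (`derive_seed()`), so stages can be re-run or reordered without
  perturbing each other's streams.
* Weight init is He-normal; biases zero. Training aborts on a non-finite
  loss.

## Known limitations

Single-slice 2D decisions (no 3D context or dose awareness); one error
family per synthetic sample; fixed perturbation magnitudes rather than
size-aware ones; phantom realism as discussed above. The `resnet34_style`
backbone is provided and tested for shape correctness but is impractical
to train on a single CPU.
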