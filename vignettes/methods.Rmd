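---
title: "Patient-level endoscopy classification and quantization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-level endoscopy classification and quantization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoquant)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the assumptions they rest on, the tunable
parameters and why their defaults are what they are, what the synthetic
data does and does not emulate, and the design decisions taken where the
methodology left genuine freedom.

## 1. The clinical setting and the unit of inference

An endoscopic examination yields, per patient, an ordered sequence of RGB
snapshots whose length varies from patient to patient. The diagnostic
question (here: IBD versus control) is asked at the *patient* level, so the
package's unit of inference is a `patient_case` — the whole sequence plus
the label — and every statistical operation downstream (splitting, fold
assignment, aggregation, bootstrap) treats the patient as the atom.
Image-level operations exist only inside the pipeline.

Two consequences are worth making explicit:

* **Leakage control.** Images of one patient are strongly correlated;
  letting them straddle the train/test boundary inflates test performance.
  `split_patients()` and `assign_folds()` therefore operate on patient ids
  only, and `train_fold()` refuses train/validation sets that share a
  patient.
* **Abstention.** A model consulted by a clinician should say nothing
  rather than guess when its confidence is low. The per-patient model
  abstains (`"unpredicted"`) when no image reaches the confidence
  threshold; during tuning an abstention is *counted as an error against
  the true class*, so the grid search cannot buy accuracy by refusing to
  answer.

## 2. The per-patient abstaining ensemble

Given per-image positive-class probabilities `p_i` with confidences
`c_i = max(p_i, 1 - p_i)` (two classes, so `c_i` lies in [0.5, 1]), and
parameters `t` (confidence threshold) and `k` (ensemble size):

1. discard predictions with `c_i < t` (the comparison is strict; a
   prediction exactly at `t` survives);
2. if nothing survives, return *Unpredicted*;
3. sort survivors by confidence, descending and stably — ties keep the
   acquisition order, which makes the result reproducible on hardware that
   produces identical confidences;
4. keep the first `min(k, #survivors)`;
5. score the patient by the confidence-weighted mean and call it positive
   when `score >= 0.5`.

**What is averaged.** The methodology says the weights are the
confidences, but not whether the averaged quantity is the probability or
the hard label. The package averages *probabilities* by default — it uses
the classifier's full output and gives strictly more information to the
decision — and offers `average = "label"` for the vote interpretation.
Both are implemented so the choice is auditable rather than silent.

**Ties at 0.5.** A score of exactly 0.5 classifies positive. For a
screening task the conservative direction is toward the disease class;
the choice is documented and a one-line change if a deployment prefers
otherwise.

**Saturation.** When `k` exceeds the number of survivors the decision no
longer depends on `k`. This is why grid-search tables typically show
identical columns on the right-hand side: not a bug, a property.

### Grid search and the selection rule

`evaluate_grid()` evaluates all `(t, k)` cells — defaults are
`t in {0.85, 0.87, 0.88, 0.90, 0.91, 0.93, 0.94, 0.96, 0.97, 0.99}` and
`k in 1..10` — computing MCC, accuracy and F1 with abstentions counted as
errors, and the abstention count per threshold. MCC drives selection
because it only rewards models that do well in all four confusion-matrix
cells, a property accuracy and F1 lack on imbalanced cohorts. Among
MCC-maximizing cells the rule prefers, in order: cells whose threshold
leaves *zero* patients unpredicted (the highest threshold that still
guarantees a prediction for everyone), then the largest `t` (minimal
dissemination of low-confidence output), then the largest `k` (use as much
information as possible). The rule is deterministic, so reruns select the
same cell.

## 3. The cleaning pipeline

Stages run in a fixed order: quality filtering, text removal, fill,
object removal, margin crop + resize. The patient-centric structure is
invariant: a patient whose images are all discarded remains in the cohort
with an empty sequence and is flagged, never silently dropped.

* **Quality score.** Variance of the 3x3 discrete Laplacian
  `[[0,1,0],[1,-4,1],[0,1,0]]` on the BT.601 luminance, computed on
  interior pixels only. Computing without padding removes a
  boundary-dialect ambiguity (zero-pad, replicate, reflect all change the
  score); the interior response is also exactly translation-invariant and
  scales quadratically with intensity, two properties the tests assert.
  Solid frames score exactly 0; sharp frames with sensor noise score in
  the thousands (a noise s.d. of 8 alone contributes a response variance
  of about 20 * 64 = 1280). The default threshold 100 sits between those
  clusters; it is a config value, not a claim about any particular
  scanner.
* **Margin detection** is the bounding box of pixels whose luminance
  exceeds a cutoff (default 10 of 255). Boxes are 0-based half-open, and
  the operation is idempotent: applied to an already-cropped image it
  returns the full frame.
* **Text/object removal** are plugin interfaces (`function(image) ->
  region_mask`): the heavy detectors used in production settings (OCR
  networks, trained object detectors) are deliberately out of scope, and
  the package ships a sidecar-box detector for wiring and testing. Fills
  are `mean_fill` and an iterative harmonic `diffusion` fill — simple,
  deterministic stand-ins for learned inpainting, declared as such. A
  failing plugin logs and passes the image through unmodified: a cleaning
  stage must not abort a cohort run.
* **Resize** is bilinear (via EBImage), after cropping. A crop already at
  the target size passes through pixel-identically.

## 4. Training recipe and the compact backbone

The training harness reproduces the published recipe: Adam at
`lr0 = 0.001`, decayed by 0.1 every 20 epochs; LASSO (L1) penalty on the
trainable weights; partial fine-tuning that freezes everything except the
final two convolution-bearing stages and the classification head.
Freezing is literal — frozen parameters are bit-identical after any number
of epochs — and the recorded learning-rate history equals
`lr_at_epoch()` for every epoch, both asserted in tests.

The shipped backbone, `tiny_cnn`, is a three-convolution network
(8/12/16 channels, 3x3 valid convolutions, ReLU, 2x2 average pooling,
linear head; about 3,000 parameters at 32x32 input) with a hand-written
backward pass. Writing the network by hand is a deliberate design
decision, not a shortcut: the quantization engine must insert fake
quantization into the forward pass and straight-through/PACT masks into
the backward pass, which requires gradient-level control no high-level
fitting interface exposes. Average pooling (LeNet-style) was chosen over
max pooling for its simpler, denser gradient; on 32x32 synthetic frames
the difference is immaterial. Larger pretrained backbones (e.g. a
fine-tuned ResNet50) are the realistic production choice but ship no
weights with this package and are not required by any test; the backbone
surface is the extension point.

Unstated hyperparameters (batch size, epoch count, L1 strength) are
config defaults, not claims: `l1_lambda = 1e-5`, `batch_size = 16`,
`epochs = 60` (three decay steps). `epochs = 0` is allowed and performs no
update pass — the reduction that makes "QAT with zero epochs equals PTQ"
an executable identity.

## 5. The quantization engine

The quantizer is `Q(x) = round(x/s + Z)` clamped to the integer range
`[alpha_q, beta_q]`, with `s = (beta - alpha)/(beta_q - alpha_q)` and
`Z = round(-(alpha/s - alpha_q))`. Design decisions on points the
formulas leave open:

* **Zero-point rounding** is half-away-from-zero (the formula alone
  leaves `Z` real-valued). The quantizer's own rounding uses the IEEE
  default (half-to-even), matching what numeric libraries do elementwise.
* **Clamping** to `[alpha_q, beta_q]` is applied after rounding; without
  it, out-of-clip inputs would leave the integer domain.
* **Schemes.** Weights default to symmetric per-channel int8
  `[-127, 127]` (zero maps to zero, one scale per output channel);
  activations to affine per-tensor uint8 `[0, 255]` — the asymmetric
  scheme suits the non-negative post-ReLU range. Degenerate calibration
  (a constant tensor) errors by default; a `unit_scale` fallback is
  available behind a flag because silently quantizing a constant tensor
  usually hides a dead layer.
* **STE boundary.** The straight-through gradient is the indicator of the
  clipping interval *with the boundary included*: a weight sitting exactly
  on the clip edge still receives gradient, so it can move back inside.
* **PACT.** The activation clip `alpha_tilde` is trainable with
  `s = alpha_tilde/(beta_q - alpha_q)` recomputed every step; its gradient
  is the saturation indicator `1{x >= alpha_tilde}` (the standard PACT
  rule — an extrapolation, flagged as such, since the source text cites
  but does not specify it). A clip driven to zero clamps at a small
  positive epsilon. `alpha_tilde` is initialized from the observer
  calibration.
* **Calibration order.** PTQ, QAT and PACT share one calibration routine:
  symmetric per-channel weight parameters from the weights themselves,
  then activation observers run with fake-quantized weights. QAT/PACT
  freeze those parameters before training (PACT's clips excepted, being
  trainable). Sharing the routine is what makes the zero-epoch reduction
  exact.
* **Layer selection.** The default policy quantizes everything except the
  first convolution and the classifier — the layers whose few parameters
  carry disproportionate task information. On `tiny_cnn`
  (`conv1/conv2/conv3/fc`) that selects `{conv2, conv3}`.
* **Size accounting.** Parameters of selected layers are counted at the
  quantized width, the rest at fp32, plus (optionally) one `(s, Z)` pair
  per weight channel and per quantized activation tensor at 8 bytes each.
  Biases stay in floating point (standard practice) but are counted with
  their layer's width so that the all-layers-int8, overhead-free total is
  *exactly* one fourth of fp32 — the accounting identity the tests pin.
  One known simplification, not a claim about deployment formats.

A property worth noting: per-channel granularity can only tighten each
channel's clipping range, so its error *bound* (`s_c/2`) never exceeds the
per-tensor bound. The realized maximum error inherits that ordering when
channel dynamic ranges actually differ — the regime per-channel
quantization exists for — and the tests exercise exactly that regime with
order-of-magnitude range heterogeneity.

## 6. Metrics and uncertainty

MCC, accuracy and F1 are computed from patient-level confusion counts with
abstentions folded in as errors of the true class. The MCC
zero-denominator convention is 0 (the value is genuinely undefined there;
0 is the least-informative choice and is what the vectorized bootstrap
needs). Bootstrap confidence intervals resample *patients* with
replacement; since every supported metric depends on a resample only
through its confusion counts, the resample is drawn directly as a
multinomial over the four categories — mathematically identical and fast
enough for the default `B = 1e5`. The reported radius is
`rho = 1.6449 * sd(resamples)`, the two-sided 5%–95% normal radius,
matching the stated normality assumption; a percentile mode exists behind
a flag. On very small test sets (a handful of patients) the multinomial
occasionally drops one class entirely, where the MCC convention pulls the
bootstrap mean slightly below the plug-in value — visible, expected, and a
reason to read `plugin` alongside `mu` at small n.

## 7. What the synthetic data does and does not show

`generate_cohort()` emulates the *structural* properties the pipeline
must survive: variable-length per-patient sequences, a bright circular
field of view on a black margin, sensor noise, solid-colour frames,
heavy blur, glyph-like text overlays in the margin, and a class signal —
reddened lesion blobs whose expected count is `0.3 + 3 * signal_strength`
per image for positive patients and 0.3 for controls. At
`signal_strength = 0` the labels are independent of the pixels (a null
cohort); the study default `signal_strength = 1.5` yields a clearly
separable task on which the compact backbone reaches per-image accuracy
around 0.9. Every artifact is recorded in a bookkeeping table, so tests
compare pipeline behaviour against generation ground truth rather than
against re-detection.

`generate_predictions()` skips the images entirely and emulates a
classifier's output: predictions correct with probability
`per_image_accuracy`, confidences Beta-distributed on [0.5, 1] with
correct predictions drawn more confident (`Beta(8, 2)`) than incorrect
ones (`Beta(2, 4)`). That separation is the premise that makes a
confidence threshold useful; the null configuration with equal shapes is
used to verify the machinery does not manufacture signal.

What passing tests on this material shows: the *machinery* is correct —
aggregation equals its brute-force reference, the grid tables equal
cell-by-cell recomputation, abstention counts are monotone, ensembling
amplifies per-image accuracy in the direction observed on real cohorts,
quantization degrades a separable task only marginally. What it does not
show: performance on clinical endoscopy. Real mucosa textures, hospital
effects, probe artifacts and label noise are all absent, and no number
produced here transfers to the private clinical dataset the methodology
was developed on.

## 8. Problem sizes and numerical choices

The scaled-down synthetic study used by the test suite and by
`scripts/acceptance.R` runs 30 patients with 5–9 images each at 64x64
(cleaned to 32x32), 2 cross-validation folds, a reduced 4x4 grid
(`t in {0.85, 0.90, 0.93, 0.97}`, `k in {1, 3, 6, 10}`), 30 training
epochs with the decay step every 15 (batch size 8), and PTQ with a 15%
calibration fraction. These sizes were chosen so the cross-validated fold
models — trained on only ~12 patients each — still converge to confident,
accurate predictions, making the validation grid search meaningful; the
full printed grids and 5-fold CV remain the package defaults for real
cohorts. With only six test patients a single misclassification moves MCC
by roughly 0.3, so seed-to-seed variation of the headline number is
coarse-grained by design.

Numerical tolerances used in tests: aggregation scores are compared to
the brute-force reference at 1e-12 (both paths are plain double
arithmetic on at most 12 summands); quantization round-trips allow
`s/2 + 1e-12`; translation invariance of the quality score allows 1e-9.
Training determinism is exact (same seed, same platform), which the suite
asserts by identity on weights and serialized artifacts.

## 9. Known limitations

* No DICOM/video ingestion; images are 8-bit PNG (JPEG decoding is not
  wired in this build).
* The inpainting fills are diffusion-based approximations; they make no
  claim of visual plausibility, only of determinism and locality.
* Quantized inference is simulated (quantize-dequantize in floating
  point); there is no integer-kernel execution path, so speed-ups are out
  of scope — only size accounting and accuracy effects are modelled.
* The `tiny_cnn` backbone is a test-scale stand-in; conclusions about
  large pretrained backbones require plugging one in.
* Probability calibration of the per-image classifier is assumed, not
  enforced; a severely miscalibrated backbone would shift the meaning of
  the confidence threshold `t`.
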