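---
title: "Inception architectures, diagnostic metrics and synthetic thermograms: methods and design choices"
author: "ThermoInception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inception architectures, diagnostic metrics and synthetic thermograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThermoInception)
```

# Scope

ThermoInception studies deep convolutional classification of frontal
breast thermograms at desk scale. Its components are (i) explicit
layer-graph builders for inception V3, inception V4 and a modified V4
("MV4") whose inception-B stage is replaced by a shallower block
preserving its 1024 concatenated feature channels; (ii) a twelve-metric
diagnostic evaluation suite with explicit undefined-value semantics;
(iii) thermal-image input handling with seeded augmentation; (iv) a
synthetic thermogram simulator; and (v) a reproducible training harness
with SGDM, Adam and RMSprop. This vignette records the scientific
assumptions and the design decisions behind each, in the order a reader
needs them to interpret results.

# Layer graphs and the output-size rule

Networks are explicit directed acyclic graphs of typed layer nodes
(`NetworkGraph`). Every spatial transformation is governed by the single
output-size rule

$$W_\mathrm{out} = \left\lfloor \frac{W - F + 2P}{S} \right\rfloor + 1,$$

with input extent $W$, filter extent $F$, zero padding $P$ per side and
stride $S$. Division is floor division with a warning when inexact
(border windows that do not fit are dropped), since no rounding rule is
otherwise implied and flooring is the common framework convention.
"Same" padding is supported at stride 1 with odd filters, where
$P = (F-1)/2$ reproduces the input extent. Shape inference
(`inferShapes`) applies this rule node by node in topological order;
concat nodes demand identical spatial extents and add channel counts.

The V4 trunk is the canonical published configuration: stem, 4
inception-A blocks, reduction-A, 7 inception-B blocks, reduction-B, 3
inception-C blocks. The canonical inception-B concatenates branches of
128 + 384 + 256 + 256 = 1024 channels. Every convolution is followed by
batch normalization and ReLU, applied uniformly across all three
architectures. The V3 trunk follows the published factorized geometry
with block counts 3/4/2 (A/B/C) and a 2048-channel feature vector;
where a textual description of V3 conflicts with the canonical
factorized filters (e.g. "all 3x3"), the builders keep the canonical
geometry and the stated block counts.

## The modified inception-B block

MV4 replaces each of the 7 inception-B blocks with a four-branch
shallow block: a 3x3 average pool capped by a convolution with 256
filters, a direct 1x1 convolution with 384 filters, and a 1x1
convolution with 192 filters feeding two parallel 3x3 convolutions of
192 filters each — 256 + 384 + 192 + 192 = 1024 concatenated channels.
Keeping 1024 channels is the block's *feature-preservation constraint*:
reduction-B and everything downstream remain geometry-compatible
unchanged, so the only structural change in MV4 is the cheaper B stage.

Two details of the source description are ambiguous and resolved as
follows, with the alternative kept available:

* **The conv under the average pool is 1x1 by default.** Read with a
  3x3 convolution over the block's 1024 input channels, that single
  branch costs 2.36M parameters per block and makes MV4 *heavier* than
  V4 in parameters and multiply-accumulates — contradicting the design
  goal of a lighter network and the reported parameter ordering. Read
  with the 3x3 attached to the pooling window (its canonical size) and
  a 1x1 convolution widened from the canonical 128 to 256 filters, the
  block is strictly cheaper. The default takes the second reading;
  `mv4BlockConfig(avgpoolConvSize = 3)` restores the first.
* **The parallel branch widths default to 192.** The literal branch
  list (256-filter parallel convolutions) sums to 1152 channels, which
  violates the stated 1024-feature total. The default honors the
  1024-channel constraint; `mv4BlockConfig(literal = TRUE)` builds the
  1152-channel variant (with `strict = FALSE` in the builder), since
  the intended geometry cannot be determined from the text.

Under the defaults, MV4 has strictly fewer layers, connections,
parameters and estimated multiply-accumulates than V4, with the
layer-count difference exactly 7 times the per-block reduction.

## Counting conventions

`architectureSummary` counts one node of any kind as one layer and one
directed edge as one connection. Published layer/connection totals for
these networks depend on an undocumented toolbox convention and are
therefore treated as descriptive metadata, not reproduction targets;
the same applies to published absolute parameter totals, which exceed
the canonical architectures' analytic counts several-fold. Parameter
counting here is analytic (conv $F_h F_w C_\mathrm{in} C_\mathrm{out}$,
dense $C_\mathrm{in} C_\mathrm{out} + C_\mathrm{out}$, batch norm $2C$
trainable plus $2C$ running statistics) and is verified in the test
suite against an oracle that materializes every weight tensor. FLOP
estimates count multiply-accumulates of conv and dense nodes only.

# Diagnostic metrics

`evaluateCounts` computes, from TP/TN/FP/FN: precision, accuracy
(percent), specificity, sensitivity, NPV, FPR, FNR, the positive and
negative likelihood ratios, AUC, EER and F1. Two conventions matter:

* **"AUC" is balanced accuracy** — the mean of sensitivity and
  specificity — and EER is its complement. This follows the evaluation
  convention of the diagnostic tables this suite reproduces, not the
  ROC-area definition.
* **Undefined means NA.** Any zero denominator (no predicted
  positives, a perfect specificity for LRP, and so on) yields an
  explicit undefined value, rendered "NA" in tables, never 0 or
  infinity. One published equation labels the negative likelihood
  ratio "LRP"; it is implemented as LRN, matching the symbol table
  that accompanies it.

Computation is in double precision; rounding (accuracy to 2 decimals,
other metrics to 3) happens only in `formatReportTable`.

# Thermal input handling

Rasters (PNG/TIFF/JPEG) are read onto the `[0, 1]` intensity scale with
bit depth preserved; whitespace-delimited temperature matrices are
min–max scaled onto the 16-bit grid with the raw temperatures kept.
Grayscale conversion uses fixed luminance weights (0.299/0.587/0.114),
resizing is bilinear, and single-channel records are replicated to 3
channels for network ingestion. Augmentation mirrors the protocol used
for thermogram training sets: left-right mirroring with probability
0.5 (the anatomically meaningful reading of "flip along the vertical
axis" for a bilaterally symmetric torso; an up-down flag exists),
per-axis upscaling up to 10% with center crop, and integer translation
up to 30 pixels with edge-replication fill, all drawn from the seeded R
generator so a seed plus a policy reproduces a whole augmentation
stream. Splits are stratified per class with floor rounding — at the
protocol's 70/30 split, 1019 healthy and 862 sick records yield test
classes of 306 and 259.

# The synthetic thermogram simulator

No public thermogram database ships with the package; the simulator
generates frames with the statistical structure the classifier relies
on, not a biophysical (Pennes bioheat) model:

* a torso-shaped region at baseline skin temperature (33 °C by
  default) over an ambient background constrained to the acquisition
  protocol's 18–25 °C room temperature;
* a smooth low-frequency anatomical variation (default amplitude
  0.4 °C) constructed *mirror-symmetric* about the midline — the
  healthy signature;
* for sick frames, one or more Gaussian hot spots confined to one
  breast, peak elevation 1–3 °C by default (tumor-associated
  hypervascularity), radius 5–10% of the frame's short side, centers
  kept at least two radii off the midline so a lesion never overlaps
  its own mirror image;
* additive Gaussian sensor noise, then 16-bit quantization over a
  22–38 °C rendering window (physiological contrast rather than the
  camera's full range; both configurable) and grayscale or fixed
  false-color rendering.

The construction makes the left–right maximum asymmetry statistic
$\max |T - \mathrm{mirror}(T)|$ exactly 0 for noise-free healthy frames
and exactly the largest lesion elevation for noise-free sick frames,
which the tests exploit. Default class sizes (1019 healthy / 862 sick)
emulate the reference study population; desk-scale runs use far fewer.
What passing tests on this simulator show is that the pipeline learns
and measures *bilateral thermal asymmetry*; they do not show
performance on real thermograms, which add pose variation, anatomical
diversity, vascular patterns and camera artifacts the simulator
deliberately omits.

# The training harness and the tiny protocol

The harness trains any built graph with softmax cross-entropy under
SGDM (momentum 0.9 — the common toolbox default, unstated in the
source), Adam or RMSprop at their conventional defaults, minibatch 10,
on a stratified split, with the entire run (split, He initialization,
minibatch order, dropout, augmentation) driven by one seed. A
non-finite loss flags the run as failed instead of raising. Validation
accuracy is reported at the end of every epoch; before each held-out
evaluation the batch-norm running statistics are refreshed by one
forward sweep over the training records, because after fast weight
movement the exponential-moving-average statistics lag the current
network and would distort evaluation. Inputs are standardized per
image (zero mean, unit variance) at batch assembly, removing
inter-subject baseline and contrast variation.

Full-size training of 299x299 inception networks is supported but not
a desk-scale path. The **tiny protocol** scales every filter count by
1/8 and the input to 75x75 — the smallest extent the V4 stem geometry
admits — preserving block topology exactly. Two adjustments are
specific to the tiny scale and documented as such:

* **Dropout-free head.** The full-size V4/MV4 head (global average
  pooling, dropout 0.8, dense, softmax) drops to ~38 active units of
  the tiny model's 192 pooled features, and the resulting gradient
  noise prevents learning within short schedules. Tiny variants
  therefore default to the dropout-free head; full-size builders keep
  the published head.
* **Pretraining.** The reference protocol is transfer learning: a
  pretrained inception backbone fine-tuned for a few epochs. From
  random initialization the tiny networks need on the order of 6–10
  epochs to learn the asymmetry cue, so 3-epoch runs mirror the
  transfer structure instead: `pretrainTinyBackbone()` trains the tiny
  backbone once on a disjoint synthetic corpus generated by the
  package (300 frames per class, lesion elevations 2–3 °C, Adam at
  1e-2, 30 epochs), strips the classification head, and 3-epoch SGDM
  fine-tuning runs start from those backbone weights, train a fresh
  head, and keep the first 10 convolution layers frozen — the same
  freeze depth the reference protocol reports. No external weights are
  involved. The fine-tuning learning rate of 1e-3 is the tiny-scale
  analogue of the protocol's 1e-4, chosen by a pilot sweep at the tiny
  width; He-initialized 1/8-width networks need a proportionally
  larger step.
* **Operating point.** The decision threshold is calibrated on the
  training split: the log-odds score's threshold with the highest
  training accuracy (ties resolved toward the symmetric point). The
  trained score separates the classes far better than the raw softmax
  argmax — whose errors were exclusively false negatives — and
  choosing the operating point from training data is the standard
  closing step for a diagnostic classifier. The held-out split never
  informs the threshold.
* **Negative control.** A label-shuffled control run is performed from
  random initialization, not from the pretrained backbone: a backbone
  whose features already cluster the classes yields above-chance
  accuracy under any head, including a random one, so the
  pretrained-state control cannot test what a control is for. The
  from-scratch control verifies that the pipeline itself — splitting,
  evaluation, the absence of train/test leakage — cannot manufacture
  accuracy without informative labels.

Problem sizes were chosen so the whole verification suite runs on one
CPU core: synthetic frames are generated at 120x160 and resized to
75x75, study-condition runs use 200 + 200 images at a 70/30 split, and
repeat properties use 10 seeded fine-tuning runs from one shared
pretrained backbone.

## Numerical notes

The conv/pool kernels are compiled (im2col + GEMM via Armadillo),
single-threaded and deterministic; batch normalization uses batch
statistics in training and running statistics (momentum 0.1, epsilon
1e-5) at evaluation; ties in max pooling resolve to the first maximum
in column-major order; gradients of the frozen prefix are not
propagated below the deepest trainable node. Analytic gradients for
every node kind are verified against central finite differences in the
test suite.

# Known limitations

* The simulator's healthy/sick contrast is a single localized
  asymmetry mechanism; diffuse bilateral warming, inflammatory
  patterns and pose asymmetry are not modelled, so accuracy here is an
  upper bound on what the same pipeline could achieve on real data.
* The tiny protocol demonstrates the training mechanics and the
  relative cost ordering of V4 vs MV4; it does not certify full-size
  accuracy, and published absolute accuracy tables on the external
  database are out of scope by design.
* Layer/connection/parameter totals printed by other toolboxes are
  convention-dependent; only ordering claims (MV4 < V4) are asserted.
* `"same"` padding is restricted to stride 1 and odd filters, which
  covers the inception family but not every conceivable graph.
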