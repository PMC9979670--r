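---
title: "Spatio-temporal optical diagnosis of colorectal polyps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal optical diagnosis of colorectal polyps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypclip)
```

## The problem

Optical diagnosis during colonoscopy asks whether a detected polyp is an
adenoma (pre-cancerous, needs resection) or a non-adenoma (hyperplastic or
sessile serrated, often left in place). A frame-by-frame image classifier
answers this question independently for every video frame, and its answers
on the *same* lesion often disagree from one frame to the next: viewpoint,
focus, specular highlights and freeze-frames all change faster than the
histology does. `polypclip` implements two ways of spending that temporal
redundancy, plus the evaluation machinery needed to show whether it helped:

1. **Prediction combination.** A convolutional frame classifier produces a
   per-frame adenoma probability $p(y\,|\,x_i) \in [0,1]$; the probabilities
   of a $k$-frame clip are combined into one clip output:
   - *soft averaging*: $z = \tfrac1k \sum_{i=1}^{k} p(y|x_i)$,
   - *plurality vote*: each frame votes by thresholding, the majority label
     wins (binary output only),
   - *extreme vote*: the single most confident frame,
     $z = p_{i^\ast}$ with $i^\ast = \arg\max_i |p(y|x_i) - 0.5|$,

   with the final label $y = \mathbf{1}[z > T]$ at $T = 0.5$. The boundary
   $z = T$ maps to class 0, so an exactly undecided output is treated as
   non-adenoma.
2. **A recurrent clip classifier (LRCN).** The same convolutional encoder
   produces one feature vector per frame; a single-layer LSTM (100 hidden
   units by default) consumes the $k$ vectors in order and only the hidden
   state after the last frame — which has integrated all earlier frames —
   passes through a linear layer and softmax to the two classes
   (many-to-one readout).

The unit of temporal analysis is the **clip**: a sliding window of $k = 15$
consecutive frames of one lesion, taken at stride 1 over maximal runs of
eligible frames. A frame is eligible when it carries an annotated polyp box,
is not a frozen repeat, and is of an admitted imaging modality; a window
survives only when at least 50% of its frames are labelled high-quality
(inclusive comparison). Consequently a clean run of $n$ eligible frames
yields $n - k + 1$ clips and its last $k - 1$ frames start none. For
datasets whose frames were sampled at intervals rather than consecutively,
`sampled_clip_config()` drops the consecutiveness requirement and the
quality filter.

## Architecture and training

Only the polyp region enters the models: each frame is cropped to its
(half-open, integer-pixel) bounding box, resized bilinearly to a square
input and standardised per channel. The default normalisation constants are
the usual ImageNet statistics, matching the initialisation regime common
for such encoders; both are overridable.

Two encoder variants share one implementation (strided convolution blocks
with ReLU, closed by a global mean+max pooling readout):

* `encoder_spec("small")` — two blocks, 64 px inputs, configurable feature
  length (64 by default). Its purpose is scientific, not cosmetic: the full
  training path (backprop through the convolutions, then BPTT through the
  LSTM) runs on one CPU in minutes, so every temporal claim the package
  makes is testable end to end.
* `encoder_spec("reference")` — a deeper stack honouring the full-scale
  contract: 224×224×3 inputs and a 2048-element feature vector, the shape
  produced by a ResNet50 backbone with its final fully connected layer
  removed. Pretrained weights are out of scope; the variant documents and
  preserves the interface.

Training follows one protocol (`train_spec()`): plain SGD, class-weighted
cross-entropy with inverse-frequency weights recomputed from the training
split (the synthetic default balance of 76% adenoma / 24% non-adenoma makes
this matter), at most 20 epochs, and a fresh random subsample of at most
5000 frames per epoch for the frame classifier. The clip model is trained
on *frozen* encoder features — the package realises "pretrain the backbone
on the available frames, then freeze it" by computing each clip's
$k \times d$ feature matrix once up front, so the encoder weights are
bit-identical before and after clip training by construction. Its learning
rate follows a reduce-on-plateau schedule (factor 0.1, patience 4) on a
validation loss monitored on a lesion-level holdout of 10% of the training
lesions; the monitored set is a package choice, since only the schedule
itself is prescribed by the protocol.

The default learning rate of $10^{-4}$ belongs to the full-scale regime.
The desk-scale encoders are three orders of magnitude smaller and train
well at 0.02–0.05, which is what the tests and the acceptance script use;
this is a capacity-matched choice made once, not a tuning loop.

Augmentation (random affine: rotation, translation, scale; random colour:
brightness, contrast, saturation) draws **one** parameter vector per clip
and applies it to every frame, so augmentation never manufactures
intra-clip variation that the temporal models could mistake for signal.
Zeroing all ranges yields the identity exactly.

## The synthetic data generator

No clinical data ship with the package. `generate_dataset()` renders
labelled polyp-like videos with precisely the statistical structure the
method assumes, and nothing more:

* two visually separable lesion textures inside an elliptical region —
  adenomas get high-frequency tubular striping, non-adenomas low-contrast
  smooth dotting (a caricature of pit/vessel patterns under narrow-band
  imaging);
* smooth per-frame camera motion (translation/rotation/scale random walks)
  with an analytically tight bounding box per frame;
* per-frame quality flags where low-quality frames are actually blurred,
  so the flag corresponds to a real degradation;
* frozen segments that repeat the previous frame *verbatim* (pixels, box
  and quality flag), making the frozen-frame exclusion rule exactly
  detectable;
* a 76/24 adenoma/non-adenoma lesion balance by default, with multiple
  lesions per patient.

Everything is a pure function of `(config, seed)`; identical inputs give
bit-identical PNG trees. A `hardness` knob scales both texture contrasts
down because the benefit of temporal aggregation only exists when
per-frame errors exist; at default contrast the classes are separable
nearly perfectly, which is what the end-to-end smoke property requires.

What the generator does **not** emulate: photorealistic mucosa, specular
highlights, instrument occlusion, NBI spectral response, or detector-style
annotation noise. Tests passing on this data therefore demonstrate the
correctness of the machinery (windowing, freezing, weighting, aggregation,
metrics) and the learnability of the pipeline — not clinical performance.

`generate_prediction_stream()` goes one step further down the same road:
it emits per-frame adenoma probabilities directly (no images), Beta-
distributed around the true label and coupled in time by a Gaussian AR(1)
copula. The defaults (`mean_correct = 0.72`, `concentration = 3`,
`temporal_correlation = 0.3`) put the per-frame accuracy at ≈0.82, inside
the 0.75–0.85 regime where temporal combination demonstrably pays; they
were fixed analytically from the Beta tail probability, not tuned against
any test. At `concentration = Inf` and `mean_correct = 1` the stream
degenerates to the noiseless case `p = label`.

## Evaluation machinery

* **Pooled metrics** (`frame_metrics()`): accuracy, sensitivity,
  specificity at $T = 0.5$ with the boundary-to-0 rule, and AUC as the
  Mann–Whitney rank statistic with midranks for ties.
* **Polyp accuracy** (`polyp_accuracy()`): the fraction of correctly
  predicted units per lesion, averaged *unweighted* over lesions, with a
  95% normal-approximation CI across lesions
  ($\bar a \pm 1.96\,s/\sqrt{n}$). This is a consistency metric: pooled
  accuracy can be carried by a few long videos while half the lesions are
  mostly misclassified; polyp accuracy cannot.
* **Clip similarity** (`ncc()`, `clip_similarity()`): the energy-normalised
  inner product at zero displacement,
  $R = \sum ab \,/\, \sqrt{\sum a^2 \sum b^2}$, averaged over the $k-1$
  consecutive pairs of a clip. The square root in the denominator is
  deliberate: it makes self-similarity exactly 1, which the reading "high
  NCC = small appearance change" requires. No mean centering is applied, so
  $R \in [0,1]$ for non-negative images. No displacement search is
  performed because preprocessed clip frames share a resolution.
  `similarity_performance_analysis()` relates per-clip similarity to the
  per-clip correctness indicator by a two-sided Pearson test at
  $\alpha = 0.05$ (the per-clip pairing is a package choice) plus binned
  accuracy curves with CI bands.
* **Box-quality robustness** (`perturb_box_to_iou()`,
  `iou_robustness_curve()`): every evaluation frame is re-cropped with a
  randomly drawn box achieving a prescribed IoU with the expert box
  (rejection sampling over integer edge jitters, ±0.01 tolerance,
  seed-deterministic), and all metrics are recomputed per IoU level for the
  frame baseline and each temporal method. The default grid is the nine
  levels 0.1…0.9; 0.05 and 0.95 are available for larger boxes. Note a
  lattice limit: with integer pixel boxes of width $w$, achievable IoUs
  near 1 are spaced $\mathcal{O}(1/w)$ apart, so targets like 0.95 ± 0.01
  require boxes of roughly 50 px or more.

## The detection-conditioned pipeline

In clinical use the crop box comes from a detector, not an expert.
`run_pipeline()` consumes per-frame detections and reduces them to one
crop box by four rules: frames whose *annotation* holds multiple polyps
are discarded (the rule keys on the ground truth, since a per-lesion label
cannot be attributed across co-occurring lesions); one detected region is
circumscribed by its rectangle; several regions are enclosed in a single
union rectangle; no region discards the frame. Discarded frames lose their
box and therefore break clip continuity exactly like non-annotated frames
— the stricter of the two readings, chosen for consistency with how gaps
are treated elsewhere. Every discard is counted by reason. The detector
itself is out of scope; `simulate_detector()` provides a parametric
stand-in (miss rate, false-positive rate, box jitter) whose identity
setting provably reproduces the expert-box pathway bit for bit.

Cross-validation (`patient_folds()`, `run_crossval()`) splits by
*patients*, never by frames or lesions. Among `n_candidates` random
near-equal partitions the one minimising the summed per-fold deviation of
five balance criteria (NBI polyp frames, lesion count, polyp pixels,
histology mix, quality) from the global distribution is kept; all criteria
are count-valued and equally weighted after normalisation to fold shares,
since no weighting is prescribed. Test predictions from all folds are
pooled before any metric is computed.

## Numerical choices and edge cases

* Boxes are 0-based, half-open integer rectangles; widths, areas and IoUs
  are integer-exact, and `iou()` agrees with rasterised pixel counting.
* Plurality ties (possible only for even $k$) break toward adenoma, the
  clinically conservative direction; $k = 15$ makes ties impossible in the
  default protocol.
* Extreme-vote ties break toward the earliest frame.
* Probabilities exactly at threshold always map to class 0, at every layer
  (per-frame votes, clip outputs, final labels).
* An all-zero image makes NCC undefined and raises an error rather than
  returning a conventional value.
* AUC with single-class labels is reported as `NA`, not invented.
* Training aborts with diagnostics when the loss becomes non-finite.
* All randomness flows through explicit integer seeds, and seeded helpers
  restore the caller's RNG state.

## Problem sizes

The test-suite and acceptance-script defaults were sized so that the whole
path stays comfortable on one CPU: rendered datasets of ~10–40 lesions at
64 px, ~500 preprocessed frames per training run, 15 epochs for the frame
classifier, prediction-stream studies with 1000 lesions × 29 frames, and
robustness sweeps over 3–4 IoU levels on ~100 frames. These sizes are the
package's own desk-scale conditions; every contract they exercise is
size-independent.

## Known limitations

* The reference encoder preserves shapes and interfaces but not pretrained
  weights; claims about ImageNet-initialised backbones are out of scope.
* The synthetic textures make class evidence available in every frame;
  real polyps can be ambiguous for entire sub-sequences, a regime the
  generator only approximates through the `hardness` knob and low-quality
  blurring.
* The Pearson similarity analysis treats clips as independent units,
  ignoring that overlapping windows share frames.
* The normal-approximation CI for polyp accuracy is the conventional
  choice but can overshoot $[0,1]$ near perfect scores; bounds are
  reported unclipped so the degenerate all-correct case stays exact.
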