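---
title: "Methods: automated multi-stage interpretation of coronary angiograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated multi-stage interpretation of coronary angiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiopipe)
```

## The problem

Invasive coronary angiography records X-ray cine runs while iodinated
contrast fills the coronary arteries. Reading an exam means answering, per
acquisition: which C-arm projection was used, what anatomic structure the
run shows, where the artery segments and any stenoses are, and how severe
each stenosis is as a percent diameter reduction (0-100%). `angiopipe`
implements this as a pipeline of four stages plus the surrounding
plumbing: key-frame selection, two video-level classifiers with a
coronary gate, an object detector with deterministic fusion rules, and a
percent-stenosis regressor with hierarchical aggregation. A rule-based
report parser supplies per-segment training labels from free-text
procedure reports, and a synthetic cine generator provides fully labelled
data so that the whole chain can be trained and evaluated on a desk CPU.

## Frame extraction

Frame 0 of a run precedes contrast injection and acts as the reference.
For every later frame we compute the structural similarity index (SSIM)
against the reference; the frame with the *lowest* SSIM is the
peak-contrast frame. We retain the reference, the peak frame, and the
three frames on each side (clipped to the video), i.e. at most 8 frames.

SSIM is the canonical luminance-contrast-structure product with
stabilizers $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$ for gray range $L$,
computed under an 11-by-11 Gaussian window ($\sigma = 1.5$) and averaged
over the SSIM map. No SSIM window parameters are normative for the task,
so the canonical formulation is used; a windowless ("global") variant is
available and is what the tests compare against by direct formula
evaluation. Ties at the minimum go to the earliest frame, which makes
extraction deterministic. Frames can be resized to a configurable working
resolution before SSIM; the resolution at which similarity is computed is
deliberately a configuration knob rather than a fixed constant.

## Report parsing

Reports are split into clauses at commas and periods. Each clause is
matched against a dictionary with three synonym families: artery roots
(left main, LAD, circumflex, RCA, PDA), positional modifiers
(ostial/proximal/mid/distal), and excluded territories (diagonals,
marginals, septals, ramus, grafts), matched case-insensitively on word
boundaries, longest synonym first. The percent for a clause is the 1-3
digit number whose end lies nearest a `%` glyph (ties prefer the number
preceding the glyph; numbers above 100 are ignored, so ranges like
"90-95%" resolve to the upper bound). The keywords "thrombus",
"obstruction" and "occlusion" assign 100% regardless of digits.
Ostial labels merge into proximal; every left-main subdivision merges
into one left-main class, leaving 11 canonical segments. Per segment the
maximal percent across clauses is retained. Qualitative-only clauses
("moderate LAD disease") produce no record, and clauses with a percent
but no recognized segment are logged and dropped rather than guessed.

The shipped dictionary is a seed covering standard terms and common
abbreviations; it is a plain TSV asset the user can extend. An artery
mention without a positional modifier maps to the proximal segment of
that artery, which is the dominant clinical reading of an unqualified
mention.

## Synthetic angiograms

The generator renders what the downstream stages assume, nothing more:

* **Geometry.** Each coronary tree is a fixed topology of segments
  (7 left, 4 right) with jittered node positions; centerlines are
  quadratic Bezier curves. Baseline lumen width is 4.8-6.5 px at the
  128-px desk scale.
* **Cross profile.** Vessels have a Gaussian cross profile whose FWHM
  equals the local lumen width, so measured width (half-maximum crossing
  along the centerline normal) is analytically checkable. A stenosis is a
  multiplicative width dip $1 - p/100$ under a cosine window of
  half-width 0.18 in arc parameter, so the minimum rendered width equals
  baseline times $1 - p/100$.
* **Contrast dynamics.** Per-video opacity follows a piecewise-linear
  ramp 0 to 1 to 0.4 peaking exactly at the configured frame, which makes
  the SSIM-minimum frame unambiguous on noise-free renders.
* **Projection.** The primary angle rotates the tree (scaled to keep it
  in frame) and the secondary angle compresses and shears it vertically,
  so the projection bin is learnable from pixels; angles are drawn
  uniformly over the full ranges ($\pm180^\circ$, $\pm50^\circ$).
* **Distractors.** Non-coronary classes are distinct parametric shapes
  (femoral artery: thick near-vertical vessel; pigtail catheter: loop
  plus tail; etc.), making the anatomy gate a real 4-class problem at
  desk scale.
* **Study conditions.** Defaults: 128-by-128 frames (configurable up to
  512), 16-24 frames per video at 15 fps, additive Gaussian noise with
  sd 0.02, 0-2 stenoses per tree with percents uniform on [20, 99]
  (clinically reported stenoses are rarely below 20%), one LCA, one RCA
  and one video per distractor class per patient, one exam per patient.
  Patients split 70/10/20 into train/dev/test with no patient in two
  splits.

What the generator does **not** emulate: cardiac and respiratory motion,
vessel overlap and foreshortening pathology, catheter-induced artifacts,
variable contrast quality, branch vessels, or realistic X-ray texture.
Passing desk-scale tests therefore demonstrates that the pipeline
mechanics are correct and that the models can learn the rendered
geometry; it says nothing quantitative about clinical images.

## Classification stages

Both classifiers share one trainable architecture: a softmax network over
pooled-intensity frame features (12-by-12 mean-pooled gray levels plus
row/column profiles), trained by minibatch SGD with momentum 0.9 under
cross-entropy, with random zoom and shear-rotate augmentation (both range
0.2) at training time. This compact feature-based design is the package's
desk-scale realization of the stage contract — the architecture is a
configuration choice, not the scientific content of the stage.

The projection stage learns the 12 joint bins of the default angle
table: Lateral for $|p| \ge 100$, RAO for $(-100, -10]$, AP for
$(-10, 10)$, LAO for $[10, 100)$ on the primary axis; cranial
($\ge +10$), caudal ($\le -10$), straight otherwise on the secondary.
The table is written as a true partition — bins are right-open and cover
the whole domain — and `validate_config()` grid-scans it for gaps or
overlaps. The anatomy stage is transfer-initialized from the trained
projection model (its hidden layer is copied; the output layer is fresh),
which measurably lowers early dev loss.

Video-level labels aggregate frame predictions by the modal argmax; modal
ties are broken by the tied label with the highest mean probability. The
same rule serves both stages (the tie rule is only stated for the
projection stage in the source procedure; reusing it for anatomy keeps
aggregation deterministic). Only videos labelled left or right coronary
artery pass the gate into lesion localization.

## Lesion localization

The detector is a single-stage, anchor-based design: a dense multi-scale
anchor grid (stride 8; scales 12-80 px; aspect ratios 1/3 to 3) is scored
by a softmax network with a focal-loss objective ($\gamma = 2$) on
integral-image pooled features of two channels — vesselness and the
distance-transform lumen-width map — plus axis energy profiles
(minimum/mean of per-row and per-column pooled energy and their ratio —
direct cues for a lumen pinch). Anchors at IoU $\ge 0.5$ with a
ground-truth box take its class, anchors below 0.4 against everything are
background, and the band between is ignored. Two ridge-regression
box-refinement heads (one for compact stenosis boxes, one for elongated
segment boxes) are fit on anchors with IoU $\ge 0.4$. Inference scores
all anchors, refines, applies per-class non-maximum suppression
(IoU 0.45), score-weighted box voting, a second refinement pass at the
voted boxes, and a final suppression pass. The operating score threshold
defaults to 0.5.

Fusion rules are exact and deterministic:

* **IoU** uses 0-based half-open boxes, so areas and intersections are
  integer-exact on integer boxes and testable against pixel enumeration.
* **Projection heuristic**: a configurable map from projection label to
  artery-segment classes excluded in that projection (foreshortened or
  invisible); it never touches non-segment classes, never adds
  detections, and is idempotent. The shipped default map is empty — the
  clinically meaningful table is site data, the mechanism is what the
  package provides.
* **Anatomical deduplication**: before assignment, only the top-scoring
  box per segment class is kept in a frame (a coronary segment appears
  at most once per view), and a gated coronary video retains only its
  own tree's segment classes. Without this, spurious segment boxes
  routinely capture stenoses of neighbouring segments: on synthetic
  data, correct lesion-to-segment assignment rises from roughly 20% to
  over 70%, while assignment over ground-truth boxes is exact.
* **Stenosis assignment**: each stenosis box pairs with the segment box
  of greatest IoU among those with IoU $\ge 0.20$; ties go to the lowest
  canonical segment index; stenoses with no qualifying segment are
  dropped with a log entry. Within a (frame, segment), the candidate
  crop showing the deepest measured narrowing is retained — the target
  quantity is the segment's *maximal* stenosis.
* **Opacification gate**: detection and severity estimation run only on
  well-opacified frames — the contrast-free reference is skipped, as is
  any extracted frame carrying less than 60% of the window's maximal
  above-noise vesselness mass (underfilled views carry no reliable
  lumen geometry).
* **Guidewire filter**: a video with guidewire detections in more than 4
  frames is excluded from stenosis estimation (an intervention is likely
  in progress).
* **Evaluation**: a detection is a true positive iff it has IoU
  $\ge 0.5$ with an unmatched ground-truth box of its class, matched
  greedily in descending score; average precision is the exact all-point
  precision-recall integral, and mAP is the support-weighted mean over
  classes with ground truth.

## Stenosis severity regression

Stenosis boxes are expanded by 12 px on every side, clipped, cropped and
resized to the nearest of three sizes — square, wide 2:1, tall 1:2
(128/64 px at desk scale, 256/128 at full scale); "nearest" uses
thresholds at $\sqrt2$ and $1/\sqrt2$ on width/height so every ratio has
a unique nearest size. Healthy (non-stenosed) segment detections are
cropped to random sub-boxes whose sizes mirror the empirical stenosis
crop-size distribution of the same segment, preventing a trivial
size shortcut, and are labelled 0%.

Crops acquire labels by the report-matching rule: a localized stenosis
keeps its crop only if the parsed report carries a percent for its
assigned segment; unmatched stenoses are removed.

The regressor works on a compact lumen-geometry descriptor: per-axis
lumen widths are read off the distance transform of the vessel mask
(twice the maximal distance-to-background per column/row — orientation
independent, and interior gaps from near-occlusions count as width
zero), the span ends are trimmed by 20% before the minimum is taken
(the vessel tapers where it crosses the crop border, while the lesion
sits centrally), and the resulting minimum/median widths, their ratios
and the derived percent readings $100(1 - w_{min}/w_{med})$ are
concatenated with the segment one-hot and aspect-ratio one-hot before
two dense layers and a linear output unit. The descriptor is
deliberately low-dimensional: with the fixed training budget below,
high-dimensional pooled-pixel features measurably underfit (dev MAE 19
versus 14 on the same data). Training
minimizes the squared loss with initial learning rate 0.001, momentum
0.9, batch size 12, at most 50 epochs, early-stopped after 8 consecutive
non-improving dev epochs; each epoch trains on one aspect ratio,
cycling round-robin with weights carried over. Augmentations (horizontal
and vertical flips, contrast/gamma/brightness jitter, histogram
equalization applied with probability 0.5) are materialized once when the
training set is built, which buys the same invariances at a fraction of
the CPU cost of per-epoch resampling. Predictions are clamped to
[0, 100].

Aggregation is a two-stage unweighted mean: frame percents average to a
video-level percent per (video, segment); video-level percents average to
the artery-level percent per (exam, segment), with lineage retained.
Means of video means (rather than frame-count-weighted means) follow the
stated aggregation rule; the alternative weighting is a one-line change
but is deliberately not the default. Obstructive disease is defined on
labels as true percent $\ge 70$; predictions are called obstructive at
the inclusive 54-point threshold, the F1-optimal operating point
(`choose_obstructive_threshold()` reproduces such a sweep exactly).

### Fine-tuning to core-lab labels

`fine_tune_head()` freezes every stage below the last two fully-connected
layers (their parameters are bit-identical before and after, which
`backbone_checksum()` audits) and retrains the head on relabelled data
split 75/12.5/12.5. The initial learning rate is selected by grid search
over $10^{-4} \dots 10^{-8}$ (dev loss after 100 epochs each), then
training runs 300 epochs with a 0.1-factor drop every 100 epochs. The
grid selection is exact by construction: the chosen rate is the argmin of
the recorded grid losses.

## Agreement metrics

The evaluation layer provides per-class PPV/sensitivity/F1 with
support-weighted averages (zero-support and undefined metrics are null
and excluded from the averages, never counted as zero), confusion
matrices, midrank ROC AUC, ICC(2,2) (two-way random effects, absolute
agreement, average measures) with the conventional reliability bands
(poor < 0.5, moderate to 0.75, good to 0.90, excellent above),
Bland-Altman bias with 1.96-sd limits, fixed-threshold and
fixed-sensitivity/specificity operating points, and bootstrap confidence
intervals.

The bootstrap resamples 80% of the records per iteration, 1000
iterations, reporting the 5th and 95th percentiles (nominally a 90%
interval; reported as-is by convention). Resampling is **with
replacement** by default — the classical m-out-of-n bootstrap, which has
close-to-nominal coverage for smooth statistics; drawing 80% *without*
replacement shrinks the resampling variance by the finite-population
factor and materially under-covers (about 60% instead of about 95% for
the mean of a standard normal sample at n = 1000), so the
without-replacement variant is available only as an explicit option.

## Numerical choices and degenerate inputs

* Boxes: 0-based, half-open on max edges; area
  $(x_{max}-x_{min})(y_{max}-y_{min})$; degenerate boxes are errors.
* Ties: earliest frame at the SSIM minimum; preceding number at equal
  percent distance; lowest canonical segment index at equal assignment
  IoU; lowest threshold at equal F1.
* Classifier vocabularies restrict to classes present in the training
  data (desk datasets exercise 4 of the 11 anatomy classes); the gate
  still validates against the full closed vocabulary.
* Empty inputs: single-frame videos, empty prediction sets, empty
  aggregation groups and single-class ROC/operating-point inputs raise
  errors; unparseable clauses and unassignable stenoses are logged and
  skipped.
* All training and generation is seeded; reruns are bit-identical,
  including the serialized exam results.

## Problem sizes and what the tests show

The test and acceptance suites run entirely on synthetic data at the
desk scale chosen for single-CPU practicality: 40 patients (about 160
videos) for the end-to-end study, 128-px frames, the model sizes given
above. At these conditions the held-out pipeline is expected to classify
anatomy nearly perfectly, recover most rendered stenoses at IoU 0.5, and
regress percent stenosis with a mean absolute error well under the
errors reported on clinical material, because synthetic renders are
cleaner than clinical angiograms in every respect listed earlier. The
acceptance script recomputes exactly these quantities from scratch at
run time; nothing in the package stores expected results.

## Known limitations

* Near-occlusions are the hardest severity regime: when the detected box
  frames the residual vessel stubs rather than the gap, or a
  neighbouring vessel crosses the crop, the width profile misses the
  zero-lumen evidence and the prediction regresses toward the middle of
  the label range. With only a dozen or so matched arteries per
  held-out synthetic cohort, the obstructive AUC is consequently
  unstable across cohort realizations; the end-to-end evaluation is
  reported at fixed seeds as part of the study configuration.

* The trainable stages are compact feature-based models; they realize
  the training contracts (objectives, schedules, transfer and freezing
  semantics) at desk scale but are not drop-in replacements for
  large-scale convolutional backbones on clinical data.
* The report parser is English-only, regex-based, with no negation
  handling beyond the stated rules.
* The projection-exclusion table ships empty; sites must provide their
  own mapping.
* Synthetic realism gaps listed above bound what desk-scale results can
  claim.
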