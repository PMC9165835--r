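---
title: "CowPose: models, parameters and design choices"
author: "CowPose authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CowPose: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CowPose)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the choices we made where the
underlying method leaves details open.

## The problem and the pipeline

Daily poses of dairy cows — standing, walking, lying — summarize activity
and welfare. Estimating them from overhead surveillance requires three
stages: locating each animal (bounding boxes), locating its body parts
and grouping parts into individuals (multi-animal pose estimation), and
classifying the assembled skeleton's pose. CowPose implements the
*bottom-up* variant of the middle stage: all part candidates are detected
first and then grouped into animals, which degrades more gracefully under
partial occlusion than cropping each animal first.

The package deliberately does not train or run the convolutional networks
that would produce heatmaps, part affinity fields or boxes from raw
pixels. Instead it implements everything around them exactly: the
ground-truth encodings the networks would be supervised with, the full
decoding/grouping stage, the box geometry and losses, the skeleton
classifier, and the metrics. This makes every stage testable end to end:
encoding the ground truth and decoding it back must be lossless under
separation assumptions stated below, and that property is enforced in the
test suite.

## Skeleton model

Sixteen keypoints (part ids 1–16): head; left/right front leg root, knee,
hoof; left/right hind leg root, knee, hoof; neck; spine; coccyx.
Visibility is three-state as in common annotation practice: 2 = labeled
and visible, 1 = labeled but occluded, 0 = missing. Every consumer in the
package treats visibility > 0 as "labeled" and ignores coordinates of
missing keypoints.

Coordinates are pixels, origin at the image top-left, x rightward,
y downward, 0-based — the convention of Labelme/LabelImg and of array
indexing in image analysis. Synthetic keypoints are rounded to integer
pixels, which is both what annotation tools deliver and what makes
"exact recovery" of a heatmap peak a well-defined notion.

The limb set is not dictated by the keypoint list, so the package adopts
a 15-edge anatomical spanning tree (head–neck–spine–coccyx axis; front
legs rooted at the neck, hind legs at the coccyx; each leg a
root–knee–hoof chain) and exposes it through `defaultLimbGraph()` and the
config. A tree has two practical advantages: every part is reachable, and
per-limb one-to-one matching can never assign two candidates of the same
part to one instance (assembly asserts this).

## Heatmap and PAF encoding

The heatmap of part $j$ is $S_j(p) = \exp(-\lVert p-x_j\rVert^2 /
2\sigma^2)$, combined across animals by the pixelwise **maximum** so that
close peaks are preserved rather than averaged. The PAF of limb $c$
assigns the unit vector from part $a$ to part $b$ to every pixel in the
band "along-segment projection in $[0, \text{length}]$, perpendicular
distance $\le$ `limbWidth`", and the **mean** of unit vectors where limbs
of several animals overlap (opposing limbs cancel — informative in
itself, since a cancelled field scores no limb hypothesis).

Parameter defaults, all configurable through `poseConfig()`:

* `sigma` = 2 px. The spread of the keypoint Gaussian at encoding
  resolution. The underlying method calls it a "fixed variance" without a
  value; 2 px at our 270×480 working resolution gives peaks that are
  sharp (support ~8 px) yet wide enough to be found by 3×3 non-maximum
  extraction.
* `limbWidth` = 4 px, the half-width of the on-limb band — roughly half a
  leg's drawn width at this scale.
* Heatmaps are computed at full image resolution. Network stride and
  downsampling belong to the (out-of-scope) learned stage, so nothing
  here needs them.

Peak extraction (`extractPeaks()`) is deliberately boring and
deterministic: a pixel is a candidate if it is $\ge$ each of its eight
neighbors and $\ge$ `peakThreshold` (default 0.1); candidates are sorted
per part by descending score with plateau ties broken by smaller y then
smaller x. Determinism here is what makes the whole decode pipeline
byte-reproducible.

## Grouping: line integral, assignment, assembly

A limb hypothesis between candidates $d_1, d_2$ is scored by
$E = \int_0^1 L_c(p(u)) \cdot \frac{d_2-d_1}{\lVert d_2-d_1\rVert}\,du$,
approximated by `nSamples` = 10 uniformly spaced samples with
nearest-pixel field lookup. $E \in [-1, 1]$, equals 1 exactly when every
sample lies in the limb's own band, and is antisymmetric in its
endpoints, so limb direction matters. Ten samples suffice because the
field is piecewise constant at pixel scale; the quadrature rule is a
package choice, stated here because no standard exists.

Per limb, the bipartite assignment maximizing total score is solved
exactly (Hungarian algorithm via `clue::solve_LSAP`); pairs scoring below
`scoreThreshold` = 0.05 are removed *after* assignment, so weak pairs
never block strong ones. The test suite checks the assignment against
exhaustive permutation search on random matrices — the implementation and
the oracle never share code. Assignment is independent per limb type, as
is standard in bottom-up grouping; a global joint optimization over all
limbs is NP-hard and deliberately not attempted.

Matched limbs sharing a candidate are merged into instances by
union-find. Instances with fewer than `minParts` = 4 keypoints are
returned as unassigned rather than reported as animals — a guard against
stray peak pairs.

**Recovery guarantee exercised by the tests:** for scenes whose animals
have disjoint, well-separated bounding boxes (the generator enforces a
12 px gap) and no keypoint jitter, encode → extract → integrate → match →
assemble returns exactly one skeleton per animal with OKS = 1. Peaks are
exact because keypoints are integer pixels; true limb pairs score exactly
1 and dominate any cross-animal pairing.

## Box geometry

The literal grid-cell decoding applies the logistic function to the whole
sum, e.g. $x_{\min} = \sigma(t_x + C_x - t_w/2)$. Taken literally this
confines every box to the unit square regardless of grid cell — an
unusual formulation, most plausibly a transcription artifact in the
source material. Rather than guessing intent, `decodeBox()` implements
the literal formula as the default and offers the canonical YOLO
decoding (`mode = "canonical"`: $\sigma(t)+C$ scaled by the grid size,
exponential width/height) behind a flag. Anchor boxes are out of scope;
$t_w, t_h$ are treated directly as extents.

CIoU loss follows the standard three-term form (overlap, normalized
center distance, aspect-ratio penalty with its adaptive weight
$\alpha = \upsilon/((1-\mathrm{IoU})+\upsilon)$, defined as 0 when
$\upsilon = 0$). A zero box height is an error, since the aspect term's
$\arctan(w/h)$ is undefined there. NMS uses `nmsIou` = 0.5 ("high
overlap" is not quantified anywhere authoritative; 0.5 is the field's
default).

## Pose classifier

Features: each labeled keypoint's $(x, y)$ normalized per axis to the
skeleton's own bounding box, missing parts at $(0,0)$ — 32 numbers. This
makes the classifier invariant to where the animal stands and how large
it appears, which is the point of classifying skeletons rather than
pixels; a raw-pixel mode exists for users who want scale information
(`normalize = FALSE`). A degenerate (zero-extent) axis falls back to
`max(extent, 1)` with a warning.

Architecture: 32 → 128 → 64 → 16 → 4, batch normalization and ReLU after
each hidden layer, softmax output. The fourth output unit exists in the
architecture we mirror; only three poses carry training data, so it is
documented as "other/transition" and reported but never trained on by
default — we do not invent labels for it. Training details left open by
the source are fixed as package defaults: Adam (lr $10^{-3}$),
cross-entropy, batch 32, 30 epochs, seed 0. Batch normalization uses
batch statistics in training and exponentially averaged running
statistics (momentum 0.9) at inference. The entire backward pass is
implemented in the package and checked against central finite differences
in the test suite, so the classifier is not a black box either.

## Evaluation

Detection counting follows the literal rule set we mirror: a prediction
matched at IoU $\ge$ threshold is a TP, any other prediction an FP, and a
ground-truth box is an FN **only when it has zero overlap with every
prediction**. That last rule is nonstandard (a grazed-but-unmatched GT
counts as neither TP nor FN, so recall can exceed the COCO value);
`classifyDetections(mode = "coco")` provides the conventional rule. AP
integrates the interpolated precision envelope over recall (all-point
interpolation).

OKS uses a single object scale $s$ (default $\sqrt{\text{GT bbox area}}$)
and uniform per-part constants $k_i = 0.1$; neither is prescribed in our
source material, and the defaults follow COCO practice in spirit (scale
from object area, per-part constant of magnitude 0.1). The visibility
indicator in the OKS sum is read as "labeled" ($v > 0$), since the
annotation coding marks visible keypoints 2 and occluded ones 1 — an
occluded but labeled keypoint still has a ground-truth position to score
against. OKS-thresholded AP matches predictions to GTs greedily by
descending OKS and counts pairs strictly above the threshold (default
0.5) over the number of GT objects.

Confusion-matrix metrics are column-precision, row-recall, trace
accuracy, and the column-share matrix ("of everything predicted standing,
what fraction was actually walking"). Zero rows/columns yield NA, never a
silent 0.

## The synthetic generator

The generator exists so that grouping, classification and evaluation can
be tested without farm footage. It emulates:

* side-view stick cows with body length 120 px and leg length 70 px on a
  270×480 canvas (a scaled-down surveillance frame);
* three pose classes constructed to differ in learnable skeleton
  features: standing (straight legs, common ground line), walking
  (standing geometry with knees/hooves displaced by sinusoids of a gait
  phase; per-leg phase offsets 0, $\pi$, $\pi/2$, $3\pi/2$ — a four-beat
  lateral gait, so some limb is displaced at every phase; a per-sample
  stride scale drawn from $U(0.1, 1)$ makes low-stride walking frames
  genuinely resemble standing, which is the confusable pair in real
  footage), and lying (lowered body axis, legs folded within
  $0.3\times$ leg length of their roots, overall height under half the
  standing height);
* per-keypoint Gaussian jitter (default sd 2 px) standing in for
  annotation noise, optional left–right flips;
* multi-cow scenes with either pairwise-disjoint boxes (12 px minimum
  gap) or one forced partially overlapping pair (box IoU in [0.1, 0.4]),
  whose covered keypoints become visibility 1 with a random half removed
  to 0 — occlusion marks keypoints invisible rather than deleting them,
  matching three-state labeling practice;
* day/night lighting (night scales intensities by 0.4 and adds sensor
  noise), mosaic augmentation (mirror/flip/90°-rotate/crop four inputs,
  stitch at a random split, drop annotations whose box area falls below
  20% of the original), and multiplicative brightness perturbation.

Scene placement first tries random positions and falls back to a
shuffled scan of a coarse origin grid, restarting the whole arrangement
up to 25 times before declaring the canvas too small — dense scenes (five
cows on the default canvas occupy ~60% of it) would otherwise fail on
unlucky arrangements that fragment the free space.

What the generator does **not** emulate, and hence what passing tests do
not show: photorealistic appearance, perspective foreshortening and the
top-down camera angle, animals touching or crossing, heatmap/PAF
*prediction error* (our fields are encoded, not inferred), and class
ambiguity beyond the stride continuum. Classifier accuracies on this
generator (typically 0.93–0.98 held out, with standing↔walking the
dominant confusion) therefore demonstrate that the architecture and
training code work and that the regime matches field experience — not
that this accuracy would transfer to any particular barn.

## Numerical and reproducibility choices

* All randomness flows through explicit seeds; generators, training and
  the pipeline are bit-reproducible given the seed, and seeded code
  restores the caller's RNG state.
* Ties in peak extraction and NMS are broken deterministically
  (score, then y, then x; confidence, then input order).
* The line integral's degenerate case ($d_1 = d_2$) is an error, as is a
  zero-length limb at encoding time (skipped with a warning).
* Problem sizes used by the test suite and acceptance script: scenes up
  to 5 cows at 270×480; 200 random assignment matrices up to 5×5; the
  classifier dataset of 600 skeletons per pose with a 9:1 train/held-out
  split. These sizes were chosen to exercise every code path at full
  fidelity while keeping a complete run in well under a minute of CPU.

## Known limitations

* No learned components: the package scores and groups *given* fields;
  plugging in predicted heatmaps/PAFs from an external network is the
  intended use, but no network ships here.
* Grouping quality under heavy occlusion is limited by per-limb
  independent assignment; a midpoint/count penalty criterion (sometimes
  used in bottom-up grouping) is not implemented because our source
  material does not state one.
* The pose classifier sees single-frame skeletons only; transitions
  (lying down, getting up) are exactly the frames it cannot represent,
  and the untrained fourth output unit does not fix that — it merely
  leaves room.
* OKS constants are uniform; per-part constants estimated from real
  annotation variance would be better and can be passed via `k`.
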