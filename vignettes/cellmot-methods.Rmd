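---
title: "Methods: detection blocks, tracking-by-detection, and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection blocks, tracking-by-detection, and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmot)
```

`cellmot` implements the computational core of a tracking-by-detection
pipeline for cells in time-lapse microscopy: lightweight neural building
blocks with exact parameter accounting against a nano-scale one-stage
detector topology, a BoT-SORT-style tracker, the standard multi-object
tracking (MOT) metric families, and a seeded synthetic-sequence generator
that makes everything testable at desk scale. This vignette explains the
models, the conventions, and the design decisions — in particular every
place where a choice was genuinely open.

## Neural building blocks

### Efficient multi-scale attention (`ema_block()`)

The attention block operates per channel group (group factor `g`, default
32, the reference configuration; channels must divide evenly). Each group of
`c = C/g` channels is processed independently:

* **1×1 branch.** The group is average-pooled along each spatial axis
  separately; the two pooled descriptors are concatenated, passed through a
  shared 1×1 convolution, split again, and turned into sigmoid gates that
  re-weight the group along height and width. The gated tensor is
  channel-wise instance-normalised (affine).
* **3×3 branch.** The raw group passes through a 3×3 convolution, expanding
  the local receptive field.
* **Cross-spatial aggregation.** Each branch produces a global descriptor
  (spatial mean, softmax over channels) that is matrix-multiplied against
  the *other* branch's flattened feature map. The sum of the two pairwise
  aggregation maps is squashed by a sigmoid into one spatial attention map
  that re-weights the group.

The output has exactly the shape of the input, so the block can be inserted
anywhere in a network. No channel dimensionality is reduced at any point.

### Inverted-residual wrapper (`iema_block()`)

The attention operator is embedded in an inverted-residual skeleton:

```
y   = EMA(BatchNorm(x))
z   = DWConv3x3(y)          # depthwise, per-channel groups, stride 1
s   = y + z                 # inner residual
out = PWConv1x1(s) + x      # pointwise projection, outer residual
```

The depthwise and pointwise stages are conv+BN+SiLU blocks; the input
normalisation is a standalone batch norm. The outer residual guarantees that
a block whose convolution weights are all zero is the exact identity — a
property the tests assert elementwise. All normalisation layers run in
inference mode (stored statistics), so forwards are bit-reproducible.

### Group-shuffle convolution (`gsconv_block()`)

A standard convolution maps `C1 → C2/2` channels (kernel and stride as
configured), a depthwise convolution (kernel 5, the slim-neck reference
choice) processes those channels, the two maps are concatenated to `C2`
channels, and a channel shuffle interleaves them (`reshape (2, C2/2) →
transpose → flatten`), mixing information between the dense and depthwise
halves. Multiply-accumulate costs are

* standard convolution: `T_SC = W·H·K1·K2·C1·C2`
* group-shuffle block: `T_GS = W·H·K1·K2·(C2/2)·(C1+1)`

so `T_GS/T_SC = (C1+1)/(2·C1)`, approaching one half from above as the input
width grows. `conv_cost()`/`gsconv_cost()` evaluate these exactly in integer
arithmetic.

## Detector topology and parameter accounting

`build_model()` assembles the nano-scale one-stage detector graph: a
backbone of strided convolutions and split-bottleneck stages, a spatial
pyramid pooling block and a partial self-attention stage at the lowest
resolution, a feature-fusion neck across the P3/P4/P5 pyramid levels
(strides 8/16/32), and a decoupled detection head with a distributional
box-regression branch and a depthwise-separable classification branch whose
width is `c3 = max(64, min(nc, 100))`. Four variants are built from one
description:

* `baseline` — the unmodified topology;
* `iema` — one inverted-residual attention block inserted on the P3 neck
  branch, directly after the small-object fusion stage (64 channels at nano
  width). P3 is the branch responsible for small objects, which is where
  small deformable cells live;
* `gsconv` — the two neck downsample convolutions feeding the P4 and P5
  fusion concatenations (64→64 and 128→128, 3×3 stride 2) replaced by
  group-shuffle convolutions;
* `iegs` — both modifications. They touch disjoint layers, so their
  parameter deltas are exactly additive.

`count_parameters()` enumerates every parameter tensor layer by layer and
supports two counting conventions:

* **deployment** (default): each fusable conv+BN pair is counted as the
  convolution weights plus one folded per-channel bias. This is the
  convention in which deployed (BN-folded) model sizes are reported, and the
  convention under which the package's reference totals are defined
  (baseline at 14 classes: 2,584,882 parameters; with both modifications:
  2,500,290). Blocks assembled from explicit separate conv and norm
  primitives — the group-shuffle internals and the inverted-residual input
  norm — keep their full affine pairs, because there is no host convolution
  to fold them into.
* **training**: every trainable scalar, batch-norm affine pairs included.

Under the deployment convention the attention insertion adds exactly
`2·64 + 48 + 640 + 4,160 = 4,976` parameters and the group-shuffle
replacement removes `184,512 − 94,944 = 89,568`, independent of the class
count; the class count enters only through the final classification
convolutions (3 scales × `(64 + 1)` parameters per class).

Detection inference is deliberately an *injection contract*: `detect()`
validates and normalises the output of a backend function per frame
(`stub_detector()` builds one from a table of boxes). Training and learned
weights are out of scope; every tracker and metric experiment in this
package runs from simulated or injected detections, which is exactly what
makes it reproducible without a GPU or external data.

## Tracker

### Motion model

Each track carries an 8-dimensional state `(cx, cy, w, h, vx, vy, vw, vh)`
in pixels and pixels/frame — box centre, size, and their velocities. The
transition matrix is constant-velocity with unit time step; the observation
matrix selects `(cx, cy, w, h)`. Process and measurement noise are diagonal
with standard deviations proportional to the current box size
(`std_weight_position = 1/20`, `std_weight_velocity = 1/160`, the
ByteTrack/BoT-SORT convention): larger cells are allowed proportionally
larger innovations. Fresh tracks start at the measurement with zero velocity
and an inflated diagonal covariance (2× position weights, 10× velocity
weights). After every update the width and height are clamped positive.
Covariances are symmetrised after each step and validated symmetric positive
semi-definite on input.

### Two-round association

Detections are split by confidence: scores ≥ `tau_high = 0.5` form the
high set, scores in `[tau_low = 0.1, 0.5)` the low set. Round 1 matches all
live tracks (active and lost) against the high set by minimising total
IoU distance (`1 − IoU`) under an optimal linear assignment; a pair is
rejected when its cost exceeds `match_threshold = 0.8`. Round 2 repeats the
procedure between the remaining tracks and the low set with the same gate.
The low-confidence round is what recovers cells whose detector score dips
temporarily (partial occlusion, deformation) — without it the track goes
lost, its linear prediction drifts off a turning cell, and the re-detection
spawns a fresh identity. The package exposes `two_rounds = FALSE` as an
ablation switch, and the test suite shows the ablation strictly increases
identity switches on curved-motion confidence-dip fixtures.

Decisions that the surrounding literature leaves open, fixed here once:

* The match gate is interpreted as a *cost* threshold (`1 − IoU > 0.8`
  rejects) and applied to both rounds.
* Detection scores are not fused into the round-1 cost by default
  (`fuse_score = FALSE` exposes the option).
* No appearance/re-identification embedding: association is IoU-only.
* Lost tracks are kept `lost_buffer = 30` frames (one second at 30 fps),
  then removed permanently; identities are never reused.
* New tracks are active immediately upon creation — no probationary state.
* Assignment ties are broken deterministically towards lower track id, then
  lower detection index, via an infinitesimal lexicographic cost
  perturbation (1e-9 scale over the matrix; real IoU differences dominate).

### Camera-motion compensation

When enabled and frames are supplied, a global transform between
consecutive frames is estimated and applied to the predicted track means
before association (detection boxes are never touched). `translation` mode
uses FFT phase correlation (integer-pixel peak); `affine` mode fits a 2×3
transform by least squares over a grid of local block translations and maps
box corners, so sizes follow the linear part. Estimation failure falls back
to the identity with a warning. Microscopy stages do drift; pure
translation is the realistic case and is recovered exactly on constructed
fixtures.

## Evaluation metrics

All metrics follow MOTChallenge conventions: 1-based frames,
`(left, top, width, height)` boxes, IoU threshold 0.5 by default, every
prediction evaluated regardless of confidence.

* **CLEAR-MOT** (`clear_mot()`): per-frame correspondence with carry-over —
  matches from the previous frame persist while still valid at the
  threshold, the remainder is matched by optimal assignment on `1 − IoU`.
  An identity switch is counted when a matched ground-truth object's
  prediction identity differs from its *last* assigned identity (gaps
  included). `MOTA = 100·(1 − (FN + FP + IDSW)/|GT|)`; empty ground truth is
  an error, not a silent zero.
* **IDF1** (`idf1()`): one global bipartite assignment between whole
  ground-truth and predicted trajectories (dummy-padded, minimising identity
  false positives plus false negatives), then
  `IDF1 = 100·2·IDTP/(2·IDTP + IDFP + IDFN)`.
* **HOTA** (`hota()`): for each localisation threshold α in 0.05…0.95, a
  single per-frame matching maximising globally-aligned similarity is
  thresholded at α; `HOTA_α = sqrt(DetA_α · AssA_α)` and the final score
  averages the 19 thresholds. The per-α decomposition is returned and
  plotted by `autoplot()`.

No reference implementation of these metrics exists in this package's
dependency footprint, so correctness is established by a dual route: the
test suite re-derives every metric with independent brute-force machinery
(exhaustive assignment enumeration, direct-definition accumulation) and
requires agreement to 1e-6 on fifty randomized fixtures, alongside exact
hand-computed toy cases.

## Synthetic sequence generator

`simulate_tracks()` emulates the regime of low-resolution cell-tracking
video: a 400×320 pixel field at 30 frames/s with many small deformable
cells. Each cell is the axis-aligned bounding box of an ellipse whose centre
follows drift + persistent heading (optionally turning at `turn_rate`
degrees/frame) + Gaussian diffusion (default 1.5 px/frame), and whose
semi-axes (~N(12, 2) px) fluctuate multiplicatively (log-sd 0.02 per frame).
Divisions occur per cell per frame with a small probability (default 0.001);
by default the parent identity terminates and two fresh identities are
born — the identity-safe convention; `parent_keeps_id = TRUE` exposes the
other convention, since public benchmarks differ here. Cells whose box
leaves the field terminate; optional Poisson entries add new cells; an
optional single-pass repulsion keeps a no-occlusion regime available for
exact-recovery tests. Identities are globally unique with contiguous frame
intervals, and output is valid MOTChallenge ground truth.

`corrupt_detections()` is the mock detector: independent per-box dropout,
Gaussian box jitter, truncated-normal confidence for true detections
(mean 0.85, sd 0.08) and Poisson low-confidence false positives (mean 0.3,
sd 0.1) sized from the cell prior. `render_frames()` produces grayscale
frames — background level 0.25 with texture noise sd 0.04 plus Gaussian
elliptical blobs of contrast 0.35 — sufficient for motion-compensation
fixtures, not photorealistic microscopy.

All randomness is drawn from counter-based hashed streams keyed by
`(seed, component, cell id, frame)`, so output is byte-identical across runs
and toggling one component (say, corruption) never shifts the draws of
another (say, motion). This is why paired ablation comparisons across seeds
are exact.

**What passing tests do and do not show.** The generator reproduces the
*structure* of the benchmark regime — geometry, kinematics, division,
detector failure modes — but not real microscopy appearance: no ambiguous
boundaries, no cell-line-specific morphology, no dense mutual occlusion, no
annotation noise. Closed-loop perfection (MOTA 100 on clean input) and the
ablation ordering are properties of the algorithms, demonstrated under
controlled conditions; they are not claims about accuracy on real data,
which depends on a trained detector and is out of this package's scope.

## Numerical choices and problem sizes

* Convolutions are evaluated by im2col + matrix multiplication; activations
  are SiLU; normalisation always uses stored statistics (inference mode).
* Kalman updates solve the innovation system directly
  (`K = (S⁻¹ H P)ᵀ` via a dense solve); a singular innovation covariance is
  a reported numerical error. Covariance symmetry is enforced to 1e-9.
* Linear assignments use the Hungarian solver from `clue`, with infeasible
  pairs carried at a prohibitive finite cost so the solver maximises the
  number of feasible matches first.
* Degenerate boxes (non-positive extent) have IoU 0 by definition; empty
  detection sets propagate as empty results everywhere.
* Test and example problem sizes — sequences of 20–60 frames with 4–10
  cells, 20-seed ablation batteries, 50 metric fixtures, 100-draw filter
  checks — were chosen as the smallest sizes at which every property under
  test is non-trivially exercised.

## Known limitations

* The detector is a graph for accounting and structural inspection plus an
  inference contract; it does not run a trained network forward pass.
* Association is IoU-only; appearance embeddings are not implemented.
* Affine motion compensation relies on block-wise translation estimates and
  degrades on strongly textured rotation; translation is the robust mode.
* HOTA follows the shared-matching formulation described above; published
  implementations differ in the third decimal across versions.
* The GFLOPs-style cost functions count multiply-accumulates of single
  layers; no whole-network FLOPs figure is produced, as those depend on
  convention.
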