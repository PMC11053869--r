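---
title: "Dilated heterogeneous convolutions: model, cost accounting and synthetic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dilated heterogeneous convolutions: model, cost accounting and synthetic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhcnn)
```

## The operator and its assumptions

A convolution filter over an `M`-channel input is a stack of `M` per-channel
kernels. The heterogeneous idea is to stop making them all the same size: a
fraction `P` of the kernels in each filter keep the full `K × K` shape while
the remaining `(1 − P)·M` become pointwise `1 × 1`. DHConv additionally
dilates the surviving large kernels by rate `r`, spreading their `K × K`
taps over a `(K − 1)·r + 1` pixel extent. The pointwise kernels preserve
per-pixel channel mixing at negligible cost; the dilated kernels preserve —
and widen — spatial context. The operator assumes `K` odd (so a symmetric
same-padding exists), `1/P` integer, and `M` divisible by `1/P` so every
filter carries a whole number `M·P` of large kernels.

`apply_dhconv()` computes the layer as two parallel branches summed: the
dilated branch padded by `r·(K − 1)/2` per side and the pointwise branch
unpadded, so the branch outputs align spatially at any stride and a stride-1
layer is shape-preserving — the property that makes drop-in backbone
replacement possible. One bias per filter is shared across both branches: a
filter is one unit regardless of its kernel mix.

**Channel layout.** Which channels of a filter keep the large kernel is a
free choice. The default `shifted` layout assigns channel `c` of filter `f`
(0-based) to the large kernel iff `(c + f) mod (1/P) = 0`, so consecutive
filters offset their large-kernel channels and every input channel is
covered by a large kernel in the same fraction `P` of filters whenever the
filter count is a multiple of `1/P`. A `leading` layout (first `M·P`
channels of every filter) is available for comparison. The shifted default
follows the original heterogeneous-kernel design; with only pictorial
evidence for the exact arrangement, the choice cannot be settled further,
which is why both are exposed and the cost model is layout-independent.

**Verification.** `dense_oracle()` materializes every (filter, channel) slot
as a dense `K_D × K_D` kernel — large-kernel taps scattered onto the
dilation grid, pointwise weights as a single centre value — and performs a
plain dense convolution in R. The fast path must agree with it to 1e-5 on a
seeded grid of `K ∈ {1,3,5}`, `P ∈ {1/4,1/2,1}`, `r ∈ {1,2,3}`,
`C, N ∈ {4,8}` (single-precision tolerance; accumulation order is not
pinned). The oracle also counts the nonzero-weight multiply–accumulates,
which must equal the analytic cost model exactly.

## Cost model conventions

FLOPs are counted as multiply–accumulates, biases excluded and no factor of
two for the addition — the convention under which the standard layer costs
`D_w·D_h·N·K²·C`. Dilation inserts holes that carry no weights, so it never
changes a count. The heterogeneous layer costs the large-kernel share
`FL_c·P` plus the pointwise share `D_w·D_h·C·(N − N·P)`, giving the closed
form ratio `R_hc = P + (1 − P)/K²`: exactly `1/3` at `P = 1/4, K = 3`, and
exactly 1 when `P = 1` (for `K = 1` the "large" kernel is itself pointwise,
so the ratio is 1 there too). Ratios are exact rationals up to double
precision and tested at 1e-12.

`count_model_flops()` walks a backbone description, propagating spatial
dimensions through the same-padding/stride contract
(`out = floor((in − 1)/s) + 1`). Only convolutions are counted;
normalization, activation and pooling layers contribute zero, and dense
heads are excluded unless requested — the analytic model covers convolutions
only, which is also why a whole-network measurement can shrink less than the
per-layer ratio suggests: the untouched stem, the 1×1 convolutions and
everything outside the backbone dilute the saving. On the ResNet-50
description the sixteen converted 3×3 bottleneck convolutions cost exactly
1/3 of their originals while the backbone total drops to about 0.70.

## Backbone conversion

`conversion_policy()` defaults to `P = 1/4`, `r = 2`, applied uniformly to
every 3×3 convolution inside a residual bottleneck block — the stem, the
1×1 convolutions and the downsample projections are never touched, and
strides are preserved. Stage-wise variation of `r` is deliberately not
attempted: nothing in the recipe this follows differentiates stages. The
per-filter reading (replace three of the four 3×3 kernels within each
filter, i.e. `P = 1/4`) determines the channel-level replacement; layer
selection is the natural lifting of that rule to a ResNet, and 16 layers
(3 + 4 + 6 + 3 blocks) match under it. When a converted layer carries
weights, large-kernel slots keep their original kernels and pointwise slots
take the original kernel's centre tap, so the identity policy
(`P = 1, r = 1`) reproduces the original layer bit-for-bit and a real
conversion starts from the best pointwise approximation of the old kernels.

## The compact detector

No deep-learning framework is available to R in this package's dependency
set, so the detector is implemented natively: a compact fully convolutional
network whose forward and backward convolution passes are hand-written in
C++ (Rcpp), assembled exactly the way the full-size recipe prescribes — a
stem convolution that is never converted, convertible 3×3 blocks passed
through `convert_backbone()`, and two 1×1 heads. The foreground head
produces the segmentation map; the objectness head scores cell centres.
Instances are extracted as connected components of the thresholded
foreground probability (mask binarization threshold 0.5), scored by the
peak objectness inside each component. This is a deliberately small stand-in
for the two-stage FPN/RPN/RoIAlign pipeline: it exercises the DHConv layers,
the conversion machinery, the training loop and the metric suite end to end
on one CPU, but it is not a reimplementation of Mask R-CNN, and results on
the synthetic scenes say nothing about benchmark performance of the
full-size architecture.

Training is per-image SGD with momentum 0.9. The loss is the sum of two
class-balanced binary cross-entropies: the foreground head against the union
of instance masks, the objectness head against discs of radius 3 px around
instance centroids. Balancing gives positive and negative pixels equal total
weight per image — with centre discs near 1% of pixels, an unweighted loss
leaves the objectness head effectively untrained in short runs. The default
`train_config()` mirrors the full-size recipe (initial rate 0.001 decayed by
0.1 every 10 epochs — `lr(e) = 0.001·0.1^⌊e/10⌋` with epochs indexed from
0 — weight decay 5e-4, 50 epochs). The short demonstration runs in the
tests use a rate of 0.1 for 3 epochs: a 642-parameter network trained for
36 steps sits in a different regime from a ResNet-50 trained for 50 epochs,
and the package treats both as ordinary configuration. Weights are
initialized fan-in-scaled normal, where the fan-in counts each kernel's true
footprint (`K²` or 1); head biases start at −2 so the untrained detector
predicts background, the usual dense-detection prior.

## Metrics

Matching is one-to-one: predictions in descending score order greedily take
the unmatched ground truth of highest IoU, requiring IoU strictly above the
threshold (default 0.5, the panoptic convention; at or above 0.5 the
matching is provably unique when predictions do not overlap each other).
From the match table: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, and a
count-based Dice `2TP/(2TP+FN+FP)`. Because published Dice values for
segmentation tasks are often pixel-based, `pixel_dice()` is exposed
separately — mean `2|x∩y|/(|x|+|y|)` over matched pairs — without claiming
either variant as anyone's reported definition. AP integrates the
monotonized precision–recall curve obtained by sweeping the detection
confidence at fixed IoU threshold; a literal sweep of the IoU threshold
inside the integral is not computable from a fixed prediction set, so the
confidence sweep is implemented, with an optional COCO-style average over
IoU 0.50–0.95. `PQ = DQ × SQ` with `DQ = TP/(TP + FN/2 + FP/2)` and `SQ`
the mean matched IoU. Every zero-denominator case returns 0 rather than
erroring or producing a non-number: evaluation must be total over degenerate
scenes (no predictions, no truths, empty masks).

## COCO I/O

Annotations use the MS COCO 2014 dialect: five sections
(info/licenses/images/annotations/categories), 0-based pixel coordinates,
`(x, y, w, h)` half-open boxes. Rasterization is pixel-centre, even-odd:
pixel `(i, j)` is set iff its centre `(i+0.5, j+0.5)` lies inside. Mask
tracing walks the boundary of the union of pixel squares along pixel edges
(one ring per 4-connected component plus hole rings, corner-touching pixels
resolved by the sharpest right turn), yielding integer-vertex polygons whose
rasterization reproduces the mask exactly — the round-trip identity the
tests enforce. Crowd annotations in uncompressed RLE are decoded
column-major; written output always uses polygons. For convex polygons of
area ≥ 100 px the raster area stays within 2% of the shoelace area; small
polygons deviate by a boundary term of order half the perimeter.

## Synthetic scenes

`generate_scene()` renders cells as ellipses with a low-order sinusoidal
radial perturbation (`R(θ) = r_ellipse(θ)·(1 + a·s(θ))`, `s` a normalized
mix of second and third harmonics), composited at z-order onto a noisy
background, blurred and 8-bit quantized. Overlap is constrained pre-occlusion
(pairwise intersection at most the allowed fraction of the smaller mask) and
each instance's full mask is kept as ground truth, matching how annotators
label partially occluded cells. The five presets encode the qualitative
regimes of the public cell benchmarks this line of work evaluates on — few
large deformed cells, many small low-contrast cells, complex low-contrast
shapes, high scale variance with occlusion, adherent overlapping cells —
with parameters chosen once as plausible for 256×256 microscopy crops. The
generator emulates shape variability, density, contrast and overlap; it does
not emulate texture, uneven illumination, imaging artefacts or out-of-focus
cells, so passing tests demonstrate the machinery works, not that the
compact detector would transfer to real microscopy.

Everything is seeded: identical seeds give byte-identical scenes, and
dataset generation derives per-image seeds from the master seed (kept below
2³¹).

## Numerical choices and problem sizes

Equivalence tolerances are 1e-5 against the dense oracle (single-precision
convention), 1e-12 for closed-form identities. The test suite's problem
sizes are chosen for a laptop-class single CPU: 6×6 spatial grids for the
operator-equivalence sweep, a 6-combination receptive-field grid up to
`K = 7, r = 4`, 96–128 px scenes for I/O and training, 12 training + 4 test
images for the end-to-end smoke run. Degenerate inputs are handled
explicitly: empty masks rasterize to empty polygon lists, zero-area polygons
warn and return empty masks, empty prediction or truth sets yield
all-zero metrics, infeasible packings raise a packing error after 1000
placement attempts per cell.

## Known limitations

* The detector is a compact surrogate, not Mask R-CNN: no FPN, no region
  proposals, no per-instance mask head; touching cells merge into one
  component unless the foreground map separates them.
* The cost model counts convolutions only; measured wall-clock speedups
  depend on memory layout and hardware and are out of scope.
* `mask_to_polygon()` emits hole rings under the even-odd convention; tools
  that union polygon lists instead will fill holes.
* Multi-category evaluation is not implemented; one foreground class
  ("cell") suffices for the intended use.
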