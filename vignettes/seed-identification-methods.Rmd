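---
title: "Identifying paddy seed varieties from silhouette key points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying paddy seed varieties from silhouette key points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paddygeom)
```

## The problem

Certified foundation paddy (unhusked rice) seed must be checked for varietal
purity, and some commercial varieties are so similar in overall size, shape
and colour that inspectors cannot tell them apart by eye. `paddygeom`
implements a machine-vision pipeline for this task: a single seed is
photographed against a contrasting background, its silhouette is segmented,
a small set of geometric key points is located on the outline, seven scalar
shape features are measured, and a shallow neural network (with a Gaussian
Bayes classifier as a comparator) assigns the variety.

The discriminative structure is the **chaff tip** — the small protrusion at
the base end of the husk where the lemma and palea meet — together with the
two concave pockets (`R_K`, `R_L`) that flank it. These pockets are exactly
the places where the outline pulls away from its convex hull, which is what
makes them measurable from a binary silhouette alone.

## Segmentation

`segment_seed()` follows a dual-band thresholding scheme:

1. extract the red band and the hue band of the RGB image (hue is the HSV
   hue angle rescaled to 0–255; achromatic pixels map to 0);
2. smooth each band with a 3×3 box mean (edge-replicated, one pass) and
   binarize it at the Otsu threshold of its 256-bin histogram;
3. OR the two binary images and fill enclosed holes;
4. keep the largest 8-connected component and mask the original image.

Two bands are used because either one alone can fail: a seed and background
that differ mostly in chroma can have nearly equal red values, while hue is
unstable for desaturated pixels. The OR of the two masks tolerates either
failure mode.

Design choices the scheme leaves open, and what this package does:

* **Smoothing operator.** A 3×3 box mean, the simplest smoothing operator;
  the kernel width is a `seg_config()` parameter and `1` disables
  smoothing.
* **Threshold polarity.** Otsu gives a threshold, not a foreground side.
  By default each band picks the side that puts fewer pixels on the image
  border, since a single seed is an interior object; the polarity can be
  forced per band.
* **Hole filling.** Background regions not 4-connected to the border are
  filled (foreground is treated as 8-connected — the standard dual
  convention).
* **Otsu ties.** The between-class variance is maximised over all 256
  thresholds; exact ties resolve to the smallest threshold. A constant
  image has no valid split and is reported as a degenerate histogram.

A note on exactness: on a noiseless two-tone rendering *with smoothing
disabled* the histogram contains exactly two values, Otsu separates them
perfectly, and the recovered mask equals the ground-truth silhouette pixel
for pixel. With smoothing enabled this exactness is provably lost at sharp
corners — a 3×3 mean mixes boundary values, and at a narrow tip or notch
apex the smoothed value of a foreground pixel can fall below that of a
background pixel elsewhere, so *no* threshold classifies both correctly.
The package's exact-recovery test therefore runs with `smooth_ksize = 1`,
while the noisy-image test (Gaussian σ = 5) uses the default 3×3 kernel,
where smoothing is beneficial and sub-unit IoU loss at corners is expected.

## Key-point geometry

All shape analysis operates on the closed outline returned by
`trace_contour()` (Moore-neighbour tracing from the topmost-leftmost
foreground pixel, clockwise in image coordinates, with Jacob's stopping
criterion). On that contour, `build_seed_geometry()` locates:

* `A`, `B` — the endpoints of the longest chord (the silhouette diameter),
  with `O` its midpoint. `A` is oriented to the chaff-tip end: the endpoint
  nearer the midpoint of the two concavity apexes.
* `C`, `D` — the perpendicular bisector chord through `O`; `P1P2` and
  `P3P4` — the perpendicular chords at the 1/5 and 4/5 positions of `AB`
  (auxiliary measurements, not part of the seven-feature vector).
* the convex hull, and the two deepest concave pockets between consecutive
  hull vertices: `R_K` (deeper, depth `d_K`) and `R_L` (depth `d_L`), each
  with its bridge endpoints (`K_u`/`K_d`, `L_u`/`L_d`) and apex (`K`, `L`).
* the chaff-tip width `LK` (distance between the apexes), the tip height
  `h_c` (maximum distance from the tip arc to the line `LK`), and the
  interior angle `phi` between the directions `K → K_d` and `L → L_d`.

Conventions adopted where the construction is genuinely open:

* **Which pocket is `K`.** The deeper one (`d_K ≥ d_L`), with ties broken
  by contour position — deterministic and pose-invariant.
* **Which bridge endpoint is `K_d`.** The one nearer the tip end `A`, so
  the `φ` direction vectors open towards the chaff tip.
* **Tip arc for `h_c`.** Of the two contour arcs joining the apexes, the
  one on the opposite side of line `LK` from the silhouette centroid.
* **`φ` convention.** The angle between free direction vectors, folded
  into [0°, 180°]; the chords are not extended to a physical intersection.
* **`CD` on a rasterised outline.** The perpendicular bisector line can
  cross a pixelated contour more than twice; the maximal-span pair of
  polygon-edge intersections is used.
* **Tie-breaking.** All remaining ties (equal chord lengths, equal
  deficiencies) resolve by row-major lexicographic order, so repeated runs
  are identical.

Two tolerances guard against rasterisation artefacts, both in
`geom_config()`:

* `min_depth` (default 1 px) ignores hull pockets shallower than the
  staircase jitter of a digitised outline.
* `hull_tol` (default 1 px) absorbs hull vertices that deviate from their
  neighbours' chord by less than a pixel before pockets are delimited.
  A digitised straight edge supports the hull at irregular staircase
  points; without this step a single physical concavity is bracketed by an
  arbitrary staircase vertex, and quantities that depend on the bridge
  endpoint (most visibly `φ`) become unstable by tens of degrees.

Pixel coordinates are 1-based `(row, col)` with pixel centres at integer
positions; lengths are Euclidean in pixel units and angles in degrees.
Sub-pixel contour refinement is deliberately out of scope: every estimate
is a pixel-grid quantity, which bounds the achievable accuracy of any
single point at about half a pixel.

## The seven features and normalization

`extract_features()` returns the descriptor in a fixed order:
`len_AB`, `len_CD`, `len_LK`, `h_c`, `d_K`, `d_L`, `phi`. Classifier input
is min–max normalized to [0, 1] with ranges learned from the training
table only (`fit_normalization()`); at prediction time out-of-range values
are clipped and constant (degenerate) features map to 0.5. The ranges are
stored inside every saved model so a model file is self-contained.

## Classifiers

`train_bpnn()` fits a one-hidden-layer feedforward network by online
(per-sample) backpropagation on squared error: logistic sigmoid on both
layers, one-hot targets, learning rate 0.01, and training complete when
the epoch-mean MSE over samples and output nodes drops below the tolerance
error 0.01. The hidden width follows `hidden_nodes(n_i, n_o, k)`
= `n_i + n_o + k` with `k ∈ {−2, 0, 2}` — 8, 10 or 12 nodes for seven
features and three varieties. Choices the training recipe leaves open:
weights initialise uniformly in [−0.5, 0.5] from a caller seed; samples are
visited in one fixed shuffled order drawn from the same seed (no momentum,
no validation-based early stopping); a 10 000-epoch cap guards against
non-separable data, in which case the model is returned with a warning and
`converged = FALSE`. A tangent-sigmoid hidden layer is available via
`activation = "tanh"` (the output layer stays logistic to match the 0/1
targets). Everything is deterministic given data and seed — two runs give
bitwise-identical weights.

`train_bayes()` is the comparison classifier: a full-covariance Gaussian
class-conditional model (quadratic discriminant) with priors proportional
to class counts and a ridge of `1e-6 · trace(S)/7` on each covariance
diagonal. The exact form of the historical comparator is not pinned down
anywhere, so the full-covariance Gaussian is a documented interpretation;
tests cross-check it against an independent density evaluation and against
`MASS::qda`.

`evaluate_confusion()` reports per-class accuracy (100 × diagonal /
column total) and average accuracy (100 × trace / grand total), rounded to
two decimals. Confusion matrices are oriented rows = predicted,
columns = true, so each column sums to the per-variety test count.

## The synthetic seed generator

No seed-image corpus ships with the package, so every stage is validated
against synthetic silhouettes with closed-form ground truth
(`seed_spec()`, `make_silhouette()`, `render_image()`,
`sample_population()`). The silhouette family is an ellipse body joined to
a protruding tip apex by the two tangent segments from the apex to the
ellipse, with a sharp V-shaped notch cut into each tangent flank. This
family was chosen because it realises every structure the extractor
measures while keeping the truth analytic:

* the tangent flank is a genuine supporting edge of the convex hull, so
  the concavity bridge line is exactly the constructed tangent and the
  notch's perpendicular depth is exact by construction (a flank drawn from
  a shoulder *on* the ellipse at any other angle is never a hull edge —
  the hull would ride the tangent instead, and the measured depth would be
  taken against a different line);
* the V mouth is collinear with the flank and the V half-angle
  (`notch_angle`, default 42°) keeps the deficiency peak sharp, so the
  apex is localised to well under a pixel;
* the longest chord is provably tail-point-to-tip-apex, giving
  `len_AB = 2a + tip_length` and a perpendicular bisector chord that
  crosses plain ellipse, giving a closed-form `len_CD`.

Rasterisation marks a pixel foreground when its centre lies inside the
polygon after the smooth and convex boundary vertices are pushed half a
pixel outward along their angle bisectors. The half-pixel shift exists
because pixel-centre contours of a plain centre-inside rasterisation sit
on average half a pixel inside the continuous outline, which would bias
every length downward; reflex vertices (the notch apexes) are *not*
shifted because the innermost-pixel estimate of a wedge tip is already
approximately unbiased. These are statements about the discretisation
model, fixed once; the recorded ground truth is always the continuous
construction.

Default study conditions (the three built-in varieties of
`default_varieties()` and the randomised test ranges): semi-axes 52–68 ×
24–29 px, tip length 24–30 px, tip width 16.5–19 px, notch depths
5.2–6.8 px (`K`) and 3.5–4.7 px (`L`), V half-angle 39–45°, arbitrary
rotation, on canvases the size of a 640 × 480 capture frame or fitted to
the seed. Notch depths below about 3.5 px are deliberately excluded: such
a wedge often contains no background pixel centre at all, so the concavity
vanishes from the raster and no contour-based method can recover it. The
three varieties differ jointly in size, tip prominence and notch depths;
their feature-space class means are separated by more than six pooled
within-class standard deviations (dominated by seed length), so a sound
classifier should approach perfect held-out accuracy — the classifier
tests are a parameter-recovery surrogate, not a claim about real seeds.

What the generator does **not** emulate: husk surface texture and colour
gradients, awns, shadows and specular highlights, touching or overlapping
seeds, and the biological shape variation of real lemma/palea outlines.
Passing tests therefore demonstrate that the pipeline measures what it
claims to measure on well-posed silhouettes, not that the published
accuracies on real TK9/TN11/TK14 seeds are reproduced — those images were
never deposited, and the published confusion tables are re-evaluated as
arithmetic only.

## Accuracy at pixel resolution

On 300 randomised noiseless silhouettes (design-time measurement, the same
conditions as the test suite), mean absolute recovery errors are about
0.35 px for `d_K` and `d_L`, 0.45 px for `len_LK`, 0.64 px for `h_c` and
0.71° for `phi`. Per-silhouette extremes reach roughly 1.6 px / 2.8°:
a single pixel quantises each contour point to ±0.5 px, so a difference of
two independent raster estimates occasionally exceeds any sub-pixel bound
regardless of construction. Accuracy statements in the test suite are
therefore made about mean absolute error across silhouettes.

## Worked example

```{r example, eval = FALSE}
library(paddygeom)

# one synthetic seed through the full pipeline
sil <- make_silhouette(seed_spec(rotation = 30, rng_seed = 1))
img <- render_image(sil$mask, noise_sd = 5, rng_seed = 2)
seg <- segment_seed(img)
mask_iou(seg$mask, sil$mask)

geom <- build_seed_geometry(seg$mask)
extract_features(geom)
autoplot(geom)

# three-variety trial at study scale
train <- sample_population(default_varieties(), n = 500, rng_seed = 501)
test  <- sample_population(default_varieties(), n = 100, rng_seed = 502)
fit <- train_bpnn(train, k = 0, seed = 73)   # 7-10-3 network
glance(fit)
pred <- predict(fit, test)
evaluate_confusion(confusion_matrix(test$label, pred$.label))
```

## Known limitations

* Single-seed scenes only; touching seeds are merged by the largest-
  component rule and give meaningless geometry.
* The lemma-vs-palea identity of the `C`/`D` endpoints is not computable
  from a silhouette; the two half-lengths of `CD` are stored unlabelled.
* Pixel-level geometry bounds accuracy at roughly half a pixel per point;
  no sub-pixel refinement is attempted.
* The hue band wraps at red (0° = 360°); segmentation relies on the red
  band via the OR when the hue histogram straddles the wrap.
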