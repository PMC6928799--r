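---
title: "Monitoring pot-tray sowing with traysow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring pot-tray sowing with traysow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traysow)
```

## The problem

Hybrid rice is raised in molded pot trays whose surface is divided by a
grid into cells; a precision seeder drops one to three seeds into each
cell. Because the sowing rate is deliberately low, some cells receive no
seed at all, and the fraction of such empty cells — the **missing rate** —
is the statistic a production line needs in real time to keep the seeding
device adjusted:

$$\mathrm{Missing\ Rate} = \frac{m}{N} \times 100\%$$

where $m$ is the number of empty cells and $N$ the number of cells
inspected. A camera above the conveyor sees a 960 × 720 px window covering
10 rows × 13 columns of cells (130 cells); three consecutive detections
pool 390 cells, close to the 406 cells of a full tray, so quality is
reported per group of three trays. `traysow` implements the full
frame-to-report pipeline plus a synthetic scene generator with exact
ground truth, so every stage is testable without access to a production
line.

## Pipeline stages

### 1. Frame gating

Frames showing the beginning or end of a tray must be discarded, and each
tray must be counted exactly once. Line segments are detected on the
grayscale frame and filtered by *vertical projected length*
$|y_2 - y_1| > 100$ px: the dark gap between two trays produces
full-height vertical edges, while seed and soil contours only produce
short segments. A two-phase state machine (`awaiting_tray` /
`tray_in_view`) emits `valid_first` for the first edge-free frame after an
edge frame and `valid_repeat` afterwards; stream start counts as "after an
edge" so a recording that begins mid-tray still yields one detection.

The segment detector is deliberately pluggable behind a small contract — a
straight rendered edge of length $L$ must come back as collinear segments
covering at least $0.8L$. The built-in backend Gaussian-smooths the image
($\sigma = 1$), thresholds central-difference gradients, splits edge
pixels by dominant gradient orientation (so the two families of gridlines
never merge at crossings), bridges one-to-two-pixel gaps with a short
morphological closing aligned with the edge direction, and fits each
elongated connected component with a segment by principal-axis
regression. Two sensitivities are used: 0.10 for the gate (the inter-tray
band steps ~0.4 in normalised intensity, giving a smoothed gradient
response ~0.15, while grid edges respond at ~0.06) and 0.04 for tilt
estimation, which must pick up the fainter grid edges.

### 2. Tilt estimation and correction

Trays ride the belt slightly oblique. Inside a fixed region of interest
(x = 70, y = 70, w = 800, h = 500 — a central crop that avoids the frame
borders), near-horizontal segments with horizontal projected length
$\ge 45$ px are kept and their slopes $k = (y_2-y_1)/(x_2-x_1)$ pooled.
The pool is averaged after removing exactly one maximum and one minimum
instance:

$$K = \frac{\sum_i k_i - k_{\max} - k_{\min}}{n - 2},$$

and converted to an angle. The geometrically correct conversion is
$\theta = \arctan K$, which is the default. A legacy small-angle variant
$\theta = K\pi/180$ (which treats a dimensionless slope as if it were
degrees) is available behind `angle_formula = "legacy"` for comparison;
at $K = 0.0349$ the two differ by nearly two orders of magnitude, and
only the arctan form keeps the end-to-end tilt-recovery error below the
0.2° tolerance the test suite enforces. The frame is then rotated about
its centre with the standard 2 × 3 affine matrix
($\alpha = \cos\theta$, $\beta = \sin\theta$), bilinear resampling, and
out-of-frame pixels filled with a neutral soil-like gray so the corners
cannot create phantom contours downstream.

With fewer than three usable slopes the trimmed mean degenerates; the
implementation falls back to the plain mean with a warning, and an empty
pool means "no rotation" rather than an error.

### 3. Fixed-threshold HSL segmentation

Under the production line's illuminant cabinet, grid, soil and seed
pixels occupy nearly disjoint *hue* bands, so no adaptive thresholding is
needed. Frames are converted to HSL on the 8-bit machine-vision scale
(H in half-degrees, $[0,180)$; S, L in $[0,255]$ — the only convention in
which the seed hue ceiling 168 and lightness ceiling 232 are both
representable in 8 bits). A pixel belongs to a class iff
$H_{\min} < H < H_{\max}$ (strict on both sides); defaults are grid
(3, 30) and seed (70, 168). Soil (hue roughly 28–68) is background and
never masked explicitly; its small overlap with the grid band can only
add a few pixels to the grid mask, which the projection-profile maxima
below tolerate. The S and L channels are ignored by design — the class
masks are provably invariant to them. Segmentation quality is scored as
the symmetric pixel-sum ratio $100 \cdot \min(\Sigma_p, \Sigma_r) /
\max(\Sigma_p, \Sigma_r)$, defined as 100 when both images are empty.

### 4. Gridline localisation and ROI

The masked grid image is grayscaled, binarised with Otsu's method and
opened once with a 3 × 3 box kernel (the smallest opening that removes
isolated speckle; note any 3 × 3 opening erases lines thinner than
3 px, which constrains the renderer below). Row and column *projection
profiles* (per-row/per-column sums of binary pixels) peak sharply at
gridlines. Each profile is split into equal-length contiguous blocks —
11 for rows, 14 for columns (10 and 13 cells plus one; the column count
is the natural completion of the stated row rule) — with the remainder
absorbed by the last block, and the per-block argmax is the gridline
coordinate. Ties break toward the block centre, then toward the smaller
index, deterministically. The located coordinates must be strictly
increasing with consecutive gaps within 25% of the median gap; violations
mark the frame unreadable (condition class `traysow_unreadable`) and the
pipeline skips it rather than reporting nonsense.

### 5. Cell pieces, contour filtering and the missing rate

The preprocessed seed binary image is cut along the located gridlines
into 130 half-open pieces $[y_r, y_{r+1}) \times [x_c, x_{c+1})$, which
tile the ROI with no shared pixels. In each piece, 8-connected components
are labelled and their outer boundaries traced; a contour is discarded
when its area is *below* 30 px (exactly 30 survives) — soil impurities
fall almost entirely under this threshold while true seed blobs lie well
above it. A piece with no surviving contour is an empty cell; $m$ over
$N = 130$ gives the per-tray missing rate, and pooled counts give the
per-group rate (the pooled rate equals `missing_rate(sum m, sum N)`
exactly, never an average of rates).

### 6. Seed counting with a 3-6-1 network

Seeds that touch merge into a single contour, so contour counting alone
underestimates the sown quantity. Each surviving contour is summarised by
three shape features — area $A$, perimeter $C$ and the shape factor

$$F = \frac{C^2}{4\pi A},$$

which is 1 for a circle and grows with elongation or merging — and mapped
to a seed count by a feed-forward network with 3 input, 6 hidden and 1
output node. The hidden activation is the bipolar sigmoid

$$f(x) = \frac{1 - e^{-x}}{1 + e^{-x}},$$

odd, zero at zero, bounded by $(-1, 1)$ (algebraically $\tanh(x/2)$). The
output node is linear: the task is a regression onto the count label, and
a bounded output unit would need its targets rescaled for no benefit.
Features and the target are z-score standardised. Training is full-batch
gradient descent on halved mean squared error with learning rate 0.01 and
momentum 0.9 for 2000 epochs — at this batch size a few hundred steps
demonstrably underfit, and 2000 epochs converge in a couple of seconds on
the full 5524-sample training set. Everything is deterministic given the
initialisation seed, and the trained model serialises to versioned JSON
(architecture, weights, standardisation constants) that reloads
losslessly.

Predictions are rounded to the nearest integer and clamped to
$[1, k_{\max}]$: a contour that survived the area filter holds at least
one seed, and the top training class pools "more than four", so
predictions at the ceiling carry an `overflow` attribute rather than
pretending to resolve 6 from 7. The per-tray seed count is the sum of
per-contour predictions.

### 7. Aggregation and evaluation

Reports pool in consecutive non-overlapping groups of three; a trailing
incomplete group is kept and flagged `partial` rather than dropped.
Against a manual reference $v$, the system value $v'$ scores the relative
error $\delta = |v' - v| / v \times 100$, computed on unrounded counts
(computing it from two-decimal rates instead changes 10.00% into 10.16%
— the magnitude-on-counts convention is the only one consistent with a
reference table that prints 20.00 for an under-count of one seed in
five). Accuracy is $100 - \bar\delta$; both are reported. When the twenty
manual/system empty-cell count pairs of the published reference table are
fed through these formulas the mean relative error comes out 5.80% (and
the mean system count 7.90), not the 5.33/7.95 printed in that table's
average row; `traysow` reports recomputed values and leaves the
discrepancy documented here rather than imitating it. The same source
states a tray has "29 rows and 24 columns … a total of 406 cells" even
though 29 × 24 ≠ 406; the package only ever models the visible 10 × 13
window, so nothing depends on the resolution of that inconsistency.

## The synthetic scene generator

`render_tray()` is first-class, tested code — the package's study
conditions are its defaults.

* **Geometry.** 10 × 13 cells of 64 px with 3 px gridlines, centred in a
  960 × 720 frame. Gridlines must be at least 3 px wide or the 3 × 3
  opening in preprocessing would erase them — a real constraint of the
  analysis pipeline that the renderer respects rather than hides.
  Ground-truth gridline coordinates are the line-centre pixels; at zero
  tilt they form arithmetic progressions with step 67 px.
* **Colours.** Each class samples H/S/L inside its nominal band with a
  safety margin (grid H in 8–25 of its (3, 30) band; seed H in 85–150 of
  (70, 168); soil H in 33–64) because quantising to 8-bit RGB and back
  perturbs the hue of these low-saturation colours by up to about one
  half-degree unit. Soil lightness is per-pixel noise (116–144), grid
  slightly brighter (166–173), seeds brighter still (178–200), and the
  inter-tray band nearly black — contrasts chosen so the gate threshold
  separates band edges from grid edges by a factor of ~2.5 on either
  side.
* **Seeds.** One cluster per non-empty cell: 1–3 seeds (probabilities
  0.35/0.45/0.2), each an ellipse with area drawn U(125, 175) px² and
  aspect ratio U(1.7, 2.1). A graded seed lot has a tight size
  distribution (coefficient of variation ~10%) and rice grains are about
  twice as long as wide; these two ranges encode exactly that. Touching
  seeds form a chain — each new ellipse is placed at 0.8–0.9 of the sum
  of the two *directional* radii along a random contact direction, giving
  shallow, orientation-independent overlap. The default empty-cell
  fraction is 0.02, matching the 1–3% missing rates a working seeder
  produces.
* **Impurities.** Seed-coloured blobs of 5–60 px², 80% below the 30 px
  filter. Both failure directions of the contour filter are therefore
  exercised: small impurities vanish, and the occasional ≥ 30 px impurity
  reproduces the known production failure mode of an undercounted empty
  cell.
* **Tilt and bands.** The finished scene rotates by the ground-truth tilt
  (bilinear, soil-mean fill); the optional tray-edge band spans the full
  frame height, 60 px wide.

`make_contour_samples()` reuses the same cluster renderer on a small
canvas, applies the same 3 × 3 opening the pipeline uses, and measures
features with the same contour code, so training and inference
distributions match by construction. The default class sizes
(2280/1216/822/620/586, total 5524) mirror a production training set.

What the generator does **not** emulate: illumination gradients (the
cabinet's diffusers make lighting uniform by design), perspective
distortion, soil texture with spatial correlation, partially buried or
mildewed seeds, and soil spill occluding gridlines. Passing tests
therefore demonstrate the correctness of the algorithmic chain under the
stated scene model, not robustness to every production pathology; the
mildew/occlusion failure modes in particular are reproduced only through
their geometric effect (undersized contours), not their cause.

## Numerical and boundary conventions

* Gate filter strict (`> 100` px, "over"); tilt filter inclusive
  (`>= 45` px, "longer than … set as a threshold" read inclusively);
  hue thresholds strict on both sides; area filter inclusive at 30 px.
* Images are plain R structures — binary/grayscale matrices `m[y+1, x+1]`
  in $[0,1]$ and RGB arrays — with 0-based pixel coordinates, origin
  top-left, y downward. Positive tilt means gridlines sloping down to
  the right; positive rotation angles turn content counter-clockwise on
  screen.
* Connected components are 8-connected (a diagonal-merge pass on top of
  the 4-connected labeller). Contour perimeter is the traced-boundary
  chain length with $\sqrt 2$ diagonal steps; for rasterized shapes this
  overestimates smooth perimeters by a few percent, so discrete shape
  factors sit slightly above their analytic values (a rasterized circle
  measures $F \approx 1.1$) — consistently on both the training and the
  inference side, which is what matters for counting.
* Degenerate inputs have defined behaviour rather than crashes: all-black
  images stay all-black through preprocessing, vertical segments are
  dropped from the slope pool, an empty slope pool means no rotation,
  `relative_error(0, 0)` is 0 while a nonzero system value against a zero
  reference is an error, and two empty masks have segmentation accuracy
  100.

## Problem sizes in the test suite

The property-based acceptance tests run the full pipeline on 50 rendered
trays with tilt uniform in [−3°, 3°] (tilt recovery within 0.2° on at
least 95%, mean gridline error at most 2 px with no line missed more than
5 px), 20 trays for exact empty-cell recovery (at least 18 exact) and
seed-count recovery (mean relative error at most 10% after training on
the full 5524-sample set), 1000 random profiles against a brute-force
per-block argmax oracle, and gate simulations over a range of clean-run
lengths. These sizes give stable pass/fail behaviour at a few minutes of
total runtime on one CPU and are fixed as the package's reference
conditions.

## Known limitations

* The hue-only rule discards the S and L channels entirely; scenes whose
  classes separate in lightness but not hue would need different
  thresholds, not a different algorithm.
* The counting network shares the intrinsic ceiling of its features:
  beyond four or five touching seeds, area grows sublinearly and the
  count saturates (hence the pooled top class and the `overflow` flag).
* One tray transit is tracked at a time; two trays in one frame, or
  conveyor reversal, are out of scope.
* The gridline locator assumes one dominant peak per block; a grid
  shifted by more than half a cell relative to the expected layout would
  need the group counts reconfigured.
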