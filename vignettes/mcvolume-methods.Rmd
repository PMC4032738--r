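---
title: "Monte Carlo volume measurement from five silhouettes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo volume measurement from five silhouettes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcvolume)
```

## The measurement problem

Grading and sorting lines need the volume of individual fruit and other
irregularly shaped products, fast and without touching them. Water
displacement is accurate but slow and destructive for porous or fragile
produce; full 3D reconstruction (wireframes, slicing, space carving) is
computationally expensive. This package implements a middle road: a
five-camera silhouette rig and plain Monte Carlo integration. The only
question the estimator ever asks of the images is *does this random 3D
point project onto the object in every view?* — no surface model is ever
built.

The object rests on a reference plane, taken as $z = 0$ of a right-handed
world frame in cm. One camera looks straight down, four look from the
sides. Each camera $j$ is a calibrated pinhole: a world point $p$ maps to
camera coordinates $(x_c, y_c, z_c) = R_j\,p + t_j$ and then to pixels

$$u = f_{xj}\, x_c / z_c + c_{xj}, \qquad v = f_{yj}\, y_c / z_c + c_{yj}.$$

Lens distortion is taken as zero; the consumer webcams this targets have
negligible distortion, and the package's scope is parameter *consumption*
(from a rig file or the synthetic generator), not calibration-target
estimation.

## From photographs to silhouettes

Segmentation assumes a bright object against a dark background. The RGB
image is converted to HSV; a working grayscale image is the weighted sum
$Gr = w_h H + w_s S + w_v V$ with all three channels first brought to a
common $[0,1]$ scale (hue divided by 360 — without this, hue's native
0–360 range would swamp any weighting), then min–max normalised to
$[0, 255]$. A $3\times3$ Gaussian filter suppresses sensor noise. A
global threshold is found by the classic iterated-means scheme —
initialise at the image mean, replace $T$ by the average of the two class
means, stop when the change is below 0.5 gray levels — and pixels
*strictly above* $T$ become object. A $5\times5$ opening removes white
specks, a $3\times3$ closing fills black pin-holes. Outside the image
everything counts as background, so erosion shrinks objects touching the
border; this conservative policy can only make silhouettes smaller, never
invent object pixels.

The weights are scene-dependent and exposed as configuration
(default `c(0, 0.3, 0.7)`); the synthetic tests use `c(0, 0, 1)` because
their value channel carries all the contrast. A constant-range grayscale
image normalises to all zeros rather than erroring, so a featureless
frame yields an empty silhouette and a clean "empty object" failure
downstream.

## The bounding box

Monte Carlo needs a sampling box $B = [x_l,x_u]\times[y_l,y_u]\times
[z_l,z_u]$ that certainly contains the object; the estimate is scaled by
its volume $V_B$, so the box should also be reasonably tight. The four
corners of the top view's minimum bounding rectangle are back-projected
and intersected with the resting plane $z = z_l$ ($z_l = 0$ for an object
on the table); the extreme $x$ and $y$ footprints give the horizontal
bounds. The top edge midpoint of one side view's rectangle is
back-projected and intersected with the four vertical planes through the
box faces; among forward intersections whose footprint lies within the
box's horizontal extent (5% slack), the *first* face crossed — smallest
ray parameter — gives $z_u$, since the object's top point must lie
between the camera and the far faces. The side view used is the one whose
optical axis is most nearly horizontal, i.e. the view that sees the
object's height with least foreshortening.

Both rectangles are grown by a 2 px safety margin before reprojection.
Rasterisation can erode a silhouette by a fraction of a pixel; the margin
converts that into a slightly larger box (a second-order effect on
efficiency) instead of a violated containment guarantee (a first-order
bias). Note that perspective alone already makes the footprint generous:
the tangent rays from a camera at height $h$ to a sphere of radius $r$
meet the ground plane at radius $h r / \sqrt{(h-r)^2 - r^2} > r$, so the
box constructed for a 3.67 cm sphere under the default rig is about 11%
wider than the sphere itself. That slack costs sampling efficiency, never
correctness.

## The estimator

With $N$ points drawn uniformly in $B$ (coordinate-wise
$X = x_l + (x_u - x_l)U$, seeded Mersenne–Twister), and $f_j$ the binary
value of silhouette $j$ at the *nearest* pixel to the projection of point
$i$,

$$\hat V = \frac{V_B}{N} \sum_{i=1}^N \prod_{j=1}^5 f_j(u_{ij}, v_{ij}).$$

Projections outside an image, or behind a camera, contribute 0.
Rounding to nearest (rather than flooring) matches the renderer's
pixel-centre convention and is symmetric. The hit indicator's support is
exactly the **visual hull** of the five silhouettes — the intersection of
the five back-projected cones — so $\hat V$ is an unbiased estimator *of
the hull volume*, with binomial error: the coefficient of variation of
repeated estimates is $\sqrt{(1-p)/(pN)}$ for hit probability
$p = V_{hull}/V_B$. For a ball in a near-tight box ($p \approx \pi/6$)
this gives about 3% at $N = 10^3$ and 0.3% at $N = 10^5$; the package's
default $N = 8\times10^5$ puts both the sampling error and its repeat-to-
repeat scatter comfortably below 1% for fist-sized produce.

The hull, however, *over*-contains the object: five views cannot see
concavities, and tangency regions between views add convex slack. The
resulting bias is corrected heuristically: for each product class, a factor

$$K = \operatorname{mean}(V_{ref} / V_{raw})$$

is calibrated on a few objects (five in the standard protocol) whose
reference volume is known — water displacement for real produce, analytic
truth in synthetic mode — and the reported volume is $K \hat V$. The
correction is per class because the hull excess depends on shape: similar
objects share a ratio, dissimilar ones do not. `calibrate_adjustment()`
keeps the calibration pairs alongside $K$ so a stored calibration is
auditable.

The voxel space-carving baseline (`carve()`) keeps every voxel of a grid
over $B$ whose *centre* passes the same membership test — deliberately
the same code path, so carving and sampling estimate the identical hull
and cross-validate each other: the package's central internal oracle is
that their volumes agree within combined (binomial + voxel-surface)
error on every synthetic scene.

## The synthetic scene generator

Hardware-free testing requires scenes whose true volume is known exactly.
The generator provides implicit-surface solids — spheres, ellipsoids,
superellipsoids, and unions of overlapping spheres — resting on $z = 0$,
plus a default rig: top camera 40 cm above the origin, four side cameras
at 35 cm distance and 10 cm height at 90° azimuth spacing, 640×480
images, focal length 1050 px (a 10 cm object spans ≈300 px from the side).
These numbers are invented but recorded in every rig file written, and no
result depends on them beyond loose bounds. Silhouettes are rendered by
per-pixel ray casting: exact ray–quadric tests for spheres and
ellipsoids, a 0.05 cm ray march inside the bounding-sphere interval for
superellipsoids (at most ~1 px silhouette error at the default geometry).

"Fruit-like" irregular objects are unions of a core sphere (radius
jittered ±10% around 3 cm) and 3–6 satellite spheres with radii 45–75% of
the core, centred 0.5–1.0 core radii away in random directions. These
have lobes and creases no five-view hull can resolve, so their raw
estimates overshoot truth by a class-consistent margin — the regime the
adjustment is designed for. True union volumes come from a deterministic
voxel-centre count at $400^3$ over the tight box; against closed-form
spheres this oracle is accurate to ~$3\times10^{-5}$ relative, far below
every tolerance used.

What the generator does *not* emulate: lighting, shadows, specularity,
colour variation, soft or miscalibrated optics, and segmentation errors
beyond optional uniform pixel-flip noise. Passing tests therefore
demonstrate the geometry and statistics of the method, not robustness of
segmentation to real-world imaging; the imaging pipeline is tested
separately on composited bright-on-dark images with known masks.

## Numerical choices and degenerate inputs

* Pixel convention: 0-based $(u, v)$ = (column, row), pixel centres at
  integers, everywhere — renderer, membership test, bounding rectangles.
* Threshold iteration stops at 0.5 gray levels; binarisation is strictly
  `> T`. Constant images raise a degenerate-histogram error.
* Empty silhouettes raise an empty-object error at bounding-rectangle
  time; a scene whose silhouette cones miss the box entirely yields a
  legitimate zero estimate.
* Ray/plane intersection refuses axis components below $10^{-12}$;
  bounding-box construction refuses geometry where the side ray crosses
  no vertical face forward of the camera.
* Rotation matrices are validated to $10^{-8}$ (orthonormality and
  $\det R = +1$); rig cameras must sit strictly above the resting plane.
* Seeding: every stochastic entry point takes an integer seed; repeat
  $i$ of a repeated measurement uses `seed + i - 1`, and experiment
  drivers derive per-shape seeds by fixed offsets, so every reported
  number is bit-reproducible from one integer.
* Adjustment calibration requires strictly positive volumes; $K$ is the
  mean of ratios (not the ratio of means), matching its definition.

## Problem sizes used by the test-suite

The packaged tests run the full protocol at its operating scale where the
claim depends on it — 25 irregular shapes at $N = 10^5$ for the
adjustment-efficacy check, 100 repeats for precision laws at
$N \le 2\times10^5$ — and reduced scales elsewhere (a 160×120 px rig for
geometry properties, $100^3$ carving grids), chosen so each property is
still decisively tested: binomial tolerances in the tests are derived
from the scale actually run.

## Known limitations

* The raw estimator measures the visual hull; $K$ transfers hull bias
  across a class only as well as the class is shape-homogeneous. A
  calibration from round fruit applied to lumpy fruit will miscorrect.
* One object per scene; touching or stacked objects merge silhouettes.
* The bounding box assumes the object rests on a known plane; `zl` is
  configurable but must be supplied for suspended objects.
* Segmentation assumes high object/background contrast; it has no colour
  constancy or shadow handling.
* Five fixed views: adding views would shrink the hull excess and reduce
  the work the heuristic adjustment has to do, but the package implements
  the five-camera design point.
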