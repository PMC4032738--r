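# mcvolume

Volume measurement of irregularly shaped objects — fruit on a grading
line is the motivating case — from five calibrated camera views, without
any 3D reconstruction. The package is aimed at postharvest/food-process
engineers and computer-vision practitioners who need a fast,
non-destructive stand-in for water displacement.

## The method

An object rests on the plane z = 0 inside a rig of five pinhole cameras
(one top view, four side views). Each view contributes a binary
silhouette f_j (1 = object). A world-space bounding box
B = [x_l,x_u]×[y_l,y_u]×[z_l,z_u] enclosing the object is built by
back-projecting the silhouettes' bounding rectangles, and the volume is
estimated by Monte Carlo integration:

    V̂  =  K · (V_B / N) · Σ_{i=1..N}  Π_{j=1..5} f_j(u_ij, v_ij)

where (u_ij, v_ij) is the pixel projection of random point i into view j,
V_B is the box volume, and N uniform points are drawn in B. The product
term asks one cheap question per point — *does it project onto the object
in every view?* — so the sum estimates the volume of the five-view
**visual hull**. Because the hull always over-contains the object, a
per-product-class heuristic adjustment K = mean(V_reference/V_raw),
calibrated on a handful of objects of known volume, removes the
systematic excess. Precision follows the binomial law
CV = √((1−p)/(pN)); at the default N = 8×10⁵ repeat-to-repeat scatter is
well below 1% for fist-sized produce.

The package also provides: the full RGB→silhouette segmentation pipeline
(HSV weighting, 3×3 Gaussian smoothing, automatic iterative threshold,
morphological cleanup), a synthetic five-camera scene generator with
analytic ground-truth shapes, a voxel space-carving baseline sharing the
same membership test, and the standard validation metrics (ARE, CV,
Pearson correlation, paired t-test).

## Worked example

Measure a calibration ball (radius 3.67 cm, true volume 207.06 cc) in a
synthetic scene:

```r
library(mcvolume)
rig  <- make_rig()                       # top @ 40 cm, 4 sides @ 35 cm
ball <- shape_sphere(3.67)
sc   <- generate_scene(ball, rig)        # renders 5 silhouettes + box
sc$scene$box
#> <bbox> [-4.11, 4.11] x [-4.11, 4.11] x [0.00, 7.71] cm, V_B = 522.30 cc

estimate_volume(sc$scene, n = 8e5, seed = 1)
#> Monte Carlo volume estimate (n = 800000, seed = 1)
#>   raw (hull) : 221.345 cc  [339028/800000 hits in a 522.30 cc box]
```

The raw estimate targets the visual hull, ~7% above the true 207.06 cc.
Calibrating the class adjustment on a known-volume object and applying it
to a fresh measurement:

```r
cal <- calibrate_adjustment(v_reference = exact_sphere_volume(3.67),
                            v_before    = 221.345, label = "ball")
adjusted_volume(estimate_volume(sc$scene, n = 8e5, seed = 2), cal)
#> Monte Carlo volume estimate (n = 800000, seed = 2)
#>   raw (hull) : 221.296 cc  [338954/800000 hits in a 522.30 cc box]
#>   adjusted   : 207.010 cc  (K = 0.93544)

repeated_measurement(sc$scene, n = 8e5, repeats = 3, seed = 10)
#> 3 repeated estimates at n = 800000: mean 221.340 cc, cv 0.1603%
```

The adjusted volume lands within 0.05 cc (0.02%) of truth, and the
triplicate coefficient of variation of 0.16% shows the estimator's
precision at the operating sample size. `run_paper_protocol()` scales
this workflow to a whole synthetic product class — calibrate K on five
objects, measure a held-out set, report accuracy before/after adjustment —
and `compare_methods()` cross-checks the sampling estimate against voxel
space carving on the same silhouettes.

See `vignettes/mcvolume-methods.Rmd` for the model, its assumptions,
parameter defaults and numerical choices.

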