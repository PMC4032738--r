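test_that("implicit membership tests are exact", {
  sph <- shape_sphere(1)
  expect_true(shape_inside(sph, c(0, 0, 1)))
  expect_true(shape_inside(sph, c(0, 0, 2)))    # boundary counts as inside
  expect_false(shape_inside(sph, c(0, 0, 3)))

  two <- shape_sphere_union(rbind(c(-3, 0, 1), c(3, 0, 1)), c(1, 1))
  expect_true(all(shape_inside(two, rbind(c(-3, 0, 1), c(3, 0, 1)))))
  expect_false(shape_inside(two, c(0, 0, 1)))
})

test_that("closed-form volumes and the voxel oracle agree", {
  expect_equal(shape_volume(shape_sphere(3.67)), 4 / 3 * pi * 3.67^3)
  # two calibration balls: their mean reference volume to printed precision
  expect_equal(mean(c(shape_volume(shape_sphere(3.67)),
                      shape_volume(shape_sphere(3.68)))),
               207.90, tolerance = 0.005 / 207.90)

  r <- 2.4
  expect_equal(shape_volume(shape_ellipsoid(r, r, r)),
               shape_volume(shape_sphere(r)))
  # superellipsoid closed form degenerates to the ellipsoid at n = 2
  expect_equal(shape_volume(shape_superellipsoid(2, 1.5, 1, n = 2)),
               shape_volume(shape_ellipsoid(2, 1.5, 1)), tolerance = 1e-12)

  # voxel oracle vs closed form on a sphere
  sph <- shape_sphere(3)
  expect_equal(mcvolume:::voxel_oracle_volume(sph, 200), shape_volume(sph),
               tolerance = 1e-3)
})

test_that("union volume is subadditive with equality iff disjoint", {
  disjoint <- shape_sphere_union(rbind(c(-5, 0, 2), c(5, 0, 2)), c(2, 2))
  parts <- 2 * shape_volume(shape_sphere(2))
  expect_equal(shape_volume(disjoint), parts, tolerance = 2e-3)

  overlapping <- shape_sphere_union(rbind(c(-1, 0, 2), c(1, 0, 2)), c(2, 2))
  expect_lt(shape_volume(overlapping), parts * 0.95)
})

test_that("the default rig is a valid five-camera ring", {
  rig <- make_rig()
  expect_named(rig, c("top", "side1", "side2", "side3", "side4"))
  for (cam in rig) {
    expect_s3_class(cam, "camera")                # constructor validated R, t
    expect_gt(camera_center(cam)[3], 0)
  }
  # top camera looks straight down at the origin
  uv <- project_point(rig$top, c(0, 0, 0))
  expect_equal(unname(uv), c(rig$top$cx, rig$top$cy), tolerance = 1e-9)
})

test_that("rotating the world by 90 degrees permutes the side views", {
  rig <- small_rig()
  shp <- shape_sphere_union(rbind(c(0.8, 0, 2), c(-0.5, 0.4, 2.6)),
                            c(2, 1.4))
  rot <- shape_sphere_union(rbind(c(0, 0.8, 2), c(-0.4, -0.5, 2.6)),
                            c(2, 1.4))   # shape rotated +90 deg about z
  s_next <- render_silhouette(rig$side2, rot)
  s_orig <- render_silhouette(rig$side1, shp)
  # identical up to floating-point ties on boundary pixels
  expect_lt(mean(unclass(s_next) != unclass(s_orig)), 1e-3)
})

test_that("rendered sphere silhouette has the tangent-cone pixel radius", {
  rig <- make_rig()
  r <- 3
  shp <- shape_sphere(r, center = c(0, 0, 4))
  cam <- rig$side1
  d <- sqrt(sum((camera_center(cam) - c(0, 0, 4))^2))
  expected_px <- cam$fx * r / sqrt(d^2 - r^2)
  sil <- render_silhouette(cam, shp)
  rect <- min_bounding_rect(sil)
  measured <- (rect["umax"] - rect["umin"] + 1) / 2
  expect_lt(abs(measured - expected_px), 1.5)
})

test_that("invisible shapes render empty with a warning", {
  cam <- small_rig()$top
  far <- shape_sphere(1, center = c(200, 0, 1))    # outside the view cone
  expect_warning(sil <- render_silhouette(cam, far), "not visible")
  expect_true(all(sil == 0))
})

test_that("a union's silhouette contains each component's silhouette", {
  cam <- small_rig()$side3
  u <- shape_sphere_union(rbind(c(0, 0, 2), c(1.5, 0.5, 3)), c(2, 1.2))
  s_u <- render_silhouette(cam, u)
  for (i in 1:2) {
    s_i <- render_silhouette(cam, shape_sphere(u$radii[i], u$centers[i, ]))
    expect_true(all(unclass(s_u) >= unclass(s_i)))
  }
})

test_that("ray-marched superellipsoid silhouettes match the quadric path", {
  cam <- small_rig()$side1
  se <- shape_superellipsoid(2, 1.6, 1.2, n = 2, center = c(0, 0, 1.5))
  el <- shape_ellipsoid(2, 1.6, 1.2, center = c(0, 0, 1.5))
  s_m <- render_silhouette(cam, se)
  s_a <- render_silhouette(cam, el)
  expect_lt(mean(unclass(s_m) != unclass(s_a)), 0.006)
})

test_that("interior points project into every rendered silhouette", {
  set.seed(41)
  rig <- small_rig()
  shp <- random_shape(shape_class("sphere_union"), 3)
  sils <- lapply(rig, function(cam) render_silhouette(cam, shp))
  tb <- shape_bbox(shp)
  pts <- cbind(runif(20000, tb$xl, tb$xu), runif(20000, tb$yl, tb$yu),
               runif(20000, tb$zl, tb$zu))
  pts <- pts[shape_inside(shp, pts), , drop = FALSE]
  # keep points at least one pixel footprint (~0.14 cm at this rig) clear
  # of the surface: rasterisation may flip pixels within that band
  depth <- apply(vapply(seq_along(shp$radii), function(i) {
    shp$radii[i] - sqrt((pts[, 1] - shp$centers[i, 1])^2 +
                          (pts[, 2] - shp$centers[i, 2])^2 +
                          (pts[, 3] - shp$centers[i, 3])^2)
  }, numeric(nrow(pts))), 1, max)
  pts <- pts[depth > 0.15, , drop = FALSE]
  expect_gt(nrow(pts), 500)
  ok <- rep(TRUE, nrow(pts))
  for (vn in names(rig)) {
    pr <- project_points(rig[[vn]], pts)
    ui <- round(pr[, "u"]); vi <- round(pr[, "v"])
    sil <- unclass(sils[[vn]])
    ok <- ok & sil[cbind(vi + 1, ui + 1)] == 1L
  }
  expect_gt(mean(ok), 0.999)
})

test_that("scene generation is seeded and noise flips the stated fraction", {
  rig <- small_rig()
  shp <- shape_sphere(3)
  clean <- generate_scene(shp, rig)
  noisy <- generate_scene(shp, rig, noise = 0.01, seed = 5)
  frac <- mean(unclass(noisy$scene$silhouettes$top) !=
                 unclass(clean$scene$silhouettes$top))
  expect_equal(frac, 0.01, tolerance = 0.3)

  again <- generate_scene(shp, rig, noise = 0.01, seed = 5)
  expect_identical(lapply(noisy$scene$silhouettes, unclass),
                   lapply(again$scene$silhouettes, unclass))
})
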