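#' Build the default five-camera rig
#'
#' One camera looks straight down from `top_height` above the workspace
#' origin; four side cameras sit at 90 degree azimuth spacing at distance
#' `side_dist` and height `side_height`, aimed at a point `look_height`
#' above the origin. Focal length defaults to 1050 px so a 10 cm object
#' spans roughly 300 px of a 640 x 480 frame at the side distance — a
#' plausible webcam geometry for a benchtop rig; no result of the package
#' depends on the exact numbers, which are always written to the rig file
#' alongside any experiment.
#'
#' @param image_size `(width, height)` in pixels.
#' @param top_height Top-camera height above z = 0 (cm).
#' @param side_dist Side-camera horizontal distance from the z axis (cm).
#' @param side_height Side-camera height (cm).
#' @param look_height Height of the side cameras' aim point (cm).
#' @param f Focal length in pixel units (both axes).
#' @return Named list of five [camera()] objects: top, side1..side4.
#' @export
make_rig <- function(image_size = c(640, 480), top_height = 40,
                     side_dist = 35, side_height = 10, look_height = 4,
                     f = 1050) {
  w <- image_size[1]; h <- image_size[2]
  cx <- w / 2; cy <- h / 2
  mk <- function(center, target, view) {
    zc <- target - center
    zc <- zc / sqrt(sum(zc^2))
    xc <- c(zc[2] * 1 - zc[3] * 0, zc[3] * 0 - zc[1] * 1, 0)  # zc x (0,0,1)
    if (sqrt(sum(xc^2)) < 1e-9) xc <- c(1, 0, 0)              # looking straight down
    xc <- xc / sqrt(sum(xc^2))
    yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
            zc[3] * xc[1] - zc[1] * xc[3],
            zc[1] * xc[2] - zc[2] * xc[1])                    # zc x xc
    R <- rbind(xc, yc, zc)
    camera(fx = f, fy = f, cx = cx, cy = cy, width = w, height = h,
           R = R, t = as.numeric(-R %*% center), view = view)
  }
  rig <- list(top = mk(c(0, 0, top_height), c(0, 0, 0), "top"))
  az <- c(0, 90, 180, 270) * pi / 180
  for (i in 1:4) {
    ctr <- c(side_dist * cos(az[i]), side_dist * sin(az[i]), side_height)
    rig[[paste0("side", i)]] <- mk(ctr, c(0, 0, look_height), paste0("side", i))
  }
  rig
}

#' Render the ideal binary silhouette of a shape
#'
#' Casts one ray per pixel centre and marks the pixel as object iff the
#' ray hits the shape at positive depth. Spheres, ellipsoids and sphere
#' unions use the exact ray-quadric test; superellipsoids are ray-marched
#' with a 0.05 cm step inside the bounding-sphere interval, giving at most
#' ~1 px silhouette error at the default geometry.
#'
#' @param cam A [camera()].
#' @param shape An `"analytic_shape"`.
#' @return A `"silhouette"` 0/1 matrix, `cam$height` x `cam$width`.
#' @export
render_silhouette <- function(cam, shape) {
  w <- cam$width; h <- cam$height
  u <- rep(0:(w - 1), each = h)
  v <- rep(0:(h - 1), times = w)
  dcam <- cbind((u - cam$cx) / cam$fx, (v - cam$cy) / cam$fy, 1)
  dw <- dcam %*% cam$R                   # rows: R' d
  org <- camera_center(cam)
  hit <- ray_hits_shape(org, dw, shape)
  if (!any(hit))
    warning("shape is not visible from camera '", cam$view, "'")
  as_silhouette(matrix(as.integer(hit), h, w))
}

# Vectorised positive-depth ray/shape intersection predicate.
# org: length-3; dirs: n x 3 (not necessarily unit).
ray_hits_shape <- function(org, dirs, shape) {
  switch(shape$kind,
    sphere = ray_hits_sphere(org, dirs, shape$center, shape$radius),
    ellipsoid = {
      o <- (org - shape$center) / shape$axes
      d <- sweep(dirs, 2, shape$axes, "/")
      ray_hits_sphere(o, d, c(0, 0, 0), 1)
    },
    sphere_union = {
      hit <- rep(FALSE, nrow(dirs))
      for (i in seq_along(shape$radii))
        hit <- hit | ray_hits_sphere(org, dirs, shape$centers[i, ],
                                     shape$radii[i])
      hit
    },
    superellipsoid = ray_march_hits(org, dirs, shape, step = 0.05),
    stop("unknown shape kind: ", shape$kind))
}

ray_hits_sphere <- function(org, dirs, center, radius) {
  oc <- org - center
  a <- rowSums(dirs^2)
  b <- 2 * (dirs %*% oc)[, 1]
  cc <- sum(oc^2) - radius^2
  disc <- b^2 - 4 * a * cc
  ok <- disc >= 0
  s_hi <- rep(-1, length(a))
  s_hi[ok] <- (-b[ok] + sqrt(disc[ok])) / (2 * a[ok])
  ok & s_hi > 0                          # far root forward => some hit forward
}

# March inside the interval where the ray crosses the shape's bounding
# sphere; prefiltering keeps the marched pixel set small.
ray_march_hits <- function(org, dirs, shape, step = 0.05) {
  ctr <- shape$center
  rad <- sqrt(sum(shape$axes^2))
  len <- sqrt(rowSums(dirs^2))
  d <- dirs / len
  oc <- org - ctr
  b <- (d %*% oc)[, 1]
  disc <- b^2 - (sum(oc^2) - rad^2)
  cand <- which(disc > 0)
  hit <- rep(FALSE, nrow(dirs))
  if (!length(cand)) return(hit)
  sq <- sqrt(disc[cand])
  s0 <- pmax(-b[cand] - sq, 0)
  s1 <- -b[cand] + sq
  live <- cand[s1 > 0]
  s0 <- s0[s1 > 0]; s1 <- s1[s1 > 0]
  n_steps <- ceiling(max(s1 - s0) / step)
  for (k in 0:n_steps) {
    if (!length(live)) break
    s <- pmin(s0 + k * step, s1)
    pts <- cbind(org[1] + s * d[live, 1], org[2] + s * d[live, 2],
                 org[3] + s * d[live, 3])
    inside <- shape_inside(shape, pts)
    hit[live[inside]] <- TRUE
    keep <- !inside & s < s1
    live <- live[keep]; s0 <- s0[keep]; s1 <- s1[keep]
  }
  hit
}

#' Assemble a five-view scene
#'
#' Bundles the rig, the per-view silhouettes and the bounding box into
#' the estimator's complete input, checking that each silhouette matches
#' its camera's image size.
#'
#' @param rig Named list of five cameras (top, side1..side4).
#' @param silhouettes Named list of five silhouettes, same names.
#' @param box A [bbox()].
#' @return An object of class `"scene"`.
#' @export
scene <- function(rig, silhouettes, box) {
  views <- c("top", "side1", "side2", "side3", "side4")
  stopifnot(all(views %in% names(rig)), all(views %in% names(silhouettes)),
            inherits(box, "bbox"))
  for (vn in views) {
    s <- silhouettes[[vn]]
    cam <- rig[[vn]]
    if (nrow(s) != cam$height || ncol(s) != cam$width)
      stop("silhouette '", vn, "' is ", nrow(s), "x", ncol(s),
           " but camera expects ", cam$height, "x", cam$width)
  }
  structure(list(rig = rig[views], silhouettes = silhouettes[views],
                 box = box), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene> 5 views,", x$rig$top$width, "x", x$rig$top$height, "px\n")
  print(x$box)
  invisible(x)
}

#' Generate a complete synthetic scene with ground truth
#'
#' Renders the five ideal silhouettes of `shape` under `rig`, optionally
#' corrupts them by flipping a given fraction of pixels (seeded), builds
#' the bounding box from the top view and the side view chosen by
#' [pick_height_view()], and returns the scene together with the shape's
#' true volume.
#'
#' @param shape An `"analytic_shape"`.
#' @param rig Camera rig; default [make_rig()].
#' @param noise Fraction of pixels to flip per silhouette (0 = ideal).
#' @param seed Integer seed for the noise; required when `noise > 0`.
#' @param margin_px Safety margin for [construct_bounding_box()].
#' @return A list: `scene` (a [scene()]), `true_volume` (cc), `shape`.
#' @export
generate_scene <- function(shape, rig = make_rig(), noise = 0, seed = 1L,
                           margin_px = 2) {
  sils <- lapply(rig, function(cam) render_silhouette(cam, shape))
  if (noise > 0) {
    sils <- with_seed(seed, lapply(sils, function(s) {
      m <- unclass(s)
      flip <- which(stats::runif(length(m)) < noise)
      m[flip] <- 1L - m[flip]
      as_silhouette(m)
    }))
  }
  hv <- pick_height_view(rig)
  box <- construct_bounding_box(rig$top, sils$top, rig[[hv]], sils[[hv]],
                                zl = 0, margin_px = margin_px)
  list(scene = scene(rig, sils, box), true_volume = shape_volume(shape),
       shape = shape)
}
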