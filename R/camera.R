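#' Pinhole camera for a five-view measurement rig
#'
#' Constructs a calibrated pinhole camera: intrinsics (focal lengths and
#' principal point in pixels, image size) plus the extrinsic pose mapping
#' world coordinates (cm, right-handed, object resting on the plane z = 0)
#' into the camera frame via \code{x_c = R p + t}. Lens distortion is taken
#' as identically zero; the webcams this model targets have negligible
#' radial and tangential distortion.
#'
#' Pixel convention: 0-based continuous coordinates \code{(u, v)} =
#' (column, row), origin at the centre of the top-left pixel. Projection
#' returns continuous coordinates; any rounding is the consumer's choice.
#'
#' @param fx,fy Focal lengths in pixel units; must be positive.
#' @param cx,cy Principal point in pixels; must lie inside the image.
#' @param width,height Image size in pixels.
#' @param R 3x3 rotation matrix, world to camera. Must be orthonormal with
#'   determinant +1 (tolerance 1e-8).
#' @param t Length-3 translation, camera frame, same length units as world
#'   coordinates (cm).
#' @param view View label, one of `"top"`, `"side1"` ... `"side4"`.
#' @param check_pose If `TRUE` (default), require the camera centre to lie
#'   strictly above the resting plane z = 0, as any physical rig camera
#'   must; disable for abstract test cameras.
#' @return An object of class `"camera"`.
#' @examples
#' cam <- camera(fx = 100, fy = 100, cx = 320, cy = 240,
#'               width = 640, height = 480,
#'               R = diag(3), t = c(0, 0, 0), view = "top")
#' project_point(cam, c(0, 0, 1))   # principal point (320, 240)
#' @export
camera <- function(fx, fy, cx, cy, width, height, R, t, view = "top",
                   check_pose = TRUE) {
  stopifnot(is.numeric(fx), is.numeric(fy), fx > 0, fy > 0)
  stopifnot(cx >= 0, cx < width, cy >= 0, cy < height)
  stopifnot(width >= 1, height >= 1)
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal (tolerance 1e-8)")
  if (abs(det(R) - 1) > 1e-8)
    stop("rotation matrix must have determinant +1 (got ", format(det(R)), ")")
  view <- match.arg(view, c("top", "side1", "side2", "side3", "side4"))
  cam <- structure(
    list(fx = fx, fy = fy, cx = cx, cy = cy,
         width = as.integer(width), height = as.integer(height),
         R = R, t = t, view = view),
    class = "camera")
  if (check_pose) {
    ctr <- camera_center(cam)
    if (ctr[3] <= 0)
      stop("camera centre must lie strictly above the plane z = 0")
  }
  cam
}

#' @export
print.camera <- function(x, ...) {
  cat(sprintf("<camera '%s'>  %dx%d px,  f = (%.1f, %.1f), c = (%.1f, %.1f)\n",
              x$view, x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  ctr <- camera_center(x)
  cat(sprintf("  centre (cm): (%.2f, %.2f, %.2f)\n", ctr[1], ctr[2], ctr[3]))
  invisible(x)
}

#' Camera centre in world coordinates
#'
#' The optical centre of a camera in world coordinates,
#' \eqn{-R^T t}, in cm.
#'
#' @param cam A [camera()].
#' @return Numeric length-3 world point.
#' @export
camera_center <- function(cam) {
  as.numeric(-crossprod(cam$R, cam$t))
}

#' Project world points to pixel coordinates
#'
#' Applies the pinhole model: \code{(x_c, y_c, z_c) = R p + t}, then
#' \code{u = fx x_c / z_c + cx}, \code{v = fy y_c / z_c + cy}. No clamping
#' to the image bounds is performed.
#'
#' `project_points()` is vectorised and returns the camera-frame depth
#' alongside the pixel coordinates so callers can detect behind-camera
#' points; `project_point()` takes a single point and signals an error when
#' the point is at or behind the camera plane.
#'
#' @param cam A [camera()].
#' @param pts Numeric matrix with one world point per row (n x 3), in cm.
#' @return `project_points()`: an n x 3 matrix with columns `u`, `v`,
#'   `depth` (camera-frame z, cm). `project_point()`: a length-2 numeric
#'   `(u, v)`.
#' @export
project_points <- function(cam, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  pc <- pts %*% t(cam$R)            # row i = R p_i (R applied on the left)
  pc <- sweep(pc, 2, cam$t, "+")
  z <- pc[, 3]
  u <- cam$fx * pc[, 1] / z + cam$cx
  v <- cam$fy * pc[, 2] / z + cam$cy
  cbind(u = u, v = v, depth = z)
}

#' @rdname project_points
#' @param p A single world point, numeric length 3.
#' @export
project_point <- function(cam, p) {
  out <- project_points(cam, matrix(p, 1, 3))
  if (out[1, "depth"] <= 0)
    stop("point is at or behind the camera plane (depth = ",
         format(out[1, "depth"]), ")")
  c(u = unname(out[1, "u"]), v = unname(out[1, "v"]))
}

#' Back-project a pixel to a world-space viewing ray
#'
#' Inverts the pinhole projection up to scale: the returned ray starts at
#' the camera centre and passes through the given pixel, so
#' `project_point(cam, origin + s * direction)` recovers `(u, v)` for any
#' s > 0.
#'
#' @param cam A [camera()].
#' @param u,v Continuous pixel coordinates (0-based, column/row).
#' @return A list with `origin` (camera centre, cm) and `direction`
#'   (unit length-3 vector).
#' @export
backproject_ray <- function(cam, u, v) {
  d_cam <- c((u - cam$cx) / cam$fx, (v - cam$cy) / cam$fy, 1)
  d <- as.numeric(crossprod(cam$R, d_cam))
  list(origin = camera_center(cam), direction = d / sqrt(sum(d^2)))
}

#' Intersect a ray with an axis-aligned plane
#'
#' Solves `origin + s * direction` for the point whose `axis` coordinate
#' equals `value`. The ray parameter s may be negative; callers that need a
#' forward intersection must check the sign themselves.
#'
#' @param origin Length-3 ray origin (cm).
#' @param direction Length-3 ray direction (need not be unit).
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param value Plane coordinate in cm.
#' @return A list with `point` (length-3) and `s` (ray parameter).
#' @export
intersect_ray_plane <- function(origin, direction, axis = c("x", "y", "z"),
                                value) {
  axis <- match.arg(axis)
  i <- match(axis, c("x", "y", "z"))
  if (abs(direction[i]) <= 1e-12)
    stop("ray is parallel to the plane ", axis, " = ", value,
         " (no intersection)")
  s <- (value - origin[i]) / direction[i]
  list(point = origin + s * direction, s = s)
}
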