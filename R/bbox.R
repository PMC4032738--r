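#' Axis-aligned world-space bounding box
#'
#' @param xl,xu,yl,yu,zl,zu Bounds in cm; each lower bound strictly below
#'   its upper bound.
#' @return An object of class `"bbox"` with a `box_volume()` accessor.
#' @export
bbox <- function(xl, xu, yl, yu, zl, zu) {
  stopifnot(xl < xu, yl < yu, zl < zu)
  structure(list(xl = xl, xu = xu, yl = yl, yu = yu, zl = zl, zu = zu),
            class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox> [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] cm, V_B = %.2f cc\n",
              x$xl, x$xu, x$yl, x$yu, x$zl, x$zu, box_volume(x)))
  invisible(x)
}

#' @rdname bbox
#' @param box A `"bbox"`.
#' @export
box_volume <- function(box) {
  (box$xu - box$xl) * (box$yu - box$yl) * (box$zu - box$zl)
}

#' Minimum bounding rectangle of a silhouette
#'
#' The tightest axis-aligned pixel rectangle containing every object
#' pixel, in 0-based (u, v) coordinates.
#'
#' @param s A `"silhouette"` 0/1 matrix.
#' @return Named numeric `(umin, vmin, umax, vmax)`.
#' @export
min_bounding_rect <- function(s) {
  idx <- which(unclass(s) == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty silhouette: no object pixels")
  c(umin = min(idx[, 2]) - 1, vmin = min(idx[, 1]) - 1,
    umax = max(idx[, 2]) - 1, vmax = max(idx[, 1]) - 1)
}

#' Construct the object bounding box from top and side views
#'
#' The x/y extent comes from the top view: the four corners of the
#' (margin-expanded) top bounding rectangle are back-projected and
#' intersected with the resting plane z = `zl`; the box's x and y bounds
#' are the min/max of the four footprints. The height comes from a side
#' view: the midpoint of the top edge of its bounding rectangle is
#' back-projected and intersected with the four vertical box faces
#' x = xl, x = xu, y = yl, y = yu; among forward intersections whose
#' footprint lies within the box's x/y extent (5% slack), the one with
#' the smallest ray parameter — the first face the ray crosses — gives
#' `zu`. A pixel safety margin (default 2 px) is added to both rectangles
#' before reprojection so rasterisation cannot break the containment
#' guarantee the Monte Carlo integral relies on.
#'
#' @param top_cam,top_sil Top-view camera and silhouette.
#' @param side_cam,side_sil Side-view camera and silhouette.
#' @param zl Lower z bound in cm; 0 for an object resting on the ground
#'   plane.
#' @param margin_px Safety margin added to the pixel rectangles.
#' @return A [bbox()].
#' @export
construct_bounding_box <- function(top_cam, top_sil, side_cam, side_sil,
                                   zl = 0, margin_px = 2) {
  rt <- expand_rect(min_bounding_rect(top_sil), margin_px,
                    top_cam$width, top_cam$height)
  corners <- rbind(c(rt["umin"], rt["vmin"]), c(rt["umax"], rt["vmin"]),
                   c(rt["umin"], rt["vmax"]), c(rt["umax"], rt["vmax"]))
  foot <- t(apply(corners, 1, function(q) {
    ray <- backproject_ray(top_cam, q[1], q[2])
    intersect_ray_plane(ray$origin, ray$direction, "z", zl)$point
  }))
  xl <- min(foot[, 1]); xu <- max(foot[, 1])
  yl <- min(foot[, 2]); yu <- max(foot[, 2])

  rs <- expand_rect(min_bounding_rect(side_sil), margin_px,
                    side_cam$width, side_cam$height)
  mid_top <- c((rs["umin"] + rs["umax"]) / 2, rs["vmin"])
  ray <- backproject_ray(side_cam, mid_top[1], mid_top[2])
  slack_x <- 0.05 * (xu - xl)
  slack_y <- 0.05 * (yu - yl)
  planes <- list(list("x", xl), list("x", xu), list("y", yl), list("y", yu))
  best <- NULL
  for (pl in planes) {
    hit <- tryCatch(
      intersect_ray_plane(ray$origin, ray$direction, pl[[1]], pl[[2]]),
      error = function(e) NULL)
    if (is.null(hit) || hit$s <= 0) next
    p <- hit$point
    if (p[1] < xl - slack_x || p[1] > xu + slack_x ||
        p[2] < yl - slack_y || p[2] > yu + slack_y) next
    if (is.null(best) || hit$s < best$s) best <- hit
  }
  if (is.null(best))
    stop("degenerate rig: side-view top point does not cross any vertical box face")
  zu <- best$point[3]
  if (zu <= zl)
    stop("degenerate rig: recovered object top lies at or below z = zl")
  bbox(xl, xu, yl, yu, zl, zu)
}

# Grow a pixel rect by m px, clamped to the image.
expand_rect <- function(r, m, width, height) {
  c(umin = max(r[["umin"]] - m, 0), vmin = max(r[["vmin"]] - m, 0),
    umax = min(r[["umax"]] + m, width - 1),
    vmax = min(r[["vmax"]] + m, height - 1))
}

#' Choose the side view used for the box height
#'
#' Returns the label of the side camera whose optical axis is most nearly
#' horizontal (smallest |z component|), i.e. the view that sees the
#' object's top edge with the least foreshortening.
#'
#' @param rig Named list of five cameras.
#' @return A view label, e.g. `"side1"`.
#' @export
pick_height_view <- function(rig) {
  sides <- grep("^side", names(rig), value = TRUE)
  tilt <- vapply(sides, function(vn) {
    axis <- as.numeric(crossprod(rig[[vn]]$R, c(0, 0, 1)))  # optical axis, world
    abs(axis[3])
  }, numeric(1))
  sides[which.min(tilt)]
}
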