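#' Read and write camera rig files
#'
#' A rig file is a YAML document with one mapping per view label
#' (`top`, `side1` ... `side4`), each holding the scalar intrinsics
#' `fx`, `fy`, `cx`, `cy`, `width`, `height`, the rotation `R` as nine
#' numbers in row-major order (world-to-camera), and the translation `t`
#' as three numbers (cm). All five views must be present; cameras are
#' validated on load (orthonormal R with determinant +1, principal point
#' inside the image, camera centre above z = 0).
#'
#' @param path Path to the rig file.
#' @return `load_camera_rig()`: a named list of five [camera()] objects in
#'   the order top, side1..side4. `write_camera_rig()`: `path`, invisibly.
#' @examples
#' rig <- make_rig()
#' f <- tempfile(fileext = ".yaml")
#' write_camera_rig(rig, f)
#' rig2 <- load_camera_rig(f)
#' stopifnot(all.equal(rig$top$R, rig2$top$R))
#' @export
load_camera_rig <- function(path) {
  if (!file.exists(path)) stop("rig file not found: ", path)
  doc <- yaml::read_yaml(path)
  views <- c("top", "side1", "side2", "side3", "side4")
  missing <- setdiff(views, names(doc))
  if (length(missing))
    stop("rig file is missing view(s): ", paste(missing, collapse = ", "))
  rig <- lapply(views, function(vn) {
    d <- doc[[vn]]
    need <- c("fx", "fy", "cx", "cy", "width", "height", "R", "t")
    absent <- setdiff(need, names(d))
    if (length(absent))
      stop("view '", vn, "' is missing key(s): ",
           paste(absent, collapse = ", "))
    if (length(d$R) != 9) stop("view '", vn, "': R must have 9 numbers")
    if (length(d$t) != 3) stop("view '", vn, "': t must have 3 numbers")
    camera(fx = d$fx, fy = d$fy, cx = d$cx, cy = d$cy,
           width = d$width, height = d$height,
           R = matrix(as.numeric(d$R), 3, 3, byrow = TRUE),
           t = as.numeric(d$t), view = vn)
  })
  names(rig) <- views
  rig
}

#' @rdname load_camera_rig
#' @param rig Named list of five [camera()] objects (names top, side1..4).
#' @export
write_camera_rig <- function(rig, path) {
  views <- c("top", "side1", "side2", "side3", "side4")
  stopifnot(all(views %in% names(rig)))
  doc <- lapply(rig[views], function(cam) {
    list(fx = cam$fx, fy = cam$fy, cx = cam$cx, cy = cam$cy,
         width = cam$width, height = cam$height,
         R = as.numeric(t(cam$R)),   # row-major on disk
         t = as.numeric(cam$t))
  })
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}
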