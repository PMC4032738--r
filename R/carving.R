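#' Voxel space-carving baseline
#'
#' Discretises the scene's bounding box into a regular grid and keeps
#' each voxel iff its centre passes the same five-view silhouette
#' membership test the Monte Carlo estimator uses ([membership()] — a
#' shared code path, so the two methods target exactly the same visual
#' hull). The surviving voxel count times the voxel volume is the carved
#' volume. Carving is the deterministic but much slower baseline the
#' sampling estimator is compared against.
#'
#' @param scn A [scene()].
#' @param resolution Voxels per axis, scalar or length-3 `(nx, ny, nz)`.
#' @return An object of class `"voxel_grid"`: logical `occupancy` array,
#'   the `box`, and `resolution`.
#' @export
carve <- function(scn, resolution = 100L) {
  res <- rep(as.integer(resolution), length.out = 3)
  stopifnot(all(res >= 2))
  box <- scn$box
  xs <- box$xl + (seq_len(res[1]) - 0.5) / res[1] * (box$xu - box$xl)
  ys <- box$yl + (seq_len(res[2]) - 0.5) / res[2] * (box$yu - box$yl)
  zs <- box$zl + (seq_len(res[3]) - 0.5) / res[3] * (box$zu - box$zl)
  occ <- array(FALSE, res)
  grid_xy <- cbind(rep(xs, times = res[2]), rep(ys, each = res[1]))
  for (k in seq_len(res[3])) {           # slice by z to bound memory
    occ[, , k] <- membership(scn, cbind(grid_xy, zs[k])) == 1L
  }
  structure(list(occupancy = occ, box = box, resolution = res),
            class = "voxel_grid")
}

#' @rdname carve
#' @param grid A `"voxel_grid"`.
#' @return `carved_volume()`: volume in cc.
#' @export
carved_volume <- function(grid) {
  sum(grid$occupancy) * box_volume(grid$box) / prod(grid$resolution)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, %d voxels kept, volume %.3f cc\n",
              x$resolution[1], x$resolution[2], x$resolution[3],
              sum(x$occupancy), carved_volume(x)))
  invisible(x)
}

#' Run the sampling estimator and the carving baseline side by side
#'
#' @param scn A [scene()].
#' @param n Random points for the Monte Carlo estimate.
#' @param resolution Carving resolution per axis.
#' @param seed Integer seed.
#' @return A one-row data frame: `v_mc`, `v_carve`, `rel_diff_pct`.
#' @export
compare_methods <- function(scn, n = 8e5, resolution = 100L, seed = 1L) {
  v_mc <- estimate_volume(scn, n = n, seed = seed)$v_raw
  v_cv <- carved_volume(carve(scn, resolution))
  data.frame(v_mc = v_mc, v_carve = v_cv,
             rel_diff_pct = abs(v_mc - v_cv) / v_cv * 100)
}
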