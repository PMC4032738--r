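#' Random shape classes for synthetic studies
#'
#' A shape class is a seeded generator of similar objects, standing in
#' for a product type (all apples, all mangoes, ...). Two classes are
#' built in:
#'
#' * `"sphere"` — spheres with radius jittered uniformly within
#'   `radius_jitter` of the base radius; the idealised calibration-ball
#'   class.
#' * `"sphere_union"` — a core sphere of the base radius plus 3-6
#'   overlapping satellite spheres (radii 45-75% of the core, centres
#'   0.5-1.0 core radii away in a random direction), resting on z = 0.
#'   These lumpy solids have concavities no five-view visual hull can
#'   recover, so their raw estimates carry the systematic overestimate
#'   the class adjustment K exists to remove.
#'
#' @param kind `"sphere"` or `"sphere_union"`.
#' @param radius Base radius in cm.
#' @param radius_jitter Relative jitter of the base radius.
#' @return An object of class `"shape_class"`; draw members with
#'   [random_shape()].
#' @export
shape_class <- function(kind = c("sphere", "sphere_union"), radius = 3,
                        radius_jitter = 0.1) {
  kind <- match.arg(kind)
  stopifnot(radius > 0, radius_jitter >= 0, radius_jitter < 1)
  structure(list(kind = kind, radius = radius,
                 radius_jitter = radius_jitter),
            class = "shape_class")
}

#' @rdname shape_class
#' @param cls A `"shape_class"`.
#' @param seed Integer seed; one seed, one member.
#' @export
random_shape <- function(cls, seed) {
  with_seed(seed, {
    r0 <- cls$radius * stats::runif(1, 1 - cls$radius_jitter,
                                    1 + cls$radius_jitter)
    if (cls$kind == "sphere") return(shape_sphere(r0))
    n_sat <- sample(3:6, 1)
    theta <- stats::runif(n_sat, 0, 2 * pi)
    phi <- acos(stats::runif(n_sat, -1, 1))
    dist <- stats::runif(n_sat, 0.5, 1.0) * r0
    ctrs <- rbind(c(0, 0, 0),
                  cbind(dist * sin(phi) * cos(theta),
                        dist * sin(phi) * sin(theta),
                        dist * cos(phi)))
    radii <- c(r0, stats::runif(n_sat, 0.45, 0.75) * r0)
    shape_sphere_union(ctrs, radii)
  })
}

#' Convergence study over the number of random points
#'
#' Measures one shape `repeats` times at each sample size in `n_grid`
#' and reports the mean absolute relative error against the true volume
#' and the coefficient of variation — the table used to choose the
#' operating sample size. With the analytic membership test over the
#' tight box, the CV follows the binomial law
#' `sqrt((1 - p) / (p n)) * 100%` with p the hit probability.
#'
#' @param shape An `"analytic_shape"`.
#' @param n_grid Vector of sample sizes.
#' @param repeats Repeats per sample size (100 for a precision study).
#' @param seed Integer seed.
#' @param scn Optional [scene()]; if supplied, the silhouette-based
#'   estimator is studied instead of the analytic one.
#' @return Data frame: `n`, `mean_are_pct`, `cv_pct`.
#' @export
run_convergence_study <- function(shape, n_grid = c(1e3, 1e4, 1e5),
                                  repeats = 100L, seed = 1L, scn = NULL) {
  stopifnot(length(n_grid) >= 1)
  truth <- shape_volume(shape)
  target <- if (is.null(scn)) shape else scn
  rows <- lapply(seq_along(n_grid), function(i) {
    runs <- repeated_measurement(target, n = n_grid[i], repeats = repeats,
                                 seed = seed + 1000L * (i - 1L))
    data.frame(n = n_grid[i],
               mean_are_pct = mean(are(truth, runs$values)),
               cv_pct = if (repeats >= 2) runs$cv else NA_real_)
  })
  do.call(rbind, rows)
}

#' End-to-end synthetic measurement protocol
#'
#' Reproduces the full measurement protocol on a synthetic product
#' class: draw `n_samples` shapes from `cls`, render each under `rig`
#' and build its scene; calibrate the adjustment K as the mean
#' truth/raw ratio on the first `calibration_size` shapes; measure the
#' remaining held-out shapes (mean of `repeats` runs each); and report
#' accuracy before and after adjustment, precision, correlation and the
#' paired t-test against ground truth.
#'
#' @param cls A [shape_class()].
#' @param n_samples Total shapes drawn (calibration + held out).
#' @param calibration_size Shapes used to calibrate K (protocol uses 5).
#' @param n_points Random points per measurement.
#' @param repeats Repeats per shape (protocol uses 3; their mean is the
#'   measured volume).
#' @param seed Integer seed; shape i uses seed `seed + i`, measurements
#'   use derived seeds.
#' @param rig Camera rig; default [make_rig()].
#' @return A list of class `"protocol_report"`: `k`, `mean_are_before`,
#'   `mean_are_after`, `are_reduction_pct`, `mean_cv_pct`, `validation`
#'   (from [validate_measurements()] on adjusted volumes), and the
#'   per-shape table `samples`.
#' @export
run_paper_protocol <- function(cls, n_samples = 25L, calibration_size = 5L,
                               n_points = 8e5, repeats = 3L, seed = 1L,
                               rig = make_rig()) {
  stopifnot(n_samples > calibration_size, calibration_size >= 1)
  per_shape <- lapply(seq_len(n_samples), function(i) {
    shp <- random_shape(cls, seed + i)
    gs <- generate_scene(shp, rig)
    runs <- repeated_measurement(gs$scene, n = n_points, repeats = repeats,
                                 seed = seed + 37L * i)
    data.frame(id = i, true_volume = gs$true_volume, v_raw = runs$mean,
               cv_pct = if (repeats >= 2) runs$cv else NA_real_)
  })
  tab <- do.call(rbind, per_shape)
  cal_idx <- seq_len(calibration_size)
  cal <- calibrate_adjustment(tab$true_volume[cal_idx], tab$v_raw[cal_idx],
                              label = cls$kind)
  held <- tab[-cal_idx, ]
  held$v_adjusted <- cal$k * held$v_raw
  held$are_before <- are(held$true_volume, held$v_raw)
  held$are_after <- are(held$true_volume, held$v_adjusted)
  mab <- mean(held$are_before)
  maa <- mean(held$are_after)
  structure(list(
    k = cal$k,
    mean_are_before = mab,
    mean_are_after = maa,
    are_reduction_pct = (1 - maa / mab) * 100,
    mean_cv_pct = mean(held$cv_pct),
    validation = validate_measurements(held$v_adjusted, held$true_volume),
    samples = held,
    config = list(class = cls, n_samples = n_samples,
                  calibration_size = calibration_size, n_points = n_points,
                  repeats = repeats, seed = seed)),
    class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic protocol: class '%s', %d samples (%d calibration), n = %g, %d repeat(s)\n",
              cfg$class$kind, cfg$n_samples, cfg$calibration_size,
              cfg$n_points, cfg$repeats))
  cat(sprintf("  K = %.5f\n", x$k))
  cat(sprintf("  mean ARE before adjustment: %6.3f %%\n", x$mean_are_before))
  cat(sprintf("  mean ARE after adjustment : %6.3f %%\n", x$mean_are_after))
  cat(sprintf("  ARE reduction             : %6.2f %%\n", x$are_reduction_pct))
  cat(sprintf("  mean CV                   : %6.3f %%\n", x$mean_cv_pct))
  invisible(x)
}

#' Measure an object from silhouette and rig files
#'
#' The file-level entry point behind the command-line `measure`
#' subcommand: load five silhouettes and a rig file, build the bounding
#' box, run the estimator in `repeats` replicates and apply an optional
#' adjustment factor.
#'
#' @param silhouette_paths Named character vector or list with entries
#'   `top`, `side1` ... `side4` (PGM or PNG files).
#' @param rig_path Camera rig file ([load_camera_rig()]).
#' @param n_points Random points per repeat.
#' @param repeats Number of repeats; their mean is reported.
#' @param seed Integer seed.
#' @param k Adjustment factor (1 = unadjusted).
#' @param label Label copied into the output row.
#' @return One-row data frame: `label`, `v_raw_cc`, `v_adjusted_cc`,
#'   `k`, `n`, `inside_count`, `cv_pct`.
#' @export
measure_scene <- function(silhouette_paths, rig_path, n_points = 8e5,
                          repeats = 3L, seed = 1L, k = 1, label = "object") {
  rig <- load_camera_rig(rig_path)
  views <- c("top", "side1", "side2", "side3", "side4")
  stopifnot(all(views %in% names(silhouette_paths)))
  sils <- lapply(views, function(vn) read_silhouette(silhouette_paths[[vn]]))
  names(sils) <- views
  hv <- pick_height_view(rig)
  box <- construct_bounding_box(rig$top, sils$top, rig[[hv]], sils[[hv]])
  scn <- scene(rig, sils, box)
  runs <- repeated_measurement(scn, n = n_points, repeats = repeats,
                               seed = seed)
  est <- estimate_volume(scn, n = n_points, seed = seed)
  data.frame(label = label, v_raw_cc = runs$mean,
             v_adjusted_cc = k * runs$mean, k = k, n = as.integer(n_points),
             inside_count = est$inside_count,
             cv_pct = if (repeats >= 2) runs$cv else NA_real_)
}

#' Write a synthetic scene to files
#'
#' Renders a shape under a rig and writes the five silhouettes (PGM),
#' the rig file (YAML) and a small ground-truth text file
#' (`truth.yaml`: true volume in cc plus the generator settings) into a
#' directory — the fixture layout consumed by [measure_scene()] and the
#' command-line tools.
#'
#' @param shape An `"analytic_shape"`.
#' @param out_dir Output directory (created if needed).
#' @param rig Camera rig.
#' @param noise Pixel-flip fraction for the silhouettes.
#' @param seed Integer seed (noise only).
#' @return Invisibly, a list of the written paths.
#' @export
simulate_scene_files <- function(shape, out_dir, rig = make_rig(),
                                 noise = 0, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gs <- generate_scene(shape, rig, noise = noise, seed = seed)
  paths <- list(rig = file.path(out_dir, "rig.yaml"),
                truth = file.path(out_dir, "truth.yaml"))
  write_camera_rig(rig, paths$rig)
  for (vn in names(gs$scene$silhouettes)) {
    p <- file.path(out_dir, paste0(vn, ".pgm"))
    write_silhouette(gs$scene$silhouettes[[vn]], p)
    paths[[vn]] <- p
  }
  yaml::write_yaml(list(true_volume_cc = gs$true_volume,
                        shape_kind = shape$kind, noise = noise, seed = seed),
                   paths$truth)
  invisible(paths)
}
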