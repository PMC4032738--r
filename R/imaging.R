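#' Convert an RGB image to H, S, V channel images
#'
#' Standard hexcone conversion. Input is an H x W x 3 array of 8-bit
#' values (0-255) or of doubles already scaled to (0,1]; output hue is in
#' degrees [0, 360), saturation and value in [0, 1].
#'
#' @param img H x W x 3 numeric array.
#' @return List of H x W matrices `h`, `s`, `v`.
#' @export
rgb_to_hsv <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  d <- dim(img)[1:2]
  mx <- max(img)
  scale <- if (mx > 1) 255 else 1
  rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = scale)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

#' Weighted HSV grayscale
#'
#' Builds the working grayscale image as the weighted sum
#' \code{Gr = w_h H + w_s S + w_v V}, with the three channels first scaled
#' to a common [0, 1] range (hue divided by 360) so the weights act on
#' commensurate quantities, then min-max normalises the result to
#' [0, 255]. A constant-range result normalises to all zeros, so a
#' featureless image yields an empty silhouette downstream rather than an
#' error.
#'
#' @param h,s,v Channel matrices as returned by [rgb_to_hsv()].
#' @param weights Length-3 numeric `(w_h, w_s, w_v)`, each in [0, 1], not
#'   all zero. The useful weighting is scene-dependent; `c(0, 0.3, 0.7)`
#'   works well for saturated objects on a dark background.
#' @return Matrix of doubles in [0, 255].
#' @export
weighted_grayscale <- function(h, s, v, weights = c(0, 0.3, 0.7)) {
  stopifnot(length(weights) == 3, all(weights >= 0), all(weights <= 1),
            any(weights > 0))
  if (!all(dim(h) == dim(s)) || !all(dim(h) == dim(v)))
    stop("H, S, V channels must have identical dimensions")
  gr <- weights[1] * (h / 360) + weights[2] * s + weights[3] * v
  rng <- range(gr)
  if (diff(rng) == 0) return(array(0, dim(gr)))
  (gr - rng[1]) / diff(rng) * 255
}

#' 3x3 Gaussian smoothing
#'
#' Separable convolution with the binomial kernel [1,2,1]/4 in each
#' direction (the discrete 3x3 Gaussian, sigma ~ 0.85 px). Borders are
#' edge-replicated, so constant images pass through unchanged.
#'
#' @param img Numeric matrix, at least 3 x 3.
#' @return Smoothed matrix, same dimensions.
#' @export
gaussian_smooth <- function(img) {
  stopifnot(is.matrix(img), nrow(img) >= 3, ncol(img) >= 3)
  pad_rows <- rbind(img[1, , drop = FALSE], img, img[nrow(img), , drop = FALSE])
  sm <- (pad_rows[1:nrow(img), ] + 2 * pad_rows[2:(nrow(img) + 1), ] +
           pad_rows[3:(nrow(img) + 2), ]) / 4
  pad_cols <- cbind(sm[, 1, drop = FALSE], sm, sm[, ncol(sm), drop = FALSE])
  (pad_cols[, 1:ncol(img)] + 2 * pad_cols[, 2:(ncol(img) + 1)] +
      pad_cols[, 3:(ncol(img) + 2)]) / 4
}

#' Automatic global threshold by iterated class means
#'
#' The classic iterative scheme: start at the global mean, then repeat
#' `T <- (mean(pixels > T) + mean(pixels <= T)) / 2` until the change is
#' below 0.5 gray levels. Suitable when object and background form two
#' reasonably separated modes, as for bright produce on a black
#' background.
#'
#' @param img Numeric matrix with at least two distinct values.
#' @return The converged threshold (double).
#' @export
iterative_threshold <- function(img) {
  x <- as.vector(img)
  if (length(unique(x)) < 2)
    stop("degenerate histogram: image has a single gray level")
  t_cur <- mean(x)
  repeat {
    hi <- x[x > t_cur]
    lo <- x[x <= t_cur]
    if (!length(hi) || !length(lo)) break  # all mass on one side; T is final
    t_new <- (mean(hi) + mean(lo)) / 2
    if (abs(t_new - t_cur) < 0.5) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

#' Threshold a grayscale image into a binary silhouette
#'
#' Pixels strictly greater than `threshold` become object (1), all others
#' background (0).
#'
#' @param img Numeric matrix.
#' @param threshold Scalar threshold.
#' @return Integer 0/1 matrix of class `"silhouette"`.
#' @export
binarize <- function(img, threshold) {
  as_silhouette((img > threshold) * 1L)
}

#' Binary silhouette container
#'
#' Wraps an H x W 0/1 matrix; 1 = object, 0 = background. Row index is the
#' image row v (0-based v maps to row v + 1), column index the column u.
#'
#' @param m 0/1 matrix.
#' @return The matrix with class `"silhouette"`.
#' @export
as_silhouette <- function(m) {
  m <- as.matrix(m)
  if (!all(m %in% c(0L, 1L)))
    stop("silhouette values must be 0 or 1")
  storage.mode(m) <- "integer"
  class(m) <- c("silhouette", class(m))
  m
}

#' @export
print.silhouette <- function(x, ...) {
  cat(sprintf("<silhouette> %d x %d px, %d object pixels (%.1f%%)\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

# Count of object pixels under a k x k all-ones element centred at each
# pixel, with zeros outside the image (the stated border policy: erosion
# shrinks at borders, dilation never reaches past them).
boxsum <- function(m, k) {
  r <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L * r, nc + 2L * r)
  pad[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- m
  cs <- apply(pad, 2, cumsum)
  rowsum_ <- cs[(k):(k + nr - 1L), , drop = FALSE] -
    rbind(0, cs[1:(nr - 1L), , drop = FALSE])
  cs2 <- t(apply(rowsum_, 1, cumsum))
  cs2[, (k):(k + nc - 1L), drop = FALSE] -
    cbind(0, cs2[, 1:(nc - 1L), drop = FALSE])
}

erode_bin <- function(m, k) (boxsum(m, k) == k * k) * 1L
dilate_bin <- function(m, k) (boxsum(m, k) > 0) * 1L

#' Morphological opening and closing
#'
#' `morph_open()` erodes then dilates with a 5 x 5 square element,
#' removing white specks in the background; `morph_close()` dilates then
#' erodes with a 3 x 3 square element, filling black specks in the object.
#' Pixels outside the image count as background for both operations, so
#' erosion shrinks the object at the image border.
#'
#' @param s A [as_silhouette()] 0/1 matrix.
#' @param k Side of the square structuring element (odd).
#' @return A silhouette of the same size.
#' @export
morph_open <- function(s, k = 5L) {
  as_silhouette(dilate_bin(erode_bin(unclass(s), k), k))
}

#' @rdname morph_open
#' @export
morph_close <- function(s, k = 3L) {
  as_silhouette(erode_bin(dilate_bin(unclass(s), k), k))
}

#' Segment an RGB image into a binary silhouette
#'
#' The full extraction pipeline: HSV conversion, weighted grayscale
#' ([weighted_grayscale()]), 3x3 Gaussian smoothing, automatic iterative
#' threshold, binarisation (strictly-greater rule), 5x5 opening and 3x3
#' closing.
#'
#' @inheritParams rgb_to_hsv
#' @inheritParams weighted_grayscale
#' @return A `"silhouette"` 0/1 matrix.
#' @export
segment <- function(img, weights = c(0, 0.3, 0.7)) {
  ch <- rgb_to_hsv(img)
  gr <- weighted_grayscale(ch$h, ch$s, ch$v, weights)
  sm <- gaussian_smooth(gr)
  th <- iterative_threshold(sm)
  morph_close(morph_open(binarize(sm, th)))
}
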