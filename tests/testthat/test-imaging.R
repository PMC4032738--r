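# Independent hexcone HSV reference, written directly from the max/min
# formulation rather than via grDevices.
hsv_oracle <- function(r, g, b) {
  r <- r / 255; g <- g / 255; b <- b / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- ifelse(d == 0, 0,
       ifelse(mx == r, ((g - b) / d) %% 6,
       ifelse(mx == g, (b - r) / d + 2, (r - g) / d + 4))) * 60
  s <- ifelse(mx == 0, 0, d / mx)
  c(h = h, s = s, v = mx)
}

test_that("RGB to HSV handles canonical and random colours", {
  img <- array(0, c(1, 1, 3))
  img[1, 1, ] <- c(255, 0, 0)
  ch <- rgb_to_hsv(img)
  expect_equal(c(ch$h[1, 1], ch$s[1, 1], ch$v[1, 1]), c(0, 1, 1))

  img[1, 1, ] <- c(128, 128, 128)
  ch <- rgb_to_hsv(img)
  expect_equal(c(ch$s[1, 1], ch$v[1, 1]), c(0, 128 / 255))

  set.seed(21)
  rgb <- matrix(sample(0:255, 60, replace = TRUE), ncol = 3)
  img <- array(0, c(nrow(rgb), 1, 3))
  img[, 1, ] <- rgb
  ch <- rgb_to_hsv(img)
  for (i in seq_len(nrow(rgb))) {
    ref <- hsv_oracle(rgb[i, 1], rgb[i, 2], rgb[i, 3])
    expect_equal(ch$h[i, 1], unname(ref["h"]), tolerance = 1e-9)
    expect_equal(ch$s[i, 1], unname(ref["s"]), tolerance = 1e-9)
    expect_equal(ch$v[i, 1], unname(ref["v"]), tolerance = 1e-9)
  }
})

test_that("weighted grayscale reduces to the chosen channel and normalises", {
  set.seed(22)
  h <- matrix(runif(30, 0, 360), 5, 6)
  s <- matrix(runif(30), 5, 6)
  v <- matrix(runif(30), 5, 6)

  gr <- weighted_grayscale(h, s, v, c(0, 0, 1))
  expect_equal(gr, (v - min(v)) / diff(range(v)) * 255, tolerance = 1e-9)

  expect_equal(weighted_grayscale(h * 0 + 5, s * 0 + 0.5, v * 0 + 0.5,
                                  c(0, 0.5, 0.5)),
               array(0, c(5, 6)))

  w <- c(0.2, 0.3, 0.5)
  raw <- w[1] * h / 360 + w[2] * s + w[3] * v
  expect_equal(weighted_grayscale(h, s, v, w),
               (raw - min(raw)) / diff(range(raw)) * 255, tolerance = 1e-9)

  expect_error(weighted_grayscale(h, s[1:3, ], v, w), "dimensions")
})

test_that("3x3 Gaussian smoothing matches kernel and separable oracle", {
  expect_equal(gaussian_smooth(matrix(7, 5, 5)), matrix(7, 5, 5))

  imp <- matrix(0, 5, 5); imp[3, 3] <- 16
  expect_equal(gaussian_smooth(imp)[2:4, 2:4],
               matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3))

  # full 2D convolution oracle with replicated borders, direct loops
  set.seed(23)
  img <- matrix(runif(12 * 9, 0, 255), 12, 9)
  kern <- outer(c(1, 2, 1), c(1, 2, 1)) / 16
  ref <- img * 0
  for (i in 1:12) for (j in 1:9) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), 12)
      jj <- min(max(j + dj, 1), 9)
      acc <- acc + kern[di + 2, dj + 2] * img[ii, jj]
    }
    ref[i, j] <- acc
  }
  expect_equal(gaussian_smooth(img), ref, tolerance = 1e-9)
})

test_that("iterative threshold finds the between-class fixed point", {
  img <- matrix(c(rep(0, 50), rep(200, 50)), 10, 10)
  expect_equal(iterative_threshold(img), 100)

  img <- matrix(c(rep(10, 70), rep(250, 30)), 10, 10)
  expect_equal(iterative_threshold(img), 130)

  expect_error(iterative_threshold(matrix(5, 4, 4)), "degenerate")

  # bimodal mixture: compare to a brute-force scan for the fixed point
  set.seed(24)
  x <- c(rnorm(300, 60, 12), rnorm(200, 190, 18))
  img <- matrix(x, 25, 20)
  cand <- seq(min(x) + 0.5, max(x) - 0.5, by = 0.1)
  g <- vapply(cand, function(tt) {
    (mean(x[x > tt]) + mean(x[x <= tt])) / 2
  }, numeric(1))
  fixed <- cand[which.min(abs(g - cand))]
  expect_lt(abs(iterative_threshold(img) - fixed), 1)
})

test_that("binarisation uses the strictly-greater rule", {
  img <- matrix(c(0, 200, 100, 40), 2, 2)
  s <- binarize(img, 100)
  expect_equal(as.integer(s), c(0L, 1L, 0L, 0L))  # 100 is background
  expect_true(all(binarize(img, 300) == 0))

  set.seed(25)
  img <- matrix(runif(400, 0, 255), 20, 20)
  tt <- runif(1, 0, 255)
  expect_equal(sum(binarize(img, tt)), sum(img > tt))
  # idempotence: re-thresholding the 0/1 image at 0.5 changes nothing
  s <- binarize(img, tt)
  expect_equal(unclass(binarize(unclass(s), 0.5)), unclass(s))
})

test_that("opening removes specks, closing fills holes", {
  m <- matrix(0L, 20, 20); m[7, 9] <- 1L
  expect_true(all(morph_open(as_silhouette(m)) == 0))

  m <- matrix(0L, 20, 20); m[5:15, 5:15] <- 1L; m[10, 10] <- 0L
  closed <- morph_close(as_silhouette(m))
  expect_equal(closed[10, 10], 1L)

  # solid square away from borders survives open-then-close unchanged
  m <- matrix(0L, 40, 40); m[10:29, 10:29] <- 1L
  out <- morph_close(morph_open(as_silhouette(m)))
  expect_equal(unclass(out), m)
})

test_that("opening is anti-extensive and closing extensive on random blobs", {
  set.seed(26)
  for (i in 1:5) {
    m <- matrix(0L, 30, 30)
    for (b in 1:4) {
      ci <- sample(8:22, 2)
      r <- sample(2:5, 1)
      ii <- pmax(ci[1] - r, 1):pmin(ci[1] + r, 30)
      jj <- pmax(ci[2] - r, 1):pmin(ci[2] + r, 30)
      m[ii, jj] <- 1L
    }
    s <- as_silhouette(m)
    expect_true(all(morph_open(s) <= s))      # never adds object pixels
    expect_true(all(morph_close(s) >= s))     # never removes them
  }
})

# Bright disc on black background, composited directly in RGB.
disc_image <- function(h = 60, w = 80, cy = 30, cx = 40, r = 18,
                       level = 220) {
  img <- array(0, c(h, w, 3))
  mask <- outer(1:h, 1:w, function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
  for (k in 1:3) img[, , k][mask] <- level
  list(img = img, mask = mask * 1L)
}

test_that("segmentation recovers a bright object on black background", {
  d <- disc_image()
  s <- segment(d$img, c(0, 0, 1))
  expect_gt(mean(unclass(s) == d$mask), 0.99)

  expect_error(segment(array(0, c(10, 10, 3)), c(0, 0, 1)), "degenerate")
})

test_that("segmentation tolerates salt-and-pepper noise", {
  set.seed(27)
  d <- disc_image()
  noisy <- d$img
  flip <- which(runif(60 * 80) < 0.01)
  for (k in 1:3) {
    ch <- noisy[, , k]
    ch[flip] <- 255 - ch[flip]
    noisy[, , k] <- ch
  }
  s_clean <- segment(d$img, c(0, 0, 1))
  s_noisy <- segment(noisy, c(0, 0, 1))
  expect_lt(mean(unclass(s_clean) != unclass(s_noisy)), 0.01)
})

test_that("segmentation is invariant to global brightness rescaling of V", {
  d <- disc_image(level = 240)
  dim_img <- d$img * 0.5          # half the exposure
  expect_equal(unclass(segment(dim_img * (255 / max(dim_img)) / 255 * 255,
                               c(0, 0, 1))),
               unclass(segment(d$img, c(0, 0, 1))))
  # direct rescale without renormalising the array scale
  expect_equal(unclass(segment(d$img * 0.6, c(0, 0, 1))),
               unclass(segment(d$img, c(0, 0, 1))))
})

test_that("silhouettes round-trip through PGM and PNG files", {
  set.seed(28)
  s <- as_silhouette(matrix(rbinom(35 * 20, 1, 0.4), 20, 35))
  for (ext in c(".pgm", ".png")) {
    f <- withr::local_tempfile(fileext = ext)
    write_silhouette(s, f)
    expect_equal(unclass(read_silhouette(f)), unclass(s),
                 ignore_attr = TRUE)
  }
})
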