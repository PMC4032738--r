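# Shared fixtures: a reduced-resolution rig for fast rendering tests and
# an abstract identity camera for pure geometry checks.

small_rig <- function() {
  make_rig(image_size = c(160, 120), f = 260)
}

identity_camera <- function(fx = 100, fy = 100, cx = 320, cy = 240) {
  camera(fx = fx, fy = fy, cx = cx, cy = cy, width = 640, height = 480,
         R = diag(3), t = c(0, 0, 0), check_pose = FALSE)
}

# Uniform random rotation (QR of a Gaussian matrix, sign-fixed to det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_camera <- function() {
  repeat {
    R <- random_rotation()
    t <- stats::rnorm(3, sd = 10)
    if ((-crossprod(R, t))[3] > 0) break
  }
  camera(fx = stats::runif(1, 200, 1500), fy = stats::runif(1, 200, 1500),
         cx = stats::runif(1, 100, 500), cy = stats::runif(1, 100, 400),
         width = 640, height = 480, R = R, t = t)
}

# Distance from a point to the line {origin + s * direction}, computed
# from the residual vector (stable under cancellation).
point_line_distance <- function(p, origin, direction) {
  d <- direction / sqrt(sum(direction^2))
  w <- p - origin
  resid <- w - sum(w * d) * d
  sqrt(sum(resid^2))
}
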