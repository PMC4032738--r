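#' Exact sphere volume
#'
#' `4/3 pi r^3`, the reference volume for calibration balls.
#'
#' @param r Radius in cm, positive.
#' @return Volume in cc.
#' @export
exact_sphere_volume <- function(r) {
  stopifnot(all(r > 0))
  4 / 3 * pi * r^3
}

#' Absolute relative error
#'
#' `|v_ref - v_app| / v_ref * 100`, in percent. Accuracy metric against
#' an exact or water-displacement reference.
#'
#' @param v_ref Reference volume(s), positive.
#' @param v_app Approximated volume(s).
#' @return Percent ARE, vectorised.
#' @export
are <- function(v_ref, v_app) {
  stopifnot(all(v_ref > 0))
  abs(v_ref - v_app) / v_ref * 100
}

#' Coefficient of variation
#'
#' `sd / mean * 100` in percent, with the sample (n-1) standard
#' deviation. Precision metric for repeated measurements of one object.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return Percent CV.
#' @export
cv_percent <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("degenerate input: mean is zero")
  stats::sd(values) / m * 100
}

#' Pearson correlation between method and reference volumes
#'
#' @param v_app,v_ref Paired volume vectors, length >= 3, each with
#'   nonzero variance.
#' @return Product-moment correlation in \[-1, 1\].
#' @export
pearson_r <- function(v_app, v_ref) {
  stopifnot(length(v_app) == length(v_ref), length(v_app) >= 3)
  if (stats::sd(v_app) == 0 || stats::sd(v_ref) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(v_app, v_ref)
}

#' Paired t-test of method vs reference volumes
#'
#' One-sample t-test on the differences `v_app - v_ref`: is the mean
#' disagreement with the reference method zero? Reports the mean
#' difference, its 95% confidence interval (t quantile, n-1 df), the t
#' statistic and the two-sided p-value. Identical-to-reference input
#' (zero-variance, zero-mean differences) returns t = 0, p = 1;
#' zero-variance differences with nonzero mean return p = 0 by
#' convention, since any nonzero constant offset is then certain.
#'
#' @param v_app,v_ref Paired volume vectors, length >= 2.
#' @return List: `mean_diff`, `ci95` (length 2), `t`, `p`, `df`.
#' @export
paired_ttest <- function(v_app, v_ref) {
  stopifnot(length(v_app) == length(v_ref), length(v_app) >= 2)
  d <- v_app - v_ref
  if (stats::sd(d) == 0) {
    return(list(mean_diff = mean(d), ci95 = c(mean(d), mean(d)),
                t = if (mean(d) == 0) 0 else Inf,
                p = if (mean(d) == 0) 1 else 0,
                df = length(d) - 1))
  }
  tt <- stats::t.test(d, mu = 0, conf.level = 0.95)
  list(mean_diff = unname(tt$estimate), ci95 = as.numeric(tt$conf.int),
       t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Validation report for a set of paired measurements
#'
#' Convenience wrapper producing the standard evaluation row: mean ARE,
#' correlation and paired t-test of method volumes against reference
#' volumes.
#'
#' @inheritParams pearson_r
#' @return A one-row data frame: `n`, `mean_are_pct`, `r`, `mean_diff`,
#'   `ci_lo`, `ci_hi`, `t`, `p`.
#' @export
validate_measurements <- function(v_app, v_ref) {
  tt <- paired_ttest(v_app, v_ref)
  data.frame(n = length(v_app),
             mean_are_pct = mean(are(v_ref, v_app)),
             r = if (length(v_app) >= 3 && stats::sd(v_app) > 0 &&
                     stats::sd(v_ref) > 0) pearson_r(v_app, v_ref)
                 else NA_real_,
             mean_diff = tt$mean_diff, ci_lo = tt$ci95[1],
             ci_hi = tt$ci95[2], t = tt$t, p = tt$p)
}
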