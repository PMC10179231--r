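#' Power of the linear-regression F-test from Cohen's f-squared
#'
#' For a regression with `df1` tested predictors and `n` observations, the
#' F statistic under the alternative is noncentral F with degrees of freedom
#' `(df1, n - df1 - 1)` and noncentrality `lambda = f2 * n`. Power is the
#' probability that this exceeds the central-F critical value at `alpha`.
#' With `df1 = 1` (the default, a single tested predictor) this reproduces
#' the conventional sample-size calculations for a per-SNP regression stage.
#'
#' @param f2 Cohen's f-squared effect size, `R^2 / (1 - R^2)`, >= 0.
#' @param n Sample size.
#' @param alpha Type-I error probability.
#' @param df1 Number of tested predictors.
#' @return Power in `[0, 1]`.
#' @examples
#' power_linear_f2(0.15, 117)   # ~0.986
#' power_linear_f2(0.02, 117)   # ~0.329
#' @export
power_linear_f2 <- function(f2, n, alpha = 0.05, df1 = 1) {
  if (f2 < 0) stop("power_linear_f2: f2 must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("power_linear_f2: alpha must be in (0, 1)")
  if (n <= df1 + 1) stop("power_linear_f2: n must exceed df1 + 1")
  df2 <- n - df1 - 1
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = f2 * n, lower.tail = FALSE)
}

#' Effect size required for a target power
#'
#' Inverts [power_linear_f2()] in `f2` by monotone bisection.
#'
#' @param power_target Target power, in `(alpha, 1)`.
#' @param n Sample size.
#' @param alpha Type-I error probability.
#' @param df1 Number of tested predictors.
#' @param tol Power tolerance of the bisection.
#' @return The smallest `f2` achieving the target power.
#' @examples
#' required_f2(0.80, 117)  # ~0.0682
#' @export
required_f2 <- function(power_target, n, alpha = 0.05, df1 = 1, tol = 1e-8) {
  if (power_target <= alpha || power_target >= 1)
    stop("required_f2: target power must lie in (alpha, 1)")
  lo <- 0; hi <- 1
  while (power_linear_f2(hi, n, alpha, df1) < power_target) {
    hi <- hi * 2
    if (hi > 1e6) stop("required_f2: target power unattainable")
  }
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (power_linear_f2(mid, n, alpha, df1) < power_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
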