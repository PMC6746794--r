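#' Analytic power for allele-score Mendelian randomization with a binary
#' outcome
#'
#' Computes the power of a one-degree-of-freedom test of the causal effect in
#' an instrumental-variable (allele score) analysis of a case-control study,
#' using the binary-outcome approximation implemented by the mRnd calculator.
#' The attenuated score-outcome coefficient on the risk-difference scale is
#' \deqn{b = K\left(\frac{OR}{1 + K(OR - 1)} - 1\right),}
#' its variance \eqn{v = (K(1-K) - b^2) / (N R^2_{xz})}, and the test has a
#' noncentral chi-square distribution with 1 df and noncentrality
#' \eqn{b^2 / v}. Power is evaluated at the \eqn{1-\alpha} quantile of the
#' central chi-square.
#'
#' @param N Total sample size (cases + controls).
#' @param K Case fraction, in (0, 1).
#' @param R2xz Proportion of exposure variance explained by the genetic
#'   score, in (0, 1).
#' @param alpha Significance level, in (0, 1). Default 0.05.
#' @param OR Causal odds ratio per unit (SD) of the exposure; may be a
#'   vector.
#' @return Numeric vector of power values in `[alpha, 1)`, with attribute
#'   `"components"`: a data.frame of `b_mr`, `v_mr`, `ncp` per OR.
#' @seealso [min_detectable_or()]
#' @examples
#' mrnd_binary_power(N = 4080, K = 1336 / 4080, R2xz = 0.10, OR = 1.33)
#' @export
mrnd_binary_power <- function(N, K, R2xz, alpha = 0.05, OR) {
  stopifnot(is_count(N), is_prob(K), is_prob(R2xz), is_prob(alpha))
  if (!is.numeric(OR) || any(!is.finite(OR)) || any(OR <= 0))
    stop2("OR must be positive and finite")
  b <- K * (OR / (1 + K * (OR - 1)) - 1)
  v <- (K * (1 - K) - b^2) / (N * R2xz)
  if (any(v <= 0))
    stop2("variance of the MR estimate is non-positive (K(1-K) <= b^2); ",
          "OR too extreme for case fraction K = ", format(K, digits = 4))
  ncp <- b^2 / v
  q <- stats::qchisq(1 - alpha, df = 1)
  pow <- stats::pchisq(q, df = 1, ncp = ncp, lower.tail = FALSE)
  attr(pow, "components") <- data.frame(OR = OR, b_mr = b, v_mr = v, ncp = ncp)
  pow
}

#' Minimum detectable causal odds ratio at a target power
#'
#' Finds, by bisection on (1, 10], the smallest causal odds ratio above 1
#' whose analytic MR power (see [mrnd_binary_power()]) reaches the target.
#'
#' @inheritParams mrnd_binary_power
#' @param target_power Target power, in (alpha, 1).
#' @param tol Absolute bisection tolerance on the OR (default 1e-4).
#' @param digits Optional rounding of the reported OR (e.g. 2 for a
#'   two-decimal headline value); `NULL` (default) returns the raw root.
#' @return The minimum detectable OR (> 1).
#' @examples
#' min_detectable_or(N = 4080, K = 1336 / 4080, R2xz = 0.10,
#'                   target_power = 0.80, digits = 2)
#' @export
min_detectable_or <- function(N, K, R2xz, alpha = 0.05, target_power = 0.80,
                              tol = 1e-4, digits = NULL) {
  stopifnot(is_prob(target_power), target_power > alpha)
  f <- function(or) mrnd_binary_power(N, K, R2xz, alpha, or) - target_power
  lo <- 1 + 1e-9
  # the approximation degenerates (v <= 0) beyond OR_max where
  # b(OR) = sqrt(K(1-K)); cap the bracket just below it
  cc <- 1 + sqrt((1 - K) / K)
  or_max <- if (cc * K < 1) cc * (1 - K) / (1 - cc * K) else Inf
  hi <- min(10, 0.999 * or_max)
  if (f(hi) < 0)
    stop2("target power ", target_power, " unreachable for OR <= 10")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  or <- (lo + hi) / 2
  if (!is.null(digits)) or <- round(or, digits)
  or
}
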