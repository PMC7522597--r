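# Prospective power for the gene burden test via the one-sample
# proportion test with arcsine-transformed effect size.

arcsine_h <- function(p0, p1) 2 * asin(sqrt(p1)) - 2 * asin(sqrt(p0))

check_power_spec <- function(p0, p1, alpha) {
  if (!(p0 > 0 && p0 < 1 && p1 > 0 && p1 < 1)) {
    stop("p0 and p1 must lie in (0, 1)")
  }
  if (p1 <= p0) stop("one-sided greater test requires p1 > p0")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
}

#' Power of the one-sided one-sample proportion test
#'
#' Normal-approximation power with the arcsine effect size
#' `h = 2*asin(sqrt(p1)) - 2*asin(sqrt(p0))`:
#' `power = Phi(h * sqrt(n) - z_{1-alpha})`. `p0` is the expected carrier
#' probability (the rescaled `P_success,g`), `p1` the alternative
#' (observed `k / N_S`), and `alpha` typically a Bonferroni-style level
#' `0.05 / m` over the joint test universe.
#'
#' @param p0 Null carrier probability.
#' @param p1 Alternative carrier probability (`> p0`).
#' @param n Sample size (number of subjects), `>= 1`.
#' @param alpha One-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
proportion_power <- function(p0, p1, n, alpha = 0.05) {
  check_power_spec(p0, p1, alpha)
  stopifnot(n >= 1)
  h <- arcsine_h(p0, p1)
  stats::pnorm(h * sqrt(n) - stats::qnorm(1 - alpha))
}

#' Smallest sample size reaching a target power
#'
#' Inverts [proportion_power()]: starting from
#' `n = ceiling(((z_{1-alpha} + z_{power}) / h)^2)`, the integer is
#' adjusted so that `proportion_power(n) >= target` and
#' `proportion_power(n - 1) < target`.
#'
#' @inheritParams proportion_power
#' @param target Target power in `(0, 1)` (default 0.8).
#' @return Smallest integer `n` achieving the target power.
#' @export
required_n <- function(p0, p1, target = 0.8, alpha = 0.05) {
  check_power_spec(p0, p1, alpha)
  if (!(target > 0 && target < 1)) stop("target power must lie in (0, 1)")
  h <- arcsine_h(p0, p1)
  n <- ceiling(((stats::qnorm(1 - alpha) + stats::qnorm(target)) / h)^2)
  n <- max(1L, as.integer(n))
  while (proportion_power(p0, p1, n, alpha) < target) n <- n + 1L
  while (n > 1L && proportion_power(p0, p1, n - 1L, alpha) >= target) {
    n <- n - 1L
  }
  n
}
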