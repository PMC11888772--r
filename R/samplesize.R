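#' A-priori sample size for an ICC reliability study
#'
#' Walter--Eliasziw--Donner approximation for the number of subjects needed
#' to show that the intraclass correlation exceeds `rho0` when the true
#' value is `rho1`, with `k` ratings per subject:
#'
#' \deqn{n = 1 + \frac{2k(z_{1-\alpha} + z_{1-\beta})^2}
#'                    {(k-1)\,[\ln(C_1/C_0)]^2},\quad
#'       C(\rho) = 1 + \frac{k\rho}{1-\rho}}
#'
#' rounded up to an integer. With the defaults (three ratings, one-sided
#' alpha 0.05, power 0.90, null ICC 0 against a target of 0.50) the
#' minimum is 15 participants.
#'
#' @param rho0 ICC under the null hypothesis (default 0).
#' @param rho1 Anticipated ICC, must exceed `rho0`.
#' @param k Ratings per subject (default 3).
#' @param alpha One-sided significance level (default 0.05).
#' @param power Desired power (default 0.90).
#' @return Minimum number of participants (integer).
#' @examples
#' icc_sample_size()                    # 15
#' icc_sample_size(k = 2)               # more subjects with fewer ratings
#' @export
icc_sample_size <- function(rho0 = 0, rho1 = 0.5, k = 3, alpha = 0.05,
                            power = 0.9) {
  if (!(rho0 >= 0 && rho0 < rho1 && rho1 < 1)) {
    stop_validation("need 0 <= rho0 < rho1 < 1")
  }
  if (k < 2) stop_validation("`k` must be at least 2")
  if (!(alpha > 0 && alpha < 1)) stop_validation("`alpha` must be in (0, 1)")
  if (!(power > 0 && power < 1)) stop_validation("`power` must be in (0, 1)")
  cfun <- function(rho) 1 + k * rho / (1 - rho)
  za <- stats::qnorm(1 - alpha)
  zb <- stats::qnorm(power)
  n <- ceiling(1 + 2 * k * (za + zb)^2 /
                 ((k - 1) * log(cfun(rho1) / cfun(rho0))^2))
  if (n <= .Machine$integer.max) as.integer(n) else n
}

#' Inflate a sample size for anticipated dropout
#'
#' @param n Minimum sample size.
#' @param rate Anticipated dropout fraction in `[0, 1)` (default 0.30).
#' @return Smallest integer at least `n * (1 + rate)`.
#' @examples
#' inflate_for_dropout(15)        # 20
#' inflate_for_dropout(7, 0.3)    # 10
#' @export
inflate_for_dropout <- function(n, rate = 0.3) {
  if (n < 1) stop_validation("`n` must be at least 1")
  if (!(rate >= 0 && rate < 1)) stop_validation("`rate` must be in [0, 1)")
  as.integer(ceiling(n * (1 + rate)))
}
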