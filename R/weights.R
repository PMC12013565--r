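#' Odds-scale shift of an event probability
#'
#' Multiplies the odds of an event by `R` and returns the resulting
#' probability, `R * p / (1 - p + R * p)`. This is the alternative-hypothesis
#' rate the risk-adjusted CUSUM is calibrated to detect: "rate doubled"
#' corresponds to `R = 2` on the odds scale, "rate halved" to `R = 0.5`. The
#' map is the identity at `R = 1` and strictly increasing in `R`.
#'
#' @param p event probability (vectorised), in (0, 1).
#' @param R odds ratio, > 0.
#' @return Shifted probability, same length as `p`.
#' @examples
#' shifted_rate(0.1, 2)   # 0.1818...
#' shifted_rate(0.5, 2)   # 2/3
#' @export
shifted_rate <- function(p, R) {
  if (any(p <= 0 | p >= 1)) stop("`p` must lie strictly inside (0, 1)")
  if (any(R <= 0)) stop("`R` must be positive")
  R * p / (1 - p + R * p)
}

#' CUSUM log-likelihood-ratio weights
#'
#' Per-procedure CUSUM increments. `weights_unadjusted()` tests a constant
#' in-control event rate `theta0` against an out-of-control rate `theta1`:
#' the weight is `log(theta1/theta0)` after an event and
#' `log((1-theta1)/(1-theta0))` otherwise. `weights_risk_adjusted()` uses the
#' Steiner construction, in which the hypotheses are odds ratios `R0` (null,
#' conventionally 1) and `R1` applied to each patient's own expected risk
#' `p_i`:
#' \deqn{W_i = \log\frac{1-p_i+R_0 p_i}{1-p_i+R_1 p_i}\quad (y_i=0),\qquad
#'       W_i = \log\frac{(1-p_i+R_0 p_i)\,R_1}{(1-p_i+R_1 p_i)\,R_0}\quad (y_i=1).}
#'
#' With `R1 > R0`, weights are positive after an event and negative
#' otherwise. When every risk equals a constant `p` and `R0 = 1`, the
#' risk-adjusted weights coincide with the unadjusted ones under the odds
#' mapping `theta0 = p`, `theta1 = shifted_rate(p, R1)`.
#'
#' @param cohort an [cohort()] object.
#' @param theta0,theta1 in-control and out-of-control event rates,
#'   `0 < theta0 < theta1 < 1`.
#' @param R0,R1 null and alternative odds ratios, `R1 > R0 > 0`.
#' @return Numeric vector of weights, one per procedure.
#' @examples
#' coh <- cohort(c(1, 0), c(0.5, 0.5))
#' weights_risk_adjusted(coh, R0 = 1, R1 = 2)  # log(4/3), log(2/3)
#' @export
weights_unadjusted <- function(cohort, theta0, theta1) {
  stopifnot(inherits(cohort, "oe_cohort"))
  check_rates(theta0, theta1)
  ifelse(cohort$outcome == 1,
         log(theta1 / theta0),
         log((1 - theta1) / (1 - theta0)))
}

check_rates <- function(theta0, theta1) {
  if (!is.numeric(theta0) || !is.numeric(theta1) ||
      theta0 <= 0 || theta1 >= 1 || theta0 >= theta1)
    stop("rates must satisfy 0 < theta0 < theta1 < 1")
  invisible(TRUE)
}

#' @rdname weights_unadjusted
#' @export
weights_risk_adjusted <- function(cohort, R0 = 1, R1 = 2) {
  stopifnot(inherits(cohort, "oe_cohort"))
  if (!(R1 > R0 && R0 > 0))
    stop("odds ratios must satisfy R1 > R0 > 0")
  steiner_weights(cohort$outcome, cohort$risk, R0, R1)
}

# Core Steiner weight formula, shared with the ARL simulator (where the
# improvement side is handled by negation and R1 < R0 is legitimate).
steiner_weights <- function(y, p, R0, R1) {
  a0 <- 1 - p + R0 * p
  a1 <- 1 - p + R1 * p
  ifelse(y == 1, log(a0 * R1 / (a1 * R0)), log(a0 / a1))
}
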