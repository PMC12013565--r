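#' Run the two-sided CUSUM with signal detection and reset
#'
#' Applies the paired recursions in procedure order, starting from 0:
#' \deqn{X_i^+ = \max(0,\; X_{i-1}^+ + W_i^+), \qquad
#'       X_i^- = \min(X_{i-1}^- - W_i^-,\; 0).}
#' The deterioration side signals at the first `i` with `X_i^+ >= h_plus`;
#' the improvement side at the first `i` with `X_i^- <= -h_minus` (the
#' threshold is inclusive, the common CUSUM convention). After a signal the
#' affected subscore — or both, under `reset_policy = "both-sides"` — is
#' reset to 0 before procedure `i + 1`, and monitoring continues. The stored
#' trajectory keeps the pre-reset value at the signal index; resets are
#' book-kept separately.
#'
#' Each side consumes the log-likelihood-ratio series built for its own
#' alternative hypothesis: `weights` (deterioration, e.g. odds doubled) and
#' `weights_minus` (improvement, e.g. odds halved, from
#' [weights_risk_adjusted()] with `R1 < 1` passed through
#' `steiner` parameters — see [chart_params()]). When `weights_minus` is
#' omitted the deterioration series drives both recursions, which reduces the
#' improvement side to the negative mirror of the deterioration side; that
#' compact single-series form is supported for completeness but a real
#' two-sided monitor should supply per-side weights (as [build_chart()]
#' does).
#'
#' @param weights numeric weight series for the deterioration side.
#' @param h_plus positive control limit for the deterioration subscore.
#' @param h_minus positive magnitude of the improvement-side limit.
#' @param weights_minus optional weight series for the improvement side
#'   (same length); defaults to `weights`.
#' @param reset_policy `"triggering-side-only"` (default) resets only the
#'   side that signalled; `"both-sides"` resets both subscores.
#' @return An object of class `cusum_trajectory`: list with `x_plus`,
#'   `x_minus` (stored, pre-reset values), `signals` and `resets`
#'   (data.frames with columns `index`, `side`), `h_plus`, `h_minus`.
#' @examples
#' tr <- run_two_sided(c(0.5, 0.6, -0.2), h_plus = 1, h_minus = 1)
#' tr$signals  # deterioration signal at procedure 2
#' @export
run_two_sided <- function(weights, h_plus, h_minus,
                          weights_minus = weights,
                          reset_policy = c("triggering-side-only",
                                           "both-sides")) {
  reset_policy <- match.arg(reset_policy)
  if (!is.numeric(h_plus) || !is.numeric(h_minus) ||
      length(h_plus) != 1L || length(h_minus) != 1L ||
      h_plus <= 0 || h_minus <= 0)
    stop("control limits must be single positive numbers")
  n <- length(weights)
  if (length(weights_minus) != n)
    stop("`weights` and `weights_minus` must have equal length")
  x_plus <- numeric(n)
  x_minus <- numeric(n)
  sig_index <- integer(0); sig_side <- character(0)
  rst_index <- integer(0); rst_side <- character(0)
  up <- 0; dn <- 0
  for (i in seq_len(n)) {
    up <- max(0, up + weights[i])
    dn <- min(dn - weights_minus[i], 0)
    x_plus[i] <- up
    x_minus[i] <- dn
    hit_up <- up >= h_plus
    hit_dn <- dn <= -h_minus
    if (hit_up) {            # deterioration listed first on simultaneous hits
      sig_index <- c(sig_index, i); sig_side <- c(sig_side, "deterioration")
    }
    if (hit_dn) {
      sig_index <- c(sig_index, i); sig_side <- c(sig_side, "improvement")
    }
    if (hit_up || hit_dn) {
      both <- reset_policy == "both-sides"
      if (hit_up || both) {
        up <- 0
        rst_index <- c(rst_index, i); rst_side <- c(rst_side, "deterioration")
      }
      if (hit_dn || both) {
        dn <- 0
        rst_index <- c(rst_index, i); rst_side <- c(rst_side, "improvement")
      }
    }
  }
  structure(list(
    x_plus = x_plus,
    x_minus = x_minus,
    signals = data.frame(index = sig_index, side = sig_side,
                         stringsAsFactors = FALSE),
    resets = data.frame(index = rst_index, side = rst_side,
                        stringsAsFactors = FALSE),
    h_plus = h_plus,
    h_minus = h_minus,
    reset_policy = reset_policy
  ), class = "cusum_trajectory")
}

#' @export
print.cusum_trajectory <- function(x, ...) {
  cat(sprintf("<cusum_trajectory> %d procedures, h+ = %g, h- = %g, %d signal(s)\n",
              length(x$x_plus), x$h_plus, x$h_minus, nrow(x$signals)))
  if (nrow(x$signals)) print(x$signals)
  invisible(x)
}

#' Chart parameter set for the combined O-E CUSUM chart
#'
#' Bundles the hypotheses and control limits that [build_chart()] needs. In
#' risk-adjusted mode the deterioration side tests the null odds ratio `R0`
#' (conventionally 1, i.e. outcomes follow each patient's expected risk)
#' against `R1 > R0` (e.g. 2: event odds doubled); the improvement side tests
#' `R0` against `R1_improve < R0` (default `1/R1`: odds halved). In
#' unadjusted mode a fixed baseline rate `p0` plays the role of every
#' expected risk, with `theta1 = shifted_rate(p0, R1)` unless `theta1` is
#' given directly.
#'
#' @param h_plus,h_minus positive control limits (deterioration /
#'   improvement magnitude).
#' @param R0 null odds ratio (default 1).
#' @param R1 deterioration-side alternative odds ratio, `> R0`.
#' @param R1_improve improvement-side alternative odds ratio, `< R0`;
#'   default `R0^2 / R1` (the reflected shift, `1/R1` when `R0 = 1`).
#' @param mode `"risk-adjusted"` (default) or `"unadjusted"`.
#' @param p0 baseline event rate, required for unadjusted mode.
#' @param theta1 optional explicit out-of-control rate for unadjusted mode;
#'   default `shifted_rate(p0, R1)`.
#' @param reset_policy passed to [run_two_sided()].
#' @return A list of class `oe_chart_params`.
#' @export
chart_params <- function(h_plus, h_minus, R0 = 1, R1 = 2,
                         R1_improve = R0^2 / R1,
                         mode = c("risk-adjusted", "unadjusted"),
                         p0 = NULL, theta1 = NULL,
                         reset_policy = "triggering-side-only") {
  mode <- match.arg(mode)
  if (h_plus <= 0 || h_minus <= 0) stop("control limits must be positive")
  if (!(R1 > R0 && R0 > 0)) stop("odds ratios must satisfy R1 > R0 > 0")
  if (!(R1_improve < R0 && R1_improve > 0))
    stop("`R1_improve` must satisfy 0 < R1_improve < R0")
  if (mode == "unadjusted") {
    if (is.null(p0)) stop("unadjusted mode requires `p0`")
    if (p0 <= 0 || p0 >= 1) stop("`p0` must lie in (0, 1)")
    if (is.null(theta1)) theta1 <- shifted_rate(p0, R1 / R0)
    check_rates(p0, theta1)
  }
  structure(list(h_plus = h_plus, h_minus = h_minus,
                 R0 = R0, R1 = R1, R1_improve = R1_improve,
                 mode = mode, p0 = p0, theta1 = theta1,
                 reset_policy = reset_policy),
            class = "oe_chart_params")
}
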