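#' Cumulative observed-minus-expected (O-E) series
#'
#' The O-E chart (also called the variable life-adjusted display, VLAD, when
#' risk-adjusted) plots the running sum of observed events minus expected
#' events across procedures. The curve moves up by `1 - p` when an event
#' occurs and down by `p` otherwise. By convention the value before the first
#' procedure is 0; the value after procedure `i` is the cumulative sum of the
#' first `i` steps. A positive final value counts potentially avoidable
#' events in excess of expectation; a negative one counts potentially avoided
#' events.
#'
#' `oe_unadjusted()` uses one fixed baseline event probability `p0` for every
#' procedure; `oe_adjusted()` uses each procedure's own expected risk, which
#' removes case-mix drift from the display.
#'
#' Steps are accumulated left to right in procedure order (plain sequential
#' summation), so results are bit-reproducible across platforms.
#'
#' @param cohort an [cohort()] object.
#' @param p0 baseline event probability in (0, 1).
#' @return An object of class `oe_series`: a list with `values` (numeric, one
#'   entry per procedure) and `type`.
#' @examples
#' coh <- cohort(c(1, 0, 0), rep(0.2, 3))
#' oe_unadjusted(coh, p0 = 0.2)$values  # 0.8 0.6 0.4
#' oe_adjusted(coh)$values
#' @export
oe_unadjusted <- function(cohort, p0) {
  stopifnot(inherits(cohort, "oe_cohort"))
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop("`p0` must be a single probability strictly inside (0, 1)")
  new_oe_series(cumsum(cohort$outcome - p0), type = "unadjusted")
}

#' @rdname oe_unadjusted
#' @export
oe_adjusted <- function(cohort) {
  stopifnot(inherits(cohort, "oe_cohort"))
  new_oe_series(cumsum(cohort$outcome - cohort$risk), type = "adjusted")
}

new_oe_series <- function(values, type) {
  structure(list(values = as.numeric(values), type = type),
            class = "oe_series")
}

#' Look up an O-E value with the pre-baseline convention
#'
#' `oe_value(oe, 0)` is 0 (the value before the first procedure), which is
#' what sequence quantification references when a sequence starts at
#' procedure 1.
#'
#' @param oe an `oe_series`.
#' @param i procedure index, 0 to `length(oe$values)`.
#' @return The cumulative O-E value after procedure `i`.
#' @export
oe_value <- function(oe, i) {
  stopifnot(inherits(oe, "oe_series"))
  n <- length(oe$values)
  if (any(i < 0 | i > n)) stop("index out of range [0, ", n, "]")
  ifelse(i == 0, 0, oe$values[pmax(i, 1L)])
}

#' @export
print.oe_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<oe_series> %s, %d procedures, final O-E = %.3f\n",
              x$type, n, x$values[n]))
  invisible(x)
}
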