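#' Detect monitoring sequences from a CUSUM trajectory
#'
#' A monitoring sequence is the interval between the procedure after the
#' subscore's last visit to zero and the signalling procedure, inclusive.
#' For a signal at index `s` on a given side, the start is `z + 1`, where
#' `z` is the largest index before `s` at which that side's subscore was
#' (effectively) zero — a reset counts as a zero, so a sequence following a
#' signal on the same side begins immediately after the reset — and `z = 0`
#' when the subscore never returned to zero, in which case the sequence
#' starts at procedure 1.
#'
#' @param trajectory a [run_two_sided()] result.
#' @return A data.frame with one row per signal, columns `side`, `start`,
#'   `end`, ordered by `end` (deterioration first on ties).
#' @examples
#' tr <- run_two_sided(c(-0.1, -0.1, 0.5, 0.6), h_plus = 1, h_minus = 10)
#' detect_sequences(tr)  # deterioration, start 3, end 4
#' @export
detect_sequences <- function(trajectory) {
  stopifnot(inherits(trajectory, "cusum_trajectory"))
  sigs <- trajectory$signals
  if (!nrow(sigs))
    return(data.frame(side = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(sigs)), function(k) {
    s <- sigs$index[k]
    side <- sigs$side[k]
    eff <- effective_subscore(trajectory, side)
    zeros <- which(eff[seq_len(s - 1)] == 0)
    z <- if (length(zeros)) max(zeros) else 0L
    data.frame(side = side, start = z + 1L, end = s,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$end, res$side != "deterioration"), , drop = FALSE]
}

# Subscore values as seen by the sequence definition: the stored value,
# except that a reset index counts as zero (the value carried forward).
effective_subscore <- function(trajectory, side) {
  x <- if (side == "deterioration") trajectory$x_plus else trajectory$x_minus
  eff <- x
  r <- trajectory$resets
  idx <- r$index[r$side == side]
  if (length(idx)) eff[idx] <- 0
  eff
}

#' Quantify a sequence as potentially avoided or avoidable events
#'
#' The impact of a sequence is the change in the cumulative O-E value across
#' it: `oe[end] - oe[start - 1]`, with the pre-first-procedure value defined
#' as 0. A positive delta during a deterioration sequence counts potentially
#' avoidable events (excess over expectation); a negative delta during an
#' improvement sequence counts potentially avoided events.
#'
#' @param oe an `oe_series` (see [oe_adjusted()]).
#' @param start,end sequence bounds (procedure indices, inclusive).
#' @return The O-E delta over the sequence, in events.
#' @export
quantify_sequence <- function(oe, start, end) {
  stopifnot(inherits(oe, "oe_series"))
  n <- length(oe$values)
  if (!(start >= 1 && start <= end && end <= n))
    stop(sprintf("sequence bounds must satisfy 1 <= start <= end <= %d", n))
  oe_value(oe, end) - oe_value(oe, start - 1L)
}

#' Build the combined risk-adjusted O-E CUSUM chart
#'
#' Orchestrates the full pipeline: the risk-adjusted O-E series, the
#' two-sided risk-adjusted CUSUM (deterioration side testing odds ratio
#' `R1`, improvement side testing `R1_improve`), sequence detection, and
#' per-sequence quantification of potentially avoided/avoidable events. In
#' unadjusted mode the baseline rate `p0` replaces the per-procedure risks
#' in both the O-E steps and the CUSUM weights.
#'
#' Under risk adjustment a deterioration sequence's O-E delta can in rare
#' cases come out slightly negative (the CUSUM weights and the O-E steps
#' are different functionals of outcome and risk); such sequences are kept
#' and flagged in the `sign_anomaly` column rather than suppressed.
#'
#' @param cohort an [cohort()] object.
#' @param params an [chart_params()] object.
#' @return An object of class `oe_chart_result`: list with `oe`
#'   (`oe_series`), `trajectory` (`cusum_trajectory`), `sequences`
#'   (data.frame: `side`, `start`, `end`, `delta_oe`, `display_count`,
#'   `sign_anomaly`), `params`, `cohort`, `label`.
#' @examples
#' set.seed(1)
#' coh <- sample_cohort(cohort_spec(60, risk = 0.2, seed = 4))
#' res <- build_chart(coh, chart_params(h_plus = 2, h_minus = 2))
#' res$sequences
#' @export
build_chart <- function(cohort, params) {
  stopifnot(inherits(cohort, "oe_cohort"),
            inherits(params, "oe_chart_params"))
  if (params$mode == "risk-adjusted") {
    oe <- oe_adjusted(cohort)
    w_plus <- steiner_weights(cohort$outcome, cohort$risk,
                              params$R0, params$R1)
    w_minus <- steiner_weights(cohort$outcome, cohort$risk,
                               params$R0, params$R1_improve)
  } else {
    oe <- oe_unadjusted(cohort, params$p0)
    th0 <- params$p0
    th1 <- params$theta1
    w_plus <- ifelse(cohort$outcome == 1, log(th1 / th0),
                     log((1 - th1) / (1 - th0)))
    th1_imp <- shifted_rate(th0, params$R1_improve / params$R0)
    w_minus <- ifelse(cohort$outcome == 1, log(th1_imp / th0),
                      log((1 - th1_imp) / (1 - th0)))
  }
  trajectory <- run_two_sided(w_plus, params$h_plus, params$h_minus,
                              weights_minus = w_minus,
                              reset_policy = params$reset_policy)
  seqs <- detect_sequences(trajectory)
  if (nrow(seqs)) {
    seqs$delta_oe <- vapply(seq_len(nrow(seqs)), function(k)
      quantify_sequence(oe, seqs$start[k], seqs$end[k]), numeric(1))
    seqs$display_count <- round(abs(seqs$delta_oe), 1)
    tol <- 1e-9
    seqs$sign_anomaly <- ifelse(seqs$side == "deterioration",
                                seqs$delta_oe < -tol, seqs$delta_oe > tol)
  } else {
    seqs$delta_oe <- numeric(0)
    seqs$display_count <- numeric(0)
    seqs$sign_anomaly <- logical(0)
  }
  structure(list(oe = oe, trajectory = trajectory, sequences = seqs,
                 params = params, cohort = cohort,
                 label = attr(cohort, "label")),
            class = "oe_chart_result")
}

#' @export
print.oe_chart_result <- function(x, ...) {
  n <- length(x$oe$values)
  cat(sprintf("<oe_chart_result> '%s': %d procedures, final O-E = %.2f\n",
              x$label, n, x$oe$values[n]))
  if (nrow(x$sequences)) {
    for (k in seq_len(nrow(x$sequences))) {
      s <- x$sequences[k, ]
      cat(sprintf("  %s sequence, procedures %d-%d: %.1f event(s) potentially %s\n",
                  s$side, s$start, s$end, s$display_count,
                  if (s$side == "deterioration") "avoidable" else "avoided"))
    }
  } else {
    cat("  no statistically abnormal sequences detected\n")
  }
  invisible(x)
}

#' @export
summary.oe_chart_result <- function(object, ...) {
  s <- object$sequences
  out <- list(
    n_procedures = length(object$oe$values),
    final_oe = object$oe$values[length(object$oe$values)],
    n_deterioration = sum(s$side == "deterioration"),
    n_improvement = sum(s$side == "improvement"),
    events_avoidable = sum(pmax(s$delta_oe[s$side == "deterioration"], 0)),
    events_avoided = -sum(pmin(s$delta_oe[s$side == "improvement"], 0))
  )
  class(out) <- "summary.oe_chart_result"
  out
}

#' @export
print.summary.oe_chart_result <- function(x, ...) {
  cat(sprintf(
    "%d procedures; final O-E %.2f; %d deterioration / %d improvement sequence(s); %.1f potentially avoidable, %.1f potentially avoided event(s)\n",
    x$n_procedures, x$final_oe, x$n_deterioration, x$n_improvement,
    x$events_avoidable, x$events_avoided))
  invisible(x)
}
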