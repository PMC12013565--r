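#' @importFrom stats rbeta rbinom rnorm runif plogis binomial coef glm fitted
#' @importFrom utils read.csv write.csv head tail
NULL

# Floor/ceiling applied to expected risks: the Steiner CUSUM weights contain
# log terms that are undefined at p = 0 or 1, so risks are clamped to
# [RISK_EPS, 1 - RISK_EPS] on entry and every clamp is reported.
RISK_EPS <- 1e-6

#' Construct a monitored procedure cohort
#'
#' A cohort is an ordered stream of procedures, each carrying a binary outcome
#' indicator and an expected (preoperative) event probability, in the order in
#' which the procedures were performed. Order is authoritative: the package
#' never re-sorts rows, because every downstream statistic (cumulative O-E,
#' CUSUM subscores, run lengths) is defined on the monitoring order.
#'
#' @param outcome integer or logical vector of event indicators; every value
#'   must be exactly 0 or 1.
#' @param risk numeric vector of expected event probabilities. Values outside
#'   `[0, 1]` are rejected; values of exactly 0 or 1 are clamped into the open
#'   interval at `1e-6` with a warning (the risk-adjusted CUSUM weights are
#'   undefined at the boundary).
#' @param label free-text cohort identifier (e.g. a surgeon code).
#' @param meta optional data.frame of per-procedure annotations (dates,
#'   identifiers); carried through unchanged.
#'
#' @return An object of class `oe_cohort`: a data.frame with columns `index`
#'   (1-based procedure order), `outcome`, `risk`, plus any `meta` columns,
#'   and a `label` attribute.
#' @examples
#' coh <- cohort(outcome = c(1, 0, 0), risk = c(0.2, 0.2, 0.2))
#' nrow(coh)
#' @export
cohort <- function(outcome, risk, label = "cohort", meta = NULL) {
  n <- length(outcome)
  if (n == 0L) stop("a cohort must contain at least one procedure")
  if (length(risk) != n) stop("`outcome` and `risk` must have equal length")
  if (!is.numeric(outcome) && !is.logical(outcome))
    stop("`outcome` must be numeric 0/1")
  outcome <- as.numeric(outcome)
  bad <- which(!(outcome %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("outcome must be 0 or 1; offending row(s): %s",
                 paste(head(bad, 5L), collapse = ", ")))
  if (!is.numeric(risk) || anyNA(risk))
    stop("`risk` must be numeric with no missing values")
  out_of_range <- which(risk < 0 | risk > 1)
  if (length(out_of_range))
    stop(sprintf("risk must lie in [0, 1]; offending row(s): %s",
                 paste(head(out_of_range, 5L), collapse = ", ")))
  risk <- clamp_risk(risk)
  df <- data.frame(index = seq_len(n), outcome = outcome, risk = risk)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != n) stop("`meta` must have one row per procedure")
    reserved <- intersect(names(meta), names(df))
    if (length(reserved))
      stop("`meta` may not use reserved column names: ",
           paste(reserved, collapse = ", "))
    df <- cbind(df, meta)
  }
  structure(df, label = label, class = c("oe_cohort", "data.frame"))
}

# Clamp risks into the open interval; one warning summarising all clamps.
clamp_risk <- function(risk, eps = RISK_EPS) {
  clamped <- which(risk < eps | risk > 1 - eps)
  if (length(clamped)) {
    warning(sprintf(
      "%d risk value(s) clamped into [%g, %g] (row(s) %s): boundary risks are not supported by the CUSUM weights",
      length(clamped), eps, 1 - eps,
      paste(head(clamped, 5L), collapse = ", ")), call. = FALSE)
    risk <- pmin(pmax(risk, eps), 1 - eps)
  }
  risk
}

#' Read an ordered procedure stream from a CSV file
#'
#' Rows must already be in monitoring (chronological) order; the file order is
#' treated as authoritative and never re-sorted. The file must be UTF-8,
#' comma-separated, with a header row.
#'
#' @param path path to a CSV file.
#' @param outcome_col,risk_col names of the outcome and risk columns.
#' @param label cohort label; defaults to the file name.
#' @return An [cohort()] object; all non-outcome, non-risk columns are kept as
#'   metadata.
#' @export
read_cohort <- function(path, outcome_col = "outcome", risk_col = "risk",
                        label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(outcome_col, risk_col), names(df))
  if (length(missing_cols))
    stop(sprintf("column(s) not found in %s: %s", path,
                 paste(missing_cols, collapse = ", ")))
  outcome <- df[[outcome_col]]
  if (!is.numeric(outcome))
    stop(sprintf("outcome column '%s' is not numeric", outcome_col))
  risk <- df[[risk_col]]
  if (!is.numeric(risk))
    stop(sprintf("risk column '%s' is not numeric", risk_col))
  meta_cols <- setdiff(names(df), c(outcome_col, risk_col, "index"))
  meta <- if (length(meta_cols)) df[meta_cols] else NULL
  cohort(outcome, risk,
         label = if (is.null(label)) basename(path) else label,
         meta = meta)
}

#' Write a cohort to CSV
#'
#' @param x an [cohort()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "oe_cohort"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.oe_cohort <- function(x, ...) {
  cat(sprintf("<oe_cohort> '%s': %d procedures, %d events (rate %.3f), mean risk %.3f\n",
              attr(x, "label"), nrow(x), sum(x$outcome),
              mean(x$outcome), mean(x$risk)))
  NextMethod()
}

#' Write a chart result to per-procedure and sequence summary tables
#'
#' Writes one CSV row per procedure (index, outcome, risk, cumulative O-E,
#' both CUSUM subscores, signal flag and the id of the sequence covering the
#' procedure, if any), a companion sequence summary CSV
#' (`<path>_sequences.csv`), and a JSON metadata file (`<path>.json`) holding
#' the chart parameters and cohort label. O-E values round-trip through the
#' text representation to at least 1e-12.
#'
#' @param result a [build_chart()] result.
#' @param path path of the per-procedure CSV; the companion file paths are
#'   derived from it.
#' @return Named character vector of the files written, invisibly.
#' @seealso [read_result()]
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "oe_chart_result"))
  proc <- result_procedure_table(result)
  seqs <- result$sequences
  stem <- sub("\\.csv$", "", path)
  seq_path <- paste0(stem, "_sequences.csv")
  meta_path <- paste0(stem, ".json")
  # 17 significant digits: lossless decimal round-trip for doubles
  fmt <- function(df) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    df
  }
  write.csv(fmt(proc), path, row.names = FALSE, quote = FALSE)
  write.csv(fmt(seqs), seq_path, row.names = FALSE, quote = FALSE)
  meta <- list(
    label = result$label,
    params = result$params[!vapply(result$params, is.null, logical(1))],
    n_procedures = nrow(proc),
    n_sequences = nrow(seqs),
    final_oe = result$oe$values[length(result$oe$values)]
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(procedures = path, sequences = seq_path, metadata = meta_path))
}

# Per-procedure flat table for export/rendering.
result_procedure_table <- function(result) {
  n <- length(result$oe$values)
  seq_id <- rep(NA_integer_, n)
  seqs <- result$sequences
  if (nrow(seqs)) {
    for (k in seq_len(nrow(seqs)))
      seq_id[seqs$start[k]:seqs$end[k]] <- k
  }
  signal <- rep(FALSE, n)
  if (nrow(result$trajectory$signals))
    signal[result$trajectory$signals$index] <- TRUE
  data.frame(
    index = seq_len(n),
    outcome = result$cohort$outcome,
    risk = result$cohort$risk,
    oe = result$oe$values,
    x_plus = result$trajectory$x_plus,
    x_minus = result$trajectory$x_minus,
    signal = signal,
    sequence_id = seq_id
  )
}

#' Read back a written chart result
#'
#' @param path the per-procedure CSV written by [write_result()].
#' @return A list with elements `procedures`, `sequences` (data.frames) and
#'   `metadata` (list).
#' @export
read_result <- function(path) {
  stem <- sub("\\.csv$", "", path)
  list(
    procedures = read.csv(path, stringsAsFactors = FALSE),
    sequences = read.csv(paste0(stem, "_sequences.csv"),
                         stringsAsFactors = FALSE),
    metadata = jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  )
}
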