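#' Specify a synthetic procedure stream
#'
#' Defines a cohort generator with the statistical structure the monitoring
#' method assumes: each procedure carries an expected risk drawn from a
#' case-mix model, and the true event probability equals that risk except
#' inside declared shift windows, where the event odds are multiplied by a
#' factor `R` (via [shifted_rate()], the same odds-scale shift the CUSUM
#' alternative hypothesis states). The recorded risk column always holds the
#' unshifted expectation: the generator never leaks the shift to the
#' monitor.
#'
#' @param n number of procedures, >= 1.
#' @param risk case-mix model: a single probability (constant risk),
#'   `list(dist = "beta", shape1 = , shape2 = )` (beta-distributed risks;
#'   `beta(2, 8)` has mean 0.2, close to the ~19% adverse-event regime of
#'   mixed surgical populations), or `list(dist = "logitnormal", mu = ,
#'   sigma = )` (normal on the log-odds scale).
#' @param windows optional data.frame with columns `start`, `end`, `R`:
#'   non-overlapping index windows within `[1, n]` and their odds
#'   multipliers (`R > 1` injects deterioration, `R < 1` improvement).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param label cohort label.
#' @return A list of class `oe_cohort_spec`.
#' @examples
#' spec <- cohort_spec(145, risk = list(dist = "beta", shape1 = 2, shape2 = 8),
#'                     seed = 11)
#' @export
cohort_spec <- function(n, risk = list(dist = "beta", shape1 = 2, shape2 = 8),
                        windows = NULL, seed = 1, label = "synthetic") {
  if (!is.numeric(n) || n < 1) stop("`n` must be at least 1")
  n <- as.integer(n)
  if (is.numeric(risk) && length(risk) == 1L) {
    if (risk <= 0 || risk >= 1) stop("constant risk must lie in (0, 1)")
    risk <- list(dist = "constant", p = risk)
  } else if (!(is.list(risk) &&
               risk$dist %in% c("constant", "beta", "logitnormal"))) {
    stop("`risk` must be a probability or a beta/logitnormal model list")
  }
  if (!is.null(windows)) {
    windows <- as.data.frame(windows)
    if (!all(c("start", "end", "R") %in% names(windows)))
      stop("`windows` needs columns start, end, R")
    if (any(windows$start < 1 | windows$end > n |
            windows$start > windows$end))
      stop("each window must satisfy 1 <= start <= end <= n")
    if (any(windows$R <= 0)) stop("window odds multipliers must be positive")
    w <- windows[order(windows$start), ]
    if (nrow(w) > 1 && any(w$start[-1] <= w$end[-nrow(w)]))
      stop("shift windows must not overlap")
  }
  structure(list(n = n, risk = risk, windows = windows,
                 seed = as.integer(seed), label = label),
            class = "oe_cohort_spec")
}

#' Draw a synthetic cohort
#'
#' @param spec an [cohort_spec()].
#' @return An [cohort()] object of `spec$n` procedures whose `risk` column
#'   holds the monitor's expectation and whose outcomes follow the (possibly
#'   window-shifted) true probabilities.
#' @examples
#' coh <- sample_cohort(cohort_spec(100, risk = 0.1, seed = 3,
#'   windows = data.frame(start = 40, end = 80, R = 3)))
#' mean(coh$outcome)
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "oe_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  p <- switch(spec$risk$dist,
    constant = rep(spec$risk$p, n),
    beta = rbeta(n, spec$risk$shape1, spec$risk$shape2),
    logitnormal = plogis(rnorm(n, spec$risk$mu, spec$risk$sigma))
  )
  p <- clamp_quiet(p)
  true_p <- p
  if (!is.null(spec$windows)) {
    for (k in seq_len(nrow(spec$windows))) {
      w <- spec$windows[k, ]
      idx <- w$start:w$end
      true_p[idx] <- shifted_rate(p[idx], w$R)
    }
  }
  y <- rbinom(n, 1L, true_p)
  cohort(y, p, label = spec$label)
}

#' Fit a plain logistic risk model
#'
#' Maximum-likelihood logistic regression of a binary outcome on a numeric
#' covariate table, returning the in-sample predicted event probabilities —
#' the `risk` column a monitored cohort needs. This is the generic
#' risk-adjustment helper; building a clinically validated risk score
#' (variable selection, hold-out calibration) is the analyst's job.
#'
#' @param covariates data.frame or matrix of numeric predictors.
#' @param outcomes binary vector, one per row of `covariates`.
#' @return Numeric vector of predicted probabilities in (0, 1), with the
#'   fitted coefficient table in the `"coefficients"` attribute and the
#'   `glm` object in the `"model"` attribute.
#' @examples
#' x <- data.frame(age = rnorm(200))
#' y <- rbinom(200, 1, plogis(-1 + x$age))
#' p <- fit_risk_model(x, y)
#' range(p)
#' @export
fit_risk_model <- function(covariates, outcomes) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(outcomes))
    stop("`covariates` and `outcomes` must have matching length")
  if (!all(outcomes %in% c(0, 1))) stop("`outcomes` must be binary 0/1")
  df <- data.frame(.outcome = outcomes)
  if (ncol(covariates)) df <- cbind(df, covariates)
  fml <- if (ncol(covariates)) .outcome ~ . else .outcome ~ 1
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged)
    stop("logistic fit did not converge (possible separation); ",
         "inspect the design matrix")
  if (any(is.na(coef(fit))))
    stop("singular design: coefficient(s) not estimable for ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  pr <- as.numeric(fitted(fit))
  if (separated || any(pr < 1e-10 | pr > 1 - 1e-10))
    stop("degenerate fit: predicted probabilities at the boundary ",
         "(complete or quasi-complete separation)")
  attr(pr, "coefficients") <- summary(fit)$coefficients
  attr(pr, "model") <- fit
  pr
}
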