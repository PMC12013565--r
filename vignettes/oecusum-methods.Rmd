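---
title: "Monitoring binary surgical outcomes with the risk-adjusted O-E CUSUM chart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring binary surgical outcomes with the risk-adjusted O-E CUSUM chart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oecusum)
```

## The monitoring problem

A surgeon (or surgical team) performs a stream of procedures, each of which
either ends in a major adverse event ($y_i = 1$) or does not ($y_i = 0$).
Patients differ: each procedure carries its own expected event probability
$p_i \in (0,1)$, usually the prediction of a logistic risk model fitted on
historical data. Two questions arise continuously as procedures accumulate:

1. *How is performance evolving relative to expectation?* — best answered by
   an intuitive display.
2. *Is the current run of results statistically abnormal?* — best answered
   by a sequential test.

The classic answers are, respectively, the cumulative observed-minus-expected
(O-E) chart — also called the variable life-adjusted display (VLAD) — and the
risk-adjusted CUSUM. The O-E chart is readable but has no signalling rule;
the CUSUM is rigorous but its score has no clinical scale. This package
implements the combined chart: the CUSUM runs silently behind the O-E
display, and whenever it signals, the whole abnormal stretch of procedures is
shaded on the O-E chart (red for deterioration, green for improvement) and
annotated with the number of events by which the stretch deviated from
expectation.

## The O-E series

After procedure $n$ the risk-adjusted O-E value is

$$\mathrm{OE}_n = \sum_{i=1}^{n} (y_i - p_i),$$

with $\mathrm{OE}_0 \equiv 0$ before the first procedure. An unadjusted
variant replaces every $p_i$ by a fixed baseline rate $p_0$. The curve rises
by $1-p_i$ on an event and falls by $p_i$ otherwise; a final value of $+k$
reads as $k$ potentially avoidable events in excess of expectation, $-k$ as
$k$ potentially avoided events. Steps are accumulated left-to-right in
procedure order by plain sequential summation: cohorts are hundreds to a few
thousands of procedures, where reproducibility across platforms matters more
than the last ulp, and the pre-baseline zero is part of the contract because
sequence quantification references $\mathrm{OE}_{\text{start}-1}$.

## The two-sided risk-adjusted CUSUM

Each side of the CUSUM is a sequential likelihood-ratio test. The null
hypothesis says outcomes follow the expected risks (odds ratio $R_0$,
conventionally 1); the alternative says the event odds are multiplied by
$R_1$. The per-procedure log-likelihood-ratio weight (Steiner's
risk-adjusted construction) is

$$W_i = \begin{cases}
  \log\dfrac{1-p_i+R_0 p_i}{1-p_i+R_1 p_i}, & y_i = 0,\\[2ex]
  \log\dfrac{(1-p_i+R_0 p_i)\,R_1}{(1-p_i+R_1 p_i)\,R_0}, & y_i = 1.
\end{cases}$$

The deterioration subscore accumulates the weights of the
odds-increase test ($R_1 > R_0$, e.g. 2 for "event odds doubled"):
$X_i^+ = \max(0, X_{i-1}^+ + W_i^+)$, signalling when $X^+ \ge h^+$. The
improvement side tests an odds *decrease* ($R_1 < R_0$, default $1/R_1$,
e.g. odds halved) and is displayed below the axis:
$X_i^- = \min(X_{i-1}^- - W_i^-, 0)$, signalling when $X^- \le -h^-$.

A point worth stating explicitly, because compact textbook notation often
hides it: the two recursions *must* consume different weight series. If the
same series drove both, the substitution $S = -X^-$ shows the improvement
recursion is identically the mirror of the deterioration one and could only
ever "signal improvement" during runs of adverse events. The package
therefore builds one weight series per side from that side's own alternative
hypothesis; `run_two_sided()` still accepts a single series (the literal
compact form) for completeness.

With constant risk $p$ and $R_0 = 1$, the Steiner weights reduce exactly to
the fixed-rate CUSUM with $\theta_0 = p$ and
$\theta_1 = R_1 p / (1 - p + R_1 p)$ — the odds-scale shift implemented by
`shifted_rate()`. This identity is the bridge between the risk-adjusted and
unadjusted parameterisations and is enforced by test to $10^{-12}$.

### Signal, reset, and threshold convention

The signal threshold is inclusive ($X \ge h$), the common CUSUM convention;
a boundary test pins this down. After a signal, the signalling side's
subscore is reset to 0 before the next procedure so monitoring continues;
resetting both sides is available (`reset_policy = "both-sides"`) but the
default resets only the triggering side, which preserves the information
accumulated by the opposite side. If both thresholds are crossed at the same
procedure (possible after independent resets), both signals are recorded,
deterioration first. No head-start value is applied after a reset.

## Sequences and event counts

For a signal at procedure $s$, the monitoring sequence runs from $z+1$ to
$s$ inclusive, where $z$ is the last procedure before $s$ at which that
side's subscore sat at zero — a reset counts as a zero, so back-to-back
same-side sequences begin immediately after the previous signal, and $z = 0$
(sequence starts at procedure 1) when the subscore never touched zero. The
sequence's clinical weight is the O-E change across it,

$$\Delta_{\mathrm{OE}} = \mathrm{OE}_{\text{end}} - \mathrm{OE}_{\text{start}-1},$$

reported exactly and rounded to one decimal for display. Deltas telescope:
adjacent same-side sequences sum to the O-E change over their union. Under
risk adjustment a deterioration sequence's delta can in principle come out
slightly negative (weights and O-E steps are different functionals of
$(y_i, p_i)$); such sequences are kept and flagged (`sign_anomaly`) rather
than suppressed, since suppressing them would break the signal–sequence
bijection.

## Choosing control limits: average run lengths

The control limit $h$ trades false alarms against detection speed, priced in
average run lengths: ARL$_0$, the mean number of procedures to a false
signal under the null, and ARL$_1$, the mean number to a true signal under
the alternative. The package offers two estimators:

- **Monte-Carlo** (`simulate_arl()`): simulates full monitoring runs with
  risks drawn from the stated case-mix (constant, beta, an empirical risk
  pool, or any sampler), outcomes at the null or shifted rate, and reports
  the mean stopping time with its standard error. Replicates that reach the
  horizon unsignalled are scored at the horizon — a downward bias that is
  conservative for false-alarm control — and their fraction is always
  reported, with a warning above 5%. All draws derive from one root seed via
  deterministic per-step substreams, so estimates are exactly reproducible
  and the engine can be vectorised across replicates.
- **Markov chain** (`markov_arl()`): the Brook–Evans finite-state
  approximation for homogeneous risk. The state lattice is aligned with the
  non-event weight (the small step taken at almost every procedure), so
  those steps move an exact number of bins, and the event step's probability
  mass is split linearly between the two adjacent bins. This first-order
  interpolation suppresses the grid-rounding bias of the plain nearest-bin
  construction, which we found to exceed Monte-Carlo error at large
  ARL (order $10^3$) designs. The default nominal resolution of 500 bins is
  refined by one doubling and the relative change is reported as
  `convergence_gap`.

`find_control_limit()` inverts the Monte-Carlo estimator: it brackets the
target ARL$_0$ by doubling $h$, then bisects, stopping when the bracket is
narrower than 0.01 or the estimate is within 2% of target, and returns the
smallest examined $h$ meeting the target (never more false alarms than asked
for). No default ARL$_0$ target ships with the package: the target is a
governance choice, not a statistical constant. The calibration examples in
this package use the study configuration "detect odds doubled, improvement
side odds halved" with an illustrative target of 500 procedures.

The improvement side is calibrated by the same machinery: its hypotheses
have $R_1 < R_0$, its reflected subscore is the plain positive CUSUM of its
own weights, and its limit applies to $-X^-$.

## The synthetic cohort generator

Because real procedure streams are confidential, every statistical property
of the package is exercised on synthetic cohorts (`cohort_spec()` /
`sample_cohort()`). The generator emulates exactly the structure the method
assumes: expected risks $p_i$ drawn from a case-mix model, and outcomes
drawn Bernoulli with probability $p_i$ — except inside declared windows,
where the true probability is `shifted_rate(p_i, R)` while the *recorded*
risk column remains $p_i$. Shifts act on the odds scale precisely because
that is the alternative hypothesis the CUSUM is calibrated for; recovery
tests therefore probe the detector on its own terms. The default demo
case-mix is beta(2, 8) (mean risk 0.20, matching the ~19% adverse-event
regime of mixed surgical populations) over 145 procedures, a realistic
14-month single-surgeon volume.

What the generator does *not* emulate: serial correlation between
procedures, drift in the case-mix over time, risk-model miscalibration
(recorded risks are exactly the generating risks outside windows), and
outcome misclassification. Passing tests therefore demonstrate correctness
of the monitoring machinery under the model's own assumptions, not
robustness of the method to violated risk adjustment — on real data the
quality of the risk model is the binding constraint, and a miscalibrated
model shifts both charts in ways no control limit can repair.

`fit_risk_model()` is a deliberately plain maximum-likelihood logistic
helper for producing a risk column from covariates; building a clinically
credible risk score (variable selection, hold-out calibration,
specialty-specific models) is out of scope.

## Numerical and design choices

- **Risk clamping.** Risks are clamped to $[10^{-6}, 1-10^{-6}]$ on entry,
  with a warning naming the rows, because the Steiner weights contain log
  terms undefined at 0 and 1.
- **Indexing.** Procedures are numbered from 1 in file order; the package
  never re-sorts. Chronological correctness is the caller's responsibility.
- **Exactness.** O-E arithmetic is tested to $10^{-12}$ against direct
  summation; the engine is tested for exact equality against an
  independently coded scalar recursion, including signal indices and reset
  bookkeeping.
- **Problem sizes.** The shipped statistical checks use 1,000 random
  cohorts of $n = 1000$ for O-E exactness, 10,000 random weight series of
  length 200 for engine equivalence, Monte-Carlo ARLs at 10,000–20,000
  replicates, a 3 × 3 homogeneous grid for cross-method agreement, and 500
  paired replicates ($n = 300$, OR = 3 over procedures 100–200, limits
  $h = 3$ chosen from the matched Markov ARL) for shift recovery. These
  sizes make Monte-Carlo error small relative to the tolerances tested.
- **Rendering.** SVG (cairo) is the canonical figure format: it is text,
  deterministic byte-for-byte for fixed input, and the shaded sequence
  bands are assertable by parsing. The CUSUM subscores can be displayed as
  a secondary panel (`show_cusum = TRUE`) for users who distrust an
  invisible signalling rule.

## Known limitations

- ARL calibration for heterogeneous case-mix is Monte-Carlo only; the
  Markov approximation applies to homogeneous risk.
- Steady-state ARLs, FIR head-starts, integral-equation solvers, EWMA/SPRT
  variants and O-E control-limit bands are out of scope.
- The sequence definition attributes the whole stretch since the last zero
  to the signal; it is a readable convention, not a changepoint estimate,
  and tends to start slightly before the true onset of a shift.
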