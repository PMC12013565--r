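Package: oecusum
Title: Risk-Adjusted Observed-Minus-Expected CUSUM Charts for Monitoring
    Binary Clinical Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prospective monitoring of binary clinical outcomes (for example
    surgical complications) with a combined risk-adjusted observed-minus-expected
    (O-E, also known as VLAD) chart and a two-sided risk-adjusted CUSUM.
    Computes cumulative O-E trajectories, Steiner-weighted CUSUM subscores with
    signal detection and reset, calibrates control limits from average-run-length
    targets by Monte-Carlo simulation or a Brook-Evans Markov-chain
    approximation, maps CUSUM signals back onto the O-E chart as shaded
    improvement/deterioration sequences, and quantifies potentially avoided or
    avoidable events per sequence. Includes a synthetic-cohort generator with
    heterogeneous preoperative risks and odds-scale performance shifts, chart
    rendering to SVG/PNG, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    optparse,
    rlang,
    stats,
    utils
Suggests:
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
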