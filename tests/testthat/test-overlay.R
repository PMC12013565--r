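test_that("sequence bounds run from after the last zero to the signal, inclusive", {
  # x_plus: 0, 0, 0.5, 1.1 -> signal at 4, last zero at 2
  tr <- run_two_sided(c(-0.2, -0.2, 0.5, 0.6), h_plus = 1, h_minus = 100)
  expect_equal(tr$x_plus, c(0, 0, 0.5, 1.1))
  seqs <- detect_sequences(tr)
  expect_equal(seqs$start, 3L)
  expect_equal(seqs$end, 4L)
  expect_equal(seqs$side, "deterioration")
})

test_that("a signal at the first procedure yields the one-procedure sequence 1-1", {
  tr <- run_two_sided(c(1.5, -0.1), h_plus = 1, h_minus = 100)
  seqs <- detect_sequences(tr)
  expect_equal(seqs$start, 1L)
  expect_equal(seqs$end, 1L)
})

test_that("an improvement signal with its last zero at 15 spans procedures 16-33", {
  # improvement side held at zero for 15 procedures, then a steady run of
  # better-than-expected outcomes until the subscore crosses -h at 33
  w_minus <- c(rep(-1, 15), rep(0.2, 25))
  tr <- run_two_sided(rep(-0.1, 40), h_plus = 100, h_minus = 3.5,
                      weights_minus = w_minus)
  seqs <- detect_sequences(tr)
  expect_equal(seqs$side[1], "improvement")
  expect_equal(seqs$start[1], 16L)
  expect_equal(seqs$end[1], 33L)
})

test_that("a sequence after a same-side signal starts right after the reset", {
  # two consecutive improvement runs: signal, reset, signal again
  w_minus <- rep(0.5, 10)
  tr <- run_two_sided(rep(-0.1, 10), h_plus = 100, h_minus = 2,
                      weights_minus = w_minus)
  seqs <- detect_sequences(tr)
  expect_equal(seqs$start, c(1L, 5L))
  expect_equal(seqs$end, c(4L, 8L))
})

test_that("sequence deltas are plain O-E differences with the baseline convention", {
  oe <- oecusum:::new_oe_series(c(-0.1, -0.2, 0.5, 1.3), "adjusted")
  expect_equal(quantify_sequence(oe, 3, 4), 1.3 - (-0.2))
  expect_equal(quantify_sequence(oe, 1, 4), 1.3)   # full span = final value
  expect_equal(quantify_sequence(oe, 2, 2), -0.1)
  expect_error(quantify_sequence(oe, 3, 5), "bounds")
  expect_error(quantify_sequence(oe, 0, 2), "bounds")
})

test_that("build_chart matches a brute-force recomputation on random cohorts", {
  for (seed in 1:60) {
    coh <- random_cohort(50, seed = 6000 + seed)
    params <- chart_params(h_plus = 1.2, h_minus = 1.2)
    res <- build_chart(coh, params)
    # oracle: independent weights, scalar recursion, backward zero scan
    p <- coh$risk; y <- coh$outcome
    wp <- ifelse(y == 1, log(2 / (1 + p)), log(1 / (1 + p)))
    wm <- ifelse(y == 1, log(0.5 / (1 - 0.5 * p)), log(1 / (1 - 0.5 * p)))
    orc <- oracle_two_sided(wp, 1.2, 1.2, w_minus = wm)
    expect_equal(res$trajectory$x_plus, orc$x_plus, tolerance = 1e-12)
    expect_equal(res$trajectory$x_minus, orc$x_minus, tolerance = 1e-12)
    oseq <- oracle_sequences(orc)
    expect_equal(nrow(res$sequences), nrow(oseq))
    if (nrow(oseq)) {
      expect_equal(res$sequences$start, as.integer(oseq$start))
      expect_equal(res$sequences$end, as.integer(oseq$end))
      expect_equal(res$sequences$side, oseq$side)
      # each delta equals the direct sum of O-E steps over the interval
      for (k in seq_len(nrow(oseq))) {
        idx <- oseq$start[k]:oseq$end[k]
        expect_equal(res$sequences$delta_oe[k], sum(y[idx] - p[idx]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("every signal maps to one sequence; same-side sequences never overlap", {
  for (seed in 1:40) {
    coh <- random_cohort(150, seed = 7000 + seed)
    res <- build_chart(coh, chart_params(h_plus = 1.5, h_minus = 1.5))
    expect_equal(nrow(res$sequences), nrow(res$trajectory$signals))
    for (side in c("deterioration", "improvement")) {
      s <- res$sequences[res$sequences$side == side, ]
      if (nrow(s) > 1) {
        s <- s[order(s$start), ]
        expect_true(all(s$start[-1] > s$end[-nrow(s)]))
      }
    }
  }
})

test_that("deltas telescope: adjacent same-side sequences sum to the span's O-E change", {
  w_minus <- rep(0.5, 12)
  coh <- cohort(rep(0, 12), rep(0.3, 12))
  tr <- run_two_sided(rep(-0.1, 12), h_plus = 100, h_minus = 2,
                      weights_minus = w_minus)
  oe <- oe_adjusted(coh)
  seqs <- detect_sequences(tr)
  expect_gte(nrow(seqs), 2)
  expect_true(all(diff(seqs$end) > 0))
  total <- sum(vapply(seq_len(nrow(seqs)), function(k)
    quantify_sequence(oe, seqs$start[k], seqs$end[k]), numeric(1)))
  expect_equal(total,
               quantify_sequence(oe, seqs$start[1], seqs$end[nrow(seqs)]),
               tolerance = 1e-12)
})

test_that("an injected deterioration window is flagged more often than in-control noise", {
  n_rep <- 80
  hits_shifted <- 0
  hits_control <- 0
  for (r in seq_len(n_rep)) {
    spec_shift <- cohort_spec(150, risk = list(dist = "beta", shape1 = 2,
                                               shape2 = 8),
                              windows = data.frame(start = 50, end = 110,
                                                   R = 3),
                              seed = 5000 + r)
    spec_ctrl <- cohort_spec(150, risk = list(dist = "beta", shape1 = 2,
                                              shape2 = 8),
                             seed = 5000 + r)
    params <- chart_params(h_plus = 3, h_minus = 3)
    rs <- build_chart(sample_cohort(spec_shift), params)$sequences
    rc <- build_chart(sample_cohort(spec_ctrl), params)$sequences
    det_s <- rs[rs$side == "deterioration", ]
    if (nrow(det_s) && any(det_s$start <= 110 & det_s$end >= 50))
      hits_shifted <- hits_shifted + 1
    if (any(rc$side == "deterioration"))
      hits_control <- hits_control + 1
  }
  expect_gt(hits_shifted / n_rep, hits_control / n_rep)
})
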