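# Independent brute-force references, written as plain step-by-step state
# machines so they share no code path with the package's engine.

# Two-sided CUSUM with signal/reset, one explicit state update per step.
oracle_two_sided <- function(w_plus, h_plus, h_minus, w_minus = w_plus,
                             both_sides = FALSE) {
  n <- length(w_plus)
  up_state <- 0
  dn_state <- 0
  x_plus <- numeric(n)
  x_minus <- numeric(n)
  signals <- list()
  resets <- list()
  i <- 1
  while (i <= n) {
    cand_up <- up_state + w_plus[i]
    if (cand_up < 0) cand_up <- 0
    cand_dn <- dn_state - w_minus[i]
    if (cand_dn > 0) cand_dn <- 0
    x_plus[i] <- cand_up
    x_minus[i] <- cand_dn
    up_state <- cand_up
    dn_state <- cand_dn
    sig_up <- cand_up >= h_plus
    sig_dn <- cand_dn <= -h_minus
    if (sig_up) signals[[length(signals) + 1]] <- list(i, "deterioration")
    if (sig_dn) signals[[length(signals) + 1]] <- list(i, "improvement")
    if (sig_up || sig_dn) {
      if (sig_up || both_sides) {
        up_state <- 0
        resets[[length(resets) + 1]] <- list(i, "deterioration")
      }
      if (sig_dn || both_sides) {
        dn_state <- 0
        resets[[length(resets) + 1]] <- list(i, "improvement")
      }
    }
    i <- i + 1
  }
  to_df <- function(lst) {
    if (!length(lst))
      return(data.frame(index = integer(0), side = character(0),
                        stringsAsFactors = FALSE))
    data.frame(index = vapply(lst, function(e) e[[1]], numeric(1)),
               side = vapply(lst, function(e) e[[2]], character(1)),
               stringsAsFactors = FALSE)
  }
  list(x_plus = x_plus, x_minus = x_minus, signals = to_df(signals),
       resets = to_df(resets))
}

# Sequence bounds from an oracle trajectory: scan backwards for the last
# index at which the side's subscore was zero (resets count as zero).
oracle_sequences <- function(orc) {
  if (!nrow(orc$signals))
    return(data.frame(side = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  rows <- list()
  for (k in seq_len(nrow(orc$signals))) {
    s <- orc$signals$index[k]
    side <- orc$signals$side[k]
    x <- if (side == "deterioration") orc$x_plus else orc$x_minus
    reset_at <- orc$resets$index[orc$resets$side == side]
    z <- 0
    j <- s - 1
    while (j >= 1) {
      val <- if (j %in% reset_at) 0 else x[j]
      if (val == 0) { z <- j; break }
      j <- j - 1
    }
    rows[[k]] <- data.frame(side = side, start = z + 1, end = s,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res[order(res$end, res$side != "deterioration"), , drop = FALSE]
}

random_cohort <- function(n, seed) {
  set.seed(seed)
  p <- rbeta(n, 2, 8)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  cohort(rbinom(n, 1, p), p, label = paste0("rand", seed))
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
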