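# Independent brute-force oracles, coded with plain loops so they share no
# machinery with the implementation they check.

# Differences only at fixed grid intervals: for each pair of adjacent
# states on the study grid, a subject contributes a delta iff it observed
# both of them.
oracle_first_differences <- function(panel) {
  grid <- sort(unique(panel$state))
  out <- NULL
  for (s in unique(panel$subject)) {
    rows <- panel[panel$subject == s, , drop = FALSE]
    for (j in 2:length(grid)) {
      cur <- rows[rows$state == grid[j], , drop = FALSE]
      prev <- rows[rows$state == grid[j - 1], , drop = FALSE]
      if (nrow(cur) == 1 && nrow(prev) == 1) {
        out <- rbind(out, data.frame(
          sample_id = cur$id, subject = s, state = cur$state,
          value = cur$value - prev$value, stringsAsFactors = FALSE))
      }
    }
  }
  out
}

oracle_first_distances <- function(panel, dm) {
  panel <- panel[panel$id %in% rownames(dm), , drop = FALSE]
  grid <- sort(unique(panel$state))
  out <- NULL
  for (s in unique(panel$subject)) {
    rows <- panel[panel$subject == s, , drop = FALSE]
    for (j in 2:length(grid)) {
      cur <- rows[rows$state == grid[j], , drop = FALSE]
      prev <- rows[rows$state == grid[j - 1], , drop = FALSE]
      if (nrow(cur) == 1 && nrow(prev) == 1) {
        out <- rbind(out, data.frame(
          sample_id = cur$id, subject = s, state = cur$state,
          value = dm[cur$id, prev$id], stringsAsFactors = FALSE))
      }
    }
  }
  out
}

oracle_from_baseline <- function(panel, baseline, dm = NULL) {
  out <- NULL
  for (s in unique(panel$subject)) {
    rows <- panel[panel$subject == s, , drop = FALSE]
    if (!is.null(dm)) rows <- rows[rows$id %in% rownames(dm), , drop = FALSE]
    rows <- rows[order(rows$state), , drop = FALSE]
    base <- rows[rows$state == baseline, , drop = FALSE]
    if (!nrow(base)) next
    for (i in seq_len(nrow(rows))) {
      if (rows$state[i] == baseline) next
      val <- if (is.null(dm)) rows$value[i] - base$value[1]
             else dm[rows$id[i], base$id[1]]
      out <- rbind(out, data.frame(
        sample_id = rows$id[i], subject = s, state = rows$state[i],
        value = val, stringsAsFactors = FALSE))
    }
  }
  out
}

oracle_static_reference <- function(panel, refs, dm) {
  out <- NULL
  for (s in unique(panel$subject)) {
    rows <- panel[panel$subject == s, , drop = FALSE]
    ref <- refs[[s]]
    if (is.null(ref) || is.na(ref) || !ref %in% rownames(dm)) next
    rows <- rows[rows$id %in% rownames(dm), , drop = FALSE]
    rows <- rows[order(rows$state), , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      out <- rbind(out, data.frame(
        sample_id = rows$id[i], subject = s, state = rows$state[i],
        value = dm[rows$id[i], ref], stringsAsFactors = FALSE))
    }
  }
  out
}

# Per-feature descriptive statistics by explicit loops.
oracle_descriptive_stats <- function(values, states) {
  st <- sort(unique(states))
  out <- NULL
  for (f in colnames(values)) {
    v <- values[, f]
    prof <- sapply(st, function(t) mean(v[states == t]))
    inc <- 0; dec <- 0
    if (length(st) > 1) {
      for (j in 1:(length(st) - 1)) {
        d <- prof[j + 1] - prof[j]
        if (d > 0) inc <- inc + d else dec <- dec + d
      }
    }
    mu <- mean(v); sdv <- sd(v)
    out <- rbind(out, data.frame(
      feature = f, mean = mu, median = median(v), variance = sdv^2, sd = sdv,
      cv = if (mu == 0) NA_real_ else sdv / mu,
      net_avg_change = if (length(st) > 1) prof[length(st)] - prof[1] else 0,
      cumulative_avg_increase = inc, cumulative_avg_decrease = dec,
      stringsAsFactors = FALSE))
  }
  out
}

# Normal-approximation Wilcoxon signed-rank with tie correction and
# continuity correction, coded from the textbook formulas.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
  2 * pnorm(-abs(z))
}

sort_series <- function(df) {
  df <- as.data.frame(df)[, c("sample_id", "subject", "state", "value")]
  df <- df[order(df$subject, df$state), , drop = FALSE]
  rownames(df) <- NULL
  df
}
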