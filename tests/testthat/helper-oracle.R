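# Independent oracles, coded from the definitions rather than via the
# package's code paths or stats::cor.

# Brute-force Pearson of the two lag-tau windows before timestep t
# (zero-based), windows extracted by direct index arithmetic.
oracle_two_period <- function(x, tau, t, zero_rule = "match") {
  a <- x[seq(t - tau, t - 1) + 1]
  b <- x[seq(t - 2 * tau, t - tau - 1) + 1]
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  sa2 <- sum((a - ma)^2)
  sb2 <- sum((b - mb)^2)
  if (sa2 == 0 || sb2 == 0) {
    if (zero_rule == "match") as.numeric(all(a == b)) else 0
  } else {
    sum((a - ma) * (b - mb)) / sqrt(sa2 * sb2)
  }
}

random_train <- function(len, p = 0.4) {
  pulse_train(as.integer(stats::runif(len) < p))
}

# A pattern with latency-coded attributes on a fixed codec, for round-trip
# checks: onsets on a period-long grid so the codec footprint always fits.
random_coded_pattern <- function(n_events, codec, period = 20L) {
  onset_ts <- 5L + (seq_len(n_events) - 1L) * period
  attrs <- lapply(seq_len(nrow(codec$slots)), function(j) {
    sample.int(codec$slots$n[j], n_events, replace = TRUE) - 1L
  })
  names(attrs) <- codec$slots$name
  event_pattern(times = onset_ts * codec$dt,
                attributes = as.data.frame(attrs),
                duration = (max(onset_ts) + period) * codec$dt,
                label = "random coded")
}
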