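test_that("a delay loop's prediction is the input tau timesteps back", {
  x <- c(1L, 0L, 0L, 1L)
  expect_equal(lagged_value(x, tau = 1, t = 1), 1L)
  expect_equal(lagged_value(x, tau = 3, t = 3), 1L)
  expect_equal(lagged_value(x, tau = 2, t = 2), 1L)  # tau = t reads X(0)
  expect_error(lagged_value(x, tau = 3, t = 2),
               class = "timingnets_loop_unpopulated")
})

test_that("the lag contract holds exhaustively on random trains", {
  set.seed(5)
  for (rep_i in 1:10) {
    tr <- random_train(40)
    for (tau in c(1L, 3L, 7L)) {
      for (t in seq(tau, 39L)) {
        expect_identical(lagged_value(tr, tau, t), tr$x[t - tau + 1L])
      }
    }
  }
})

test_that("two_period_correlation matches the Pearson formula and conventions", {
  cfg <- rtn_config(tau_max = 8)
  # identical windows
  x <- rep(c(1L, 0L, 1L, 0L), 2)
  cc <- two_period_correlation(x, tau = 4, t = 8, cfg)
  expect_equal(cc$corr_raw, 1)
  expect_equal(cc$corr_eff, 1)
  # perfect anticorrelation, rectified away
  x <- c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L)   # B = 0,0,1,1 then A = 1,1,0,0
  cc <- two_period_correlation(x, tau = 4, t = 8, cfg)
  expect_equal(cc$corr_raw, -1)
  expect_equal(cc$corr_eff, 0)
  # hand-evaluated zero correlation: A = 1,1,0,0 vs B = 1,0,1,0
  x <- c(1L, 0L, 1L, 0L, 1L, 1L, 0L, 0L)
  cc <- two_period_correlation(x, tau = 4, t = 8, cfg)
  expect_equal(cc$corr_raw, 0)
  # zero-variance: silence matching silence counts as full correlation
  x <- integer(8)
  expect_equal(two_period_correlation(x, 4, 8, cfg)$corr_eff, 1)
  expect_equal(two_period_correlation(x, 4, 8,
                 rtn_config(tau_max = 8, zero_variance_rule = "zero"))$corr_eff, 0)
  # constant-vs-nonconstant windows resolve to 0 under "match"
  x <- c(1L, 0L, 0L, 0L)
  expect_equal(two_period_correlation(x, 2, 4, cfg)$corr_raw, 0)
  expect_error(two_period_correlation(integer(8), 4, 7, cfg),
               class = "timingnets_loop_inactive")
})

test_that("loop correlations equal the independent brute-force oracle", {
  set.seed(23)
  cfg <- rtn_config(tau_max = 12)
  for (rep_i in 1:25) {
    tr <- random_train(sample(30:60, 1), p = stats::runif(1, 0.2, 0.7))
    for (tau in cfg$taus) {
      ts <- seq(2L * tau, length(tr$x))
      for (t in ts[seq(1, length(ts), by = 3)]) {
        got <- two_period_correlation(tr, tau, t, cfg)$corr_raw
        expect_equal(got, oracle_two_period(tr$x, tau, t), tolerance = 1e-12)
      }
    }
  }
})

test_that("loop weight scales with delay under proportional weighting", {
  prop <- rtn_config(tau_max = 16)
  unif <- rtn_config(tau_max = 16, weighting = "uniform")
  expect_equal(loop_weight(1.0, 4, prop), 4.0)
  expect_equal(loop_weight(0.5, 10, prop), 5.0)
  expect_equal(loop_weight(0.7, 13, unif), 0.7)
})

test_that("network_step compares weighted vote sums winner-take-all", {
  cfg <- rtn_config(taus = 2L)
  # single active loop: periodic 1,0 history, loop tau = 2 predicts the pulse
  x <- c(1L, 0L, 1L, 0L, 1L)
  st <- network_step(x, t = 4, cfg)
  expect_equal(st$S1, 2)
  expect_equal(st$S0, 0)
  expect_equal(st$y_hat, 1L)
  expect_equal(st$error_raw, 0)

  # all loops inactive: tie, predict silence
  st0 <- network_step(c(1L, 1L), t = 0, cfg)
  expect_equal(st0$S0, 0)
  expect_equal(st0$S1, 0)
  expect_equal(st0$y_hat, 0L)

  # wrong call: error is the vote margin
  x <- c(1L, 0L, 1L, 0L, 0L)   # loop tau=2 predicts 1 at t=4 but X(4)=0
  st <- network_step(x, t = 4, cfg)
  expect_equal(st$y_hat, 1L)
  expect_equal(st$error_raw, st$S1 - st$S0)
  expect_gt(st$error_raw, 0)
})

test_that("rtn_run is deterministic and reproduces network_step rowwise", {
  set.seed(31)
  tr <- random_train(40)
  cfg <- rtn_config(tau_max = 10)
  trace1 <- rtn_run(tr, cfg)
  trace2 <- rtn_run(tr, cfg)
  expect_identical(trace1, trace2)
  for (t in c(0L, 7L, 20L, 39L)) {
    st <- network_step(tr, t, cfg)
    row <- trace1[trace1$t == t, ]
    expect_equal(row$y_hat, st$y_hat)
    expect_equal(row$S0, st$S0)
    expect_equal(row$S1, st$S1)
    expect_equal(row$error_raw, st$error_raw)
  }
  expect_error(rtn_run(pulse_train(integer(0)), cfg))
})

test_that("errors vanish exactly on correct predictions; error_norm peaks at 1", {
  set.seed(37)
  for (rep_i in 1:8) {
    trace <- rtn_run(random_train(50), rtn_config(tau_max = 8))
    agree <- trace$y_hat == trace$x
    expect_true(all(trace$error_raw[agree] == 0))
    expect_true(all(trace$error_raw[!agree] ==
                      abs(trace$S1 - trace$S0)[!agree]))
    expect_true(all(trace$error_norm >= 0 & trace$error_norm <= 1))
    if (any(trace$error_raw > 0)) expect_equal(max(trace$error_norm), 1)
  }
})

test_that("silence is a fixed point: all-zero input yields no errors", {
  trace <- rtn_run(pulse_train(integer(50)), rtn_config(tau_max = 12))
  expect_true(all(trace$y_hat == 0L))
  expect_true(all(trace$error_raw == 0))
  expect_true(all(trace$error_norm == 0))
})

test_that("loops at multiples of the pattern period carry full correlation", {
  set.seed(41)
  for (p in c(3L, 5L, 8L)) {
    base <- random_primitive_cycle(p)
    x <- rep(base, 6)
    cfg <- rtn_config(tau_max = 2L * p)
    t <- length(x)
    spec <- loop_spectrum(x, t, cfg)
    on_period <- spec$active & spec$tau %% p == 0L
    expect_equal(spec$corr_eff[on_period], rep(1, sum(on_period)),
                 tolerance = 1e-12)
  }
})

test_that("loop_spectrum profiles periodicity across the delay axis", {
  base <- c(1L, 0L, 0L, 1L, 0L)          # primitive period 5
  x <- rep(base, 5)
  cfg <- rtn_config(tau_max = 10)
  spec <- loop_spectrum(x, t = 25, cfg)
  expect_equal(spec$corr_eff[spec$tau == 5], 1)
  expect_equal(spec$corr_eff[spec$tau == 10], 1)
  # delays above the period and coprime with it see less than full
  # correlation: their windows span a whole cycle, shifted off-phase
  # (shorter off-period windows can still coincide by accident)
  coprime <- spec$active & spec$tau > 5L & spec$tau != 10L
  expect_true(all(spec$corr_eff[coprime] < 1 - 1e-9))
  # constant input: every active loop fully correlated under "match"
  spec1 <- loop_spectrum(rep(1L, 30), t = 30, cfg)
  expect_true(all(spec1$corr_eff[spec1$active] == 1))
  # inactive loops are flagged and weightless
  spec2 <- loop_spectrum(x, t = 5, cfg)
  expect_true(all(!spec2$active[spec2$tau > 2]))
  expect_true(all(spec2$weight[!spec2$active] == 0))
})

test_that("config validation rejects malformed delay sets", {
  expect_error(rtn_config(taus = c(1L, 1L, 2L)),
               class = "timingnets_invalid_argument")
  expect_error(rtn_config(taus = 0L), class = "timingnets_invalid_argument")
  expect_error(rtn_config(), class = "timingnets_invalid_argument")
  expect_equal(rtn_config(tau_max = 5)$taus, 1:5)
})
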