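# The recurrent timing net: an array of delay loops with delays tau, each
# holding a circulating copy of the recent input. Loop i's prediction of
# X(t) is the value arriving back from its loop, Y_i(t) = X(t - tau_i); its
# current credibility is the Pearson correlation between the input's last
# two lag-tau windows. Weighted loop votes are compared winner-take-all to
# produce the network expectancy, and the margin |S1 - S0| on a wrong call
# is the prediction error.

#' Timing-net configuration
#'
#' @param taus Integer vector of loop delays in timesteps (>= 1, distinct).
#'   A practical default is all integers 1..tau_max with tau_max at least
#'   twice the longest repetition period under study, so that both the
#'   period and its first subharmonic have a loop.
#' @param tau_max Shorthand for `taus = 1:tau_max`.
#' @param weighting `"proportional_to_tau"` (default): a loop's vote is its
#'   effective correlation times its delay, so longer agreeing windows
#'   carry more evidence; `"uniform"`: correlation only.
#' @param rectify_negative Clip negative correlations to 0 before weighting
#'   (default `TRUE`): an anti-correlated loop abstains rather than casting
#'   an inverted vote.
#' @param zero_variance_rule How to resolve the Pearson correlation when a
#'   window is constant: `"match"` (default) scores 1 if the two windows
#'   are identical and 0 otherwise, so sustained silence is itself an
#'   expected pattern; `"zero"` always scores 0.
#' @param tie_break `"predict_zero"`: on a tied vote the network predicts
#'   silence.
#' @param seed Optional integer recorded for provenance; the update itself
#'   is deterministic.
#' @return An object of class `rtn_config`.
#' @export
rtn_config <- function(taus = NULL, tau_max = NULL,
                       weighting = c("proportional_to_tau", "uniform"),
                       rectify_negative = TRUE,
                       zero_variance_rule = c("match", "zero"),
                       tie_break = "predict_zero",
                       seed = NULL) {
  weighting <- match.arg(weighting)
  zero_variance_rule <- match.arg(zero_variance_rule)
  tie_break <- match.arg(tie_break, "predict_zero")
  if (is.null(taus)) {
    if (is.null(tau_max)) {
      stop_tn("invalid_argument", "provide either `taus` or `tau_max`")
    }
    taus <- seq_len(check_count(tau_max, "tau_max"))
  }
  taus <- as.integer(taus)
  if (length(taus) == 0L || any(is.na(taus)) || any(taus < 1L)) {
    stop_tn("invalid_argument", "loop delays must be integers >= 1")
  }
  if (anyDuplicated(taus)) {
    stop_tn("invalid_argument", "loop delays must be distinct")
  }
  structure(list(taus = sort(taus), weighting = weighting,
                 rectify_negative = isTRUE(rectify_negative),
                 zero_variance_rule = zero_variance_rule,
                 tie_break = tie_break,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "rtn_config")
}

#' @export
print.rtn_config <- function(x, ...) {
  cat(sprintf(paste0("<rtn_config> %d loops (tau %d..%d), weighting %s,",
                     " rectify %s, zero-variance '%s'\n"),
              length(x$taus), min(x$taus), max(x$taus), x$weighting,
              x$rectify_negative, x$zero_variance_rule))
  invisible(x)
}

#' Circulating loop value
#'
#' The value arriving back from a delay loop at timestep `t`:
#' Y(t) = X(t - tau), the loop's prediction of X(t). Defined once the loop
#' is populated (t >= tau); earlier timesteps signal a
#' `timingnets_loop_unpopulated` condition so the caller can treat the loop
#' as inactive.
#'
#' @param history Input history as a [pulse_train()] or 0/1 vector; only
#'   X(0..t-1) is consulted.
#' @param tau Loop delay in timesteps.
#' @param t Zero-based timestep being predicted.
#' @return 0 or 1.
#' @export
lagged_value <- function(history, tau, t) {
  x <- as_pulse_vector(history)
  tau <- check_count(tau, "tau")
  t <- check_count(t, "t", min = 0L)
  if (t < tau) {
    stop_tn("loop_unpopulated", "loop tau = %d is unpopulated at t = %d", tau, t)
  }
  x[t - tau + 1L]
}

#' Two-period loop correlation
#'
#' Pearson correlation between the input's last two lag-tau windows before
#' timestep `t`: A = X(t-tau .. t-1) versus B = X(t-2*tau .. t-tau-1), the
#' loop's running evidence that the input repeats with period tau. Both
#' windows end before `t`, so the prediction at `t` never uses X(t).
#' Requires t >= 2*tau (both windows available); otherwise signals a
#' `timingnets_loop_inactive` condition.
#'
#' Constant windows have no defined Pearson correlation; they are resolved
#' by `config$zero_variance_rule` (see [rtn_config()]). `corr_eff` is
#' `corr_raw` clipped to \[0, 1\] when `config$rectify_negative` is on.
#'
#' @inheritParams lagged_value
#' @param config An [rtn_config()].
#' @return List with `corr_raw` and `corr_eff`.
#' @export
two_period_correlation <- function(history, tau, t, config = rtn_config(taus = tau)) {
  x <- as_pulse_vector(history)
  tau <- check_count(tau, "tau")
  t <- check_count(t, "t", min = 0L)
  if (t < 2L * tau) {
    stop_tn("loop_inactive",
            "loop tau = %d has no two full windows at t = %d", tau, t)
  }
  a <- x[(t - tau + 1L):t]
  b <- x[(t - 2L * tau + 1L):(t - tau)]
  const_a <- tau < 2L || stats::var(a) == 0
  const_b <- tau < 2L || stats::var(b) == 0
  corr_raw <- if (const_a || const_b) {
    if (config$zero_variance_rule == "match") as.numeric(all(a == b)) else 0
  } else {
    stats::cor(a, b)
  }
  corr_eff <- if (config$rectify_negative) max(corr_raw, 0) else corr_raw
  list(corr_raw = corr_raw, corr_eff = corr_eff)
}

#' Loop vote weight
#'
#' The weight a loop's prediction carries in the winner-take-all vote:
#' its effective correlation, scaled by the loop duration tau under
#' `"proportional_to_tau"` weighting.
#'
#' @param corr_eff Effective correlation from [two_period_correlation()].
#' @param tau Loop delay in timesteps.
#' @param config An [rtn_config()].
#' @return Numeric weight.
#' @export
loop_weight <- function(corr_eff, tau, config) {
  switch(config$weighting,
         proportional_to_tau = corr_eff * tau,
         uniform = corr_eff)
}

#' One network update
#'
#' At timestep `t`, every populated loop (t >= 2*tau) votes its circulating
#' value X(t - tau) with weight given by [loop_weight()]. S1 and S0 are the
#' summed weights of loops predicting pulse and silence; the network
#' prediction is 1 iff S1 > S0 (ties predict silence). After observing
#' X(t), the prediction error is the vote margin |S1 - S0| when the call
#' was wrong and 0 otherwise. Loops without two full windows contribute
#' nothing, so an all-inactive step yields S0 = S1 = 0 and a prediction of
#' silence.
#'
#' @inheritParams two_period_correlation
#' @param loop_readouts Also return the per-loop readout table.
#' @return List with `y_hat`, `S0`, `S1`, `error_raw`, and (optionally)
#'   `loops`: a data frame with one row per active loop
#'   (`tau`, `prediction`, `corr_raw`, `corr_eff`, `weight`).
#' @export
network_step <- function(history, t, config, loop_readouts = FALSE) {
  x <- as_pulse_vector(history)
  t <- check_count(t, "t", min = 0L)
  if (t >= length(x)) {
    stop_tn("invalid_argument", "t = %d is beyond the input history", t)
  }
  active <- config$taus[2L * config$taus <= t]
  s0 <- 0
  s1 <- 0
  loops <- if (loop_readouts) vector("list", length(active)) else NULL
  for (k in seq_along(active)) {
    tau <- active[k]
    pred <- x[t - tau + 1L]
    cc <- two_period_correlation(x, tau, t, config)
    w <- loop_weight(cc$corr_eff, tau, config)
    if (pred == 1L) s1 <- s1 + w else s0 <- s0 + w
    if (loop_readouts) {
      loops[[k]] <- data.frame(tau = tau, prediction = pred,
                               corr_raw = cc$corr_raw, corr_eff = cc$corr_eff,
                               weight = w)
    }
  }
  y_hat <- if (s1 > s0) 1L else 0L
  obs <- x[t + 1L]
  error_raw <- if (y_hat != obs) abs(s1 - s0) else 0
  list(y_hat = y_hat, S0 = s0, S1 = s1, error_raw = error_raw,
       loops = if (loop_readouts) do.call(rbind, loops) else NULL)
}

#' Run the timing net over a pulse train
#'
#' Applies [network_step()] at every timestep t = 0..T-1 in order and
#' records input, prediction, vote sums and error. `error_norm` is
#' `error_raw` divided by its maximum over the trace (an all-zero error
#' trace stays zero). Deterministic given (train, config).
#'
#' @param train A [pulse_train()] (or 0/1 vector, taken at the default dt).
#' @param config An [rtn_config()].
#' @param loop_readouts Keep per-loop readouts for every timestep in
#'   `attr(trace, "loops")` (long format: t, tau, prediction, corr_raw,
#'   corr_eff, weight).
#' @return A `prediction_trace`: a data frame with columns `t`, `x`,
#'   `y_hat`, `S0`, `S1`, `error_raw`, `error_norm` and attributes `config`
#'   and `dt`.
#' @export
rtn_run <- function(train, config, loop_readouts = FALSE) {
  if (!inherits(train, "pulse_train")) {
    train <- pulse_train(as_pulse_vector(train))
  }
  if (!inherits(config, "rtn_config")) {
    stop_tn("invalid_argument", "`config` must be an rtn_config")
  }
  x <- train$x
  n <- length(x)
  if (n == 0L) stop_tn("invalid_argument", "empty input train")
  y_hat <- integer(n)
  s0 <- numeric(n)
  s1 <- numeric(n)
  err <- numeric(n)
  loops <- if (loop_readouts) vector("list", n) else NULL
  for (t in seq_len(n) - 1L) {
    st <- network_step(x, t, config, loop_readouts = loop_readouts)
    y_hat[t + 1L] <- st$y_hat
    s0[t + 1L] <- st$S0
    s1[t + 1L] <- st$S1
    err[t + 1L] <- st$error_raw
    if (loop_readouts && !is.null(st$loops)) {
      loops[[t + 1L]] <- cbind(t = t, st$loops)
    }
  }
  emax <- max(err)
  trace <- data.frame(t = seq_len(n) - 1L, x = x, y_hat = y_hat,
                      S0 = s0, S1 = s1, error_raw = err,
                      error_norm = if (emax > 0) err / emax else err)
  attr(trace, "config") <- config
  attr(trace, "dt") <- train$dt
  if (loop_readouts) attr(trace, "loops") <- do.call(rbind, loops)
  class(trace) <- c("prediction_trace", "data.frame")
  trace
}

#' Per-delay periodicity profile
#'
#' The state of every loop at timestep `t`: its circulating prediction,
#' two-period correlation and vote weight. Over the delay axis this is the
#' model's analogue of an autocorrelogram: loops whose delay equals an
#' event periodicity (the repetition period or a multiple) carry maximal
#' correlation. Loops not yet populated with two windows are reported
#' inactive with zero weight. `t` may equal the history length (profiling
#' the step about to be predicted).
#'
#' @inheritParams two_period_correlation
#' @return Data frame with columns `tau`, `active`, `prediction`,
#'   `corr_raw`, `corr_eff`, `weight`.
#' @export
loop_spectrum <- function(history, t, config) {
  x <- as_pulse_vector(history)
  t <- check_count(t, "t", min = 0L)
  if (t > length(x)) {
    stop_tn("invalid_argument", "t = %d is beyond the input history", t)
  }
  rows <- lapply(config$taus, function(tau) {
    if (2L * tau > t) {
      return(data.frame(tau = tau, active = FALSE, prediction = NA_integer_,
                        corr_raw = NA_real_, corr_eff = NA_real_, weight = 0))
    }
    cc <- two_period_correlation(x, tau, t, config)
    data.frame(tau = tau, active = TRUE, prediction = x[t - tau + 1L],
               corr_raw = cc$corr_raw, corr_eff = cc$corr_eff,
               weight = loop_weight(cc$corr_eff, tau, config))
  })
  do.call(rbind, rows)
}
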