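# Behavioral observables extracted from prediction traces: expectancy
# violations, adaptation time, and fill-in of missing beats.

#' Detect expectancy violations
#'
#' One violation per timestep with positive prediction error, classified by
#' the mismatch direction: `unexpected_event` when a pulse arrives that the
#' network did not predict (y_hat = 0, x = 1), `missing_event` when a
#' predicted pulse fails to arrive (y_hat = 1, x = 0). The magnitude is the
#' trace-normalized error at that timestep.
#'
#' @param trace A `prediction_trace` from [rtn_run()].
#' @return Data frame with columns `t`, `kind`, `magnitude`, sorted by `t`;
#'   zero rows for an error-free trace.
#' @export
detect_violations <- function(trace) {
  stopifnot(is.data.frame(trace))
  v <- trace[trace$error_raw > 0, , drop = FALSE]
  out <- data.frame(
    t = v$t,
    kind = ifelse(v$x == 1L, "unexpected_event", "missing_event"),
    magnitude = v$error_norm,
    stringsAsFactors = FALSE
  )
  out[order(out$t), , drop = FALSE]
}

#' Adaptation time of the network to a pattern
#'
#' How many repetitions of a pattern the network needs before its
#' predictions become violation-free: `t_stable` is the smallest timestep
#' from which no violations occur up to `horizon`, and `repetitions` is
#' `ceiling((t_stable - pattern_start) / period)`. "Adapted" means strictly
#' zero violations to the horizon; if violations persist through the last
#' timestep before `horizon`, `repetitions` is `Inf`.
#'
#' @param trace A `prediction_trace` from [rtn_run()].
#' @param pattern_start Zero-based timestep where the pattern segment
#'   begins.
#' @param period Repetition period of the pattern in timesteps.
#' @param horizon End of the examined window (exclusive); defaults to the
#'   end of the trace.
#' @return An `adaptation_result` list: `pattern_start`, `period`,
#'   `t_stable`, `repetitions`.
#' @export
adaptation_time <- function(trace, pattern_start, period, horizon = NULL) {
  stopifnot(is.data.frame(trace))
  pattern_start <- check_count(pattern_start, "pattern_start", min = 0L)
  period <- check_count(period, "period")
  horizon <- if (is.null(horizon)) max(trace$t) + 1L else
    check_count(horizon, "horizon")
  viol <- trace$t[trace$error_raw > 0 & trace$t >= pattern_start &
                    trace$t < horizon]
  t_stable <- if (length(viol)) max(viol) + 1L else pattern_start
  repetitions <- if (t_stable >= horizon) {
    Inf
  } else {
    ceiling((t_stable - pattern_start) / period)
  }
  structure(list(pattern_start = pattern_start, period = period,
                 t_stable = t_stable, repetitions = repetitions),
            class = "adaptation_result")
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf("<adaptation_result> period %d from t = %d: stable at t = %d (%s repetitions)\n",
              x$period, x$pattern_start, x$t_stable,
              format(x$repetitions)))
  invisible(x)
}

#' Missing-beat fill-in check
#'
#' Whether the network filled in an omitted beat: `TRUE` iff its prediction
#' at the omitted timestep is a pulse (y_hat = 1), i.e. the expectancy
#' persisted although the stimulus fell silent.
#'
#' @param trace A `prediction_trace` from [rtn_run()].
#' @param omitted_t Zero-based timestep of the omitted onset (see
#'   [inject_deviant()], which records it in `meta$omitted_t`).
#' @return Logical.
#' @export
fill_in_check <- function(trace, omitted_t) {
  stopifnot(is.data.frame(trace))
  omitted_t <- check_count(omitted_t, "omitted_t", min = 0L)
  row <- trace$y_hat[trace$t == omitted_t]
  if (length(row) != 1L) {
    stop_tn("invalid_argument", "timestep %d not present in the trace", omitted_t)
  }
  row == 1L
}
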