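# Reproducible experiment scenarios tying stimuli, model and analysis
# together, plus the functions behind the command-line interface
# (inst/cli/rtn.R). Each scenario builds the stimulus of one canonical
# rhythmic paradigm; defaults use a 50 ms timestep so the default periods
# sit in the musical tempo range.

#' Canonical rhythmic scenarios
#'
#' Builds the stimulus of a named paradigm:
#'
#' * `isochronous` / `onset_offset`: isochronous sequence framed by lead
#'   and tail silence, showing onset and offset mismatches.
#' * `repeat_pattern`: a repeating cycle (given as `base`, or drawn with
#'   [random_primitive_cycle()] when only `period` is given).
#' * `omission`: isochronous sequence with one beat deleted after the
#'   rhythm is established.
#' * `tempo_change`: isochronous sequence that abruptly switches period.
#' * `pattern_change`: repeating cycle that switches to a different cycle
#'   at a cycle boundary.
#' * `attribute_change`: latency-coded events whose attribute value
#'   changes from one event onward.
#'
#' Scenario parameters are passed via `params` and have defaults matching
#' the package's demonstration figures; every scenario records its deviant
#' timesteps (if any) on the returned train.
#'
#' @param scenario Scenario name; see Details.
#' @param params Named list of overrides for the scenario defaults.
#' @param dt Seconds per timestep.
#' @return A [pulse_train()].
#' @export
scenario_stimulus <- function(scenario, params = list(), dt = 0.05) {
  p <- function(name, default) params[[name]] %||% default
  scenario <- match.arg(scenario,
                        c("isochronous", "onset_offset", "repeat_pattern",
                          "omission", "tempo_change", "pattern_change",
                          "attribute_change"))
  switch(scenario,
    isochronous = ,
    onset_offset = make_isochronous(
      period = p("period", 4L), n_events = p("n_events", 8L),
      lead_silence = p("lead_silence", 8L), tail_silence = p("tail_silence", 12L),
      dt = dt),
    repeat_pattern = {
      base <- p("base", random_primitive_cycle(p("period", 7L)))
      make_repeating_pattern(base, n_cycles = p("n_cycles", 6L),
                             lead_silence = p("lead_silence", 0L),
                             tail_silence = p("tail_silence", 0L), dt = dt)
    },
    omission = {
      train <- make_isochronous(
        period = p("period", 4L), n_events = p("n_events", 8L),
        lead_silence = p("lead_silence", 8L), tail_silence = p("tail_silence", 0L),
        dt = dt)
      inject_deviant(train, "omission", event = p("omit_event", 6L))
    },
    tempo_change = {
      train <- make_isochronous(
        period = p("period", 4L), n_events = p("n_events", 14L),
        lead_silence = p("lead_silence", 8L), tail_silence = p("tail_silence", 0L),
        dt = dt)
      inject_deviant(train, "tempo_change", at_event = p("at_event", 6L),
                     new_period = p("new_period", 6L))
    },
    pattern_change = {
      base <- p("base", c(1L, 0L, 1L, 0L, 0L, 0L))
      new_base <- p("new_base", c(1L, 1L, 0L, 0L, 1L, 0L))
      train <- make_repeating_pattern(base, n_cycles = p("n_cycles", 9L),
                                      lead_silence = p("lead_silence", 8L),
                                      tail_silence = p("tail_silence", 0L), dt = dt)
      inject_deviant(train, "pattern_change", at_cycle = p("at_cycle", 5L),
                     new_base = new_base)
    },
    attribute_change = {
      period <- p("period", 10L)
      n_events <- p("n_events", 9L)
      change_at <- p("change_at_event", 6L)
      codec <- multiplex_codec(dt = dt, onset_burst = 0L,
                               slots = c(attr = p("n_values", 4L)))
      onsets_ts <- p("lead_silence", 10L) + (seq_len(n_events) - 1L) * period
      pattern <- event_pattern(
        times = onsets_ts * dt,
        attributes = data.frame(attr = rep(p("value", 1L), n_events)),
        duration = (max(onsets_ts) + codec$footprint) * dt,
        label = "attribute change")
      train <- encode_events(pattern, codec)
      for (ev in seq(change_at, n_events)) {
        train <- inject_deviant(train, "attribute_change", event = ev,
                                attribute = "attr", new_value = p("new_value", 3L))
      }
      train$period <- period
      train$meta$change_point <- min(train$deviants)
      train
    }
  )
}

#' Default delay set for a scenario
#'
#' All integer delays 1..tau_max with tau_max twice the longest repetition
#' period present in the stimulus, so the period and its first subharmonic
#' both have loops.
#'
#' @param train A [pulse_train()] with a recorded period.
#' @return An [rtn_config()].
#' @export
default_config_for <- function(train) {
  periods <- c(train$period, train$meta$old_period)
  periods <- periods[!vapply(periods, is.null, logical(1))]
  if (length(periods) == 0L) {
    stop_tn("invalid_argument", "train has no recorded period; pass taus explicitly")
  }
  rtn_config(tau_max = 2L * max(unlist(periods)))
}

#' Experiment configuration
#'
#' Bundles a scenario, its parameters, the timing-net configuration and a
#' seed into one reproducible unit; [read_experiment_config()] loads the
#' same fields from a JSON file.
#'
#' @param scenario Scenario name (see [scenario_stimulus()]).
#' @param params Scenario parameter overrides.
#' @param rtn An [rtn_config()], or `NULL` to derive the default delay set
#'   from the stimulus.
#' @param seed Integer seed for stimulus randomness.
#' @param dt Seconds per timestep.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(scenario, params = list(), rtn = NULL,
                              seed = 1L, dt = 0.05) {
  structure(list(scenario = scenario, params = params, rtn = rtn,
                 seed = as.integer(seed), dt = dt),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path JSON file with fields `scenario`, `params`, `rtn`, `seed`,
#'   `dt`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop_tn("format_error", "no such file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$scenario)) {
    stop_tn("format_error", "%s: experiment config needs a `scenario`", path)
  }
  rtn <- if (!is.null(obj$rtn)) {
    rtn_config(taus = obj$rtn$taus, tau_max = obj$rtn$tau_max,
               weighting = obj$rtn$weighting %||% "proportional_to_tau",
               rectify_negative = obj$rtn$rectify_negative %||% TRUE,
               zero_variance_rule = obj$rtn$zero_variance_rule %||% "match",
               seed = obj$rtn$seed)
  }
  experiment_config(obj$scenario, params = as.list(obj$params), rtn = rtn,
                    seed = obj$seed %||% 1L, dt = obj$dt %||% 0.05)
}

write_manifest <- function(config, out_dir, files) {
  manifest <- list(
    package = "timingnets",
    version = as.character(utils::packageVersion("timingnets")),
    scenario = config$scenario,
    params = config$params,
    rtn = if (!is.null(config$rtn)) unclass(config$rtn),
    seed = config$seed,
    dt = config$dt,
    files = files
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

#' Generate a scenario stimulus to disk
#'
#' Writes the scenario's pulse grid (and, for encodable scenarios, nothing
#' further) plus a manifest sufficient to reproduce the run bit-for-bit.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
cmd_generate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  train <- scenario_stimulus(config$scenario, config$params, dt = config$dt)
  files <- list(stimulus = file.path(out_dir, "stimulus.pulses"))
  write_pulse_grid(train, files$stimulus)
  files$manifest <- write_manifest(config, out_dir, files["stimulus"])
  invisible(files)
}

#' Run a full experiment
#'
#' Stimulus -> timing-net trace -> violation report -> adaptation summary
#' -> raster figure, all written to `out_dir` with a manifest.
#' Deterministic given (config, seed).
#'
#' @inheritParams cmd_generate
#' @return List with `files` (the written paths) plus the in-memory
#'   `train`, `trace`, `violations` and `adaptation`, invisibly.
#' @export
cmd_run <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  train <- scenario_stimulus(config$scenario, config$params, dt = config$dt)
  rtn <- config$rtn %||% default_config_for(train)
  trace <- rtn_run(train, rtn)
  violations <- detect_violations(trace)
  period <- train$period %||% 1L
  start <- train$meta$change_point %||% train$meta$lead %||% 0L
  adapt <- adaptation_time(trace, pattern_start = start, period = period)

  files <- list(stimulus = file.path(out_dir, "stimulus.pulses"),
                trace = file.path(out_dir, "trace.tsv"),
                violations = file.path(out_dir, "violations.csv"),
                adaptation = file.path(out_dir, "adaptation.json"),
                raster = file.path(out_dir, "raster.png"))
  write_pulse_grid(train, files$stimulus)
  write_trace(trace, files$trace)
  utils::write.csv(violations, files$violations, row.names = FALSE, quote = FALSE)
  adapt_out <- unclass(adapt)
  adapt_out$repetitions <- if (is.finite(adapt$repetitions)) {
    adapt$repetitions
  } else {
    "never"
  }
  jsonlite::write_json(adapt_out, files$adaptation, auto_unbox = TRUE, digits = NA)
  render_raster(train, trace, files$raster)
  config$rtn <- rtn
  files$manifest <- write_manifest(config, out_dir, files)
  invisible(list(files = files, train = train, trace = trace,
                 violations = violations, adaptation = adapt))
}

#' Analyze an existing trace file
#'
#' Reads a trace written by [cmd_run()] or [write_trace()] and writes the
#' violation report (CSV) and, when a period is supplied, the adaptation
#' summary (JSON).
#'
#' @param trace_path Path to a trace TSV.
#' @param out_dir Output directory.
#' @param pattern_start,period,horizon Passed to [adaptation_time()] when
#'   `period` is given.
#' @return Named list of written file paths, invisibly.
#' @export
cmd_analyze <- function(trace_path, out_dir, pattern_start = 0L,
                        period = NULL, horizon = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trace <- read_trace(trace_path)
  files <- list(violations = file.path(out_dir, "violations.csv"))
  utils::write.csv(detect_violations(trace), files$violations,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(period)) {
    adapt <- adaptation_time(trace, pattern_start, period, horizon)
    files$adaptation <- file.path(out_dir, "adaptation.json")
    out <- unclass(adapt)
    out$repetitions <- if (is.finite(adapt$repetitions)) adapt$repetitions else "never"
    jsonlite::write_json(out, files$adaptation, auto_unbox = TRUE, digits = NA)
  }
  invisible(files)
}

#' End-to-end demonstration bundles
#'
#' Regenerates one of the package's demonstration scenarios end to end
#' (stimulus -> trace -> violations -> raster): `onset_offset` (isochronous
#' rhythm framed by silence), `omission` (missing beat), `tempo_change`,
#' `pattern_change`, `attribute_change`.
#'
#' @param scenario Demonstration name.
#' @param out_dir Output directory.
#' @param seed Seed recorded in the manifest.
#' @return As [cmd_run()], invisibly.
#' @export
cmd_demo <- function(scenario = c("onset_offset", "omission", "tempo_change",
                                  "pattern_change", "attribute_change"),
                     out_dir, seed = 1L) {
  scenario <- match.arg(scenario)
  cmd_run(experiment_config(scenario, seed = seed), out_dir)
}
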