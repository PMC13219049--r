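# Plain-text file formats (onset lists, pulse grids, traces, configs) and
# the raster figure writer. All writers are deterministic and all round
# trips are lossless.

fmt_num <- function(x) sprintf("%.17g", x)   # round-trips doubles exactly

#' Write / read an onset list
#'
#' Onset-list files describe an [event_pattern()] one event per row with
#' columns `time_s,event_id,<attr1>,<attr2>,...`. The extension selects the
#' dialect: `.csv` (with `# duration=<s>` / `# label=<text>` comment lines
#' carrying the pattern fields that have no column) or `.json` (an object
#' with `duration`, `label` and an `events` array using the same field
#' names).
#'
#' @param pattern An [event_pattern()].
#' @param path File path ending in `.csv` or `.json`.
#' @return `write_onset_list()` returns `path` invisibly;
#'   `read_onset_list()` returns the [event_pattern()].
#' @export
write_onset_list <- function(pattern, path) {
  stopifnot(inherits(pattern, "event_pattern"))
  ext <- tolower(tools::file_ext(path))
  n <- length(pattern$times)
  if (ext == "json") {
    events <- lapply(seq_len(n), function(i) {
      ev <- list(time_s = pattern$times[i], event_id = i)
      for (nm in names(pattern$attributes)) ev[[nm]] <- pattern$attributes[[nm]][i]
      ev
    })
    jsonlite::write_json(list(duration = pattern$duration, label = pattern$label,
                              events = events),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext == "csv") {
    df <- data.frame(time_s = fmt_num(pattern$times), event_id = seq_len(n))
    for (nm in names(pattern$attributes)) df[[nm]] <- pattern$attributes[[nm]]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# duration=%s", fmt_num(pattern$duration)),
                 sprintf("# label=%s", pattern$label)), con)
    utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    stop_tn("format_error", "unsupported onset-list extension '.%s'", ext)
  }
  invisible(path)
}

#' @rdname write_onset_list
#' @param dt Timestep in seconds used only to default the duration (one
#'   timestep past the last onset) when the file does not carry one.
#' @export
read_onset_list <- function(path, dt = 0.05) {
  if (!file.exists(path)) stop_tn("format_error", "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    ev <- obj$events
    if (is.null(ev) || is.null(ev$time_s)) {
      stop_tn("format_error", "%s: JSON onset list needs an `events` array with `time_s`", path)
    }
    attrs <- ev[setdiff(names(ev), c("time_s", "event_id"))]
    if (any(ev$time_s < 0)) {
      stop_tn("format_error", "%s: negative onset time", path)
    }
    return(event_pattern(ev$time_s,
                         attributes = if (length(attrs)) attrs else NULL,
                         duration = obj$duration %||% (max(ev$time_s) + dt),
                         label = obj$label %||% ""))
  }
  if (ext != "csv") stop_tn("format_error", "unsupported onset-list extension '.%s'", ext)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body_at <- which(!grepl("^#", lines))
  if (length(body_at) == 0L) stop_tn("format_error", "%s: no header row", path)
  header_line <- body_at[1L]
  header <- strsplit(lines[header_line], ",", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "time_s" || header[2L] != "event_id") {
    stop_tn("format_error",
            "%s:%d: header must start with `time_s,event_id`", path, header_line)
  }
  rows <- lines[body_at[-1L]]
  rows <- rows[nzchar(trimws(rows))]
  parse_row <- function(i) {
    fields <- strsplit(rows[i], ",", fixed = TRUE)[[1L]]
    if (length(fields) != length(header)) {
      stop_tn("format_error", "%s:%d: expected %d fields, got %d",
              path, header_line + i, length(header), length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop_tn("format_error", "%s:%d: non-numeric field", path, header_line + i)
    }
    if (vals[1L] < 0) {
      stop_tn("format_error", "%s:%d: negative onset time", path, header_line + i)
    }
    vals
  }
  mat <- do.call(rbind, lapply(seq_along(rows), parse_row))
  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s=", key), meta, value = TRUE)
    if (length(hit)) sub(sprintf("^# %s=", key), "", hit[1L]) else NULL
  }
  duration <- get_meta("duration")
  duration <- if (is.null(duration)) max(mat[, 1L]) + dt else as.numeric(duration)
  attrs <- NULL
  if (length(header) > 2L) {
    attrs <- as.data.frame(mat[, -(1:2), drop = FALSE])
    names(attrs) <- header[-(1:2)]
  }
  event_pattern(mat[, 1L], attributes = attrs, duration = duration,
                label = get_meta("label") %||% "")
}

#' Write / read a pulse grid
#'
#' A pulse-grid file is one line of space-separated 0/1 values preceded by
#' a `# dt=<seconds>` comment header; further optional comment lines
#' (`# period=`, `# onsets=`, `# deviants=`, `# label=`) carry the train's
#' annotations.
#'
#' @param train A [pulse_train()].
#' @param path File path.
#' @return `write_pulse_grid()` returns `path` invisibly;
#'   `read_pulse_grid()` returns the [pulse_train()].
#' @export
write_pulse_grid <- function(train, path) {
  stopifnot(inherits(train, "pulse_train"))
  lines <- sprintf("# dt=%s", fmt_num(train$dt))
  if (!is.null(train$period)) lines <- c(lines, sprintf("# period=%d", train$period))
  if (!is.null(train$onsets)) {
    lines <- c(lines, sprintf("# onsets=%s", paste(train$onsets, collapse = " ")))
  }
  if (length(train$deviants)) {
    lines <- c(lines, sprintf("# deviants=%s", paste(train$deviants, collapse = " ")))
  }
  if (nzchar(train$label)) lines <- c(lines, sprintf("# label=%s", train$label))
  writeLines(c(lines, paste(train$x, collapse = " ")), path)
  invisible(path)
}

#' @rdname write_pulse_grid
#' @export
read_pulse_grid <- function(path) {
  if (!file.exists(path)) stop_tn("format_error", "no such file: %s", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != 1L) {
    stop_tn("format_error", "%s: expected exactly one data line, got %d",
            path, length(body))
  }
  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s=", key), meta, value = TRUE)
    if (length(hit)) sub(sprintf("^# %s=", key), "", hit[1L]) else NULL
  }
  dt <- get_meta("dt")
  if (is.null(dt)) stop_tn("format_error", "%s: missing `# dt=<seconds>` header", path)
  x <- suppressWarnings(as.integer(strsplit(trimws(body), "\\s+")[[1L]]))
  if (any(is.na(x)) || !all(x %in% c(0L, 1L))) {
    stop_tn("format_error", "%s: pulse values must be 0 or 1", path)
  }
  parse_ints <- function(s) if (is.null(s)) NULL else
    as.integer(strsplit(trimws(s), "\\s+")[[1L]])
  period <- get_meta("period")
  pulse_train(x, dt = as.numeric(dt), onsets = parse_ints(get_meta("onsets")),
              label = get_meta("label") %||% "",
              period = if (is.null(period)) NULL else as.integer(period),
              deviants = parse_ints(get_meta("deviants")) %||% integer(0))
}

#' Write / read a prediction trace
#'
#' Tab-separated columns `t, x, y_hat, S0, S1, error_raw, error_norm`
#' preceded by a `# dt=<seconds>` comment line. Numeric columns are written
#' with enough digits to round-trip exactly; on read the schema is
#' validated and `error_norm` is checked to lie in \[0, 1\].
#'
#' @param trace A `prediction_trace` from [rtn_run()].
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()`
#'   returns the `prediction_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  cols <- c("t", "x", "y_hat", "S0", "S1", "error_raw", "error_norm")
  if (!all(cols %in% names(trace))) {
    stop_tn("format_error", "trace is missing column(s): %s",
            paste(setdiff(cols, names(trace)), collapse = ", "))
  }
  if (nrow(trace) == 0L) stop_tn("invalid_argument", "refusing to write an empty trace")
  out <- data.frame(t = trace$t, x = trace$x, y_hat = trace$y_hat,
                    S0 = fmt_num(trace$S0), S1 = fmt_num(trace$S1),
                    error_raw = fmt_num(trace$error_raw),
                    error_norm = fmt_num(trace$error_norm))
  con <- file(path, "w")
  on.exit(close(con))
  dt <- attr(trace, "dt")
  if (!is.null(dt)) writeLines(sprintf("# dt=%s", fmt_num(dt)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_tn("format_error", "no such file: %s", path)
  first <- readLines(path, n = 1L)
  dt <- if (grepl("^# dt=", first)) as.numeric(sub("^# dt=", "", first)) else NULL
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  cols <- c("t", "x", "y_hat", "S0", "S1", "error_raw", "error_norm")
  if (!all(cols %in% names(df))) {
    stop_tn("format_error", "%s: missing column(s): %s", path,
            paste(setdiff(cols, names(df)), collapse = ", "))
  }
  if (any(df$error_norm < 0 | df$error_norm > 1)) {
    stop_tn("format_error", "%s: error_norm outside [0, 1]", path)
  }
  df <- df[, cols]
  df$t <- as.integer(df$t)
  df$x <- as.integer(df$x)
  df$y_hat <- as.integer(df$y_hat)
  for (col in c("S0", "S1", "error_raw", "error_norm")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  attr(df, "dt") <- dt
  class(df) <- c("prediction_trace", "data.frame")
  df
}

#' Write / read a timing-net configuration
#'
#' JSON mirroring the [rtn_config()] field names exactly.
#'
#' @param config An [rtn_config()].
#' @param path File path.
#' @export
write_rtn_config <- function(config, path) {
  stopifnot(inherits(config, "rtn_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_rtn_config
#' @export
read_rtn_config <- function(path) {
  if (!file.exists(path)) stop_tn("format_error", "no such file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rtn_config(taus = obj$taus, weighting = obj$weighting %||% "proportional_to_tau",
             rectify_negative = obj$rectify_negative %||% TRUE,
             zero_variance_rule = obj$zero_variance_rule %||% "match",
             tie_break = obj$tie_break %||% "predict_zero",
             seed = obj$seed)
}

#' Raster figure of stimulus, expectancy and error
#'
#' The package's standard figure: stimulus pulses as black bars in the top
#' band, network expectancies as red bars in the bottom band, open bars
#' whose height is the normalized error magnitude below, dashed vertical
#' lines at expectancy violations, dotted vertical lines at injected
#' deviant timesteps, and a thin midline over silent stretches of the
#' stimulus. Layout is deterministic given the inputs.
#'
#' @param train The stimulus [pulse_train()].
#' @param trace The matching `prediction_trace` (same length).
#' @param path Optional output file, `.png` or `.svg` by extension.
#' @param width,height Figure size in inches when writing a file.
#' @return The ggplot object, invisibly.
#' @export
render_raster <- function(train, trace, path = NULL, width = 8, height = 3.2) {
  stopifnot(inherits(train, "pulse_train"), is.data.frame(trace))
  if (length(train$x) != nrow(trace)) {
    stop_tn("invalid_argument", "train (%d steps) and trace (%d rows) differ in length",
            length(train$x), nrow(trace))
  }
  t_in <- trace$t[trace$x == 1L]
  t_pred <- trace$t[trace$y_hat == 1L]
  viol <- detect_violations(trace)
  err <- trace[trace$error_norm > 0, , drop = FALSE]

  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 1.25, linewidth = 0.2, colour = "grey70")
  if (length(train$deviants)) {
    p <- p + ggplot2::geom_vline(
      data = data.frame(t = train$deviants),
      mapping = ggplot2::aes(xintercept = .data$t),
      linetype = "dotted", colour = "grey40")
  }
  if (nrow(viol)) {
    p <- p + ggplot2::geom_vline(
      data = viol, mapping = ggplot2::aes(xintercept = .data$t),
      linetype = "dashed", colour = "grey25", linewidth = 0.3)
  }
  if (length(t_in)) {
    p <- p + ggplot2::geom_segment(
      data = data.frame(t = t_in),
      mapping = ggplot2::aes(x = .data$t, xend = .data$t, y = 1.5, yend = 2.5),
      colour = "black", linewidth = 1)
  }
  if (length(t_pred)) {
    p <- p + ggplot2::geom_segment(
      data = data.frame(t = t_pred),
      mapping = ggplot2::aes(x = .data$t, xend = .data$t, y = 0, yend = 1),
      colour = "red", linewidth = 1)
  }
  if (nrow(err)) {
    p <- p + ggplot2::geom_segment(
      data = err,
      mapping = ggplot2::aes(x = .data$t, xend = .data$t,
                             y = -1.25, yend = -1.25 + .data$error_norm),
      colour = "black", linewidth = 0.5)
  }
  p <- p +
    ggplot2::scale_y_continuous(
      breaks = c(-0.75, 0.5, 2), limits = c(-1.3, 2.6),
      labels = c("error", "prediction", "input")) +
    ggplot2::labs(x = "timestep", y = NULL,
                  title = if (nzchar(train$label)) train$label else NULL) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(panel.grid = ggplot2::element_blank())

  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
      grDevices::png(path, width = width, height = height, units = "in", res = 150)
    } else if (ext == "svg") {
      grDevices::svg(path, width = width, height = height)
    } else {
      stop_tn("invalid_argument", "unsupported raster extension '.%s'", ext)
    }
    print(p)
    grDevices::dev.off()
  }
  invisible(p)
}
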