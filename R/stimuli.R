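# Stimulus construction: symbolic event patterns, latency-multiplexed
# encoding into binary pulse trains, canonical rhythmic paradigms and
# oddball-style deviant injection.
#
# Timestep convention: a timestep index t is zero-based (t = 0 is the first
# grid point, X(t) = x[t + 1] in R's one-based storage). All stimulus and
# model operations are defined on this integer grid; dt only maps it to
# seconds.

#' Binary pulse train on a fixed timestep grid
#'
#' The network input: a sequence X(t) of 0s and 1s, one value per timestep
#' of width `dt` seconds. A pulse (1) typically marks a spike volley locked
#' to a sensory event onset or to a latency-coded event attribute.
#'
#' @param x Numeric or integer vector of 0/1 values, one per timestep.
#' @param dt Seconds per timestep. Default 0.05 s, so musical event rates of
#'   roughly 0.5--4 Hz map onto periods of 5--40 timesteps.
#' @param onsets Optional integer vector of zero-based timestep indices of
#'   event onsets. Every annotated onset must index a pulse.
#' @param label Free-text label.
#' @param period Repetition period in timesteps, when the train is built
#'   from a repeating cycle; `NULL` otherwise.
#' @param deviants Integer vector of zero-based timesteps altered by
#'   [inject_deviant()]; empty for an unperturbed train.
#' @param meta List of construction metadata (scenario parameters, codec,
#'   source pattern) carried along for deviant injection and decoding.
#'
#' @return An object of class `pulse_train`: a list with fields `x`, `dt`,
#'   `onsets`, `label`, `period`, `deviants`, `meta`.
#' @seealso [make_isochronous()], [make_repeating_pattern()],
#'   [encode_events()], [inject_deviant()]
#' @export
pulse_train <- function(x, dt = 0.05, onsets = NULL, label = "",
                        period = NULL, deviants = integer(0), meta = list()) {
  if (length(x) == 0L) {
    stop_tn("invalid_argument", "a pulse train must have at least one timestep")
  }
  xi <- as_pulse_vector(x)
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop_tn("invalid_argument", "`dt` must be a single positive number of seconds")
  }
  if (!is.null(onsets)) {
    onsets <- as.integer(onsets)
    if (any(onsets < 0L) || any(onsets >= length(xi))) {
      stop_tn("invalid_argument", "onset indices must lie within the train")
    }
    if (any(xi[onsets + 1L] != 1L)) {
      stop_tn("invalid_argument", "every annotated onset must index a pulse (x = 1)")
    }
  }
  structure(
    list(x = xi, dt = dt, onsets = onsets, label = as.character(label),
         period = if (is.null(period)) NULL else as.integer(period),
         deviants = sort(as.integer(deviants)), meta = meta),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d timesteps (dt = %g s), %d pulses",
              length(x$x), x$dt, sum(x$x)))
  if (!is.null(x$period)) cat(sprintf(", period %d", x$period))
  if (length(x$deviants)) {
    cat(sprintf(", deviant timesteps: %s", paste(x$deviants, collapse = ", ")))
  }
  if (nzchar(x$label)) cat(sprintf("  [%s]", x$label))
  cat("\n")
  invisible(x)
}

#' @export
length.pulse_train <- function(x) length(x$x)

#' Isochronous pulse sequence
#'
#' Events at exactly equal inter-onset intervals, optionally framed by
#' silence: pulses at t = lead_silence + k * period for k = 0..n_events-1.
#'
#' @param period Inter-onset interval in timesteps (>= 1).
#' @param n_events Number of events (>= 1).
#' @param lead_silence,tail_silence Silent timesteps before the first and
#'   after the last pulse.
#' @param dt Seconds per timestep.
#' @return A [pulse_train()] of length
#'   `lead_silence + (n_events - 1) * period + 1 + tail_silence`, with the
#'   onset annotation filled and `period` recorded.
#' @examples
#' make_isochronous(period = 4, n_events = 3, lead_silence = 2, tail_silence = 2)
#' @export
make_isochronous <- function(period, n_events, lead_silence = 0L,
                             tail_silence = 0L, dt = 0.05) {
  period <- check_count(period, "period")
  n_events <- check_count(n_events, "n_events")
  lead_silence <- check_count(lead_silence, "lead_silence", min = 0L)
  tail_silence <- check_count(tail_silence, "tail_silence", min = 0L)
  idx <- lead_silence + (seq_len(n_events) - 1L) * period
  len <- lead_silence + (n_events - 1L) * period + 1L + tail_silence
  x <- integer(len)
  x[idx + 1L] <- 1L
  pulse_train(x, dt = dt, onsets = idx, label = "isochronous", period = period,
              meta = list(scenario = "isochronous", lead = lead_silence,
                          tail = tail_silence, n_events = n_events))
}

#' Repeating rhythmic pattern
#'
#' Concatenates `n_cycles` copies of a base cycle (any 0/1 pattern of length
#' P, with arbitrary spacings within the cycle) between lead and tail
#' silence. The repetition period P is recorded on the result.
#'
#' @param base 0/1 vector of length P >= 1 (or a `pulse_train`, whose `x` is
#'   used), one repetition of the pattern.
#' @param n_cycles Number of repetitions (>= 1).
#' @inheritParams make_isochronous
#' @return A [pulse_train()]; every pulse is annotated as an onset.
#' @export
make_repeating_pattern <- function(base, n_cycles, lead_silence = 0L,
                                   tail_silence = 0L, dt = 0.05) {
  base <- as_pulse_vector(base)
  if (length(base) == 0L) {
    stop_tn("invalid_argument", "the base cycle must be non-empty")
  }
  n_cycles <- check_count(n_cycles, "n_cycles")
  lead_silence <- check_count(lead_silence, "lead_silence", min = 0L)
  tail_silence <- check_count(tail_silence, "tail_silence", min = 0L)
  x <- c(integer(lead_silence), rep(base, n_cycles), integer(tail_silence))
  pulse_train(x, dt = dt, onsets = which(x == 1L) - 1L,
              label = "repeating pattern", period = length(base),
              meta = list(scenario = "repeat_pattern", lead = lead_silence,
                          tail = tail_silence, base = base,
                          n_cycles = n_cycles))
}

#' Random primitive cycle
#'
#' Draws a 0/1 cycle of the given length whose minimal repetition period is
#' exactly `period`: it is non-constant and equals no repetition of a
#' shorter cycle whose length divides `period`. Used to generate the random
#' repeating patterns of the adaptation sweeps; uses R's RNG, so call
#' `set.seed()` for reproducibility.
#'
#' @param period Cycle length in timesteps (>= 2).
#' @param p_on Per-timestep pulse probability (default 0.5).
#' @param max_tries Rejection-sampling cap.
#' @return Integer 0/1 vector of length `period`.
#' @export
random_primitive_cycle <- function(period, p_on = 0.5, max_tries = 1000L) {
  period <- check_count(period, "period", min = 2L)
  for (i in seq_len(max_tries)) {
    base <- as.integer(stats::runif(period) < p_on)
    if (is_primitive_cycle(base)) return(base)
  }
  stop_tn("invalid_argument",
          "failed to draw a primitive cycle of length %d in %d tries",
          period, max_tries)
}

is_primitive_cycle <- function(base) {
  p <- length(base)
  if (length(unique(base)) < 2L) return(FALSE)
  divs <- seq_len(p - 1L)
  divs <- divs[p %% divs == 0L]
  !any(vapply(divs, function(d) all(base == rep_len(base[seq_len(d)], p)),
              logical(1)))
}

#' Symbolic event pattern
#'
#' Events as onset times in seconds plus non-negative integer attribute
#' value indices (e.g. a loudness or pitch category), prior to encoding
#' into pulses.
#'
#' @param times Strictly increasing onset times in seconds (>= 0).
#' @param attributes `NULL`, or a data frame / named list with one
#'   non-negative integer value per event and attribute.
#' @param duration Total pattern duration in seconds; all onsets must fall
#'   strictly before it.
#' @param label Free-text label.
#' @return An object of class `event_pattern` with fields `times`,
#'   `attributes` (a data frame, possibly with zero columns), `duration`,
#'   `label`.
#' @export
event_pattern <- function(times, attributes = NULL, duration, label = "") {
  times <- as.numeric(times)
  if (length(times) == 0L || any(!is.finite(times)) || any(times < 0)) {
    stop_tn("invalid_argument", "onset times must be finite, non-negative seconds")
  }
  if (any(diff(times) <= 0)) {
    stop_tn("invalid_argument", "onset times must be strictly increasing")
  }
  if (length(duration) != 1L || !is.finite(duration) || any(times >= duration)) {
    stop_tn("invalid_argument", "all onsets must fall strictly before `duration`")
  }
  if (is.null(attributes)) {
    attributes <- data.frame(row.names = seq_along(times))
  } else {
    attributes <- as.data.frame(attributes)
    if (nrow(attributes) != length(times)) {
      stop_tn("invalid_argument",
              "`attributes` must have one row per event (%d), got %d",
              length(times), nrow(attributes))
    }
    for (nm in names(attributes)) {
      v <- attributes[[nm]]
      if (any(!is.finite(v)) || any(v != as.integer(v)) || any(v < 0)) {
        stop_tn("invalid_argument",
                "attribute '%s' must hold non-negative integer value indices", nm)
      }
      attributes[[nm]] <- as.integer(v)
    }
  }
  structure(list(times = times, attributes = attributes,
                 duration = as.numeric(duration), label = as.character(label)),
            class = "event_pattern")
}

#' @export
print.event_pattern <- function(x, ...) {
  cat(sprintf("<event_pattern> %d events over %g s", length(x$times), x$duration))
  if (ncol(x$attributes)) {
    cat(sprintf(", attributes: %s", paste(names(x$attributes), collapse = ", ")))
  }
  if (nzchar(x$label)) cat(sprintf("  [%s]", x$label))
  cat("\n")
  invisible(x)
}

#' Latency-multiplexed pulse codec
#'
#' Layout for encoding event attributes as pulse latencies relative to an
#' onset-locked burst: each event contributes the burst pulses at the onset
#' timestep plus, per attribute, one pulse at
#' `base_latency + value` timesteps after the onset. Slot windows must be
#' mutually disjoint and disjoint from the burst.
#'
#' `slots` may be given as a named integer vector of value counts
#' (e.g. `c(loudness = 4, pitch = 8)`), in which case base latencies are
#' packed contiguously after the burst; or as a named list of
#' `c(base_latency, n_values)` pairs for explicit layout.
#'
#' @param dt Seconds per timestep.
#' @param onset_burst Integer timestep offsets of the onset burst relative
#'   to the event onset (default a single pulse at offset 0).
#' @param slots Attribute slot layout; see Details. `NULL` for onset-only
#'   coding.
#' @return An object of class `multiplex_codec` with fields `dt`,
#'   `onset_burst`, `slots` (data frame `name`, `base`, `n`), and
#'   `footprint` (total encoded width in timesteps).
#' @export
multiplex_codec <- function(dt = 0.05, onset_burst = 0L, slots = NULL) {
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop_tn("invalid_argument", "`dt` must be a single positive number of seconds")
  }
  onset_burst <- sort(unique(as.integer(onset_burst)))
  if (length(onset_burst) == 0L || any(onset_burst < 0L)) {
    stop_tn("invalid_argument", "`onset_burst` offsets must be non-negative integers")
  }
  if (is.null(slots)) {
    slot_df <- data.frame(name = character(0), base = integer(0), n = integer(0),
                          stringsAsFactors = FALSE)
  } else if (is.numeric(slots)) {
    if (is.null(names(slots)) || any(!nzchar(names(slots)))) {
      stop_tn("invalid_argument", "slot value counts must be named by attribute")
    }
    n <- as.integer(slots)
    base0 <- max(onset_burst) + 1L
    bases <- base0 + c(0L, cumsum(n)[-length(n)])
    slot_df <- data.frame(name = names(slots), base = bases, n = n,
                          stringsAsFactors = FALSE)
  } else if (is.list(slots)) {
    if (is.null(names(slots)) || any(!nzchar(names(slots)))) {
      stop_tn("invalid_argument", "slots must be named by attribute")
    }
    slot_df <- data.frame(
      name = names(slots),
      base = vapply(slots, function(s) as.integer(s[[1L]]), integer(1)),
      n = vapply(slots, function(s) as.integer(s[[2L]]), integer(1)),
      stringsAsFactors = FALSE
    )
  } else {
    stop_tn("invalid_argument", "`slots` must be NULL, a named vector or a named list")
  }
  if (any(slot_df$n < 1L) || any(slot_df$base < 0L)) {
    stop_tn("invalid_argument", "slot base latencies must be >= 0 and counts >= 1")
  }
  occupied <- onset_burst
  for (i in seq_len(nrow(slot_df))) {
    win <- slot_df$base[i] + seq_len(slot_df$n[i]) - 1L
    if (any(win %in% occupied)) {
      stop_tn("invalid_argument",
              "slot '%s' overlaps the onset burst or another slot", slot_df$name[i])
    }
    occupied <- c(occupied, win)
  }
  footprint <- max(occupied) + 1L
  structure(list(dt = dt, onset_burst = onset_burst, slots = slot_df,
                 footprint = footprint),
            class = "multiplex_codec")
}

#' Encode an event pattern as a pulse train
#'
#' Places, for each event, the codec's onset-burst pulses at the event's
#' onset timestep and one pulse per attribute at
#' `onset + base_latency + value`. Onsets must sit on the timestep grid and
#' encodings of consecutive events must not overlap; collisions are refused
#' rather than merged, so decoding stays unambiguous.
#'
#' @param pattern An [event_pattern()].
#' @param codec A [multiplex_codec()].
#' @param total_length Train length in timesteps; defaults to
#'   `round(pattern$duration / codec$dt)`.
#' @return A [pulse_train()] with onsets annotated and the codec and source
#'   pattern retained in `meta` (used by [decode_events()] and
#'   [inject_deviant()]).
#' @export
encode_events <- function(pattern, codec, total_length = NULL) {
  stopifnot(inherits(pattern, "event_pattern"), inherits(codec, "multiplex_codec"))
  ti <- pattern$times / codec$dt
  idx <- as.integer(round(ti))
  if (any(abs(ti - idx) > 1e-6)) {
    stop_tn("encoding_error",
            "event onsets must sit on the dt = %g s timestep grid", codec$dt)
  }
  if (length(idx) > 1L && any(diff(idx) < codec$footprint)) {
    stop_tn("encoding_error",
            "codec footprint (%d timesteps) exceeds the minimum inter-event interval (%d)",
            codec$footprint, min(diff(idx)))
  }
  total_length <- if (is.null(total_length)) {
    as.integer(round(pattern$duration / codec$dt))
  } else {
    check_count(total_length, "total_length")
  }
  extra <- setdiff(names(pattern$attributes), codec$slots$name)
  if (length(extra)) {
    stop_tn("encoding_error", "pattern attribute(s) not in codec: %s",
            paste(extra, collapse = ", "))
  }
  pos <- integer(0)
  for (i in seq_along(idx)) {
    pos <- c(pos, idx[i] + codec$onset_burst)
    for (j in seq_len(nrow(codec$slots))) {
      nm <- codec$slots$name[j]
      if (!nm %in% names(pattern$attributes)) next
      v <- pattern$attributes[[nm]][i]
      if (v >= codec$slots$n[j]) {
        stop_tn("encoding_error",
                "event %d: attribute '%s' value %d outside slot range [0, %d)",
                i, nm, v, codec$slots$n[j])
      }
      pos <- c(pos, idx[i] + codec$slots$base[j] + v)
    }
  }
  if (anyDuplicated(pos)) {
    stop_tn("encoding_error", "encoded pulses collide at timestep(s) %s",
            paste(unique(pos[duplicated(pos)]), collapse = ", "))
  }
  if (any(pos >= total_length)) {
    stop_tn("encoding_error", "encoded pulses fall beyond the train length %d",
            total_length)
  }
  x <- integer(total_length)
  x[pos + 1L] <- 1L
  pulse_train(x, dt = codec$dt, onsets = idx, label = pattern$label,
              meta = list(codec = codec, pattern = pattern))
}

#' Decode a pulse train back into an event pattern
#'
#' Inverse of [encode_events()]: reads each annotated onset's slot windows
#' against the codec layout and recovers attribute value indices. Slots
#' with no pulse for any event are dropped; a slot window holding more than
#' one pulse is an error.
#'
#' @param train A [pulse_train()] with onset annotations.
#' @param codec The [multiplex_codec()] used to encode it.
#' @return An [event_pattern()].
#' @export
decode_events <- function(train, codec) {
  stopifnot(inherits(train, "pulse_train"), inherits(codec, "multiplex_codec"))
  if (is.null(train$onsets)) {
    stop_tn("encoding_error", "decoding requires onset annotations on the train")
  }
  x <- train$x
  vals <- lapply(seq_len(nrow(codec$slots)), function(j) {
    vapply(train$onsets, function(o) {
      win <- o + codec$slots$base[j] + seq_len(codec$slots$n[j]) - 1L
      win <- win[win < length(x)]
      hits <- which(x[win + 1L] == 1L)
      if (length(hits) > 1L) {
        stop_tn("encoding_error",
                "slot '%s' at onset %d holds %d pulses; cannot decode",
                codec$slots$name[j], o, length(hits))
      }
      if (length(hits) == 0L) NA_integer_ else hits - 1L
    }, integer(1))
  })
  names(vals) <- codec$slots$name
  vals <- vals[vapply(vals, function(v) any(!is.na(v)), logical(1))]
  attributes <- if (length(vals)) as.data.frame(vals) else NULL
  event_pattern(times = train$onsets * train$dt, attributes = attributes,
                duration = length(x) * train$dt, label = train$label)
}

#' Inject an oddball deviant into a pulse train
#'
#' Perturbs an established rhythmic stimulus the way oddball paradigms do:
#'
#' * `omission`: deletes the onset pulse of event `event` (and, with
#'   `remove_attributes = TRUE` on an encoded train, its attribute pulses).
#' * `timing_shift`: moves the onset pulse of event `event` by `shift`
#'   timesteps.
#' * `attribute_change`: moves one event's attribute pulse within its slot
#'   (`event`, `attribute`, `new_value`); requires an [encode_events()]
#'   train.
#' * `tempo_change`: keeps events up to and including `at_event` in place
#'   and respaces all later events at `new_period` timesteps.
#' * `pattern_change`: for a [make_repeating_pattern()] train, replaces
#'   cycles `at_cycle` onward with repetitions of `new_base`.
#'
#' Altered timesteps are recorded in `$deviants` (for the tail-rebuilding
#' kinds: every timestep whose value changed, with the first one also in
#' `meta$change_point`).
#'
#' @param train A [pulse_train()].
#' @param kind Deviant kind; see Details.
#' @param event,shift,remove_attributes,attribute,new_value,at_event,new_period,at_cycle,new_base
#'   Kind-specific parameters; event and cycle indices are one-based.
#' @return The perturbed [pulse_train()].
#' @export
inject_deviant <- function(train,
                           kind = c("omission", "timing_shift",
                                    "attribute_change", "tempo_change",
                                    "pattern_change"),
                           event = NULL, shift = NULL,
                           remove_attributes = FALSE,
                           attribute = NULL, new_value = NULL,
                           at_event = NULL, new_period = NULL,
                           at_cycle = NULL, new_base = NULL) {
  stopifnot(inherits(train, "pulse_train"))
  kind <- match.arg(kind)
  switch(kind,
    omission = deviant_omission(train, event, remove_attributes),
    timing_shift = deviant_timing_shift(train, event, shift),
    attribute_change = deviant_attribute_change(train, event, attribute, new_value),
    tempo_change = deviant_tempo_change(train, at_event, new_period),
    pattern_change = deviant_pattern_change(train, at_cycle, new_base)
  )
}

check_event_index <- function(train, event) {
  if (is.null(train$onsets)) {
    stop_tn("invalid_argument", "train has no onset annotations")
  }
  event <- check_count(event, "event")
  if (event > length(train$onsets)) {
    stop_tn("invalid_argument", "event index %d out of range (train has %d events)",
            event, length(train$onsets))
  }
  event
}

deviant_omission <- function(train, event, remove_attributes) {
  event <- check_event_index(train, event)
  o <- train$onsets[event]
  removed <- o + if (remove_attributes && !is.null(train$meta$codec)) {
    codec <- train$meta$codec
    pat <- train$meta$pattern
    offs <- codec$onset_burst
    for (j in seq_len(nrow(codec$slots))) {
      nm <- codec$slots$name[j]
      if (!is.null(pat) && nm %in% names(pat$attributes)) {
        offs <- c(offs, codec$slots$base[j] + pat$attributes[[nm]][event])
      }
    }
    sort(offs)
  } else {
    0L
  }
  x <- train$x
  x[removed + 1L] <- 0L
  train$x <- x
  train$onsets <- train$onsets[-event]
  train$deviants <- sort(unique(c(train$deviants, removed)))
  train$meta$deviant_kind <- "omission"
  train$meta$omitted_t <- o
  train$meta$change_point <- min(removed)
  train
}

deviant_timing_shift <- function(train, event, shift) {
  event <- check_event_index(train, event)
  if (is.null(shift) || length(shift) != 1L || shift != as.integer(shift)) {
    stop_tn("invalid_argument", "`shift` must be a single integer of timesteps")
  }
  shift <- as.integer(shift)
  o <- train$onsets[event]
  new <- o + shift
  if (new < 0L || new >= length(train$x)) {
    stop_tn("invalid_argument", "shifted onset %d falls outside the train", new)
  }
  if (train$x[new + 1L] == 1L) {
    stop_tn("invalid_argument", "shifted onset %d collides with an existing pulse", new)
  }
  train$x[o + 1L] <- 0L
  train$x[new + 1L] <- 1L
  train$onsets[event] <- new
  train$onsets <- sort(train$onsets)
  train$deviants <- sort(unique(c(train$deviants, o, new)))
  train$meta$deviant_kind <- "timing_shift"
  train$meta$change_point <- min(o, new)
  train
}

deviant_attribute_change <- function(train, event, attribute, new_value) {
  event <- check_event_index(train, event)
  codec <- train$meta$codec
  pat <- train$meta$pattern
  if (is.null(codec) || is.null(pat)) {
    stop_tn("invalid_argument",
            "attribute_change needs a train built by encode_events()")
  }
  j <- match(attribute, codec$slots$name)
  if (is.na(j)) {
    stop_tn("invalid_argument", "codec has no attribute slot '%s'", attribute)
  }
  new_value <- check_count(new_value, "new_value", min = 0L)
  if (new_value >= codec$slots$n[j]) {
    stop_tn("invalid_argument", "new value %d outside slot range [0, %d)",
            new_value, codec$slots$n[j])
  }
  old_value <- pat$attributes[[attribute]][event]
  o <- train$onsets[event]
  old_pos <- o + codec$slots$base[j] + old_value
  new_pos <- o + codec$slots$base[j] + new_value
  if (new_pos == old_pos) {
    stop_tn("invalid_argument", "new value equals the current value")
  }
  if (train$x[new_pos + 1L] == 1L) {
    stop_tn("invalid_argument", "target slot position %d already holds a pulse", new_pos)
  }
  train$x[old_pos + 1L] <- 0L
  train$x[new_pos + 1L] <- 1L
  train$meta$pattern$attributes[[attribute]][event] <- new_value
  train$deviants <- sort(unique(c(train$deviants, old_pos, new_pos)))
  train$meta$deviant_kind <- "attribute_change"
  train$meta$change_point <- min(old_pos, new_pos)
  train
}

# Aligned element-wise diff of two trains that may differ in length; a
# position counts as changed when the values differ or only one train
# reaches it with a pulse.
changed_positions <- function(old_x, new_x) {
  n <- max(length(old_x), length(new_x))
  oldp <- c(old_x, integer(n - length(old_x)))
  newp <- c(new_x, integer(n - length(new_x)))
  which(oldp != newp) - 1L
}

deviant_tempo_change <- function(train, at_event, new_period) {
  at_event <- check_event_index(train, at_event)
  new_period <- check_count(new_period, "new_period")
  onsets <- train$onsets
  n <- length(onsets)
  if (at_event >= n) {
    stop_tn("invalid_argument", "tempo change needs at least one event after `at_event`")
  }
  new_onsets <- onsets
  later <- seq(at_event + 1L, n)
  new_onsets[later] <- onsets[at_event] + (later - at_event) * new_period
  tail_len <- length(train$x) - (onsets[n] + 1L)
  len <- new_onsets[n] + 1L + tail_len
  x <- integer(len)
  x[new_onsets + 1L] <- 1L
  dev <- changed_positions(train$x, x)
  pulse_train(x, dt = train$dt, onsets = new_onsets, label = train$label,
              period = new_period, deviants = sort(unique(c(train$deviants, dev))),
              meta = c(train$meta[setdiff(names(train$meta), c("deviant_kind",
                         "change_point", "new_period", "old_period"))],
                       list(deviant_kind = "tempo_change",
                            change_point = if (length(dev)) min(dev) else NA_integer_,
                            old_period = train$period,
                            new_period = new_period)))
}

deviant_pattern_change <- function(train, at_cycle, new_base) {
  base <- train$meta$base
  n_cycles <- train$meta$n_cycles
  if (is.null(base) || is.null(n_cycles)) {
    stop_tn("invalid_argument",
            "pattern_change needs a train built by make_repeating_pattern()")
  }
  at_cycle <- check_count(at_cycle, "at_cycle")
  if (at_cycle > n_cycles) {
    stop_tn("invalid_argument", "cycle index %d out of range (train has %d cycles)",
            at_cycle, n_cycles)
  }
  new_base <- as_pulse_vector(new_base)
  if (length(new_base) == 0L) {
    stop_tn("invalid_argument", "the new base cycle must be non-empty")
  }
  lead <- train$meta$lead %||% 0L
  tail <- train$meta$tail %||% 0L
  x <- c(integer(lead), rep(base, at_cycle - 1L),
         rep(new_base, n_cycles - at_cycle + 1L), integer(tail))
  dev <- changed_positions(train$x, x)
  pulse_train(x, dt = train$dt, onsets = which(x == 1L) - 1L,
              label = train$label, period = length(new_base),
              deviants = sort(unique(c(train$deviants, dev))),
              meta = list(scenario = "pattern_change", lead = lead, tail = tail,
                          base = base, new_base = new_base, n_cycles = n_cycles,
                          deviant_kind = "pattern_change",
                          change_point = if (length(dev)) min(dev) else NA_integer_,
                          old_period = length(base),
                          switch_at = lead + (at_cycle - 1L) * length(base)))
}
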