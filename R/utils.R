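`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can distinguish invalid arguments from
# format errors, encoding collisions and loop-state signals.
stop_tn <- function(class, fmt, ...) {
  stop(structure(
    class = c(paste0("timingnets_", class), "timingnets_error",
              "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1L))
  ))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop_tn("invalid_argument", "`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

# Accept either a pulse_train or a bare 0/1 vector wherever the model only
# needs the input history X.
as_pulse_vector <- function(x) {
  if (inherits(x, "pulse_train")) return(x$x)
  if (!is.numeric(x)) {
    stop_tn("invalid_argument", "expected a pulse_train or a numeric 0/1 vector")
  }
  xi <- as.integer(x)
  if (any(is.na(xi)) || any(xi != x) || !all(xi %in% c(0L, 1L))) {
    stop_tn("invalid_argument", "pulse values must be exactly 0 or 1")
  }
  xi
}
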