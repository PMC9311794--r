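#' Construct a signal trace
#'
#' A uniformly (or, for sparse channels such as capillary lactate sampling,
#' irregularly) sampled physiological channel with protocol-phase
#' annotations. Phases are half-open intervals `[start_s, end_s)`; a sample
#' belongs to a phase when its timestamp (left edge of the sampling interval)
#' falls inside the window.
#'
#' @param time_s Numeric vector of sample timestamps in seconds, strictly
#'   increasing.
#' @param value Numeric vector of samples, same length as `time_s`, finite.
#' @param channel Channel name, e.g. `"O2Hb_BB"`, `"HR"`, `"force"`.
#' @param muscle `"BB"`, `"VL"` or `"none"`.
#' @param fs Sampling rate in Hz for uniformly sampled traces, `NA` for
#'   irregular ones. If missing it is inferred from `time_s` when the grid is
#'   uniform.
#' @param phases Named list of numeric `c(start_s, end_s)` half-open
#'   intervals; must lie within the trace span and must not overlap.
#' @return A `signal_trace`: a tibble with columns `time_s`, `value` and
#'   attributes `channel`, `muscle`, `fs`, `phases`.
#' @export
#' @examples
#' tr <- signal_trace(seq(0, 9.9, by = 0.1), sin(seq(0, 9.9, by = 0.1)),
#'                    channel = "O2Hb_BB", muscle = "BB",
#'                    phases = list(baseline = c(0, 5), effort = c(5, 10)))
#' phase_summary(tr, "effort")
signal_trace <- function(time_s, value, channel, muscle = "none",
                         fs = NULL, phases = list()) {
  if (length(time_s) != length(value)) {
    abort("time_s and value must have the same length")
  }
  if (!all(is.finite(value))) abort("trace values must be finite")
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    abort("time_s must be strictly increasing")
  }
  if (is.null(fs)) {
    fs <- infer_fs(time_s)
  }
  span <- range(time_s)
  for (ph in names(phases)) {
    iv <- phases[[ph]]
    if (length(iv) != 2 || iv[1] >= iv[2]) {
      abort(sprintf("phase '%s' must be a c(start, end) interval", ph))
    }
  }
  if (length(phases) > 1) {
    ord <- order(vapply(phases, `[`, numeric(1), 1L))
    ivs <- phases[ord]
    for (i in seq_len(length(ivs) - 1)) {
      if (ivs[[i]][2] > ivs[[i + 1]][1] + 1e-9) {
        abort("phase intervals must not overlap")
      }
    }
  }
  out <- tibble(time_s = as.numeric(time_s), value = as.numeric(value))
  structure(out,
            channel = channel, muscle = muscle, fs = fs, phases = phases,
            class = c("signal_trace", class(out)))
}

infer_fs <- function(time_s) {
  if (length(time_s) < 2) return(NA_real_)
  dt <- diff(time_s)
  if (max(dt) - min(dt) < 1e-9 * max(dt)) 1 / mean(dt) else NA_real_
}

trace_channel <- function(trace) attr(trace, "channel")
trace_fs <- function(trace) attr(trace, "fs")
trace_phases <- function(trace) attr(trace, "phases")

# logical index of samples inside the half-open phase window
phase_index <- function(trace, phase) {
  phases <- trace_phases(trace)
  if (!phase %in% names(phases)) {
    abort(sprintf("trace '%s' has no phase '%s' (phases: %s)",
                  trace_channel(trace), phase,
                  paste(names(phases), collapse = ", ")))
  }
  iv <- phases[[phase]]
  trace$time_s >= iv[1] & trace$time_s < iv[2]
}

# clone a trace with new values (same grid and annotations)
with_values <- function(trace, value, channel = trace_channel(trace)) {
  signal_trace(trace$time_s, value, channel = channel,
               muscle = attr(trace, "muscle"), fs = trace_fs(trace),
               phases = trace_phases(trace))
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> channel=%s muscle=%s fs=%s Hz, %d samples\n",
              trace_channel(x), attr(x, "muscle"),
              format(trace_fs(x)), nrow(x)))
  ph <- trace_phases(x)
  if (length(ph)) {
    cat("phases:",
        paste(sprintf("%s [%g, %g)", names(ph),
                      vapply(ph, `[`, numeric(1), 1),
                      vapply(ph, `[`, numeric(1), 2)),
              collapse = ", "), "\n")
  }
  NextMethod()
}

#' @rdname signal_trace
#' @param x A `signal_trace`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.signal_trace <- function(x, ...) {
  phases <- trace_phases(x)
  phase <- rep(NA_character_, nrow(x))
  for (ph in names(phases)) phase[phase_index(x, ph)] <- ph
  tibble(channel = trace_channel(x), time_s = x$time_s, value = x$value,
         phase = phase)
}

#' @rdname signal_trace
#' @param object A `signal_trace`.
#' @exportS3Method ggplot2::autoplot
autoplot.signal_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$phase, group = 1)) +
    ggplot2::labs(x = "time (s)", y = trace_channel(object),
                  colour = "phase") +
    ggplot2::theme_minimal()
}
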