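#' Baseline reference value of a trace
#'
#' The mean of the samples in the final 30 s of the baseline phase
#' (half-open window `[baseline_end - 30, baseline_end)`), used to express
#' hemoglobin-species NIRS signals as deltas from rest.
#'
#' @param trace A [signal_trace()] with an annotated `baseline` phase of at
#'   least 30 s.
#' @param window_s Width of the averaging window in seconds (default 30).
#' @return A scalar baseline value.
#' @export
baseline_reference <- function(trace, window_s = 30) {
  phases <- trace_phases(trace)
  if (!"baseline" %in% names(phases)) {
    abort(sprintf("trace '%s' has no annotated baseline phase",
                  trace_channel(trace)))
  }
  iv <- phases[["baseline"]]
  if (iv[2] - iv[1] < window_s - 1e-9) {
    abort(sprintf("baseline phase is %.1f s long; need >= %g s",
                  iv[2] - iv[1], window_s))
  }
  idx <- trace$time_s >= iv[2] - window_s & trace$time_s < iv[2]
  if (!any(idx)) abort("no samples in the baseline reference window")
  mean(trace$value[idx])
}

#' Re-express a trace as difference from baseline
#'
#' @param trace A [signal_trace()].
#' @param baseline Finite scalar, typically from [baseline_reference()].
#' @return A `signal_trace` with `baseline` subtracted from every sample and
#'   a `D.`-prefixed channel name.
#' @export
delta_series <- function(trace, baseline) {
  if (!is.finite(baseline)) abort("baseline must be finite")
  with_values(trace, trace$value - baseline,
              channel = paste0("D.", trace_channel(trace)))
}

#' Per-phase summary statistics of a trace
#'
#' Peak (maximum), mean, minimum and delta (last minus first sample) over the
#' samples whose timestamps fall in the half-open phase window.
#'
#' @param trace A [signal_trace()].
#' @param phase Name of an annotated phase.
#' @param stats Which statistics to return.
#' @return A one-row tibble with the requested statistics.
#' @export
phase_summary <- function(trace, phase,
                          stats = c("peak", "mean", "min", "delta")) {
  stats <- match.arg(stats, several.ok = TRUE)
  idx <- phase_index(trace, phase)
  if (!any(idx)) {
    abort(sprintf("phase '%s' contains no samples of trace '%s'",
                  phase, trace_channel(trace)))
  }
  v <- trace$value[idx]
  out <- list(peak = max(v), mean = mean(v), min = min(v),
              delta = v[length(v)] - v[1])
  as_tibble(out[stats])
}

phase_stat <- function(trace, phase, aggregation) {
  nm <- c(peak = "peak", mean = "mean", min = "min", delta = "delta")[[aggregation]]
  phase_summary(trace, phase, stats = nm)[[nm]]
}

#' Extract a subject's feature row from raw traces
#'
#' Reduces one subject's channel traces to the per-variable summary values a
#' scenario catalogue demands. Hemoglobin-species NIRS channels (O2Hb, HHb,
#' tHb) are low-pass filtered and expressed as baseline deltas before the
#' per-phase statistics; TSI is filtered but kept in absolute percent;
#' systemic channels (HR, SpO2, lactate) are summarised unfiltered;
#' mechanical variables come from [power_summary()] of the force and
#' velocity traces; scalar variables (subject characteristics, RPE) are read
#' from `scalars`.
#'
#' @param traces Named list of [signal_trace()] objects; NIRS channels are
#'   named `<signal>_<muscle>` (e.g. `O2Hb_BB`), systemic ones `HR`, `SpO2`,
#'   `lactate`, mechanics `force` and `velocity`.
#' @param catalogue A scenario catalogue from [scenario_catalogue()].
#' @param filter A [filter_params()] object for the NIRS channels.
#' @param scalars Named list or one-row data frame of scalar variables.
#' @return A one-row tibble with one column per catalogue variable.
#' @export
extract_features <- function(traces, catalogue, filter = filter_params(),
                             scalars = list()) {
  validate_catalogue(catalogue)
  if (nrow(catalogue) == 0) return(tibble(.rows = 1))
  scalars <- as.list(scalars)

  needed_channels <- unique(trace_channel_for(catalogue))
  needed_channels <- setdiff(needed_channels[!is.na(needed_channels)],
                             names(traces))
  if (length(needed_channels)) {
    missing_vars <- catalogue$variable[
      trace_channel_for(catalogue) %in% needed_channels]
    abort(paste0("missing channels: ",
                 paste(needed_channels, collapse = ", "),
                 " (needed for variables: ",
                 paste(missing_vars, collapse = ", "), ")"))
  }

  # prepare processed NIRS series once per channel
  processed <- list()
  get_processed <- function(channel, signal) {
    if (!is.null(processed[[channel]])) return(processed[[channel]])
    tr <- lowpass_zero_phase(traces[[channel]], filter)
    if (signal != "TSI") {
      tr <- delta_series(tr, baseline_reference(tr))
    }
    processed[[channel]] <<- tr
    tr
  }

  pow <- NULL
  get_power <- function() {
    if (is.null(pow)) {
      if (is.null(traces[["force"]]) || is.null(traces[["velocity"]])) {
        abort("mechanical variables need both 'force' and 'velocity' traces")
      }
      mass <- scalars[["BM"]]
      if (is.null(mass)) abort("body mass 'BM' is needed in scalars to derive relative power")
      pow <<- power_summary(power_trace(traces[["force"]], traces[["velocity"]]),
                            body_mass = mass)
    }
    pow
  }

  vals <- purrr::pmap_dbl(catalogue, function(scenario, variable, family,
                                              muscle, signal, aggregation,
                                              phase, ...) {
    if (signal == "scalar") {
      v <- scalars[[variable]]
      if (is.null(v)) abort(sprintf("scalar variable '%s' not supplied", variable))
      return(as.numeric(v))
    }
    if (signal == "power") {
      return(get_power()[[variable]])
    }
    if (family == "NIRS") {
      channel <- paste0(signal, "_", muscle)
      return(phase_stat(get_processed(channel, signal), phase, aggregation))
    }
    channel <- switch(signal, HR = "HR", SpO2 = "SpO2", lactate = "lactate",
                      abort(sprintf("unknown signal '%s'", signal)))
    phase_stat(traces[[channel]], phase, aggregation)
  })

  tibble::as_tibble_row(setNames(as.list(vals), catalogue$variable))
}

# which raw channel a catalogue row reads from (NA for scalars)
trace_channel_for <- function(catalogue) {
  ifelse(catalogue$signal == "scalar", NA_character_,
  ifelse(catalogue$signal == "power", "force",
  ifelse(catalogue$family == "NIRS",
         paste0(catalogue$signal, "_", catalogue$muscle),
         catalogue$signal)))
}
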