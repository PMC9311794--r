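#' Tethered-running power trace
#'
#' The product of the horizontal towing force and the running velocity,
#' sample by sample. Both traces must share the sampling rate and timestamps;
#' no implicit resampling is performed.
#'
#' @param force A [signal_trace()] in newtons.
#' @param velocity A [signal_trace()] in m/s on the same time grid.
#' @return A `signal_trace` of power in watts.
#' @export
power_trace <- function(force, velocity) {
  fs_f <- trace_fs(force)
  fs_v <- trace_fs(velocity)
  if (!isTRUE(all.equal(fs_f, fs_v)) ||
      nrow(force) != nrow(velocity) ||
      max(abs(force$time_s - velocity$time_s)) > 1e-9) {
    abort(sprintf(
      "force (fs = %s Hz, n = %d) and velocity (fs = %s Hz, n = %d) are not aligned",
      format(fs_f), nrow(force), format(fs_v), nrow(velocity)))
  }
  with_values(force, force$value * velocity$value, channel = "power")
}

#' Sprint power summary
#'
#' Peak, mean and minimum power over the all-out effort phase, in absolute
#' watts and relative to body mass, plus the fatigue index
#' `FI = (peak - minimum) / peak * 100`.
#'
#' @param power A power [signal_trace()] (watts) with an annotated effort
#'   phase.
#' @param body_mass Subject body mass in kg, > 0.
#' @param effort_phase Name of the effort phase annotation.
#' @return A one-row tibble with `pP`, `mP`, `minP` (W), `pP_rel`, `mP_rel`,
#'   `minP_rel` (W/kg) and `FI` (%).
#' @export
#' @examples
#' t <- seq(0, 29.999, by = 0.001)
#' p <- signal_trace(t, 2000 - 30 * t, channel = "power",
#'                   phases = list(effort = c(0, 30)))
#' power_summary(p, body_mass = 73.2)
power_summary <- function(power, body_mass, effort_phase = "effort") {
  if (!is.finite(body_mass) || body_mass <= 0) {
    abort("body_mass must be a positive number (kg)")
  }
  s <- phase_summary(power, effort_phase, stats = c("peak", "mean", "min"))
  if (s$peak == 0) abort("peak power is zero; fatigue index is undefined")
  tibble(
    pP = s$peak, mP = s$mean, minP = s$min,
    pP_rel = s$peak / body_mass,
    mP_rel = s$mean / body_mass,
    minP_rel = s$min / body_mass,
    FI = (s$peak - s$min) / s$peak * 100
  )
}
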