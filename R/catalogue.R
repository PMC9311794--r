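#' Scenario variable catalogues
#'
#' The node universe of each correlation network. Exercise scenarios (a 30 s
#' all-out tethered run, with or without inspiratory-muscle pre-activation)
#' use 46 variables; recovery scenarios (18 min post-effort) use 52. The
#' default composition is:
#'
#' * 6 subject characteristics: `Age`, `Hgt`, `BM`, `BF`, `MIP`, `SI`;
#' * 7 running-mechanics variables: peak/mean/minimum power, absolute and
#'   relative to body mass, plus the fatigue index `FI`;
#' * systemic responses: blood lactate, heart rate, pulse-oximetry
#'   saturation (and, in exercise scenarios, the perceived-exertion score);
#' * 24 NIRS muscle-oxygenation variables: peak/mean/minimum of O2Hb, HHb,
#'   tHb (baseline deltas) and of the absolute tissue saturation index TSI,
#'   for the biceps brachii (`BB`) and vastus lateralis (`VL`).
#'
#' Variable names follow the field's abbreviations: a `p`, `m`, `min` or `D`
#' prefix marks peak, mean, minimum or delta (last minus first sample of the
#' phase); a `_BB`/`_VL` suffix names the muscle.
#'
#' @param scenario One of `"AO30"`, `"IMPA_AO30"`, `"RECOVERY"`,
#'   `"IMPA_RECOVERY"`.
#' @return A tibble with one row per variable and columns `scenario`,
#'   `variable`, `family` (characteristic/mechanical/systemic/NIRS), `muscle`
#'   (BB/VL/none), `signal` (source channel), `aggregation`
#'   (peak/mean/min/delta/scalar) and `phase` (baseline/effort/recovery or
#'   `NA` for scalars).
#' @export
#' @examples
#' nrow(scenario_catalogue("AO30"))     # 46
#' nrow(scenario_catalogue("RECOVERY")) # 52
scenario_catalogue <- function(scenario = c("AO30", "IMPA_AO30",
                                            "RECOVERY", "IMPA_RECOVERY")) {
  scenario <- match.arg(scenario)
  kind <- scenario_kind(scenario)
  cat <- if (kind == "exercise") exercise_catalogue() else recovery_catalogue()
  cat$scenario <- scenario
  dplyr::relocate(cat, "scenario")
}

scenario_kind <- function(scenario) {
  if (scenario %in% c("AO30", "IMPA_AO30")) "exercise" else "recovery"
}

all_scenarios <- function() c("AO30", "IMPA_AO30", "RECOVERY", "IMPA_RECOVERY")

characteristic_rows <- function() {
  tibble(
    variable = c("Age", "Hgt", "BM", "BF", "MIP", "SI"),
    family = "characteristic", muscle = "none", signal = "scalar",
    aggregation = "scalar", phase = NA_character_
  )
}

mechanical_rows <- function() {
  tibble(
    variable = c("pP", "mP", "minP", "pP_rel", "mP_rel", "minP_rel", "FI"),
    family = "mechanical", muscle = "none", signal = "power",
    aggregation = c("peak", "mean", "min", "peak", "mean", "min", "scalar"),
    phase = "effort"
  )
}

nirs_rows <- function(phase) {
  grid <- expand.grid(
    stat = c("p", "m", "min"),
    sig = c("O2Hb", "HHb", "tHb", "TSI"),
    muscle = c("BB", "VL"),
    stringsAsFactors = FALSE
  )
  tibble(
    variable = paste0(grid$stat, grid$sig, "_", grid$muscle),
    family = "NIRS", muscle = grid$muscle, signal = grid$sig,
    aggregation = c(p = "peak", m = "mean", min = "min")[grid$stat],
    phase = phase
  )
}

exercise_catalogue <- function() {
  systemic <- tibble(
    variable = c("pLac", "mLac", "DLac",
                 "pHR", "mHR", "minHR", "DHR", "DSpO2", "RPE"),
    family = "systemic", muscle = "none",
    signal = c("lactate", "lactate", "lactate",
               "HR", "HR", "HR", "HR", "SpO2", "scalar"),
    aggregation = c("peak", "mean", "delta",
                    "peak", "mean", "min", "delta", "delta", "scalar"),
    phase = c("recovery", "recovery", "recovery",
              "effort", "effort", "effort", "effort", "recovery",
              NA_character_)
  )
  out <- dplyr::bind_rows(characteristic_rows(), mechanical_rows(),
                          systemic, nirs_rows("effort"))
  stopifnot(nrow(out) == 46L)
  out
}

recovery_catalogue <- function() {
  systemic <- tibble(
    variable = c("restLac", "pLac", "mLac", "minLac", "DLac",
                 "restHR", "pHR", "mHR", "minHR", "DHR",
                 "restSpO2", "pSpO2", "mSpO2", "minSpO2", "DSpO2"),
    family = "systemic", muscle = "none",
    signal = rep(c("lactate", "HR", "SpO2"), each = 5),
    aggregation = rep(c("mean", "peak", "mean", "min", "delta"), times = 3),
    phase = rep(c("baseline", rep("recovery", 4)), times = 3)
  )
  out <- dplyr::bind_rows(characteristic_rows(), mechanical_rows(),
                          systemic, nirs_rows("recovery"))
  stopifnot(nrow(out) == 52L)
  out
}

#' Validate a variable catalogue
#'
#' Checks uniqueness of names and field levels; warns (rather than errors)
#' when an exercise catalogue deviates from 46 variables or a recovery
#' catalogue from 52, so custom node universes remain usable but the
#' deviation is always visible.
#'
#' @param catalogue A catalogue tibble as from [scenario_catalogue()].
#' @return The catalogue, invisibly, after validation.
#' @export
validate_catalogue <- function(catalogue) {
  needed <- c("scenario", "variable", "family", "muscle", "signal",
              "aggregation", "phase")
  missing <- setdiff(needed, names(catalogue))
  if (length(missing)) {
    abort(paste0("catalogue is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(catalogue$variable)) {
    abort("catalogue variable names must be unique")
  }
  bad_family <- setdiff(catalogue$family,
                        c("characteristic", "mechanical", "systemic", "NIRS"))
  if (length(bad_family)) {
    abort(paste0("unknown variable family: ",
                 paste(bad_family, collapse = ", ")))
  }
  bad_agg <- setdiff(catalogue$aggregation,
                     c("peak", "mean", "min", "delta", "scalar"))
  if (length(bad_agg)) {
    abort(paste0("unknown aggregation: ", paste(bad_agg, collapse = ", ")))
  }
  kind <- scenario_kind(catalogue$scenario[1])
  expected <- if (kind == "exercise") 46L else 52L
  if (nrow(catalogue) != expected) {
    warn(sprintf(
      "catalogue for %s scenario has %d variables (default universe has %d)",
      kind, nrow(catalogue), expected))
  }
  invisible(catalogue)
}

# Internal latent key: variables from different catalogues that share a name
# but summarise a different phase (the NIRS stats) are distinct latent
# quantities; everything else (characteristics, mechanics, systemic summaries
# with matching definition) is shared within a session.
catalogue_keys <- function(catalogue) {
  paste0(catalogue$variable, "@", ifelse(is.na(catalogue$phase), "scalar",
                                         catalogue$phase))
}
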