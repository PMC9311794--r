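#' Specification of a synthetic cohort
#'
#' Describes the statistical structure of a simulated study: cohort size,
#' subject characteristics on the published scale (mean and SEM of an
#' n = 15 group; sampling SD is `SEM * sqrt(15)`), the planted correlation
#' structure (equicorrelated blocks and hub-and-spoke stars over the latent
#' feature variables), extra independent per-variable noise, the
#' multiplicative inspiratory-muscle pre-activation (IM_PA) effect injected
#' into the pre-activated scenarios, and the master seed from which all
#' per-subject random streams are derived.
#'
#' @param n_subjects Cohort size, >= 3 (correlation p-values are undefined
#'   below that). Default 15.
#' @param characteristic_params Named list `variable = c(mean, sem)` for the
#'   six subject characteristics.
#' @param latent_params Optional named list `key = c(mean, sem)` overriding
#'   entries of the default latent scale table ([latent_defaults()]); keys
#'   are `variable@phase`.
#' @param correlation_blocks List of `list(members =, r =)` with `r` in
#'   `[0, 1)`; members are latent keys.
#' @param hub_specs List of `list(hub =, spokes =, r =)`; with
#'   `transitive = TRUE` (the default in [plant_covariance()]) spoke pairs
#'   get `r^2`, the factor-model closure that keeps the matrix PSD.
#' @param noise_sd Independent per-variable noise SD added on top of the
#'   correlated draw (0 keeps planted correlations exact).
#' @param impa_effect Named multiplicative shifts applied to the
#'   pre-activation scenarios; see [impa_default_effect()].
#' @param impa_noise_sd SD of the subject-level lognormal perturbation of
#'   the multipliers (session-to-session variability).
#' @param trace_noise_sd White-noise SD added to synthetic NIRS traces so
#'   the low-pass filter has something to remove; 0 gives noiseless traces.
#' @param seed Master seed (mandatory).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 15,
                           characteristic_params = default_characteristics(),
                           latent_params = list(),
                           correlation_blocks = default_correlation_blocks(),
                           hub_specs = default_hub_specs(),
                           noise_sd = 0,
                           impa_effect = impa_default_effect(),
                           impa_noise_sd = 0.08,
                           trace_noise_sd = 0.3,
                           seed = NULL) {
  if (is.null(seed)) abort("a seed is mandatory for a synthetic_spec")
  if (n_subjects < 3) abort("n_subjects must be >= 3")
  for (b in correlation_blocks) {
    if (b$r < 0 || b$r >= 1) abort("block correlations must lie in [0, 1)")
  }
  for (h in hub_specs) {
    if (abs(h$r) >= 1) abort("hub correlations must satisfy |r| < 1")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    characteristic_params = characteristic_params,
    latent_params = latent_params,
    correlation_blocks = correlation_blocks,
    hub_specs = hub_specs,
    noise_sd = noise_sd,
    impa_effect = impa_effect,
    impa_noise_sd = impa_noise_sd,
    trace_noise_sd = trace_noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_characteristics <- function() {
  list(Age = c(23, 1), Hgt = c(1.77, 0.02), BM = c(73.2, 2.0),
       BF = c(6.5, 0.5), MIP = c(144.3, 10.2), SI = c(123.7, 3.7))
}

#' Default IM_PA effect
#'
#' Multiplicative shifts of the absolute power variables matching the
#' published group-mean ratios between the pre-activated and control
#' sessions (mean power about +11%). Relative power and the fatigue index
#' are re-derived from the shifted absolutes, so the fatigue index drops
#' slightly, as observed.
#'
#' @return Named numeric vector of multipliers.
#' @export
impa_default_effect <- function() {
  c(pP = 2501.1 / 2296.7, mP = 1894.0 / 1706.9, minP = 1372.3 / 1210.3)
}

#' Default latent feature scales
#'
#' Location (group mean) and SEM for every latent variable of the exercise
#' and recovery catalogues, keyed `variable@phase`. Values reported by the
#' source literature (power, fatigue index, lactate peak, heart rate,
#' saturation, minimum TSI) anchor the scales; the remaining NIRS delta
#' magnitudes are physiologically plausible arbitrary-unit choices
#' (desaturation of the more active vastus lateralis exceeding the biceps
#' brachii). Relative power and FI appear with `NA`: they are derived from
#' the absolutes and body mass, never drawn.
#'
#' @return A tibble with columns `key`, `mean`, `sem`.
#' @export
latent_defaults <- function() {
  def <- c(
    # mechanical (absolute W; relatives and FI derived)
    "pP@effort" = "2296.7 126.3", "mP@effort" = "1706.9 104.7",
    "minP@effort" = "1210.3 89.2",
    # systemic, exercise side
    "pHR@effort" = "176 2", "mHR@effort" = "150 3", "minHR@effort" = "95 3",
    "DHR@effort" = "75 5",
    "RPE@scalar" = "18.5 0.3",
    # lactate kinetics (shared by both catalogue phases)
    "pLac@recovery" = "17.2 0.6", "mLac@recovery" = "13.5 0.6",
    "minLac@recovery" = "10.5 0.6", "DLac@recovery" = "2.0 0.5",
    "restLac@baseline" = "0.8 0.1",
    # pulse oximetry
    "DSpO2@recovery" = "0.5 0.2", "pSpO2@recovery" = "97.5 0.2",
    "mSpO2@recovery" = "96.5 0.3", "minSpO2@recovery" = "94.5 0.4",
    "restSpO2@baseline" = "97.4 0.2",
    # heart-rate recovery
    "pHR@recovery" = "174 2", "mHR@recovery" = "120 3",
    "minHR@recovery" = "92 3", "DHR@recovery" = "-78 5",
    "restHR@baseline" = "65 3",
    # NIRS, effort phase (Hb species as baseline deltas, a.u.; TSI absolute %)
    "pO2Hb_BB@effort" = "1.0 0.4", "mO2Hb_BB@effort" = "-6.0 0.8",
    "minO2Hb_BB@effort" = "-12.0 1.2",
    "pO2Hb_VL@effort" = "0.5 0.4", "mO2Hb_VL@effort" = "-10.0 1.0",
    "minO2Hb_VL@effort" = "-20.0 1.5",
    "pHHb_BB@effort" = "8.0 0.8", "mHHb_BB@effort" = "4.0 0.6",
    "minHHb_BB@effort" = "-0.5 0.3",
    "pHHb_VL@effort" = "15.0 1.2", "mHHb_VL@effort" = "8.0 1.0",
    "minHHb_VL@effort" = "-0.5 0.3",
    "ptHb_BB@effort" = "3.0 0.5", "mtHb_BB@effort" = "-1.0 0.5",
    "mintHb_BB@effort" = "-5.0 0.8",
    "ptHb_VL@effort" = "4.0 0.6", "mtHb_VL@effort" = "-2.0 0.6",
    "mintHb_VL@effort" = "-8.0 1.0",
    "pTSI_BB@effort" = "64.0 1.0", "mTSI_BB@effort" = "48.0 1.5",
    "minTSI_BB@effort" = "32.2 1.8",
    "pTSI_VL@effort" = "71.0 1.0", "mTSI_VL@effort" = "60.0 1.5",
    "minTSI_VL@effort" = "50.1 1.7",
    # NIRS, recovery phase (reoxygenation with hyperaemic overshoot)
    "pO2Hb_BB@recovery" = "6.0 0.8", "mO2Hb_BB@recovery" = "2.0 0.5",
    "minO2Hb_BB@recovery" = "-10.0 1.2",
    "pO2Hb_VL@recovery" = "8.0 1.0", "mO2Hb_VL@recovery" = "3.0 0.6",
    "minO2Hb_VL@recovery" = "-18.0 1.5",
    "pHHb_BB@recovery" = "7.0 0.8", "mHHb_BB@recovery" = "1.5 0.5",
    "minHHb_BB@recovery" = "-2.0 0.4",
    "pHHb_VL@recovery" = "14.0 1.2", "mHHb_VL@recovery" = "3.0 0.8",
    "minHHb_VL@recovery" = "-2.0 0.4",
    "ptHb_BB@recovery" = "4.0 0.6", "mtHb_BB@recovery" = "1.0 0.4",
    "mintHb_BB@recovery" = "-4.0 0.6",
    "ptHb_VL@recovery" = "5.0 0.8", "mtHb_VL@recovery" = "1.0 0.5",
    "mintHb_VL@recovery" = "-7.0 1.0",
    "pTSI_BB@recovery" = "69.0 0.9", "mTSI_BB@recovery" = "62.0 1.0",
    "minTSI_BB@recovery" = "33.0 1.8",
    "pTSI_VL@recovery" = "76.0 0.8", "mTSI_VL@recovery" = "70.0 1.0",
    "minTSI_VL@recovery" = "51.0 1.7"
  )
  parts <- strsplit(unname(def), " ")
  tibble(
    key = names(def),
    mean = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
    sem = vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  )
}

#' @rdname synthetic_spec
#' @export
default_correlation_blocks <- function() {
  nirs_keys <- function(muscle, phase) {
    grid <- expand.grid(stat = c("p", "m", "min"),
                        sig = c("O2Hb", "HHb", "tHb", "TSI"),
                        stringsAsFactors = FALSE)
    paste0(grid$stat, grid$sig, "_", muscle, "@", phase)
  }
  triple <- function(sig, muscle, phase) {
    paste0(c("p", "m", "min"), sig, "_", muscle, "@", phase)
  }
  blocks <- list(
    list(members = c("pP@effort", "mP@effort", "minP@effort"), r = 0.85),
    list(members = c("pHR@effort", "mHR@effort", "minHR@effort"), r = 0.7),
    list(members = c("pHR@recovery", "mHR@recovery", "minHR@recovery"),
         r = 0.7),
    list(members = c("pLac@recovery", "mLac@recovery", "minLac@recovery"),
         r = 0.7),
    list(members = c("pSpO2@recovery", "mSpO2@recovery", "minSpO2@recovery"),
         r = 0.7)
  )
  for (muscle in c("BB", "VL")) {
    for (phase in c("effort", "recovery")) {
      blocks <- c(blocks, list(list(members = nirs_keys(muscle, phase),
                                    r = 0.45)))
      for (sig in c("O2Hb", "HHb", "tHb", "TSI")) {
        blocks <- c(blocks, list(list(members = triple(sig, muscle, phase),
                                      r = 0.75)))
      }
    }
  }
  blocks
}

#' @rdname synthetic_spec
#' @export
default_hub_specs <- function() {
  # peak lactate as a physiological hub: coupled to the mean muscle
  # reoxygenation responses of both muscles and to its own kinetics; 0.35
  # keeps the assembled matrix PSD alongside the NIRS and lactate blocks
  spokes <- c(as.vector(outer(paste0("m", c("O2Hb", "HHb", "tHb", "TSI")),
                              c("_BB@recovery", "_VL@recovery"), paste0)),
              "mLac@recovery", "minLac@recovery")
  list(list(hub = "pLac@recovery", spokes = spokes, r = 0.35))
}

#' Plant a correlation structure over a variable catalogue
#'
#' Assembles the latent correlation matrix from equicorrelated blocks and
#' hub-and-spoke stars: the matrix starts as the identity, block members get
#' the block `r`, hub-spoke pairs get the hub `r` and (with
#' `transitive = TRUE`) spoke pairs get `r^2`, the factor-model closure.
#' Overlapping structures combine by the maximum. If the assembled matrix is
#' not positive semi-definite it is repaired by clipping negative
#' eigenvalues to zero and renormalising the diagonal; a repair that moves
#' any planted entry by more than `max_shift` is an error naming the worst
#' pair.
#'
#' @param spec A [synthetic_spec()].
#' @param catalogue A catalogue tibble, or a character vector of latent
#'   keys.
#' @param transitive Close hub structures into factor models (spoke-spoke
#'   `r^2`).
#' @param max_shift Largest tolerated repair shift per entry.
#' @return A correlation matrix with unit diagonal over the catalogue's
#'   latent keys.
#' @export
plant_covariance <- function(spec, catalogue, transitive = TRUE,
                             max_shift = 0.05) {
  keys <- if (is.character(catalogue)) catalogue else catalogue_keys(catalogue)
  k <- length(keys)
  C <- diag(k)
  dimnames(C) <- list(keys, keys)
  set_pair <- function(i, j, r) {
    C[i, j] <<- max(C[i, j], r)
    C[j, i] <<- C[i, j]
  }
  resolve <- function(vars, what) {
    idx <- match(vars, keys)
    if (anyNA(idx)) {
      abort(sprintf("%s names unknown variables: %s", what,
                    paste(vars[is.na(idx)], collapse = ", ")))
    }
    idx
  }
  for (b in spec$correlation_blocks) {
    idx <- resolve(b$members, "correlation block")
    for (i in idx) for (j in idx) if (i < j) set_pair(i, j, b$r)
  }
  for (h in spec$hub_specs) {
    hub <- resolve(h$hub, "hub spec")
    spokes <- resolve(h$spokes, "hub spec")
    for (s in spokes) set_pair(hub, s, h$r)
    if (transitive) {
      for (i in spokes) for (j in spokes) if (i < j) set_pair(i, j, h$r^2)
    }
  }
  planted <- C
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    lam <- pmax(ev$values, 0)
    C2 <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    d <- sqrt(diag(C2))
    C2 <- C2 / outer(d, d)
    shift <- abs(C2 - planted)
    if (max(shift) > max_shift) {
      worst <- which(shift == max(shift), arr.ind = TRUE)[1, ]
      abort(sprintf(
        "planted correlation structure is too far from PSD: repairing moves (%s, %s) by %.3f",
        keys[worst[1]], keys[worst[2]], max(shift)))
    }
    warn(sprintf(
      "planted matrix was not PSD; repaired by eigenvalue clipping (max entry shift %.4f)",
      max(shift)))
    C <- C2
    dimnames(C) <- list(keys, keys)
  }
  C
}

# deterministic per-subject seed stream derived from the master seed
subject_seed <- function(master, i, salt = 0L) {
  as.integer((as.numeric(master) * 1009 + i * 7919 + salt * 104729) %%
               2147483647)
}

#' Generate a synthetic cohort
#'
#' Draws subject characteristics and latent feature values from the planted
#' multivariate-normal model, enforces the deterministic relationships the
#' extraction pipeline would impose (peak >= mean >= min within each stat
#' triple, deltas inside the feasible range, relative power = absolute
#' power / body mass, fatigue index from peak and minimum power), and
#' projects the joint latent vector onto each scenario's catalogue. The
#' pre-activation scenarios are the control draws with the IM_PA effect
#' applied (see [apply_impa_effect()]).
#'
#' Output is deterministic for a fixed `(spec, seed)`; per-subject random
#' streams are derived from the master seed by fixed offsets, so subject i's
#' data do not change when the cohort grows.
#'
#' @param spec A [synthetic_spec()].
#' @param catalogues Named list of scenario catalogues; defaults to the four
#'   standard scenarios.
#' @return A `cohort`: list with `subjects` (characteristics tibble),
#'   `features` (named list of subjects-by-variables tibbles, one per
#'   scenario), `latent` (the union latent table, keyed), and provenance
#'   (`spec`, `seed`).
#' @export
generate_cohort <- function(spec,
                            catalogues = lapply(
                              setNames(nm = all_scenarios()),
                              scenario_catalogue)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  union_cat <- union_catalogue(catalogues)
  keys <- union_cat$key
  scales <- latent_scales(spec, union_cat)
  C <- plant_covariance(spec, keys)
  # PSD factor for the (possibly singular, post-repair) correlation matrix
  ev <- eigen(C, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  n <- spec$n_subjects
  k <- length(keys)

  draw_one <- function(i) {
    set.seed(subject_seed(spec$seed, i, salt = 1L))
    z <- as.numeric(L %*% rnorm(k))
    if (spec$noise_sd > 0) z <- z + rnorm(k, sd = spec$noise_sd)
    scales$mean + scales$sd * z
  }
  latent <- t(vapply(seq_len(n), draw_one, numeric(k)))
  colnames(latent) <- keys
  latent <- enforce_feature_consistency(latent, union_cat)

  ids <- sprintf("S%02d", seq_len(n))
  char_vars <- names(spec$characteristic_params)
  subjects <- as_tibble(latent[, paste0(char_vars, "@scalar"), drop = FALSE])
  names(subjects) <- char_vars
  subjects <- dplyr::bind_cols(tibble(subject_id = ids), subjects)

  latent_tbl <- dplyr::bind_cols(tibble(subject_id = ids),
                                 as_tibble(as.data.frame(latent)))

  features <- purrr::imap(catalogues, function(cat, scen) {
    tab <- project_features(latent, cat, ids)
    if (grepl("^IMPA", scen)) {
      tab <- apply_impa_effect(tab, spec$impa_effect,
                               noise_sd = spec$impa_noise_sd,
                               seed = subject_seed(spec$seed, 0L, salt = 2L))
    }
    tab
  })

  structure(list(subjects = subjects, features = features,
                 latent = latent_tbl, catalogues = catalogues,
                 spec = spec, seed = spec$seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, scenarios: %s (seed %d)\n",
              nrow(x$subjects), paste(names(x$features), collapse = ", "),
              x$seed))
  invisible(x)
}

# union of scenario catalogues keyed by variable@phase, one row per latent
union_catalogue <- function(catalogues) {
  all <- dplyr::bind_rows(catalogues)
  all$key <- catalogue_keys(all)
  all <- dplyr::distinct(all, .data$key, .data$variable, .data$family,
                         .data$muscle, .data$signal, .data$aggregation,
                         .data$phase)
  if (anyDuplicated(all$key)) {
    abort("catalogues disagree on the definition of a shared variable")
  }
  all
}

# mean/sd per latent key: characteristics from the synthetic_spec, features from the
# defaults table with spec overrides; SEM -> SD uses sqrt(15), the reference
# group size behind the published scales
latent_scales <- function(spec, union_cat) {
  defs <- latent_defaults()
  over <- spec$latent_params
  cp <- spec$characteristic_params
  get <- function(key, variable) {
    if (variable %in% names(cp)) return(cp[[variable]])
    if (key %in% names(over)) return(over[[key]])
    hit <- match(key, defs$key)
    if (!is.na(hit)) return(c(defs$mean[hit], defs$sem[hit]))
    if (variable %in% c("pP_rel", "mP_rel", "minP_rel", "FI")) {
      return(c(NA_real_, NA_real_))  # derived downstream
    }
    abort(sprintf("no latent scale known for '%s'", key))
  }
  ms <- t(mapply(get, union_cat$key, union_cat$variable))
  list(mean = ifelse(is.na(ms[, 1]), 0, ms[, 1]),
       sd = ifelse(is.na(ms[, 2]), 0, ms[, 2] * sqrt(15)))
}

# deterministic relationships the extraction pipeline imposes on features
enforce_feature_consistency <- function(latent, union_cat) {
  keys <- colnames(latent)
  # 1. sort each peak/mean/min triple; the grouping stem strips the stat
  # prefix so that e.g. pP/mP/minP and pP_rel/mP_rel/minP_rel form
  # separate triples despite sharing a signal
  stat_rows <- union_cat[union_cat$aggregation %in% c("peak", "mean", "min"), ]
  stem <- sub("^(min|p|m)", "", stat_rows$variable)
  groups <- split(stat_rows, paste(stem, stat_rows$phase))
  for (grp in groups) {
    have <- c("peak", "mean", "min") %in% grp$aggregation
    if (!all(have) || nrow(grp) != 3) next
    idx <- match(grp$key[match(c("peak", "mean", "min"), grp$aggregation)],
                 keys)
    vals <- latent[, idx, drop = FALSE]
    latent[, idx] <- t(apply(vals, 1, sort, decreasing = TRUE))
  }
  # 2. clamp deltas to the feasible range of their triple
  delta_rows <- union_cat[union_cat$aggregation == "delta", ]
  for (ri in seq_len(nrow(delta_rows))) {
    row <- delta_rows[ri, ]
    peers <- union_cat[union_cat$signal == row$signal &
                         union_cat$muscle == row$muscle &
                         !is.na(union_cat$phase) &
                         union_cat$phase %in% row$phase &
                         union_cat$aggregation %in% c("peak", "min"), ]
    if (nrow(peers) != 2) next
    p <- latent[, match(peers$key[peers$aggregation == "peak"], keys)]
    mn <- latent[, match(peers$key[peers$aggregation == "min"], keys)]
    span <- p - mn
    di <- match(row$key, keys)
    latent[, di] <- pmin(pmax(latent[, di], -span), span)
  }
  # 2b. couple NIRS phases: the recovery window opens at the effort end
  # value, so its minimum cannot sit above the effort minimum (declining
  # signals) nor its peak below the effort peak (rising signals)
  nirs <- union_cat[union_cat$family == "NIRS", ]
  for (sig in unique(nirs$signal)) {
    for (mus in unique(nirs$muscle)) {
      k_e <- function(st) paste0(st, sig, "_", mus, "@effort")
      k_r <- function(st) paste0(st, sig, "_", mus, "@recovery")
      if (!all(c(k_e("min"), k_r("min"), k_e("p"), k_r("p")) %in% keys)) next
      latent[, k_r("min")] <- pmin(latent[, k_r("min")], latent[, k_e("min")])
      latent[, k_r("p")] <- pmax(latent[, k_r("p")], latent[, k_e("p")])
    }
  }
  # 2b2. NIRS phase-mean feasibility: a 0.1 Hz band-limited trace needs
  # ~5 s per transition, so within the 30 s effort window the phase mean
  # cannot sit closer than ~18% of the excursion to either extreme; over
  # the 18 min recovery the same argument leaves a ~6% margin (early dip,
  # overshoot and settling tail all consume mean budget)
  margins <- c(effort = 0.18, recovery = 0.06)
  for (phs in names(margins)) {
    nirs_ph <- nirs[!is.na(nirs$phase) & nirs$phase == phs, ]
    for (sig in unique(nirs_ph$signal)) {
      for (mus in unique(nirs_ph$muscle)) {
        sel <- nirs_ph[nirs_ph$signal == sig & nirs_ph$muscle == mus, ]
        kp <- sel$key[sel$aggregation == "peak"]
        km <- sel$key[sel$aggregation == "mean"]
        kn <- sel$key[sel$aggregation == "min"]
        if (length(kp) != 1 || length(km) != 1 || length(kn) != 1) next
        span <- latent[, kp] - latent[, kn]
        mg <- margins[[phs]]
        latent[, km] <- pmin(pmax(latent[, km], latent[, kn] + mg * span),
                             latent[, kp] - mg * span)
      }
    }
  }
  # 2c. discrete-channel mean feasibility: a series of n samples whose
  # first/last values are pinned by the delta and whose extremes are the
  # drawn peak/min cannot have an arbitrary mean — with the 10-point
  # lactate curve the floor is substantial. Clamp the mean draw into the
  # feasible interval (with half a sample's slack for the constructor).
  channel_samples <- c("lactate@recovery" = 10, "HR@effort" = 30,
                       "HR@recovery" = 1080, "SpO2@recovery" = 1080)
  for (ch in names(channel_samples)) {
    sig <- sub("@.*", "", ch)
    phs <- sub(".*@", "", ch)
    rows <- union_cat[union_cat$signal == sig & !is.na(union_cat$phase) &
                        union_cat$phase == phs, ]
    agg_key <- function(a) rows$key[rows$aggregation == a]
    if (!all(vapply(c("peak", "mean", "min"), function(a)
      length(agg_key(a)) == 1, logical(1)))) next
    n_s <- channel_samples[[ch]]
    p <- latent[, agg_key("peak")]
    mn <- latent[, agg_key("min")]
    d <- if (length(agg_key("delta")) == 1) {
      abs(latent[, agg_key("delta")])
    } else 0
    slack <- 0.5 * (p - mn) / n_s
    lo <- mn + (d + (p - mn)) / n_s + slack
    hi <- p - (d + (p - mn)) / n_s - slack
    mk <- agg_key("mean")
    latent[, mk] <- pmin(pmax(latent[, mk], lo), hi)
  }
  # 3. derived mechanics: relatives and fatigue index
  if (all(c("pP@effort", "minP@effort", "BM@scalar") %in% keys)) {
    bm <- latent[, "BM@scalar"]
    for (v in c("pP", "mP", "minP")) {
      rel <- paste0(v, "_rel@effort")
      if (rel %in% keys) latent[, rel] <- latent[, paste0(v, "@effort")] / bm
    }
    if ("FI@effort" %in% keys) {
      latent[, "FI@effort"] <-
        (latent[, "pP@effort"] - latent[, "minP@effort"]) /
        latent[, "pP@effort"] * 100
    }
  }
  # 4. characteristics and Borg scale stay in their physical ranges
  char_keys <- union_cat$key[union_cat$family == "characteristic"]
  latent[, char_keys] <- pmax(latent[, char_keys], 1e-6)
  if ("RPE@scalar" %in% keys) {
    latent[, "RPE@scalar"] <- pmin(pmax(latent[, "RPE@scalar"], 6), 20)
  }
  latent
}

project_features <- function(latent, catalogue, ids) {
  keys <- catalogue_keys(catalogue)
  tab <- latent[, keys, drop = FALSE]
  colnames(tab) <- catalogue$variable
  dplyr::bind_cols(tibble(subject_id = ids),
                   as_tibble(as.data.frame(tab)))
}

#' Inject the inspiratory-muscle pre-activation effect
#'
#' Applies per-variable multiplicative shifts to a feature table, with an
#' optional subject-level lognormal perturbation of the multiplier
#' (session-to-session variability), and re-derives relative power and the
#' fatigue index when the table carries them. Variables not named in
#' `effect` are returned bit-identical.
#'
#' @param features A subjects-by-variables tibble (with `subject_id`).
#' @param effect Named numeric vector/list of positive multipliers.
#' @param noise_sd SD of the lognormal multiplier noise (0 = deterministic).
#' @param seed Seed for the multiplier noise; required when `noise_sd > 0`.
#' @return A new feature tibble.
#' @export
apply_impa_effect <- function(features, effect, noise_sd = 0, seed = NULL) {
  effect <- unlist(effect)
  if (length(effect) == 0) return(features)
  if (any(effect <= 0)) abort("effect multipliers must be positive")
  unknown <- setdiff(names(effect), names(features))
  if (length(unknown)) {
    abort(paste0("effect names unknown variables: ",
                 paste(unknown, collapse = ", ")))
  }
  out <- features
  n <- nrow(out)
  if (noise_sd > 0) {
    if (is.null(seed)) abort("a seed is required for noisy effect injection")
    set.seed(seed)
  }
  for (v in names(effect)) {
    mult <- rep(effect[[v]], n)
    if (noise_sd > 0) mult <- mult * exp(rnorm(n, sd = noise_sd))
    out[[v]] <- out[[v]] * mult
  }
  # keep derived mechanics consistent with the shifted absolutes
  if (all(c("pP", "mP", "minP") %in% names(out))) {
    pw <- t(apply(cbind(out$pP, out$mP, out$minP), 1, sort,
                  decreasing = TRUE))
    out$pP <- pw[, 1]; out$mP <- pw[, 2]; out$minP <- pw[, 3]
    if (all(c("pP_rel", "BM") %in% names(out))) {
      out$pP_rel <- out$pP / out$BM
      out$mP_rel <- out$mP / out$BM
      out$minP_rel <- out$minP / out$BM
    }
    if ("FI" %in% names(out)) out$FI <- (out$pP - out$minP) / out$pP * 100
  }
  out
}
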