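# Synthetic raw-trace construction.
#
# Each channel is designed as a smooth piecewise template whose per-phase
# peak/mean/min/delta statistics equal the subject's latent feature values
# exactly on the sample grid. Exactness for the extremes and endpoints comes
# from mixing two envelope curves that share the positions of their extremes
# (the mix weight solves the mean); a bounded "polish" pass absorbs any
# residual mean error using the headroom between the curve and its extremes.
# Channels that the extraction pipeline low-pass filters (NIRS) are designed
# from atoms wide enough to sit below the 0.1 Hz cut-off and are then
# pre-compensated so that the *filtered* trace reproduces the design:
# iterating x <- x + F(design - F(x)) converges to F(x) = design on the
# filter's pass band.

smoothstep <- function(z) (1 - cos(pi * pmin(pmax(z, 0), 1))) / 2

# cosine bump: 0 at |u - centre| >= width/2, 1 at the centre
cos_bump <- function(u, centre, width) {
  smoothstep(1 - abs(u - centre) / (width / 2))
}

# redistribute a mean error over samples with headroom, never touching the
# extremes or endpoints, staying strictly inside [mn, p]
polish_mean <- function(x, m, p, mn, keep = integer(0), passes = 3) {
  n <- length(x)
  free <- setdiff(seq_len(n), keep)
  for (pass in seq_len(passes)) {
    err <- m - mean(x)
    if (abs(err) < 1e-12 * max(1, abs(m))) break
    head_room <- if (err > 0) p - x[free] else x[free] - mn
    w <- pmax(head_room, 0)
    if (sum(w) <= 0) break
    delta <- err * n * w / sum(w)
    delta <- sign(delta) * pmin(abs(delta), 0.9 * pmax(head_room, 0))
    x[free] <- x[free] + if (err > 0) abs(delta) else -abs(delta)
  }
  x
}

# Generic segment: from s0 to s1, maximum p attained at i_p, minimum mn at
# i_mn, mean m. Exact on the grid for unfiltered channels.
make_segment <- function(n, s0, s1, p, mn, m,
                         ramp = 0.08, i_p = 0.3, w_p = 0.16,
                         i_mn = 0.65, w_mn = 0.16) {
  if (n == 1) return(max(mn, min(p, m)))
  u <- seq(0, 1, length.out = n)
  if (p - mn < 1e-12) return(rep(p, n))
  s0 <- max(mn, min(p, s0))
  s1 <- max(mn, min(p, s1))
  m <- max(mn, min(p, m))
  ramp_up <- u < ramp
  ramp_dn <- u > 1 - ramp
  x_high <- rep(p, n)
  x_high[ramp_up] <- s0 + (p - s0) * smoothstep(u[ramp_up] / ramp)
  x_high[ramp_dn] <- s1 + (p - s1) * smoothstep((1 - u[ramp_dn]) / ramp)
  x_high <- x_high + (mn - x_high) * cos_bump(u, i_mn, w_mn)
  x_low <- rep(mn, n)
  x_low[ramp_up] <- s0 + (mn - s0) * smoothstep(u[ramp_up] / ramp)
  x_low[ramp_dn] <- s1 + (mn - s1) * smoothstep((1 - u[ramp_dn]) / ramp)
  x_low <- x_low + (p - x_low) * cos_bump(u, i_p, w_p)
  ic_p <- which.min(abs(u - i_p))
  ic_mn <- which.min(abs(u - i_mn))
  x_high[ic_p] <- p; x_low[ic_p] <- p
  x_high[ic_mn] <- mn; x_low[ic_mn] <- mn
  x_high[1] <- s0; x_low[1] <- s0
  x_high[n] <- s1; x_low[n] <- s1
  mh <- mean(x_high); ml <- mean(x_low)
  lam <- if (abs(mh - ml) < 1e-12) 0 else (mh - m) / (mh - ml)
  lam <- max(0, min(1, lam))
  x <- lam * x_low + (1 - lam) * x_high
  polish_mean(x, m, p, mn, keep = c(1L, n, ic_p, ic_mn))
}

# Effort-phase NIRS template: starts at the peak (the warm-up delivers the
# signal there), declines to the minimum and holds it to the phase end.
# The decline window adapts: when the target mean hugs one extreme, the
# transition moves toward the other end of the phase so the mean stays
# reachable by the envelope mix.
make_decline_segment <- function(n, p, mn, m) {
  u <- seq(0, 1, length.out = n)
  if (p - mn < 1e-12) return(rep(p, n))
  m <- max(mn, min(p, m))
  shape <- function(d0, d1) {
    x <- rep(p, n)
    mid <- u >= d0 & u <= d1
    x[mid] <- p + (mn - p) * smoothstep((u[mid] - d0) / (d1 - d0))
    x[u > d1] <- mn
    x
  }
  highs <- list(c(0.55, 0.8), c(0.7, 0.9), c(0.8, 0.95))
  lows <- list(c(0.05, 0.35), c(0.02, 0.2), c(0.01, 0.1))
  x_high <- NULL
  for (w in highs) {
    x_high <- shape(w[1], w[2])
    if (mean(x_high) >= m) break
  }
  x_low <- NULL
  for (w in lows) {
    x_low <- shape(w[1], w[2])
    if (mean(x_low) <= m) break
  }
  mh <- mean(x_high); ml <- mean(x_low)
  lam <- if (abs(mh - ml) < 1e-12) 0 else (mh - m) / (mh - ml)
  lam <- max(0, min(1, lam))
  x <- lam * x_low + (1 - lam) * x_high
  polish_mean(x, m, p, mn, keep = c(1L, which(u >= 0.96), n))
}

# Recovery-phase NIRS template: continues from the effort end value s0,
# dips to the recovery minimum early, rises to the (overshoot) peak and
# settles towards s1. All atoms are >= 60 s wide.
make_recovery_segment <- function(n, s0, s1, p, mn, m) {
  u <- seq(0, 1, length.out = n)
  if (p - mn < 1e-12) return(rep(p, n))
  s0 <- max(mn, min(p, s0))
  s1 <- max(mn, min(p, s1))
  m <- max(mn, min(p, m))
  # the early dip and the overshoot spike narrow (down to ~30 s on an
  # 18 min phase) when the target mean leaves little area budget
  build_high <- function(w_rise) {
    x <- rep(p, n)
    x[u <= 0.03] <- s0 + (mn - s0) * smoothstep(u[u <= 0.03] / 0.03)
    mid <- u > 0.03 & u < 0.03 + w_rise
    x[mid] <- mn + (p - mn) * smoothstep((u[mid] - 0.03) / w_rise)
    late <- u > 0.85
    x[late] <- p + (s1 - p) * smoothstep((u[late] - 0.85) / 0.15)
    x
  }
  build_low <- function(w_spk) {
    x <- rep(mn, n)
    x[u <= 0.03] <- s0 + (mn - s0) * smoothstep(u[u <= 0.03] / 0.03)
    x <- x + (p - x) * cos_bump(u, 0.45, w_spk)
    late <- u > 0.85
    x[late] <- mn + (s1 - mn) * smoothstep((u[late] - 0.85) / 0.15)
    x
  }
  x_high <- NULL
  for (w in c(0.14, 0.07, 0.03)) {
    x_high <- build_high(w)
    if (mean(x_high) >= m) break
  }
  x_low <- NULL
  for (w in c(0.2, 0.1, 0.05, 0.03)) {
    x_low <- build_low(w)
    if (mean(x_low) <= m) break
  }
  ic_p <- which.min(abs(u - 0.45))
  ic_mn <- which.min(abs(u - 0.03))
  x_high[ic_p] <- p; x_low[ic_p] <- p
  x_high[ic_mn] <- mn; x_low[ic_mn] <- mn
  x_high[1] <- s0; x_low[1] <- s0
  x_high[n] <- s1; x_low[n] <- s1
  mh <- mean(x_high); ml <- mean(x_low)
  lam <- if (abs(mh - ml) < 1e-12) 0 else (mh - m) / (mh - ml)
  lam <- max(0, min(1, lam))
  x <- lam * x_low + (1 - lam) * x_high
  polish_mean(x, m, p, mn, keep = c(1L, n, ic_p, ic_mn))
}

# endpoints for a segment that must satisfy last - first = delta within
# [mn, p]: the first value is placed inside its feasible interval at the
# target mean's relative position, so segments with means near an extreme
# keep enough area budget to reach it
delta_endpoints <- function(p, mn, delta, m = (p + mn) / 2) {
  delta <- max(-(p - mn), min(p - mn, delta))
  lo <- mn + max(0, -delta)
  hi <- p - max(0, delta)
  frac <- if (p - mn < 1e-12) 0.5 else (m - mn) / (p - mn)
  f0 <- lo + max(0, min(1, frac)) * (hi - lo)
  c(first = f0, last = f0 + delta)
}

# protocol timeline (seconds)
protocol_phases <- function() {
  list(baseline = c(0, 180), warmup = c(180, 780),
       effort = c(780, 810), recovery = c(810, 1890))
}

nirs_rest_levels <- function() {
  c(O2Hb = 25, HHb = 15, tHb = 40, TSI_BB = 66.1, TSI_VL = 73.7)
}

# which end of the effort excursion sits at the phase start
nirs_direction <- function(signal) {
  if (signal %in% c("HHb")) "rise" else "decline"
}

#' Generate raw signal traces for a synthetic cohort
#'
#' Builds, per subject, the full protocol timeline (3 min seated baseline,
#' 10 min warm-up and pre-effort interval, 30 s all-out effort, 18 min
#' recovery) for every channel: the eight NIRS series at 10 Hz, heart rate
#' and pulse-oximetry saturation at 1 Hz, force and velocity at 1000 Hz
#' during the effort, and the sparse capillary-lactate samples (one at rest,
#' then one immediately post-effort and every 2 min up to 18 min — 10
#' recovery samples). Traces are constructed so that running the feature
#' extraction pipeline on them (with the same filter settings) recovers the
#' cohort's latent feature values; with `trace_noise_sd = 0` the agreement
#' is within 1%.
#'
#' @param cohort A [generate_cohort()] result.
#' @param session `"control"` (realises the AO30 + RECOVERY features) or
#'   `"impa"` (the pre-activated scenarios).
#' @param subjects Subject ids to build (default all).
#' @param filter [filter_params()] the downstream extraction will use; the
#'   NIRS pre-compensation targets this filter.
#' @return Named list (by subject id) of named lists of [signal_trace()]
#'   objects: `O2Hb_BB`, ..., `TSI_VL`, `HR`, `SpO2`, `lactate`, `force`,
#'   `velocity`.
#' @export
generate_raw_traces <- function(cohort, session = c("control", "impa"),
                                subjects = NULL,
                                filter = filter_params()) {
  session <- match.arg(session)
  scen_ex <- if (session == "control") "AO30" else "IMPA_AO30"
  scen_rec <- if (session == "control") "RECOVERY" else "IMPA_RECOVERY"
  feats_ex <- cohort$features[[scen_ex]]
  feats_rec <- cohort$features[[scen_rec]]
  if (is.null(feats_ex) || is.null(feats_rec)) {
    abort(sprintf("cohort lacks the %s/%s scenario features",
                  scen_ex, scen_rec))
  }
  ids <- subjects %||% cohort$subjects$subject_id
  bad <- setdiff(ids, cohort$subjects$subject_id)
  if (length(bad)) {
    abort(paste0("unknown subjects: ", paste(bad, collapse = ", ")))
  }
  fs_nirs <- 10
  sos <- butter_sos(filter$order, filter$cutoff_hz / (fs_nirs / 2))
  out <- lapply(ids, function(id) {
    i <- match(id, cohort$subjects$subject_id)
    ex <- as.list(feats_ex[i, ])
    rec <- as.list(feats_rec[i, ])
    build_subject_traces(ex, rec, sos,
                         noise_sd = cohort$spec$trace_noise_sd,
                         noise_seed = subject_seed(cohort$seed, i,
                                                   salt = 3L +
                                                     (session == "impa")))
  })
  names(out) <- ids
  out
}

build_subject_traces <- function(ex, rec, sos, noise_sd, noise_seed) {
  ph <- protocol_phases()
  rest <- nirs_rest_levels()
  traces <- list()
  set.seed(noise_seed)

  # ---- NIRS channels (10 Hz, filtered downstream) --------------------
  fs <- 10
  t_all <- seq(0, 1890 - 1 / fs, by = 1 / fs)
  n_of <- function(iv) round((iv[2] - iv[1]) * fs)
  for (muscle in c("BB", "VL")) {
    for (sig in c("O2Hb", "HHb", "tHb", "TSI")) {
      chan <- paste0(sig, "_", muscle)
      rest_level <- if (sig == "TSI") rest[[paste0("TSI_", muscle)]] else 0
      p_e <- ex[[paste0("p", sig, "_", muscle)]]
      m_e <- ex[[paste0("m", sig, "_", muscle)]]
      mn_e <- ex[[paste0("min", sig, "_", muscle)]]
      p_r <- rec[[paste0("p", sig, "_", muscle)]]
      m_r <- rec[[paste0("m", sig, "_", muscle)]]
      mn_r <- rec[[paste0("min", sig, "_", muscle)]]
      dirn <- nirs_direction(sig)
      x <- build_nirs_channel(
        targets = c(p_e = p_e, m_e = m_e, mn_e = mn_e,
                    p_r = p_r, m_r = m_r, mn_r = mn_r),
        rest_level = rest_level, dirn = dirn, ph = ph, fs = fs, sos = sos)
      if (noise_sd > 0) x <- x + rnorm(length(x), sd = noise_sd)
      traces[[chan]] <- signal_trace(t_all, x, channel = chan,
                                     muscle = muscle, fs = fs, phases = ph)
    }
  }

  traces <- c(traces, build_unfiltered_traces(ex, rec, ph))
  traces
}

# Filtered channels cannot realise arbitrary per-phase statistics exactly:
# the 30 s effort window holds only a handful of degrees of freedom below a
# 0.1 Hz cut-off, and energy leaks across phase boundaries. The constructor
# therefore closes the loop on the *filtered* trace: it measures the
# statistics the extraction pipeline would see and shifts the design
# targets by the residual until the extracted values match the latent ones
# (a fixed-point iteration; the stat map is close to the identity, so a
# few steps suffice).
build_nirs_channel <- function(targets, rest_level, dirn, ph, fs, sos,
                               max_iter = 20) {
  n_of <- function(iv) round((iv[2] - iv[1]) * fs)
  n_eff <- n_of(ph$effort)
  n_rec <- n_of(ph$recovery)
  idx_eff <- n_of(ph$baseline) + n_of(ph$warmup) + seq_len(n_eff)
  idx_rec <- max(idx_eff) + seq_len(n_rec)
  range_scale <- max(targets["p_r"], targets["p_e"]) -
    min(targets["mn_r"], targets["mn_e"])
  tol <- max(5e-4 * range_scale, 1e-9)

  build <- function(d) {
    eps <- 1e-6 * max(1, range_scale)
    d["p_e"] <- max(d["p_e"], d["mn_e"] + eps)
    d["m_e"] <- min(max(d["m_e"], d["mn_e"]), d["p_e"])
    d["p_r"] <- max(d["p_r"], d["mn_r"] + eps)
    d["m_r"] <- min(max(d["m_r"], d["mn_r"]), d["p_r"])
    eff <- if (dirn == "decline") {
      make_decline_segment(n_eff, d[["p_e"]], d[["mn_e"]], d[["m_e"]])
    } else {
      -make_decline_segment(n_eff, -d[["mn_e"]], -d[["p_e"]], -d[["m_e"]])
    }
    s0_rec <- max(d[["mn_r"]], min(d[["p_r"]], eff[n_eff]))
    s1_rec <- max(d[["mn_r"]], min(d[["p_r"]], rest_level))
    rec_seg <- make_recovery_segment(n_rec, s0_rec, s1_rec,
                                     d[["p_r"]], d[["mn_r"]], d[["m_r"]])
    uw <- seq(0, 1, length.out = n_of(ph$warmup))
    warm <- rest_level + (eff[1] - rest_level) * smoothstep(pmin(uw / 0.8, 1))
    c(rep(rest_level, n_of(ph$baseline)), warm, eff, rec_seg)
  }
  precompensate <- function(design, iters) {
    x <- design
    for (it in seq_len(iters)) {
      r <- design - filtfilt_zero_phase(sos, x)
      x <- x + filtfilt_zero_phase(sos, r)
    }
    x
  }
  stats_of <- function(x) {
    xf <- filtfilt_zero_phase(sos, x)
    c(p_e = max(xf[idx_eff]), m_e = mean(xf[idx_eff]),
      mn_e = min(xf[idx_eff]),
      p_r = max(xf[idx_rec]), m_r = mean(xf[idx_rec]),
      mn_r = min(xf[idx_rec]))
  }
  d <- targets
  best_d <- d
  best_err <- Inf
  x <- precompensate(build(d), 4)
  for (it in seq_len(max_iter)) {
    s <- stats_of(x)
    err <- targets - s
    if (max(abs(err)) < best_err) {
      best_err <- max(abs(err))
      best_d <- d
    }
    if (max(abs(err)) < tol) break
    # per-component gains: the filtered extremes respond with slope < 1
    # (the filter shaves what the shift adds), the means almost exactly;
    # the adaptive widths make the map only piecewise smooth, so the mean
    # update stays damped
    gain <- c(p_e = 1.4, m_e = 0.8, mn_e = 1.4,
              p_r = 1.2, m_r = 0.8, mn_r = 1.2)
    d <- d + gain[names(d)] * err
    x <- precompensate(build(d), 4)
  }
  precompensate(build(best_d), 8)
}

build_unfiltered_traces <- function(ex, rec, ph) {
  traces <- list()
  t_hr <- seq(0, 1889, by = 1)
  # ---- heart rate (1 Hz, unfiltered) ---------------------------------
  t_hr <- seq(0, 1889, by = 1)
  hr_rest <- rec$restHR
  ep_e <- delta_endpoints(ex$pHR, ex$minHR, ex$DHR, ex$mHR)
  eff_hr <- make_segment(30, ep_e["first"], ep_e["last"],
                         ex$pHR, ex$minHR, ex$mHR,
                         ramp = 0.1, i_p = 0.75, w_p = 0.2,
                         i_mn = 0.25, w_mn = 0.2)
  ep_r <- delta_endpoints(rec$pHR, rec$minHR, rec$DHR, rec$mHR)
  rec_hr <- make_segment(1080, ep_r["first"], ep_r["last"],
                         rec$pHR, rec$minHR, rec$mHR,
                         ramp = 0.04, i_p = 0.1, w_p = 0.1,
                         i_mn = 0.7, w_mn = 0.2)
  warm_hr <- hr_rest + (eff_hr[1] - hr_rest) *
    smoothstep(seq(0, 1, length.out = 600))
  hr <- c(rep(hr_rest, 180), warm_hr, eff_hr, rec_hr)
  traces$HR <- signal_trace(t_hr, hr, channel = "HR", fs = 1, phases = ph)

  # ---- pulse oximetry (1 Hz, unfiltered) -----------------------------
  spo2_rest <- rec$restSpO2
  ep_s <- delta_endpoints(rec$pSpO2, rec$minSpO2, rec$DSpO2, rec$mSpO2)
  rec_sp <- make_segment(1080, ep_s["first"], ep_s["last"],
                         rec$pSpO2, rec$minSpO2, rec$mSpO2,
                         ramp = 0.04, i_p = 0.6, w_p = 0.2,
                         i_mn = 0.1, w_mn = 0.12)
  spo2 <- c(rep(spo2_rest, 810), rec_sp)
  traces$SpO2 <- signal_trace(t_hr, spo2, channel = "SpO2", fs = 1,
                              phases = ph)

  # ---- capillary lactate (sparse samples) ----------------------------
  ep_l <- delta_endpoints(rec$pLac, rec$minLac, rec$DLac, rec$mLac)
  lac_rec <- make_segment(10, ep_l["first"], ep_l["last"],
                          rec$pLac, rec$minLac, rec$mLac,
                          ramp = 0.01, i_p = 4 / 9, w_p = 0.25,
                          i_mn = 8 / 9, w_mn = 0.2)
  lac_t <- c(90, 810 + seq(0, 1080, by = 120))
  lac_ph <- ph
  lac_ph$recovery <- c(810, 1891)  # include the 18-min sample
  traces$lactate <- signal_trace(lac_t, c(rec$restLac, lac_rec),
                                 channel = "lactate", phases = lac_ph)

  # ---- force & velocity (1000 Hz over the 30 s effort) ---------------
  fs_m <- 1000
  t_m <- seq(780, 810 - 1 / fs_m, by = 1 / fs_m)
  pw <- make_segment(length(t_m), 0.85 * ex$pP, ex$minP,
                     ex$pP, ex$minP, ex$mP,
                     ramp = 0.03, i_p = 0.1, w_p = 0.15,
                     i_mn = 0.8, w_mn = 0.2)
  ratio <- 40  # N per (m/s): force/velocity split of the power product
  traces$force <- signal_trace(t_m, sqrt(pw * ratio), channel = "force",
                               fs = fs_m, phases = ph["effort"])
  traces$velocity <- signal_trace(t_m, sqrt(pw / ratio), channel = "velocity",
                                  fs = fs_m, phases = ph["effort"])
  traces
}

#' Extract the feature table of a whole cohort from its raw traces
#'
#' Convenience wrapper running [extract_features()] per subject with the
#' subject's characteristics (and RPE, for exercise scenarios) as scalars.
#'
#' @param traces Result of [generate_raw_traces()].
#' @param cohort The cohort the traces came from.
#' @param catalogue Scenario catalogue to extract.
#' @param filter [filter_params()] for the NIRS channels.
#' @return A subjects-by-variables tibble with `subject_id`.
#' @export
extract_cohort_features <- function(traces, cohort, catalogue,
                                    filter = filter_params()) {
  scen <- catalogue$scenario[1]
  rows <- purrr::map(names(traces), function(id) {
    i <- match(id, cohort$subjects$subject_id)
    scalars <- as.list(cohort$subjects[i, -1])
    if ("RPE" %in% catalogue$variable) {
      scalars$RPE <- cohort$features[[scen]]$RPE[i]
    }
    extract_features(traces[[id]], catalogue, filter, scalars = scalars)
  })
  dplyr::bind_cols(tibble(subject_id = names(traces)),
                   dplyr::bind_rows(rows))
}
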