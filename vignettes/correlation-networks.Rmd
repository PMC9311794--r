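---
title: "Correlation networks of exercise physiology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation networks of exercise physiology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiograph)
```

This vignette is the package's account of its science: the model it
implements, the parameters that matter, what the synthetic data do and do
not emulate, and the numerical and design choices behind the code. The
worked numbers shown in the README are produced by the code there; this
document states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The analysis model

The object of study is the *interplay* of physiological variables during
and after a 30 s all-out tethered sprint, with and without
inspiratory-muscle pre-activation (IM_PA). Instead of comparing variables
one at a time, each experimental scenario is represented as an undirected
weighted graph over a fixed variable universe:

* exercise scenarios use 46 variables, recovery scenarios 52
  (`scenario_catalogue()`);
* an edge joins variables *i, j* when their Pearson correlation across
  subjects is significant at `alpha` (default 0.05), with the two-sided
  p-value from `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom;
* the edge weight is `|r|`; the sign is kept as the `signed_r` attribute.

Assumptions worth making explicit:

* **Linearity.** Pearson correlation captures linear association only;
  the network is blind to non-monotone coupling.
* **Marginal gating, no multiplicity correction.** With 46 variables there
  are 1035 pairs; at `alpha = 0.05` a null cohort yields ~5% spurious
  edges by construction. This is deliberate — the method treats the
  marginal `p <= 0.05` rule as part of its definition — and it is exactly
  what the null-calibration check in the acceptance script measures. Users
  who want family-wise control can lower `alpha`, at the cost of changing
  the method.
* **Small n.** At n = 15 the gate sits at `|r| >= critical_r(15)` ≈ 0.514;
  individual edges are noisy, which is why the package's claims are about
  calibration and recovery rates over replicates, never about a single
  cohort's edge list.

### Edge weights and centralities

Centrality algorithms need nonnegative weights, and the graph tool this
literature uses (Gephi) expects a positive `weight` attribute, so the
weight is `|r|` with the sign preserved separately. Four metrics are
implemented from scratch (`degree_centrality()`,
`betweenness_centrality()`, `eigenvector_centrality()`, `pagerank()`) with
Gephi-compatible conventions as defaults, each switchable in
`centrality_params()`:

| parameter | default | why |
| --- | --- | --- |
| `betweenness_normalized` | `TRUE` | divide by `(V-1)(V-2)/2`; printed betweenness values of order 0.1 on 46-node graphs are only consistent with normalization |
| `betweenness_weighted` | `FALSE` | unweighted shortest paths; weighted mode uses distance `1/weight` (a stronger correlation is a shorter path); `1 - |r|` is a defensible alternative the code does not default to |
| `eigenvector_iterations` | 100 | the conventional fixed iteration count |
| `pagerank_damping` | 0.85 | the standard damping factor |
| `pagerank_epsilon` | 0.001 | reporting convergence; tests tighten it to `1e-12` when comparing against exact solves |
| `*_weighted` | `FALSE` | unweighted topology by default |

Two implementation details depart from the naive textbook loop:

* **Eigenvector centrality iterates on `A + I`.** Plain power iteration on
  a bipartite adjacency (every star graph is bipartite) oscillates between
  two vectors and never converges. Adding the identity shifts all
  eigenvalues by +1 without changing eigenvectors, making the Perron root
  strictly dominant so the iteration converges on every graph. Results are
  max-normalized (largest value exactly 1); isolated nodes get 0.
* **PageRank treats isolated nodes as dangling**, redistributing their
  probability uniformly, so the vector sums to 1 on any graph.

Every metric has an independent oracle (`oracle_suite()`, graphs of at
most 9 nodes): betweenness by exhaustive simple-path enumeration,
eigenvector by dense eigendecomposition — with the uniform start vector
projected onto the dominant eigenspace, which is the power-iteration limit
and settles the degenerate case of tied disconnected components — and
PageRank by solving the stationarity equations directly. The test suite
and the acceptance script sweep random small graphs against these oracles
at `1e-6`.

### Tie-aware top-5 tables

Reported centrality values are rounded to `round_decimals = 3` (the
display precision of this literature's metric tables); nodes whose rounded
values coincide share a dense rank, and the "top-5" table returns *all*
nodes with dense rank ≤ 5 — often far more than five nodes, especially
for integer-valued degree. The rounding threshold is the package's
interpretation of "similar results" for ties, and it is exposed as a
parameter because the original choice is not documented anywhere.

## 2. Signal processing

NIRS channels are smoothed with a low-pass Butterworth filter
(`filter_params()`: order 10, cut-off 0.1 Hz) applied forward and backward
(zero net phase). "10th-order zero-phase" is read literally: a 10th-order
design applied twice, so the effective magnitude response is squared
(order 20 in magnitude). Hemoglobin-species channels are then referenced
to the mean of the final 30 s of the 3 min baseline and analysed as
deltas; TSI stays in absolute percent (consistent with how resting TSI is
reported as an absolute percentage). Phase summaries (peak, mean, min,
delta = last − first sample) use half-open windows `[start, end)` with
timestamps at the left edge of the sampling interval.

Numerical choices:

* **Biquad cascade, not transfer-function form.** At 0.1 Hz on a 10 Hz
  signal the normalized cut-off is 0.02 and all ten poles crowd near
  `z = 1`; the expanded polynomial coefficients lose about eight digits
  and the nominal DC gain of the `b, a` form is visibly wrong (~0.978).
  The filter is therefore designed in zero-pole-gain form (analog
  Butterworth prototype, bilinear transform) and applied as second-order
  sections, which keeps the DC gain exact to machine precision.
* **Edge handling.** Odd-reflection padding with exact steady-state
  initial conditions per section. The padding length scales with the
  slowest pole's time constant (`-1/log r`, ~100 samples here, padded to
  transient decay below `1e-13`); a fixed short pad would let edge
  transients leak hundreds of samples into the signal and break the
  zero-phase reverse symmetry that the tests assert at `1e-9`.
* **Reflect-padding limits.** Any reflect-padded zero-phase filter
  produces an edge artifact proportional to the gap between the signal's
  endpoint value and its local mean. Physiological traces that begin and
  end at a settled level (as the protocol's baseline and late recovery do)
  are unaffected; the tone-rejection test uses a sine with an integer
  number of periods for the same reason.

Sprint power is the sample-wise product of towing force and velocity at
1000 Hz, deliberately unsmoothed before peak extraction (no smoothing of
the mechanical chain is described in this literature; an optional window
would bias the peak). The minimum is taken over the whole 30 s effort.
`FI = (pP - minP)/pP * 100`.

## 3. The synthetic cohort generator

The generator's role is to make every downstream stage testable without
access to any study's raw data. It is a statistical emulator, not a
physiological model:

* **Latent model.** Features are drawn from a multivariate normal whose
  correlation matrix is assembled from equicorrelated blocks and
  hub-and-spoke stars (`plant_covariance()`). A Gaussian copula matches
  the analysis's own assumptions (Pearson correlation), which makes
  parameter recovery well-posed. Published group means anchor the scales;
  SEM × √15 converts published standard errors (n = 15 groups) to
  sampling SDs.
* **Defaults are the study conditions.** 15 subjects; characteristics
  23 ± 1 y, 1.77 ± 0.02 m, 73.2 ± 2.0 kg, 6.5 ± 0.5 %BF, MIP
  144.3 ± 10.2, S-Index 123.7 ± 3.7 (mean ± SEM); mechanical and
  physiological scales from the published control-session table (e.g.
  pP 2296.7 ± 126.3 W, mP 1706.9 ± 104.7 W, peak lactate 17.2 ± 0.6 mM,
  post-effort TSI minima 32.2/50.1%). NIRS delta magnitudes, for which no
  table values exist, are plausible arbitrary-unit choices with the more
  active vastus lateralis desaturating more than the biceps brachii.
* **Planted structure.** Stat triples of one signal correlate at 0.75,
  all NIRS summaries within a muscle-phase at 0.45, absolute power at
  0.85, systemic triples at 0.7, and peak lactate acts as a hub (r = 0.35)
  into the mean reoxygenation responses — echoing the centrality of peak
  lactate this literature reports. The assembled matrix is slightly
  non-PSD under the max-combination rule; it is repaired by eigenvalue
  clipping with a warning, and the repair is bounded (no planted entry may
  move by more than 0.05, or generation errors).
* **IM_PA effect.** The pre-activated scenarios are the control draws
  with multiplicative shifts on absolute power equal to the published
  group-mean ratios (pP ×1.089, mP ×1.110, minP ×1.134), a subject-level
  lognormal multiplier noise (sd 0.08, representing session-to-session
  variability smaller than the between-subject spread), and re-derived
  relative power and fatigue index. Physiological variables are left
  unshifted, matching the observation that conventional tests found no
  effect there.
* **Determinism.** One master seed; each subject's stream is derived by a
  fixed offset, so subject *i*'s data are invariant to cohort size.

### Enforced consistency

The extraction pipeline imposes deterministic relationships that
independent latent draws would violate, so after the draw the generator
enforces: peak ≥ mean ≥ min within every stat triple (sorted per
subject); deltas clamped to `[-(peak-min), peak-min]`; relative power
= absolute/body mass and FI from pP and minP (derived, not drawn);
recovery NIRS extremes consistent with the effort phase they continue
from; and phase means kept a feasibility margin away from the extremes —
18% of the excursion in the 30 s effort window, 6% in the 18 min
recovery, and the sample-count bound for the sparse channels (a 10-point
lactate curve with pinned endpoints and extremes simply cannot attain an
arbitrary mean). These clamps perturb the planted marginals only in the
tails; the planted-correlation recovery test (n = 500, tolerance 0.05)
measures the net effect.

### Trace synthesis and the round-trip contract

`generate_raw_traces()` builds the full protocol timeline (3 min baseline,
10 min warm-up/pre-effort interval, 30 s effort, 18 min recovery; NIRS at
10 Hz, HR and SpO₂ at 1 Hz, force/velocity at 1000 Hz, lactate sampled at
rest and then every 2 min through recovery — one rest plus ten recovery
samples). Unfiltered channels realise their latent statistics exactly on
the sample grid by mixing two envelope curves that share the positions of
their extremes (the mix weight solves the mean, a bounded polish pass
absorbs the residual). Filtered (NIRS) channels cannot realise arbitrary
statistics — a 30 s window holds only a handful of degrees of freedom
below a 0.1 Hz cut-off — so the constructor closes the loop on the
*filtered* trace: designs are built from atoms wide enough to sit in the
pass band, pre-compensated (`x <- x + F(design - F(x))`, which converges
to `F(x) = design` in-band), and the design targets are shifted by the
measured extraction residual until the pipeline's output matches the
latent values.

The round-trip contract — extraction on zero-noise traces reproduces the
latent features within 1% — is asserted with the latent value's magnitude
as the denominator, floored by the channel-phase dynamic range for the
near-zero arbitrary-unit NIRS variables (a 0.3 a.u. peak inside a
20 a.u. excursion is "recovered" in any meaningful sense when the error is
well under 1% of the excursion). White noise (`trace_noise_sd`, default
0.3 a.u.) can be added on top so the filter has something to remove; the
round-trip contract is stated for the noiseless limit.

What the generator does **not** emulate: lactate kinetics or any
mechanistic IM_PA physiology; motion artifacts, adipose-tissue effects or
device drift in NIRS; non-Gaussian marginals; coupling between subject
characteristics and responses (characteristics are independent by
default — whether they correlate with responses in real cohorts is
unknown, and independence is an assumption, not a claim; `hub_specs` can
couple them). Passing tests therefore demonstrate that the *pipeline* is
correct and calibrated, not that real physiology behaves like the
emulator.

## 4. Node universes

The 46-variable exercise catalogue is pinned: 6 characteristics + 7
mechanical + 9 systemic (peak/mean/delta lactate, peak/mean/min/delta HR,
delta SpO₂, RPE) + 24 NIRS (2 muscles × 4 signals × peak/mean/min). The
52-variable recovery catalogue keeps the characteristics, mechanics and
NIRS families (recovery phase) and expands the systemic family to 15
(rest/peak/mean/min/delta for lactate, HR and SpO₂); its exact composition
is not documented in the source literature, so it is configuration — the
counts are pinned, the composition is overridable, and
`validate_catalogue()` warns (never errors) when a custom universe
deviates from 46/52.

"Rest" values are encoded as the mean over the baseline phase, keeping
the aggregation vocabulary to peak/mean/min/delta/scalar. Delta variables
are last − first sample of their phase; window-averaged endpoints would be
a defensible alternative and can be built from `phase_summary()` output.

## 5. Degenerate inputs and tie-breaks

* Zero-variance variables and pairs with fewer than 3 complete
  observations have undefined correlations: flagged with a warning,
  treated as "no edge", never coerced to 0.
* `|r| = 1` maps to `p = 0` exactly.
* Node order is the catalogue order everywhere (adjacency construction,
  iteration order, reports), so outputs are deterministic; ranking ties
  are broken by node name only in display order, never in rank.
* An edgeless graph errors for eigenvector centrality (undefined) but
  returns `NA` in the tidy `centrality()` table so pipelines degrade
  gracefully; a failing scenario inside `run_pipeline()` is isolated and
  reported without aborting the other scenarios.
* Identical paired samples give t = 0, p = 1; a nonzero constant paired
  difference (zero variance, nonzero mean) errors.

## 6. Problem sizes

The shipped checks run at the sizes the methodology needs rather than the
largest sizes imaginable: null calibration at 200 replicate 15 × 46
cohorts; hub recovery at 200 replicates of the r = 0.8, 8-spoke planted
star; effect detection at 500 paired replicates; oracle sweeps over ≥ 50
random graphs of ≤ 9 nodes; round-trips on single synthetic subjects
(a full-timeline subject is ~19k NIRS samples per channel plus 30k
mechanical samples, and the closed-loop constructor dominates the cost).

## 7. Known limitations

* Pairwise-complete correlation matrices are not guaranteed PSD under
  missingness; the graph gate uses each pair's own test and is unaffected,
  but downstream consumers of `correlation_matrices()` should know.
* Weighted betweenness uses exact tie detection on path lengths with a
  relative tolerance; adversarial weight sets could split true ties.
* The trace synthesiser guarantees the round-trip contract for the
  latent ranges its defaults produce; extreme user-supplied scales (e.g.
  a mean forced against an extreme beyond the feasibility clamps) degrade
  gracefully via the best-iterate fallback but may exceed 1%.
* Edge counts of synthetic cohorts are emergent (planted structure +
  calibrated type-I rate), not calibrated to any published study's counts
  — those depend on the unpublished raw data.
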