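---
title: "Methods: movement classification and route demarcation in flywayr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement classification and route demarcation in flywayr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`flywayr` detects common long-distance movement routes of nomadic
waterbirds from GPS telemetry. This vignette documents the models and
procedures the package implements, the tunable parameters and their
defaults, the synthetic world used for testing, and the numerical and
design choices a maintainer should know about.

## 1. From fixes to daily displacement lines

The observational unit is a *daily displacement line*: the great-circle
segment between a bird's positions at consecutive species-specific 24-hour
anchors. Diurnal movers that roost overnight are anchored at local
midnight, nocturnal movers at local midday, so each line captures one
day's net displacement rather than within-day foraging structure.

Conventions the package fixes (none of which follow automatically from the
daily-line idea, so each is configurable):

- **Anchor selection.** The fix nearest the anchor instant within a
  tolerance window (`tolerance_h`, default ±3 h) becomes the day's anchor;
  a day with no qualifying fix is an explicit missing record. Dates run
  contiguously from the first to the last anchored day, so gaps are
  visible to the movement model rather than silently spliced.
- **Timezone.** One configurable UTC offset per dataset (`tz_offset_h`,
  default +10) defines "local midnight". Shifting all timestamps by +12 h
  and switching the anchor from midnight to midday leaves the step-length
  sequence unchanged (a tested invariance).
- **Distances.** Haversine on a sphere of mean radius 6371.0088 km; step
  lengths in km, turning angles as the signed change of great-circle
  bearing wrapped to (-pi, pi]. No position interpolation is ever applied
  across missing days.
- **Post-dispersal filter.** Birds enter the analysis only with strictly
  more than `min_days` (default 30) days of data after their dispersal
  date. If no dispersal date is recorded it is inferred as the first day
  whose mean position lies more than `dispersal_radius_km` (default 10 km,
  the residency radius) from the capture site; birds with neither a date
  nor locatable capture site are excluded with a warning.

## 2. The movement HMM

Daily lines are classified with an N-state hidden Markov model. State
\(j\) emits a step length from a gamma distribution parameterised by mean
and standard deviation (\(\mathrm{shape} = \mu^2/\sigma^2\),
\(\mathrm{rate} = \mu/\sigma^2\)), optionally mixed with a point mass at
zero (estimated only when zero steps occur, since the gamma has no support
at 0), and a turning angle from a von Mises distribution with mean
\(\mu_j\) and concentration \(\kappa_j \ge 0\). Missing days contribute an
emission vector of ones, which preserves the transition structure across
gaps; a missing turning angle (always the case on the first observed step)
contributes nothing.

**Likelihood and fitting.** The log likelihood is computed by the scaled
forward recursion (in C++), summed over birds; it is verified in the test
suite against exhaustive path enumeration on small instances. Maximisation
is quasi-Newton (L-BFGS-B) on unconstrained working parameters: log
transforms for the gamma moments, the pair
\((\kappa\cos\mu, \kappa\sin\mu)\) for each angle distribution, and
row-wise multinomial logits for the initial and transition distributions.
Bounds of ±15 on the logits (±30 on the angle pair, [-7, 12] on the log
moments) prevent runaway excursions when a transition probability tends to
zero; up to `maxit` (500) iterations per restart. Free-parameter count is
\((N-1) + N(N-1) + 2N + 2N\) (+N with estimated zero mass), and
\(\mathrm{AIC} = -2\log L + 2p\) exactly.

**Random restarts.** Each of `n_restarts` (default 6) runs draws step
means log-uniformly between the 5th and 95th percentiles of the observed
steps (SDs equal to means), \(\kappa\) uniform on [0.5, 3], and transition
rows from a Dirichlet with weight 5 on the diagonal; the best run is kept.
The mean draws are *stratified* — one draw per equal interval of the log
range — because movement data are dominated by short steps: unstratified
draws frequently start every mean low, merge the short classes and leave
the fit in a poor local optimum that an extra spurious state can then
"repair", biasing AIC towards too many states. Fits are deterministic
given seed and data, and states are relabelled in ascending step-mean
order afterwards.

**Model choice and decoding.** `aic_sweep()` fits each candidate state
count (default 2–6) and selects the minimum AIC, ties going to fewer
states. `viterbi_decode()` computes the global most-likely path in log
space, ties toward the lower state index; missing days are bridged by
transition-only steps and carry no state. The state with the largest mean
step is *the* long-distance class, and its decoded lines are the input to
route demarcation. The comparison classifier takes lines strictly longer
than the pooled median + 2 sample SD (n−1 denominator) of all observed
lines of the species.

**Pooling.** The pipeline default fits one model per species with per-bird
log likelihoods summed. Per-bird fitting (`by_bird = TRUE`) is available;
pooling is the default because the synthetic datasets (and most small
deployments) are too short for 30–50 free parameters per bird.

## 3. Route demarcation by kernel utilization distribution

Long-distance lines are discretised at fixed 10 km arc-length spacing
(both endpoints always included, so a line of length \(L\) yields
\(\lfloor L/s\rfloor + 1\) points), projected into a local Lambert
azimuthal equal-area plane (km) centred on the point centroid, and
smoothed with an isotropic bivariate Gaussian kernel using the ad hoc
reference bandwidth \(h_{\mathrm{ref}} = \sqrt{(s_x^2+s_y^2)/2}\,
n^{-1/6}\). The density is evaluated on a regular grid — cell size
\(h/4\) by default, bounding box padded by half its span and at least
\(3h\) — and renormalised to integrate to exactly 1 on the grid.

Contours are *mass*-defined: for level \(L\) the density threshold is the
smallest value whose super-level set holds at least \(L\%\) of the mass.
This guarantees nesting across the conventional 95/90/80/70/60/50 levels
and makes the contained mass (not the density value) the reported
quantity. The super-level set is kept as a grid mask — the unit of all
membership, representativeness, overlap and zonal computations — and
polygonised by marching squares (`grDevices::contourLines`) for GeoJSON
output. Overlap between two routes is evaluated by testing each region's
cell centres for membership in the other, so regions on different grids or
projection centres compare correctly.

The href sensitivity table rebuilds the KED50 under the conventional
variant set (70% of the minimum per-individual href, mean and median
per-individual href, and 30/50/70% of the global value) and reports each
bandwidth, KED50 area and the proportion of sampled points inside.

## 4. Habitat and climate comparison

Use-versus-availability is computed on raster cells (cell-centre
membership; no area weighting): the covariate distribution inside the
KED50 against the distribution inside the bounding box of the species'
movements. Continuous rasters are quantile-binned — 9 bins by default,
with the reference region selectable between the bounding box
(elevation-style) and the full raster (rainfall-style deciles). A Pearson
chi-square goodness of fit compares used counts against background
proportions (df = bins − 1; a bin used but absent from the background
makes the statistic infinite rather than erroring). Bins are flagged
over-/under-represented at a relative difference of `flag_threshold`
(default 20%) — "substantial" selection or avoidance is not an estimated
quantity here, so the threshold is an explicit, documented configuration.

## 5. The synthetic world

The generator exists so that every stage has inputs with the statistical
structure the analysis assumes. Its defaults are the stated world of the
package's tests:

- **Movement presets.** SNI-like: 5 states, four short classes with means
  0.3–2.7 km and a long-distance class of mean 48 km, SD 71 km. RSB-like:
  6 states, five short classes under 4 km and a long class of 43 ± 73 km.
  Short states are sticky (0.85 self-transition) with a 4% daily chance of
  entering the long-distance state, which persists at 0.30 — so flights
  punctuate multi-day residency and the long state has a stationary
  probability near 5%.
- **Corridor orientation.** On long-distance days the heading is redrawn
  von Mises around the local corridor bearing (concentration 5), directed
  towards the farther corridor end so tracks shuttle along the ~900 km
  SW–NE axis; birds beyond the 100 km corridor buffer re-aim at the axis.
  Short-distance days follow the plain turning-angle process, so residency
  locales drift slowly around the endpoint of the last flight — the
  marginal step and angle distributions stay exactly the configured state
  distributions, which the moment-recovery tests require. Passing
  `corridor = NULL` gives a pure, isotropic realisation of the HMM for
  parameter-recovery tests.
- **Duty cycle.** Hourly fixes through each local day, whole days dropped
  with probability 0.1, positions scattered uniformly within a 1 km disc
  around the interpolated path (so anchors are recoverable to within the
  jitter radius — a bounded, not Gaussian, error by design).
- **Wet/dry structure.** Water years run July–June; the default
  classification labels 2017–2020 dry and 2016–2017 plus 2020–2023 wet. In
  dry years the probability of *entering* the long-distance state is
  multiplied by `dry_factor` (default 0.2), leaving everything else
  untouched; over the default 7-year span this concentrates roughly 85–95%
  of long-distance lines in wet years.
- **Environment.** Flatness classes 8–9 inside the corridor buffer and
  declining with distance; elevation 80–300 m in the buffer with a
  600–1100 m "range" band 150–400 km east of the axis; rainfall a smooth
  west–east gradient (≈100–1300 mm) placing the corridor in the middle
  deciles.

What a green test on this world does **not** establish: realism of fix
error (no Argos-class error model; measurement error is treated as
negligible), behavioural covariates, true residency-site ecology, or any
claim about real tracking data. The generator reproduces the *statistical
shape* the method assumes — several short-movement classes, one
heavy-tailed long class, corridor-aligned flights, duty-cycled gaps — and
nothing more.

## 6. Numerical choices and degenerate inputs

- Scaled forward recursion with per-day max-shifting; likelihood −Inf
  (never an exception) for impossible observations such as a zero step
  with zero mass 0. An all-missing series contributes 0 with a warning.
- von Mises density uses the exponentially scaled Bessel function so large
  concentrations stay finite; sampling is Best–Fisher rejection.
- AIC ties → fewer states; Viterbi ties → lower state index; states are
  reported in ascending step-mean order.
- KDE grids are capped at 600 cells per axis (cell size coarsened with a
  warning); a cell larger than the bandwidth warns about an
  under-resolved surface.
- Degenerate inputs error early and informatively: single-point href,
  empty regions in overlap, fewer distinct raster values than bins,
  single observed line for a sample SD, unclassified water years.
- The generative zero-mass parameter may be exactly 1 (all steps zero);
  the estimated one is kept strictly below 1 by its logit transform.

## 7. Design decisions that were genuinely open

- **Dispersal-date inference** reuses the 10 km residency radius, since no
  operational definition of "dispersal date" exists beyond the residency
  notion itself.
- **Concordance metric.** Between two KED50s, overlap is reported as both
  directional area fractions; where one number is needed (the HMM vs
  threshold concordance check) the minimum of the two is used — the
  conservative choice.
- **Cells, not sampled points,** for zonal tabulation; and grid masks, not
  polygons, for membership — both because the mass-defined super-level set
  is the actual estimand and polygonisation is only a presentation step.
- **Pipeline scale.** The default pipeline configuration runs 4 birds per
  species at a 4-hourly duty cycle so a full two-species run (simulation
  through report) completes in minutes on one CPU; the generator defaults
  themselves (8 birds, hourly fixes) are unchanged by this.

## 8. Known limitations

No autocorrelated-kernel or Brownian-bridge estimators; no covariates on
transition probabilities, hierarchical HMMs or continuous-time
formulations; no per-individual UD averaging; no derivation of wet/dry
labels from rainfall data (they are configuration); plate-carree bounding
boxes are lon/lat rectangles, adequate at the mid-latitudes the package
targets.
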