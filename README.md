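# flywayr

Tools for identifying and characterising common long-distance movement
routes — inland "flyways" — of nomadic waterbirds from GPS telemetry.

Aggregate-nesting waterbirds such as straw-necked ibis (SNI) and royal
spoonbill (RSB) breed opportunistically in ephemeral inland wetlands and
move hundreds of kilometres between sites, without the fixed endpoints of
classical migration. Managers need to know whether these nomadic movements
concentrate on common routes, and what characterises them. `flywayr`
implements an end-to-end pipeline for that question:

1. **Trajectory preparation** — Movebank-style fix tables are filtered to
   birds with more than 30 days of post-dispersal data and reduced to daily
   displacement lines: great-circle segments between positions at
   species-specific 24-h anchors (local midnight for diurnal movers, midday
   for nocturnal ones), with step lengths `l_t` (km) and turning angles
   `theta_t` in (-pi, pi]. Missing days stay missing.
2. **Movement classification** — an N-state hidden Markov model with
   state-dependent emissions `l_t ~ Gamma(mean_j, sd_j)` (optional zero
   mass) and `theta_t ~ vonMises(mu_j, kappa_j)`, fitted by maximising the
   scaled forward-algorithm likelihood over all birds jointly, with random
   restarts and AIC (`AIC = -2 logL + 2p`) selection over N = 2..6 states.
   The class with the largest mean step is the long-distance class; lines
   are assigned by Viterbi decoding. A simple threshold classifier
   (median + 2 SD of all daily lines) provides the comparison method.
3. **Route demarcation** — long-distance lines are sampled to points every
   10 km, projected to a local equal-area plane, and smoothed into a kernel
   utilization distribution with the ad hoc bandwidth
   `href = sqrt((var_x + var_y)/2) * n^(-1/6)`. The smallest super-level
   set holding 50% of the mass (KED50) is the core route; representativeness,
   between-species overlap and href sensitivity quantify it.
4. **Habitat and climate** — raster covariates (a 0–9 terrain-flatness
   index, elevation, annual rainfall) are tabulated inside the KED50 versus
   the movement bounding box, with Pearson chi-square goodness-of-fit tests
   and over/under-representation flags, plus breeding-site intersection.
5. **Wet/dry stratification** — July–June water years carry configured
   wet/dry labels; long-distance lines are counted and the KED50 rebuilt per
   stratum.

A synthetic world (`simulate_daily_track()`, `simulate_gps_fixes()`,
`generate_environment()`, `generate_breeding_sites()`) generates telemetry
and rasters with the statistical structure the analysis assumes, so every
stage is testable without external data.

## Worked example

```r
library(flywayr)

# simulate three straw-necked-ibis-like birds for two years along the
# default corridor, with an hourly duty cycle and 10% daily dropout
cfg <- sim_config(); cfg$n_days <- 730L
sim <- simulate_tracking_data(n_birds = 3, species = "SNI", seed = 1, config = cfg)

# daily displacement lines (midnight anchors for a diurnal species)
fixes  <- filter_post_dispersal(sim$fixes)
series <- build_daily_lines(fixes, day_anchor = "midnight")
series_summary(series)$pooled
#>   n_days n_lines n_missing  mean_km median_km    sd_km
#> 1   2189    2149        19 3.502841   1.35198 16.25151

# five-state movement HMM; the largest-mean class is long-distance
fit <- fit_hmm(series, n_states = 5, n_restarts = 2, seed = 2)
round(fit$params$step_mean, 2)
#> [1]  0.84  1.43  1.48  2.94 72.50
ld  <- extract_long_distance(viterbi_decode(series, fit$params))

# core route: KED50 of the kernel utilization distribution
pts   <- sample_points_on_lines(ld, spacing_km = 10)
ud    <- kde_ud(pts, href_adhoc(pts))
ked50 <- contour_region(ud_contours(ud), 50)
c(href = href_adhoc(pts), area = ked50$area_km2)
#>      href         area
#>  89.72745 164542.62455

# how representative is the route of all fixes?
representativeness(fixes, ked50)$pooled
#> [1] 0.769168

# wet/dry stratification of the long-distance lines
stratified_proportions(ld, default_year_classification())
#>   class count percent_exact percent
#> 1   wet    40      88.88889    88.9
#> 2   dry     5      11.11111    11.1
```

With only three birds over two years the long-state mean (72.5 km) is a
noisy estimate of the generating 48 km (about 45 flight days feed it); the
seven-year, eight-bird default world and the test suite pin it down much
more tightly. Interpretation: 2149 usable daily lines, of which 45 are
long-distance flights concentrated (88.9%) in wet water years; the core
route covers ~165,000 km2 and contains 76.9% of all GPS fixes.

The threshold comparison, habitat tables and stratified KED50s follow the
same pattern (`threshold_classify()`, `compare_covariate()`,
`stratified_ked50()`); `run_pipeline(run_config(seed))` chains every stage
and writes CSV/GeoJSON/ASCII-grid outputs, a JSON summary and a markdown
report.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch on synthetic
data (both species: simulation, preparation, HMM fitting and decoding,
threshold comparison, KED50 demarcation, representativeness, habitat
comparison, wet/dry stratification) and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
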