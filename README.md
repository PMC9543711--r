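# popwave

Travelling-wave analysis of cyclic population growth.

Cyclic populations monitored across a large region — the motivating case
is a rodent crop pest surveyed by tens of thousands of field-margin
transects — usually cycle neither in perfect unison nor independently:
the cycle sweeps across the landscape as a periodic travelling wave.
popwave detects and characterises such waves from transect-level
abundance surveys. It is aimed at population ecologists and pest-
monitoring programmes with spatio-temporally irregular index data.

## The model

Surveys (date, projected coordinates, 0-100 abundance index) are
aggregated greedily into centroids of 5 km radius and 91-day quarters.
For a centroid *i* with mean index N in consecutive quarters, the
response is the log-difference growth rate

    r_ti = ln(N_{t+1,i} + 3.03) - ln(N_{t,i} + 3.03)

weighted by w = n_t n_{t+1} / (n_t + n_{t+1}) (observation variance is
proportional to 1/n). A wave hypothesis maps coordinates to a signed
distance D — a planar projection sin(θ)X + cos(θ)Y, or ± the Euclidean
distance from an epicentre (γ, ψ) — and aligns phases through the
space-modified time

    ρ_ti = T_ti + D_i / ζ,

with ζ the wave speed (m/day). The growth equation is a weighted
Gaussian GAM, r = α₁ + f(ρ) + ε, with thin-plate penalized smooths (≤ 12
bases). Twelve model structures are supported: three nulls (intercept;
time-only, i.e. true synchrony; static spatial pattern), single planar /
expanding-radial / contracting-radial waves, river-split pairs, and dual
additive pairs. Wave parameters are estimated by a deterministic direct
search followed by simulated annealing over the inner GAM's AIC, models
are compared by an adjusted AIC (AIC + 2K, K = number of wave
parameters), and parameter uncertainty comes from likelihood profiling
with a χ²₁ cutoff. A synthetic-data module simulates surveys over known
wave fields (including an adaptive monitoring design) so the whole
pipeline is validated by parameter recovery.

## Worked example

Simulate a single expanding radial wave on a compact region, aggregate
the surveys, and compare a subset of the catalogue:

```r
library(popwave)

spec <- wave_field(
  list(wave_component("radial-expanding", gamma = 5e4, psi = 3.75e4,
                      zeta = 405)),
  extent = c(xmin = 0, xmax = 1e5, ymin = 0, ymax = 7.5e4),
  duration = 1092)
design <- sampling_design("uniform", n_surveys_per_quarter = 150, seed = 1)
surveys <- generate_surveys(spec, design)

obs <- compute_growth(aggregate_surveys(surveys, assign_centroids(surveys)))
cmp <- fit_catalogue(obs, labels = c("N1", "N2", "P", "RE", "RC"),
                     iterations = 500, seed = 1)
cmp
```

```
Travelling-wave model comparison (adjusted AIC = AIC + 2K)
 label K    aic adjusted_aic  delta error
    RE 3 367.94       373.94   0.00  <NA>
    N2 0 411.01       411.01  37.07  <NA>
     P 2 409.53       413.53  39.60  <NA>
    RC 3 410.37       416.37  42.43  <NA>
    N1 0 923.13       923.13 549.19  <NA>
Selected: RE
```

The data were generated from an expanding radial wave, and the
expanding radial model wins by 37 adjusted-AIC units over the
true-synchrony null and the planar wave. The fitted parameters:

```r
cmp$fits$RE$params
#> Wave parameters for model RE (K = 3)
#>     gamma       psi      zeta
#> -4083.615  1040.139   497.204
```

Coordinates are mean-centred metres (`uncentre()` maps back to the
original projection); the true centred epicentre here is (-930, 84) and
the true speed 405 m/day, so this deliberately small demo (about 600
growth observations) recovers the epicentre to ~3 km and the speed to
~90 m/day — the study-scale experiment in `scripts/acceptance.R`, with
roughly five times the data, does substantially better.
`convert_speed(497, rounded = TRUE)` reports the fitted speed as 182
km/year. Profile a parameter with `profile_ci(cmp$fits$RE, "zeta",
grid)`, visualise wave contributions with
`conditional_contribution()`, and map predictions with
`predict_field()` / `front_speed()`.

An end-to-end YAML-configured run (simulate → preprocess → fit →
profile → report, with every artefact and seed recorded) is available
as `run_pipeline()`; a thin command-line wrapper sits in
`inst/scripts/popwave.R`.

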