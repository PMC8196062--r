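# discorient

Analysis of larval-fish orientation behavior observed in a **drifting in
situ chamber (DISC)** — a transparent 20 cm circular arena that drifts
with the current while a camera films a single larva from below and
compasses record the chamber's slow rotation. The package is for
behavioral and dispersal ecologists who work with digitized DISC
deployments (or want ground-truthed synthetic ones): it turns position
tracks into orientation statistics, separates genuine compass orientation
from attraction to the rotating chamber, tests what the population is
swimming toward, and quantifies how swimming behavior develops with age.

## What it computes

For a sample of position bearings θ₁…θₙ (degrees clockwise from north),
the mean resultant length

r = ‖ (1/n) Σᵢ (sin θᵢ, cos θᵢ) ‖

measures concentration (0 = uniform, 1 = a point), with circular standard
deviation √(−2 ln r). The **Rayleigh test** of uniformity uses Z = n·r²
with the standard series approximation for p. The analysis chain per
deployment is:

1. subsample the track to 1 Hz and drop the acclimation window;
2. compute position bearings from the arena center, swimming speeds, and
   turning angles;
3. rotate bearings into the cardinal frame with the synchronized compass
   (`cardinal = camera + heading`), and classify the deployment:
   **non-oriented** (cardinal Rayleigh p ≥ α), **device-biased**
   (significant, but more concentrated in the rotating camera frame than
   in the cardinal frame), or **oriented**;
4. pool oriented larvae's mean bearings in **second-order Rayleigh
   tests** against candidate goals — a cardinal direction, the current
   (net GPS drift), the wind, the sun azimuth (built-in NOAA-style
   ephemeris), or the natal reef (geodesic bearing) — overall and by age
   group (2–10, 12–20, 22–30 days post-hatch);
5. regress speed and turning angle on age (OLS, 95% bands) and
   orientation success on age (logistic regression, likelihood-ratio
   test).

A seeded **biased correlated random-walk simulator** generates complete
DISC-like cohorts (trajectories, compass, GPS drift, metadata, ground
truth) under alternative orientation strategies: H0 no goal, H1 one
shared bearing, H2 condition-dependent (goal flips at a switch age), H3
context-dependent (goal = nearest point of a reef line), H4 a per-larva
mixture — plus arena-fixed goals that emulate device bias.

## Worked example

```r
library(discorient)

cfg <- sim_config(n_larvae = 30, ages_dph = rep(seq(2, 30, 4), length.out = 30),
                  strategy = "H4_mixed", goal_bearings_deg = c(90, 270),
                  seed = 11)
coh <- simulate_cohort(cfg)
rep <- analyze_cohort(coh)
rep
#> <run_report> 30 deployments: 100.0% (30 of 30) oriented, 0 device-biased, 0 non-oriented

classify_deployment(coh$deployments[[1]]$trajectory, coh$deployments[[1]]$compass)
#> <frame_analysis> 'd001': oriented (rho cam 0.160 vs card 0.927, p = 0, bearing 274.6)

gs <- rep$group_summaries
format_group_table(gs[gs$age_group == "all", ])
#> hypothesis   ages      n  mean +/- SD        r      p
#> cardinal     all      30   276.7 +/- 2.33   0.07   0.88
#> current      all      28   156.7 +/- 2.05   0.12   0.66
#> wind         all      30   105.5 +/- 2.54   0.04   0.95
#> sun_azimuth  all      30   345.4 +/- 1.85   0.18   0.38
#> natal_reef   all      30    49.0 +/- 2.25   0.08   0.83

rep$trend_speed
#> <trend_fit> speed ~ age: slope 0.003854, intercept 0.3922, stat 26.7 (df = 28), p = 1.88e-21
```

Reading it: every larva in this mixed-strategy cohort passes the
individual orientation screen (deployment `d001`'s bearings concentrate
at 274.6° in the cardinal frame, far more than in the rotating camera
frame — genuine orientation, not device bias), yet no goal hypothesis is
significant at the population level: half the cohort swims east and half
west, so the pooled mean bearings cancel (cardinal r = 0.07, p = 0.88).
Swimming speed still rises with age. This "most larvae orient, but not
toward a common bearing" signature is exactly what mixed individual
strategies produce.

The same steps run as a scripted workflow: `analysis/01_simulate_cohorts.R`
through `analysis/04_ontogeny_trends.R` generate H0/H1/H4 cohorts, analyze
them, render the hypothesis grids and fit the ontogenetic trends, writing
tables under `results/`.

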