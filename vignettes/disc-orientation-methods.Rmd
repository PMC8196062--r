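---
title: "Methods: analyzing larval orientation behavior from drifting-chamber deployments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analyzing larval orientation behavior from drifting-chamber deployments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discorient)
```

## The measurement problem

A drifting in situ chamber (DISC) is a transparent cylindrical arena —
20 cm in diameter, 10 cm high — suspended at depth from a GPS-equipped
surface float and coupled to the subsurface current by a drogue. A single
fish larva swims inside while a camera below records its position; the
chamber rotates slowly as it drifts, and onboard compasses record the
rotation. A deployment yields a 20-minute video (5 min acclimation, 15 min
acquisition), a compass trace, a GPS drift track, and metadata (age of the
larva in days post-hatch, start time and position, wind).

The scientific questions this package addresses are:

1. does an individual larva hold a non-random position in the arena
   (individual orientation)?
2. is an apparent preference genuine compass orientation, or attraction to
   a feature of the rotating chamber (device bias)?
3. do larvae, as a population, share a common goal — a fixed cardinal
   bearing, the sun azimuth, the current or wind direction, or the bearing
   of their natal reef?
4. how do swimming speed, path straightness and orientation success change
   with age?

## The statistical chain

**Position bearings, not headings.** The tested angles are the bearings of
the larva's 1 Hz subsampled positions as seen from the arena center
(`position_bearings()`), in degrees clockwise from "up" in the camera
frame. Positions closer than 0.5 cm to the center are excluded: the
bearing of a point near the origin is numerically ill-conditioned, and a
larva hovering at the center expresses no directional preference anyway.

**First-order test.** For a sample of $n$ bearings
$\theta_1,\dots,\theta_n$, the mean resultant vector has length

$$ r = \frac{1}{n}\left\| \sum_i (\sin\theta_i, \cos\theta_i) \right\|, $$

and the Rayleigh statistic is $Z = n r^2$. The p-value uses the standard
series approximation

$$ p = e^{-Z}\!\left[1 + \frac{2Z - Z^2}{4n}
   - \frac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288 n^2}\right], $$

clamped to $[0,1]$. The companion dispersion is the circular standard
deviation $\sqrt{-2\ln r}$ (radians). Both are validated two ways: against
published $(n, r, p)$ and $(r, \mathrm{SD})$ pairs, and against a
100,000-draw uniform-resampling Monte-Carlo oracle at small $n$.

**Frame correction and the device-bias filter.** The chamber heading
$h(t)$ links frames: $\text{cardinal} = (\text{camera} + h(t)) \bmod 360$.
The sign convention (heading = compass direction of the camera-frame "up"
axis) is a single explicit constant (`rotation_sign`), so records using
the opposite convention can be ingested. Each deployment is classified
(`classify_deployment()`):

* `non_oriented` — cardinal-frame Rayleigh $p \ge \alpha$;
* `device_biased` — $p < \alpha$ but the camera-frame $r$ exceeds the
  cardinal-frame $r$: the larva was more concentrated relative to the
  rotating chamber than relative to the compass, i.e. tracking a chamber
  feature;
* `oriented` — the remainder. The measure-zero tie goes to `oriented`.

If the chamber never rotates the two frames differ by a constant, $r$ is
identical in both (rotation invariance), and no deployment can be flagged
device-biased — the filter has power only when the chamber actually turns.

**Second-order tests and the hypothesis battery.** Population-level
questions use the mean bearings of oriented larvae, one unweighted unit
vector per larva, in a second-order Rayleigh test. We chose the unweighted
form (ignoring each larva's own $r$) because a single pooled $r$ per group
is what a summary table of this design reports; a weighted variant would
change the null distribution and is deliberately out of scope. For each
cue hypothesis the per-larva bearing is first re-expressed relative to its
own deployment's reference (`relative_bearings()`), so cue-tracking
populations concentrate near 0°. Note an identifiability limit: by
rotation invariance, any reference that is (nearly) constant across
deployments gives (nearly) the same $r$ and $p$ as the cardinal test —
only cues that vary between deployments (sun azimuth across
morning/afternoon, variable drift) are statistically distinguishable from
a fixed compass goal.

**Reference directions.** Sun azimuth comes from a NOAA-style
low-precision solar ephemeris implemented in the package (accurate to
well under 0.5°; cross-checked against an independently implemented PSA
ephemeris), evaluated at the midpoint of the acquisition window — the
azimuth drifts under 5° in 15 minutes, so the midpoint choice is
innocuous. Current direction is the great-circle bearing from the first to
the last GPS fix of the window: net displacement is robust to fix-level
jitter, and displacements under a configurable noise floor (default 5 m)
are flagged unreliable rather than used. The natal-reef reference is the
geodesic bearing from the deployment start to the fixed transect midpoint.
Wind is stored direction-*toward*; meteorological direction-from inputs
must be converted on ingestion.

**Ontogenetic trends.** Mean instantaneous speed (displacement between
consecutive 1 Hz positions) and mean unsigned turning angle (the angle
produced by three successive positions; unsigned because signed turns
average near zero) are regressed on age by ordinary least squares with
t-based 95% confidence bands. Orientation success (oriented vs not) is
modeled by binomial logistic regression with a likelihood-ratio
chi-square (df = 1) against the intercept-only model; we report the LR
rather than the Wald statistic because it is exact under the nested-model
comparison the question poses. Complete separation is detected (diverging
fitted probabilities or an absurd slope) and flagged instead of reported
as a finite estimate. Age, not body size, is the developmental covariate
throughout. Speed and bearings share the single 1 Hz code path; computing
speed from full-rate frames would change its absolute level (finer
sampling inflates path length) but not the ontogenetic comparison.

## The synthetic cohort generator

Because the raw deployment videos live in an external archive, every
stage is exercised on synthetic cohorts with known ground truth
(`sim_config()`, `simulate_cohort()`). The generator emulates the study
conditions: 120 deployments, ages 2–30 dph with 8 larvae per age, 900 s
acquisition at 1 Hz, a 10 cm-radius arena, a rotating chamber (default
0.5°/s — several revolutions per trial), GPS drift at 4.38 ± 2.72 cm/s,
and morning/afternoon deployment windows at a tropical western-Caribbean
site in May–August 2016.

Movement is a biased correlated random walk. Per step the heading is
drawn von Mises with concentration $\kappa$ around the circular blend of
the previous heading (weight $w$, the persistence) and the goal direction
(weight $1-w$), plus a wrapped-normal turning jitter whose SD declines
with age (default 52° − 0.7°/dph, floored at 5°) — younger larvae swim
more erratically. Step length is speed(age)·dt with truncated-normal
noise; the default speed model interpolates 0.45 cm/s at 2 dph to
0.62 cm/s at 30 dph. Defaults $\kappa = 2$ and $w = 0.5$ give strongly
directional but visibly noisy paths. The orientation-strategy hypotheses
are implemented as goal rules: none (H0, $\kappa$ forced to 0), a single
shared bearing (H1), a condition-dependent flip at a switch age (H2,
east-early/west-late by default), a context-dependent goal toward the
nearest point of the reef line (H3), and a per-larva mixture (H4). A
configurable fraction of larvae instead carry an *arena-fixed* goal that
co-rotates with the chamber — the ground truth the device-bias filter
must catch.

Numerical choices worth knowing:

* **Wall handling.** The wall is reflecting, implemented radially
  (overshoot beyond the radius is folded back along the radius). The true
  larva–wall interaction is unobserved; reflection keeps the bearing
  statistics interpretable, but it is a modeling choice, not an observed
  behavior.
* **von Mises sampling** uses the Best–Fisher rejection algorithm;
  $\kappa < 10^{-6}$ degenerates to the uniform and $\kappa > 10^{7}$ to a
  point mass.
* **Determinism.** Every deployment derives a private seed from the
  cohort seed and its index, so cohorts are bit-reproducible and any
  single deployment can be regenerated alone.

## What passing tests do and do not show

The generator produces positions with realistic autocorrelation, and that
exposes a genuine property of the position-based Rayleigh approach: at
observed swim speeds (≈0.5 cm/s in a 10 cm-radius arena) a larva crosses
the arena in minutes, so its 900 1 Hz positions are far from independent.
Under a goalless walk (H0) the per-larva Rayleigh test — which, as
applied in this design, treats positions as independent draws — rejects
far above its nominal level; no realistic speed brings it near $\alpha$.
The i.i.d. type-I property therefore holds (and is verified) for
independently drawn uniform positions, while the calibrated guarantee for
trajectories lives one level up: under H0 the per-larva *mean bearings*
are uniform across larvae, and the second-order test keeps its level.
Individual-orientation fractions from confined-arena data should be read
with this in mind; the population-level battery is the robust inference.

A related confound: the measured mean turning angle in the arena is
dominated by wall encounters at higher speeds, so although the generative
heading-noise SD declines with age, the *measured* turning-angle trend of
a simulated cohort can come out flat or slightly positive. The regression
machinery itself recovers negative trends correctly (verified on directly
generated kinematic summaries); the discrepancy is a property of confined
arenas plus reflecting walls, not of the estimator.

Two smaller empirical notes. The solar azimuth at this tropical site is
*not* monotone through a June day — near the summer zenith passage the
sweep direction briefly reverses (both our ephemeris and the independent
oracle agree), so the monotone-sweep property is checked on a winter day.
And geodesic initial bearings (WGS84) differ from spherical great-circle
bearings by up to ≈0.15° at mid-latitudes, which sets the tolerance of
that cross-check.

Features of real data the generator does not emulate: tides and shear in
the drift, chamber tilt and drogue dynamics, larva–wall behavioral
interaction (thigmotaxis), midday disruption of orientation, digitization
noise in the video positions, and any sensory mechanism — goals are
imposed, not perceived.

## Problem sizes

The test suite and the acceptance script regenerate everything they
measure: Table-style closed-form cross-checks (instant), Monte-Carlo
oracle comparisons at $10^5$ draws, type-I calibration over 1,000
uniform deployments of 900 positions, bearing recovery over 100 cohorts
of 120 larvae at $\kappa = 2$, and bias-filter discrimination over 200
replicates per goal frame. These sizes give binomial standard errors
comfortably inside the asserted bands (e.g. ±0.7% on a 5% rejection rate
at 1,000 trials) while a full run completes in a few minutes on one core.

## Known limitations

* The per-larva Rayleigh screen is anti-conservative on autocorrelated
  trajectories (above); an effective-sample-size or block-resampling
  correction would be a natural extension but is not part of this design.
* The second-order test is unweighted; larvae with barely significant
  individual orientation count as much as tightly oriented ones.
* Device-bias filtering compares a single pair of resultant lengths; a
  larva tracking a chamber feature *and* a compass cue simultaneously is
  resolved to whichever frame concentrates it more.
* The sun-azimuth hypothesis is evaluated at one instant per deployment;
  a larva tracking the moving sun within a trial concentrates slightly
  less than one tracking the midpoint azimuth.
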