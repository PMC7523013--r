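---
title: "Methods: linking pigeon orientation to VOC gradients and air-mass transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking pigeon orientation to VOC gradients and air-mass transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

olfnav implements the quantitative chain by which olfactory-navigation
studies relate where released homing pigeons fly to what their noses could
have told them: per-bird orientation and homing indices from GPS tracks,
air-mass residence statistics from back-trajectories, VOC summaries from
aviary time series, and a rank-correlation analysis tying them together.
This vignette records the models, their assumptions, the defaults, and the
numerical and design decisions a maintainer would want explained.

```{r setup}
library(olfnav)
```

## Geodesy and circular statistics

All positions are treated on a sphere of radius 6371.0 km. At the ≤100 km
scale of pigeon releases the departure from an ellipsoid is below 0.5 %, far
under GPS and behavioural noise, and a sphere keeps every formula (haversine
distance, forward azimuth, destination point) in closed form. Bearings are
degrees clockwise from true north; "west" is 270° throughout. The circular
mean returns the resultant direction and mean vector length r ∈ [0, 1]; for
perfectly symmetric inputs (r = 0) the direction is reported as `NA` rather
than an arbitrary angle, and downstream code must handle that flag.

## Homing indices

`compute_indices()` reduces each track to one row:

* **Initial orientation** — the unweighted circular mean of *step headings*
  for steps starting within 10 km (configurable) of the release site. Step
  headings, not bearings from the release point, are used: they describe
  what the bird is doing locally, and the two coincide for straight flights.
  A bearing-from-release mode would be a monotone smoothing of the same
  information; step headings were chosen and are what the tests pin down.
  Birds with r < 0.1 are flagged inconsistent and excluded from
  associations.
* **Deviation from west** — the wrapped difference between the initial
  direction and 270°. Both the signed variant in (−180°, 180°] and the
  absolute variant in [0°, 180°] are computed (`dev_west`, `dev_west_abs`).
  The association analysis uses the absolute variant by default: the three
  release sites lie at different compass directions from home, so the
  signed deviation of a pure homer changes sign from site to site and any
  monotone coupling with a covariate washes out when sites are pooled,
  whereas the absolute deviation measures "how far from due west" uniformly
  across sites.
* **HEI** = (a/l)·(b−c)/b over a window of 50 min of *active flight*
  (steps with speed > 10 km/h), ending early if the bird comes within
  0.5 km of home. Two readings of the truncation rule are possible; the
  package takes: the 50 min clock counts only active steps, but the path
  length l includes *every* step up to the truncation fix — resting does
  not shorten the path already flown. Birds lost before either condition
  use their last recorded fix. The home-arrival radius (0.5 km,
  configurable) is a definition the index needs but field descriptions
  rarely state; half a kilometre is within sight of a loft.
* **MAAP** — the flight is downsampled to hourly boundaries (nearest fix
  within ±5 min; boundaries with no fix, e.g. logger dropouts, are skipped
  rather than penalised), and the mean absolute difference between the
  required azimuth to home and the observed azimuth is returned. The
  observed azimuth is the *displacement bearing between consecutive hourly
  samples*, not an instantaneous logger heading: at 1 fix/10 s an
  instantaneous heading is dominated by GPS jitter, while the hourly
  displacement is exactly the quantity the penalty is meant to measure.
* **Endpoint distance** — home to last recorded fix, km.

`spearman_rho()` implements the rank correlation directly (average ranks,
Pearson correlation of ranks, two-sided p via the t-approximation on n−2
degrees of freedom) rather than delegating, because the sea:land covariate
legitimately takes +∞ (trajectories that never left the sea): ranks are
well defined for ±∞ and nothing needs capping. A seeded permutation mode
is available for small cohorts; at n ≈ 100+ the t-approximation is
accurate, which the tests verify against base R on tie-free cases.

## Air-mass residence and wind profiles

Hourly back-trajectory points are classified into three exclusive classes:
**above boundary layer** when transport altitude exceeds the local
mixing-layer depth — this test takes precedence, because air decoupled from
the surface carries no surface scent regardless of what is below — then
**marine boundary layer** over sea, else **land**. For a backward
trajectory the window is the 24 h before release (offsets −24…−1); the
origin point is excluded (it is the release itself). Residence ratios use
x/0 = +∞ and 0/0 = NaN; NaN birds drop out of associations, +∞ birds do
not.

The wind profile is a 16-sector × 6-speed-class occupancy matrix P with
θ = 0 aligned with west and θ = π with east (compass 270° ↦ θ = 0), so that
WWC = Σ cos(θ)·S·P is positive for westerly-dominated regimes and bounded
by ±max(S). S defaults to the ordinal ranks 1…6; a `midpoint` option
substitutes the speed-class midpoints in m/s. The six default class edges
(0, 1, 2, 4, 6, 8, ∞ m/s) are a configuration choice documented here: light
airs and the 1–2 m/s sea-breeze onset get their own classes, and everything
above 8 m/s is rare at the study coast.

## VOC summaries

* **Background subtraction** interpolates instrument background linearly
  between run midpoints (held constant outside), subtracts, clips negatives
  to zero and *counts* the clipped records in an attribute — non-negativity
  is an invariant of mixing ratios, but silent clipping would hide drift.
* **Diel cycles** average within day × hour first and take statistics
  across days, so a day with denser sampling cannot dominate an hour; the
  campaign "maximum hourly mean ± 1σ" is the max of the across-day hourly
  means with the sd of the daily means at that hour.
* **Bivariate polar maps** pair each mixing-ratio record with the nearest
  meteorology record within 60 s and report plain per-cell means over
  10° × 1 m/s bins, masking cells with fewer than 3 pairs. No kernel or GAM
  smoothing is applied (reference implementations of such plots usually
  smooth): unsmoothed cell means are exactly testable against a group-by
  oracle, and smoothing is presentation, not inference.
* **Lifetimes** are OH-only: τ = 1/(k_OH·[OH]) with [OH] = 2×10⁶
  molecules cm⁻³ by default, and e-folding distance u·τ at u = 2.2 m/s.
  For species with substantial O₃/NO₃ chemistry (limonene and other
  terpenes especially) the OH-only lifetime overstates persistence, so
  these distances are upper bounds for such species; the package
  deliberately does not model multi-oxidant loss.

## What the synthetic study system emulates

The generator module reproduces the statistical structure the analysis
assumes, with defaults fixed once:

* **Geometry.** Home aviary at 43.65714° N, 10.30408° E on a coastal plain;
  a straight north–south coastline at 10.282° E (the sea ~1.8 km west of
  the aviary); three release sites reconstructed from their
  bearing/distance to home (241°/59.9 km, 309°/50.5 km, 270°/61.0 km — all
  inland, east of the coast).
* **Sea breeze** (`gen_sea_breeze_met`): 1-min records; wind von Mises
  (κ = 8, ≈ ±25° spread) around 150° until noon and after 20:00 h, around
  270° in the 12:00–20:00 onshore window; temperature 12–25 °C and RH
  60–85 % as anti-phased diel sinusoids; lognormal speeds around 2.2 m/s,
  brisker in the afternoon.
* **VOC sources** (`gen_voc_series`): mixing ratio = baseline +
  directional gain × von Mises kernel on wind direction × diel emission
  factor, times lognormal noise. Defaults: marine DMS peaked at 270°,
  nocturnal monoterpenes from inland (120°), daytime isoprene (60°),
  aromatics from 135°.
* **Flights** (`gen_track`): correlated random walk at 1 fix/10 s,
  lognormal speeds (median 60 km/h, a typical pigeon cruise), von Mises
  headings (κ = 2) around a blend of the instantaneous home azimuth and
  due west with weight w ∈ [0, 1] — the olfactory mechanism in miniature:
  air poor in marine signal pulls the bird west.
* **Back-trajectories** (`gen_trajectory`): 24 hourly backward steps
  upwind at 8 m/s (~700 km/day, a realistic synoptic flow at 150 m
  transport altitude) with von Mises jitter; altitude ≈ 150 m; mixing
  depth with a day/night cycle (≈800 m / ≈300 m).
* **Cohorts** (`simulate_cohort`): each bird's trajectory is drawn from the
  *regional* ensemble — prevailing direction uniform, origin at the
  release-region centroid. This is a deliberate design decision: a 24 h
  synoptic trajectory spans hundreds of km, so the air-mass histories of
  sites 60 km apart are statistically common; and because the release sites
  differ in distance to the coast *and* in home azimuth, site-specific
  trajectory origins would make the sea fraction a function of site and
  confound the no-bias null (a pure-homing cohort would show a spurious
  deviation-vs-ratio correlation through site geometry alone). With the
  regional ensemble the covariate is independent of site by construction:
  the null is exchangeable, and the package's null-calibration tests
  verify a nominal rejection rate. The westward weight is
  w = bias_coef × (1 − sea fraction), clamped to [0, 1]; `bias_coef = 1`
  is the default "built-in bias" condition and `bias_coef = 0` the null.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: plume structure and turbulent odour
intermittency; terrain, landmarks and route memory; inter-individual
variation in speed or motivation; multi-day homing with stopovers;
correlated weather across release days; instrument drift beyond a smooth
background. Recovery results here are statements about the rank-level
coupling the generator builds in, not about effect sizes in the field.

## Problem sizes and runtime choices

The recovery analyses simulate cohorts of 100 birds flying 15 min each:
the orientation analysis only uses the first 10 km (~10 min at 60 km/h), so
longer flights cannot change the statistic, and 15 min leaves margin for
slow birds. Replicate counts are 100 cohorts for the biased condition and
200 for the null. Meteorology defaults to 7 simulated days. These sizes are
the package's own choices for a thorough-but-quick test suite; all of them
scale up through arguments.

## Numerical notes

* Duplicate GPS fixes produce zero-length steps with `NA` heading; they are
  kept in path length but excluded from heading statistics.
* The von Mises sampler is the Best–Fisher rejection scheme; κ = ∞ is
  honoured exactly (no noise), κ ≈ 0 falls back to uniform.
* Seeds: every generator is a pure function of (arguments, seed); cohort
  child streams derive from the scenario seed by a fixed integer map kept
  below 2³¹.
* Ties in ranks use average ranks; a rank vector with zero variance is an
  error rather than rho = 0/0.
* The t-approximation p-value at |rho| = 1 is reported as 0; `glance()`
  then shows an infinite t statistic rather than NaN.

## Known limitations

OH-only lifetimes understate loss for O₃-reactive species, as noted above.
The residence classifier trusts the trajectory model's mixing depth; no
uncertainty in trajectory position is propagated. MAAP needs flights of at
least two hourly samples and is `NA` for shorter tracks. The Spearman
analysis pools release sites (stratified or mixed models are out of scope);
with real site-specific trajectories the geometry confound described above
is a caveat the analyst must weigh, exactly as in the field setting.
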