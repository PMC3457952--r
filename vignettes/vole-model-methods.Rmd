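---
title: "The volePOM individual-based model and its pattern-oriented tests"
author: "volePOM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The volePOM individual-based model and its pattern-oriented tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volePOM)
```

## The model in brief

`volePOM` simulates field vole (*Microtus agrestis*) populations as
individual agents on a 1 m resolution raster landscape with a daily
time step. Each vole carries an identity, sex, age, natal location, a
daily foraging position, and -- once acquired -- a circular territory.
The daily scheduler runs, in order: vegetation update, then every vole
in freshly shuffled order (mortality, aging, territory assessment and
eviction, mating and reproduction, male restlessness, dispersal), then
the optional predator layer, then output recording. All demographic
rates and behavioural switches sit in a 17-parameter registry
(V1--V17, `voleParams()`) whose defaults are the post-calibration
values; auxiliary life-history constants (gestation 21 d, litter size
truncated Poisson with mean 5, weaning at 14 d, physiological lifespan
N(15, 3) months) are standard literature values for the species and are
not part of the calibrated set.

Habitat quality is the product of a per-class base quality and a daily
*digestibility*: 0.7 plus the square root of the proportion of biomass
younger than 14 days, capped at 1.0, so quality swings by up to 30%
between fresh spring growth and mature standing vegetation. Grass
grows on days at or above V14 = 3.552 °C; seven consecutive such days
open the breeding season (never before day V15 = 80), and conception
cannot start from day V11 = 230.

A territory at a location is acceptable at radius *r* (scanned within
the sex-specific bounds, female 8--8 m, male 9--23 m) when mean cell
quality times the multiplier V3 = 2.1 reaches 1.0 and the number of
voles within the circle, resident included, stays below the density
threshold V13 = 4 scaled by the ratio of the sex-specific to the female
minimum territory area. Voles need a territory to breed; a female
conceives when a settled adult male's territory covers her position
(nearest male wins, ties to the lowest id); offspring enter the
simulation at the nest when weaned at 14 days, sexes drawn evenly.
Older same-sex residents evict younger ones at more than 50% territory
overlap when the age gap reaches V8 = 30 days. Voles without a
territory disperse by a correlated random walk (8 × 5 m steps per day),
attempt settlement before each step, and suffer the additional
dispersal mortality V9 = 0.055 per dispersal day on top of the
background daily mortality V10 = 0.0025; there is no limit on
consecutive dispersal days (V16 is disabled). Roaming mature males
attempt infanticide (V17 = 1) on un-weaned litters they encounter, with
success declining linearly from certain at birth to impossible at
weaning.

## Interpretation choices where the published description is silent

The behavioural description above under-determines a daily scheduler;
the following choices were genuinely open and are the package's own.

* **Coordinates and geometry.** 0-based cell coordinates, positions at
  cell centres, Euclidean distances in metres; territory overlap is the
  analytic circle-lens area over the younger vole's circle area.
* **Seasonal territoriality.** Territorial competition (the density
  displacement rule and eviction) operates only during the breeding
  window; outside it territories lapse into loose winter ranges held on
  habitat quality alone. Winter territoriality relaxes in *Microtus*;
  without this, autumn eviction cascades cull the season's female
  surplus and produce a spuriously male-biased spring.
* **Nest defense.** A female with an active pregnancy or un-weaned
  litter is exempt from the crowding displacement (crowding still
  suppresses her next conception).
* **Male ranges.** During the breeding season a male claims the largest
  radius of sufficient quality (his patrolled mate-access range), with
  tenure gated by the crowding rule at his minimum radius, and only
  settles where at least one adult female falls inside the claimed
  circle -- male territory quality involves mature females. Outside
  the season males, like females, take the smallest acceptable radius.
* **Juveniles are pre-territorial.** Weaned voles below the maturation
  ages (V1 = 30 d males, V2 = 23 d females) range around the natal nest
  (12 m daily radius), do not count against their mother's crowding
  threshold, and cannot claim a territory; they are not "dispersing",
  so V9 does not apply to them. Adults without a territory are
  dispersing proper.
* **Daily foraging position.** Settled voles take a fresh position
  uniform over their territory disk each day. This matters only for
  observation (trapping, local counts); without it the virtual trapping
  module would record zero movement for residents.
* **Vegetation bookkeeping.** The new-green cohort ledger follows
  biomass by age in days; mature biomass decays by 2%/day on days below
  the growth temperature (winter dieback), so each spring's growth
  again dominates the sward. Drought effects are deliberately absent.

Two auxiliary constants have no literature anchor at all: the
infanticide encounter radius and the juvenile natal range. Both were
fixed once by the package's own calibration machinery -- the same
procedure the package exposes to users -- by minimising the equal-weight
mean proportional deviation of the three headline pattern statistics of
the homogeneous-block scenario (day-90 and day-200 sex ratios, breeding
female density) with every V parameter held at its published value.
The selected values are 18 m and 12 m and are not revisited.

## The four packaged scenarios

* `scenarioBlock()` -- a 200 × 200 m unmanaged-grassland block inside an
  equally large dispersal-only surround, Finland-like weather,
  predators off, 10 years with 5 discarded (the full published protocol
  uses 20/10 years; the shrink is recorded in `scaleFactor`). Censuses
  mirror the original field protocol by counting voles on high-quality
  habitat.
* `scenarioTrapMeadow()` -- a 500 × 400 m meadow in forest with three
  14 × 7 live-trap grids (7 m spacing, 30 m between grids, 1 m capture
  radius) identified daily over the final two of seven years.
* `scenarioPatches(n)` -- n ∈ {1, 3, 16} grassland patches of equal
  total area (6.25 ha) in a 700 × 700 m dispersal-only matrix, with
  specialist predators and a trickle of vole immigration (the landscape
  is open), 50 years.
* `scenarioMosaic()` -- a seeded random-rectangle farmland mosaic with
  Dirichlet class shares, standing in for a real mixed landscape, used
  with `patchSeasonDensities()` and `habitatDensityFit()` for the
  habitat-by-season density comparison.

The predator layer is deliberately minimal: specialists with a 50 m
home range, at most one kill per day with a 5% per-local-vole daily
capture probability (prey escape at low density), survival requiring 10
local voles with starvation after 45 unsuccessful days, annual
reproduction, founders arriving in year 3 and two autumn immigrants per
year. The delayed numerical response -- predators reproduce once a
year while voles rebound within weeks -- plus the starvation lag
generates multi-annual boom-bust dynamics whose amplitude falls as the
landscape fragments.

## What the synthetic scenarios do and do not emulate

The generators reproduce the *structure* of the study settings (block
plus sink, meadow plus trap grids, patch lattices) but not real GIS
maps, real weather series, or farming dynamics: weather is a seeded
sinusoid with noise, habitat base qualities are package defaults ranked
by habitat type, and the mosaic is statistical rather than surveyed.
Passing the packaged tests therefore demonstrates that the behavioural
rules reproduce the field patterns *under these idealized conditions*;
it does not validate the model against any particular real landscape.

## Pattern statistics and their tolerances

`sexRatio()` returns the mean of daily females-per-male over a ±15-day
census window (means of daily ratios; the ratio-of-sums convention is a
flag). `femaleDensity()` divides the mean female count by the
high-quality habitat area. `ageStructureFit()` is the mean over
May--September mid-month snapshots of the summed squared proportion
differences. `habitatDensityFit()` totals absolute ln-scale deviations
over habitat × season observations, with densities below 9 voles/ha
lumped (zero deviation inside the lump), against a pass mark of 10.
`cycleMetrics()` reports amplitude ln(max/min) of annual peaks, mean
peak spacing, and the low-phase length, and classifies the fluctuation
regime. `dispersalStats()` rebuilds the mark-release-recapture
statistics from capture records, restricting natal dispersal to voles
born within the grids dilated by one home-range diameter; two
home-range diameters span 90 m (males) and 70 m (females).

`evaluatePatternSet()` applies the printed pass lines (±2% for the
block statistics, the 10.0 pass mark, the dispersal criteria, the three
cycling regimes) and flags near-misses within 1.25× tolerance as
marginal, mirroring the historically accepted fit whose day-90 ratio
missed by 2.1%.

## Calibration engine

`runReplicates()` (minimum ten seeds during fitting), `perturb()`
(one-at-a-time ±5/10/20% candidates, integer parameters rounded),
`hillClimb()` (greedy best-improving acceptance with a full evaluation
trace and a forbidden set), `sequentialPom()` (fit set 1 to tolerance,
gate sets 2--4, return to set 1 on failure with the failed
parameterization forbidden), and `sensitivitySweep()` (11 values
spanning ±80% per parameter, one at a time, overall deviance capped at
1.0) implement the staged protocol. The expensive model evaluations
are injected as functions, so the same machinery drives toy objectives
in the test suite and full simulations from the command line
(`exec/volepom fit`, `sensitivity`).

## Numerical choices

All randomness flows from two splitmix64 streams (voles + vegetation;
predators) derived from the run seed, so runs are bit-identical per
seed and toggling a harmless predator layer does not perturb the vole
draw sequence. Agent order is freshly shuffled each day. Years are
365 days; calendar dates exist only at the I/O boundary (leap days are
dropped on import). Mean circle quality treats out-of-grid cells as
quality zero; interior circles are resolved O(1) through a
distance-to-boundary transform. Ties in mate choice break to the
lowest id; blocked dispersal steps re-orient randomly.

## Problem sizes

The packaged desk-scale protocols (10-year block, 7-year meadow,
40--50-year cycling runs, 10 replicates) were chosen so a full
pattern evaluation completes in minutes on a single core; every
scenario accepts the full published dimensions and durations through
its arguments, and `scaleFactor` travels with all outputs so
scaled-down runs are never silently compared to full-scale targets.

## Known limitations

* The desk-scale block reproduces breeding female density within a few
  percent, but the day-200 sex ratio reaches about 2.1--2.3 females per
  male against the printed 1.95, and the day-90 ratio carries about
  10--15% of the summer female excess into spring: overwinter survival
  is sex-symmetric here, and none of the published mechanisms removes a
  standing female surplus between autumn and April.
* The cycling scenarios reproduce the fragmentation contrast
  (single-patch amplitude ≈ 2, sixteen-patch ≈ 1.3) but not the full
  five-year high-amplitude regime: with a 6.25 ha prey base the
  crash-rebuild loop completes in about three years, because prey
  recovery is fast relative to the small capacity and predator cohorts
  cannot compound across winters without immediately suppressing prey.
* Food is not depletable, drought is absent, and the habitat quality
  ranking across classes is a package default, so habitat-by-season
  density comparisons are structural checks rather than quantitative
  fits.
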