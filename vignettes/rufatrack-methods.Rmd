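---
title: "Methods: rule-based telemetry analysis of red knot spring migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based telemetry analysis of red knot spring migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rufatrack)
```

`rufatrack` turns coded-VHF detection histories of migrating *rufa* red
knots into departure timelines, Delaware Bay route classifications,
stopover inventories, flight speeds and wind-support estimates. Every
inference is a deterministic rule with an explicit threshold; this vignette
documents those rules, the conventions chosen at their edges, what the
synthetic-data generator emulates, and what passing the test suite does and
does not demonstrate about real field data.

All timestamps are UTC (ISO-8601 in files, POSIXct internally); all
coordinates are WGS84 decimal degrees with longitudes normalized to
[-180, 180); all distances are great-circle (haversine) on a sphere of
radius 6371.0 km. The spherical approximation differs from an ellipsoid by
well under half a percent, which is irrelevant against 30/50/150-km
decision thresholds, and it keeps all geometry closed-form. The initial
bearing uses the standard spherical formula, consistent with the same
sphere.

## Detection quality control

A Motus-style receiver logs a detection when it decodes a tag's burst of
three rapid pulses; radio noise occasionally decodes as a valid tag id, so
false positives must be removed by structure, not by identity. Three rules
apply, each rejection attributed to exactly one rule, in the order
pulse count → frequency offset → burst-interval runs:

- `min_pulses` (default 3): fewer pulses than a complete burst.
- `freq_offset` (default tolerance 2 kHz): off-frequency decodes, only
  when the offset field is present.
- `burst_interval` (tolerance 0.1 s, up to 10 missed bursts, minimum run
  3): within each tag-by-station sequence, successive gaps must equal an
  integer multiple of that tag's burst interval; maximal consistent runs
  shorter than 3 detections are rejected.

Running the interval rule last, on the survivors of the other two, makes
filtering idempotent: a second pass over already-filtered data recomputes
exactly the same runs and changes nothing. If runs were formed first, a
mid-run frequency-offset rejection could split a surviving run on the next
pass. The receiver-noise context is deliberately *not* modelled beyond the
run rule — there is no per-station noise model to calibrate, and the run
rule is the testable core of interval-based filtering.

Bouts — contiguous runs of valid detections of one tag at one station —
are the unit of all downstream inference. A new bout starts at a station
change or a same-station gap above `bout_max_gap_min` (default 30 min, a
convention; nothing downstream is sensitive to it at the hour-to-day
scales of the stopover and route rules).

## Departure timing under uncertainty

With no receiving station within 50 km of the capture site, most birds'
departures cannot be dated exactly. Two cases:

- the bird's first bout away from the capture site (station > 50 km from
  the deployment coordinates) is at a station inside the inland Carolinas
  region: departure is *known*, dated to that bout, weight 1. An inland
  detection means the bird is actively migrating overland, so the first
  away detection dates the initiation of migration.
- otherwise: a *window* from the deployment date to the date of first away
  detection, both endpoints inclusive, with uniform weights 1/n over its n
  days (5-day window ⇒ 0.2 per day). Both endpoints are candidate days
  because a bird can depart the evening of tagging, and the first away
  detection can occur on the departure day itself; inclusivity is
  configurable in principle but the inclusive convention is what makes a
  4-day gap a 5-day window with weight 0.2.

Birds never detected away from the capture site contribute no estimate and
are excluded (signalled as `NULL`). Summing weights across birds gives the
departure timeline; total mass equals the number of contributing birds by
construction. The weighted median is the smallest date at which cumulative
normalized mass reaches 0.5 (with a 1e-12 guard against floating-point
shortfall at exact halves).

## Delaware Bay route classification

A bird's bay use is scored by the first matching rule, using only bouts
between deployment and the end of the northbound season (15 June of the
deployment year):

1. **stopped** — ≥ 2 bouts at bay stations (within `bay_buffer_km` = 30 km
   of the watershed) whose detections span > `min_stop_days` = 1 day.
2. **likely_stopped** — ≥ 2 bouts in the annulus within another
   `likely_buffer_km` = 60 km, touching ≥ 2 calendar days: repeated
   presence just outside the defined watershed.
3. **skipped** — the bird appears north of the bay's maximum latitude and
   the elapsed time from its last detection at or below that latitude
   leaves less than one day of slack over a direct great-circle flight at
   `assumed_transit_speed_ms` = 20 m s⁻¹ (a typical observed net ground
   speed), with any bay detections being single fly-through passages
   (total bay span ≤ 1 day).
4. **likely_skipped** — northern detection with ≥ 1 day of slack, but all
   intermediate detections are inland: inside the Great Lakes Basin or
   more than `inland_offset_km` = 150 km from the Atlantic coastline
   polyline. The trajectory is inconsistent with mid-Atlantic coastal use,
   but the timing alone cannot exclude an undetected stop.
5. **unknown** — anything else, including birds with a single ambiguous
   post-departure detection.

The tree is total and deterministic: every bird with at least one
post-deployment bout receives exactly one class. Buffered membership tests
use exact point-in-polygon plus cross-track geodesic distance to the
polygon boundary; the 30-km cluster and buffer conventions are pairwise
("clique") rather than chained, the closest literal reading of "within
30 km of each other". Headline proportions (e.g. percent skipping the bay)
are reported over classifiable birds only; unknowns are counted but
excluded from the denominator.

Body mass at capture is compared across pooled strategy groups (stopped,
skipped, unknown) with a classical one-way ANOVA computed from between-
and within-group sums of squares (`F = MSB/MSW`, `R² = SSB/SST`); the
closed form is cross-checked against `anova(lm(...))` in the test suite.

## Stopovers

Only bouts more than 50 km from the tagging location are candidates
(closer detections are local movement around the capture area). Two rules,
both strict at their thresholds ("spanning more than" is read literally, so
a span of exactly 4.0 h is not a stopover):

- single station: a maximal run of same-station bouts with no intervening
  bout elsewhere spanning > 4 h;
- station cluster: a maximal run of bouts whose stations are pairwise
  within 30 km, spanning > 6 h.

Overlapping qualifying runs are merged, so each bout belongs to at most one
stopover. For up to ten bouts the implementation is verified against
exhaustive enumeration of all qualifying contiguous windows. Delaware Bay
stopover *duration* is a separate, simpler quantity: elapsed time between a
bird's first and last detection within the buffered bay region, in days,
for birds with at least two bay detections — a closed interval, matching
how detection spans are measured throughout.

The stopover heat map is a raster: each cell counts the individuals with at
least one stopover station within 50 km of the cell center (cell size
0.25°, each individual at most once per cell). At cell resolution this
yields the same counts as overlaying buffered station polygons while
avoiding geodesic polygon buffering entirely.

## Flights and wind support

Consecutive same-station bouts collapse into passages; every contiguous
passage window is a candidate flight, kept when its first-to-last
great-circle displacement is ≥ 150 km (excluding local movements) and its
duration ≤ 18 h. Duration runs from the *last* detection at the beginning
station to the *first* detection at the ending station, so net ground speed
= displacement / duration is conservative about time actually in flight.
How a multi-day history should be segmented into distinct flights is
underdetermined; the package enumerates all candidate windows and accepts
them greedily by decreasing displacement (ties: earlier departure) subject
to no station being shared between a bird's accepted flights. Total
trajectory length sums the successive great-circle legs, so total ≥
displacement always, with equality only for collinear routes.

Wind is sampled from a gridded u/v field (u eastward, v northward, m s⁻¹ —
the vector points where air moves *to*) at the departure station's
coordinates, at the grid time closest to departure (ties to the earlier
slice), with bilinear spatial interpolation by default and a nearest-node
mode for grids too coarse to interpolate meaningfully. Where wind should be
sampled geographically is a genuine choice — the departure station is used
because departure-time conditions drive the decision to fly; a
midpoint-of-route convention would need no other change. Tailwind support
is the projection `u·sin β + v·cos β` onto the preferred bearing β (the
great-circle bearing to the ending station); positive values are tailwinds,
so a due-north flight counts winds from just south of east through just
south of west as supportive. |T| ≤ wind speed with equality only when the
wind blows exactly along track, and T(β + 180°) = −T(β). The ground-speed
association uses a closed-form Pearson r with a two-sided p from the
t-transform on n − 2 df, cross-checked against `cor.test`.

## The synthetic-data generator

`simulate_scenario()` produces a complete, schema-valid study — stations,
deployments, regions, 6-hourly wind, detections, and per-bird truth — so
that every pipeline stage can be tested against known ground truth. Its
defaults are the study conditions, chosen once:

- **Cohort**: 40 birds — 11 bay stoppers, 21 inland skippers, 8
  Atlantic-coast birds that stop at New York Bay instead of Delaware Bay —
  matching the field finding that roughly three quarters of knots skip the
  bay. Deployments span late April to early May with 1–8 days of residency
  before departure (observed windows span up to ~4 weeks).
- **Network**: 16 stations (capture-area gap of > 50 km, coastal corridor,
  a three-station bay cluster, a Great Lakes corridor, James/Hudson Bay);
  a `dense` option adds inland and coastal infill. Tags use 4.7–11.3 s
  burst intervals at 166.38 MHz.
- **Movement**: piecewise great-circle segments between route stations at
  constant per-segment speed — matching the pipeline's own kinematic
  assumptions so truth stays computable in closed form. Realized speed =
  airspeed (birdwise N(16, 1) m s⁻¹) + 1.0 × tailwind at segment start +
  N(0, 2) m s⁻¹, floored at 5 m s⁻¹. With the default mean southwesterly
  flow (u = 2, v = 4 m s⁻¹ plus smooth harmonic perturbations of ~3 m s⁻¹,
  capped at 25 m s⁻¹) this yields ~20 m s⁻¹ mean northward ground speeds
  and mostly tailwind departures. Bay stopovers last 2–17 days,
  Atlantic-coast stopovers 2–10 days.
- **Detection**: each station pass emits a burst-interval-periodic bout
  (4–10 bursts, ±0.02 s clock jitter) with probability `p_detect` = 0.8;
  stopovers emit bouts every 1–4 h. False positives arrive as Poisson 0.2
  per station-day with real tag ids, random times (hence non-periodic
  structure), a 70/30 mix of incomplete and complete pulse counts, and
  wide frequency offsets — the three failure modes the QC rules target.
  Body mass is drawn ~9 g heavier for skippers than stoppers (N(140, 13)
  vs N(131, 13) g), echoing the observed condition difference.
- **Reproducibility**: one global seed derives per-bird substreams, so the
  same seed is byte-identical and adding a bird does not perturb others.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: correlated movement (no turning within legs,
no wind drift of the track itself), detection-probability dependence on
distance, antenna pattern or noise floor, station outages, tag failure and
mortality, partial-burst decodes at range, or behaviourally realistic
stopover decisions. The generator exists to validate the pipeline's rules
against a world that obeys its assumptions; field data do not.

## Numerical conventions and degenerate inputs

- Strict vs inclusive thresholds: stopover spans (> 4 h, > 6 h) and the
  bay-stop day rule (> 1 day) are strict; flight filters (≥ 150 km,
  ≤ 18 h) are inclusive; both follow the rule statements verbatim.
- Departure weights are exact binary fractions 1/n; sums are asserted to
  1e-9.
- Nearest-time ties in wind sampling go to the earlier slice; queries
  outside the grid extent (or beyond one time step past the ends) are
  errors, not extrapolations.
- Exact-fit regressions: zero residual variance gives t = ±∞ (p = 0) for a
  nonzero slope; a constant response gives slope 0 with R² = 0; constant
  predictors and zero-variance correlations are errors, as is an ANOVA
  with no within-group variance.
- Empty inputs propagate as valid empty tables with correct headers;
  writers are deterministic (stable ordering by tag then time, fixed
  ISO-8601 timestamp rendering with millisecond precision only where
  sub-second structure exists).

## Test-suite problem sizes

The suite validates oracle equivalences on deliberately small inputs
(≤ 10 bouts for exhaustive stopover enumeration; 1000 random point pairs
for the chord-length geodesy oracle; 10,000 random triples for tailwind
algebra) and end-to-end recovery on 40-bird cohorts: one noiseless
dense-coverage scenario that must recover 100% of pooled strategies, all
known departure dates exactly (windows must contain the true date — the
most a window can claim), and every true stopover; and one default noisy
scenario that must keep pooled-strategy accuracy ≥ 90% among classified
birds, false-positive retention ≤ 5% and true-positive retention ≥ 95%.
Estimator calibration uses 200 replicates of the 40-flight wind-coupling
model for the Pearson r sampling distribution and 10,000 null simulations
for the ANOVA type-I error.

## Known limitations

- Route classes 3–4 depend on the assumed 20 m s⁻¹ transit speed; a bird
  flying into sustained headwinds can accrue apparent slack and fall to
  `unknown` (never spuriously to `stopped`).
- The coastline inland test needs an `atlantic_coast` polyline region;
  without one, only Great Lakes membership can certify an inland route,
  and `likely_skipped` becomes rarer.
- Region polygons are exterior rings only (no holes), adequate for
  watershed/basin-scale screens but not for fine coastal geometry.
- Wind is sampled at one point and one pressure level per flight; no
  along-route averaging.
- Stopover rules cannot separate true multiday refueling stopovers from
  rest stops of under a day; that distinction is out of scope.
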