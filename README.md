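# rufatrack

Rule-based analysis of automated VHF telemetry (Motus-style) detection data
for northbound spring migration of *rufa* red knots (*Calidris canutus
rufa*), with a synthetic-data generator that provides complete study inputs
with known ground truth.

## The problem

Red knots wintering or staging in the Southeast United States migrate north
in May toward Arctic breeding grounds, either along the Atlantic coast —
classically staging in Delaware Bay to refuel on horseshoe crab eggs — or
along an inland route through the Great Lakes Basin. Coded VHF nanotags and
a continental network of automated receiving stations make it possible to
score which route each bird took, when it departed, where it stopped, and
how fast it flew — but the raw detection stream is noisy (false positives
decode as real tags), the receiver network is sparse (often no station near
the capture site), and every inference must be expressed as an explicit,
reproducible rule.

`rufatrack` implements that rule set as a tested pipeline:

1. **Detection QC** — a detection is kept only if it has a complete burst
   (≥ 3 pulses), an in-band frequency offset, and sits in a run of ≥ 3
   detections whose successive gaps match integer multiples (k ≤ 10) of the
   tag's burst interval to within 0.1 s. Every rejection is attributed to
   exactly one rule.
2. **Departure timing** — a bird first detected away from the capture site
   (> 50 km) by an inland Carolinas station has a *known* departure date
   with weight 1; otherwise it gets an inclusive day window from deployment
   to first away detection with uniform weights 1/n (a 5-day window
   contributes 0.2 to each day). Summing weights over birds gives the
   uncertainty-weighted departure timeline; its weighted median is the
   smallest date with cumulative mass ≥ 0.5.
3. **Route classification** — each bird is scored
   `stopped / likely_stopped / skipped / likely_skipped / unknown` for
   Delaware Bay use: ≥ 2 bouts at stations within 30 km of the bay
   watershed spanning > 1 day ⇒ stopped; repeated multi-day presence in the
   60-km annulus just outside ⇒ likely stopped; a northward passage whose
   elapsed time leaves < 1 day of slack over a direct great-circle flight
   at 20 m s⁻¹ ⇒ skipped; ample slack but purely inland evidence ⇒ likely
   skipped; anything else ⇒ unknown. Headline proportions are computed over
   classifiable birds only.
4. **Stopovers** — detections > 50 km from the tagging site spanning > 4 h
   at one station (no intervening detections elsewhere) or > 6 h across
   stations within 30 km of each other; plus a 50-km-buffer stopover heat
   map of individual counts per grid cell.
5. **Flight kinematics** — migratory flights between stations ≥ 150 km
   apart lasting ≤ 18 h; net ground speed v = displacement / (t_first,end −
   t_last,begin), with displacement the orthodrome (great-circle) distance
   on a 6371-km sphere.
6. **Wind support** — surface (1000 hPa) wind sampled at the departure
   station at the grid time closest to departure; tailwind support
   `T = u·sin β + v·cos β` for preferred bearing β (the great-circle
   bearing to the ending station); any wind within 90° of the track is a
   tailwind (T > 0). Ground speed vs tailwind is summarized with a
   closed-form Pearson r and t-based p-value.

## Worked example

Simulate a 40-bird cohort (11 bay stoppers, 21 inland skippers, 8
Atlantic-coast birds that stop outside Delaware Bay) under the default
noisy conditions (detection probability 0.8 per station pass, 0.2 false
positives per station-day, wind-coupled flight speeds) and run the full
pipeline:

```r
library(rufatrack)
sim <- simulate_scenario(sim_scenario(seed = 42))
report <- run_pipeline(sim$detections[, 1:6], sim$stations,
                       sim$deployments, sim$regions, sim$wind)
print(report)
#> rufatrack study report
#>   QC: 11151 detections in, 10937 valid (min_pulses 153, freq_offset 38, burst_interval 23)
#>   departures: 40 birds (21 known, 19 window); weighted median 2019-04-30
#>   strategy: stopped 11, likely_stopped 0, skipped 29, likely_skipped 0, unknown 0; skipped-pooled 72% of 40 classifiable
#>   Delaware Bay duration: 11.7 +/- 4.8 d (median 13.6, range 4.2-16.8, n = 11)
#>   flights: 52 (40 birds); median displacement 1000 km; mean speed 19.8 m/s
#>   speed~tailwind: r = 0.55 (P = 2.45e-05, n = 52); tailwind departures 100%
```

Reading this: 214 of 11,151 simulated detections were rejected by the three
QC rules (all 214 injected false positives among them); 21 birds got known
departure dates from inland Carolinas stations and 19 got day windows; all
40 birds were classified, 72% pooled as skipping Delaware Bay (the
generator's truth is 29/40 = 72.5%, and every call matches its bird's true
pooled strategy); the 11 bay stopovers averaged 11.7 days measured
first-to-last bay detection; and the 52 extracted flights averaged
19.8 m s⁻¹ with ground speed significantly correlated with departure
tailwind, as built into the generator's speed model
(speed = airspeed + tailwind + noise).

`write_results(report, "out/")` writes the per-figure tables
(`departures.csv`, `timeline.csv`, `strategies.csv`, `stopovers.csv`,
`delaware_durations.csv`, `flights.csv`), `heatmap.geojson` and
`summary.json`, deterministically. `write_scenario(sim, "data/")` writes
the simulated inputs in the package's input schemas plus `truth.json`.

With real field data, supply `detections.csv`, `stations.csv`,
`deployments.csv`, `regions.geojson` (watershed/basin polygons) and a
long-format wind CSV to `load_dataset()`, then call `run_pipeline()` the
same way.

## Package layout

- `R/config.R` — `rufa_config()`, every numeric rule with its default
- `R/io.R` — readers/writers, `load_dataset()`, `validate_dataset()`
- `R/qc.R` — `filter_detections()`, `bout_detections()`
- `R/departure.R` — `estimate_departure()`, `departure_timeline()`
- `R/route.R` — `classify_delaware_strategy()`, `summarize_strategies()`,
  `mass_by_strategy()`
- `R/stopover.R` — `detect_stopovers()`, `delaware_stopover_durations()`,
  `stopover_heatmap()`
- `R/flights.R` — `extract_flights()` and trajectory kinematics
- `R/wind.R` — `sample_wind()`, `tailwind_support()`,
  `speed_wind_association()`
- `R/simulate.R` — `sim_scenario()`, `simulate_scenario()`,
  `simulate_wind()`
- `R/report.R` — `run_pipeline()`, `build_report()`, `write_results()`

See `vignettes/rufatrack-methods.Rmd` for the full methodological account:
rule conventions and their edge cases, what the synthetic generator does
and does not emulate, and known limitations.
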