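---
title: "Methods: context-specific physical activity from fused accelerometer and GPS streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-specific physical activity from fused accelerometer and GPS streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`actispace` quantifies *where* and *when* young children accumulate physical
activity by fusing two per-child sensor streams recorded over several
consecutive days: hip-worn accelerometer counts aggregated into 10-second
epochs, and a GPS logger sampling at the same cadence between 06:00 and
22:00. This vignette is the package's account of the underlying procedure,
the choices it embeds, and what its validation does and does not establish.

## The measurement model

Each child-day is a pair of time series on a shared local clock. The
accelerometer stream carries vertical-axis counts per epoch plus per-epoch
summaries (sd and range, in milli-gravity) of the raw signal; the GPS stream
carries position, elevation and logged speed. All timestamps are naive local
time: school bells and the 6–8 AM home-anchor window are local-clock
concepts, and no DST transition falls inside a measurement week.

The analysis proceeds in stages, each a pure function of tabular input:

1. **Wear status.** The recording is divided into 15-minute blocks. A block
   is non-wear when the 60-minute window centred on it shows both a raw sd
   below 13 mg and a raw range below 50 mg — an unworn device lies still. We
   receive variability as per-epoch summaries rather than raw waveforms, so
   the window statistic must be assembled from them: the window sd is the
   root-mean-square of the member epochs' sds (the pooled within-epoch sd
   under negligible between-epoch mean drift, a good approximation at 10 s
   epochs), and the window range is the maximum of the member ranges. With
   tri-axial summaries the rule is applied per axis and two of three axes
   must be quiet; with a single summary column that column decides. Windows
   are clipped at the recording edges and evaluated only when at least 30
   minutes of signal remain; unevaluable blocks stay worn. Streams without
   raw summaries fall back to all-worn with a warning rather than guessing
   wear from counts.

2. **Intensity.** Counts are classified with children's vertical-axis
   cut-points defined at a 15 s reference epoch (sedentary ≤ 25, moderate
   ≥ 574, vigorous ≥ 1003 counts/15 s by default — the values are
   configuration, not constants) and rescaled to the recording epoch by the
   linear factor `target/reference`. Class intervals are closed on the
   lower moderate and vigorous boundaries (counts exactly at the moderate
   boundary are MPA); the sedentary boundary is inclusive from below. A
   cut-point set that does not match the stream's epoch length is an error,
   never a silent rescale. MVPA is MPA ∪ VPA.

3. **GPS cleaning.** Three outlier rules, each judged against the previous
   *retained* fix: missing speed; speed above 130 km/h with an absolute
   speed difference above 30 km/h; elevation change above 1000 m. "Absolute"
   difference is our reading — the sign convention is not fixed by common
   practice — and cleaning is idempotent by construction.

4. **Trips.** A trip opens at the first fix of three successive fixes at
   ≥ 1 km/h (30 s of sustained movement at 10 s cadence). Inside an open
   trip, a spell of sub-threshold fixes is a *pause* if its still fixes span
   at most 2 min, and any single above-threshold fix resumes the trip; a
   longer spell ends the trip at the last moving fix. Trips below 100 m or
   60 s, or containing an inter-fix time gap above 30 s, are discarded
   whole (the gap rule is a trip-level discard, not a split). Mode comes
   from the 90th percentile (linear interpolation between order statistics)
   of the member fix speeds, pause fixes excluded: ≥ 1 km/h pedestrian,
   ≥ 10 bicycle, ≥ 35 vehicle. The motorized boundary is genuinely
   ambiguous in the field — 35 km/h appears in method descriptions and
   25 km/h in result tables — so it is a parameter (`vehicle_min`),
   defaulting to 35. Pause time counts toward trip duration; the trip starts
   at the first fix of the qualifying run, not the third.

5. **Anchors and context.** The home anchor is the arithmetic centroid, in
   a local azimuthal-equidistant projection, of all fixes between 06:00 and
   08:00 on sleep-at-home days, computed separately for weekdays and
   weekend days; its distance to the parent-reported postal-code centroid
   is the validation statistic, and the postal centroid is the documented
   fallback when a day type has no qualifying mornings. Every fix then gets
   one of nine integrated home–school categories built from 10/100/400/800 m
   bands around both anchors. The < 10 m bands use straight-line distance
   (and a fix inside the school parcel polygon is at school regardless of
   its distance to the school point); the wider bands use a distance
   provider — straight-line by default, optionally scaled by a constant
   detour factor ≥ 1 to emulate street networks, or a user-supplied
   road-graph function. When both anchors claim a fix the smaller distance
   wins, with ties to the home side; band combinations that correspond to
   no listed category — including 400–800 m from both anchors — are
   `unclassified` rather than forced into a neighbouring row, which is why
   category weartime sums to total weartime only with `unclassified`
   included. Separately, fixes within 10 m of park, sports-terrain or
   playground polygons receive non-exclusive public-space labels
   (point-in-polygon plus distance-to-boundary in the local projection).

6. **Fusion and day summaries.** Each epoch takes the nearest fix within
   10 s of its timestamp (ties to the earlier fix). An epoch is *retained*
   when it is both worn and GPS-matched; a weekday is valid with ≥ 8 h of
   retained weartime, a weekend day with ≥ 6 h, both inclusive. Valid days
   are summarized into minutes of sedentary, LPA and MVPA per context
   category, per trip state (with a `trip_unclassified` level so the
   partition is exhaustive), per hour, per school-schedule period
   (half-open `[start, bell)`, shortened Wednesday/Friday bells supported)
   and per public-space label. Percentages are minutes over weartime *in
   the same cell*. Cohort tables take unweighted means and sample SDs
   (n − 1) over valid days — days, not children, are the unit — with
   single-day cells flagged and their SD reported as 0; cohort percentages
   are aggregate ratios (mean minutes / mean weartime), matching how such
   tables are conventionally assembled.

## The synthetic cohort

Because no participant data accompany this problem, the package carries a
first-class generator. `generate_cohort()` lays out schools (60 m square
parcels) with nearby public-space polygons, places homes 150–1200 m from
the assigned school, offsets a postal centroid uniformly up to 100 m from
the true home, and builds each day as an itinerary of epoch-aligned
segments: weekday school attendance with escorted trips timed to arrive
five minutes before the bell, after-school outings or yard play, weekend
outings, and evening routines. Trip mode is sampled per day from
configurable probabilities restricted to modes feasible for the distance
(bicycle ≥ 300 m, vehicle ≥ 800 m, so every simulated trip survives the
distance and duration filters by construction); trajectories are
piecewise-linear great-circle paths, giving an exact arc-length oracle.

Intensity is realized per epoch: outside trips, a baseline sedentary/light
mixture per state is punctuated by Poisson-arriving MVPA bursts with
geometric durations (mean 45 s), reflecting the short sporadic activity
pattern of 4–6-year-olds; during trips, a per-mode intensity profile
applies (cycling MVPA deliberately low — a vertical-axis hip sensor
underestimates cycling). Burst rates (school 8/h, yard 8/h, public spaces
10/h, other locations 5/h, home indoor 1/h) were chosen so a default
cohort accumulates on the order of 50 daily MVPA minutes with school
contributing about half on weekdays — the documented scale for this age
group — and are stated here as the generator's definition of realistic,
not as quantities the validation compares against.

`emit_sensors()` converts truth to device streams. Counts are drawn
uniformly within the intensity class's count interval at the scaled
cut-points, making classification exactly invertible; non-wear epochs emit
zero counts and raw summaries far below the 13 mg/50 mg thresholds while
worn epochs sit far above them. GPS noise is AR(1) per axis (stationary sd
10 m, lag-one correlation 0.95 at 10 s): GPS error drifts rather than
jittering white, and white noise of realistic amplitude would inflate
summed path lengths far beyond what loggers show. Dropout is i.i.d. per
fix (2%), which also exercises the 30 s gap filter. During non-wear the
logger keeps recording at the place the device was left (episodes are
constrained to home segments), mirroring devices recharged at home — this
is what keeps 6–8 AM anchor inference possible on weekend mornings with
delayed wear.

What the generator does *not* emulate: raw 30–100 Hz waveforms, urban
canyon multipath or indoor signal loss beyond i.i.d. dropout, road-network
routing (trips fly straight), weather and seasonality, sibling
co-movement, and between-child behavioural heterogeneity beyond geometry.
Passing recovery tests therefore shows the pipeline implements its rules
correctly and degrades gracefully under calibrated noise — not that it
would be unbiased on field data with structured GPS failure modes.

## Numerical choices and degenerate inputs

* Geodesy is spherical (mean radius 6 371 008.8 m): haversine distances,
  and an azimuthal-equidistant local frame whose forward and inverse maps
  are exact mutual inverses — the zero-noise identifiability tests depend
  on that exactness. At city scale the projection error is centimetres.
* Window membership in non-wear detection is the half-open interval
  `[centre − 30 min, centre + 30 min)`, implemented with open-ended
  `findInterval` bounds rather than an epsilon: a subtracted `1e-9` s
  underflows at POSIX-time magnitudes and silently admits the boundary
  epoch (caught by the brute-force oracle during development).
* Pause duration is the time span of the sub-threshold fixes themselves
  (first to last still fix). The boundary case `span = 120 s` is a pause;
  `> 120 s` ends the trip.
* The p90 uses R's type-7 quantile. Empty trips are an error; degenerate
  streams (no fixes, all-still) yield zero trips, not errors.
* Duplicate GPS timestamps are dropped at speed derivation; the logged
  speed is trusted by default and derivation only fills gaps unless
  explicitly overridden.
* Epoch–fix matching ties break toward the earlier fix; the tolerance
  equals one epoch so a dropout of a single fix never orphans an epoch.
* Day boundaries are calendar days; with devices logging 06:00–22:00 this
  is equivalent to device days.
* All validation thresholds, bands and tolerances live in
  `pipeline_config()` and round-trip losslessly through YAML; invalid
  configurations are rejected at construction and again at load.

## Validation design and problem sizes

The package's correctness argument is property-based, at these sizes
(chosen to finish comfortably on a single CPU):

* trip segmentation, pauses, filters and mode classification agree exactly
  with an independent per-fix state-machine implementation of the rules on
  1 000 random streams of up to 200 fixes with mixed regimes, gaps and
  still spells (the package itself uses run-length algebra, so the two
  codepaths share nothing but the rules);
* non-wear flags agree exactly with a per-block brute-force window
  evaluation on 500 random day signals;
* cut-point rescaling matches the closed form to 10⁻⁹ on 100 random sets;
* on a noiseless 20-child × 7-day cohort the full pipeline — including
  anchor inference from the emitted GPS — reproduces every ground-truth
  day-summary cell exactly, and the context, trip-state and temporal
  partitions each sum to weartime to machine precision;
* under the default noise model the cohort-mean MVPA per context stays
  within 5 min/day of truth and home-anchor inference within 5 m over 50
  Monte-Carlo seeds. The dominant residual is structural, not a bug: with
  10 m position noise against a 10 m at-home band, roughly 60% of true
  at-home epochs land in `close_to_home` (Rayleigh leakage), so the
  at-home/close-to-home pair absorbs almost all of the error budget while
  polygon-based school assignment is nearly noise-immune. Real studies
  face the same indistinguishability.

## Known limitations

Network distances default to a detour-factor approximation unless a road
graph is plugged in; the home anchor is a point, not a parcel; GPS-based
trip detection cannot see indoor movement and misclassifies slow scooter
travel as walking; uniaxial counts underestimate cycling intensity; and
the valid-day rule conditions on *combined* sensor availability, so GPS
dropout depresses weartime even when the accelerometer was worn — all
properties shared with the measurement tradition this package implements,
kept here so results remain comparable.
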