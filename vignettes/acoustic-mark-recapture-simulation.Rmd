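---
title: "Simulating acoustically assisted mark-recapture whale surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating acoustically assisted mark-recapture whale surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mark-recapture abundance estimation of whales needs encounters: a vessel must
find a group, close with it, and "mark" it by photo-identification or biopsy.
For rare or wide-ranging species (Antarctic blue whales being the extreme
case) visual searching alone yields very few encounters per day at sea.
Passive acoustics extends the detection range by an order of magnitude: a
vocalising group can be heard tens of kilometres away, tracked by bearings,
and run down until it can be seen and marked. `amrsim` is a discrete-time,
individual-based simulator of this process. It predicts the *expected
encounter rate* (encounters per hour of total survey time, nights and
off-effort weather included) of three survey designs:

* **AMR** — acoustically assisted mark-recapture: the full machinery;
* **VMR** — visual-only mark-recapture: the same vessel and marking rules with
  the acoustics switched off;
* **LT** — a visual line-transect survey on fixed parallel transects, with no
  marking stops, as the classical baseline.

The simulator is a planning tool: it maps biological, instrumental and
logistical parameters to expected encounter rates, so that survey designs and
equipment choices can be compared before committing ship time. It does not
perform the downstream mark-recapture estimation itself.

## Model components

### Whale groups

The simulation unit is the *group* (for Kaikoura sperm whales a "group" is a
single animal). Groups move by a correlated random walk: at each step the
heading receives a wrapped-Normal increment with standard deviation
`turn_sd * sqrt(dt / 0.5)` degrees (so the heading diffusion rate is
independent of the step size) and the step length is
`speed_mean * dt * (1 + Normal(0, distance_sd_frac))`, floored at zero. A
group whose candidate step leaves the rectangular survey area reverses
direction (heading + 180°) and is clamped to the boundary. Neither `turn_sd`
nor `distance_sd_frac` is an empirically measured quantity; the defaults (30°
per half-hour step, CV 0.2) produce smoothly wandering tracks and are exposed
in the configuration.

Two spatial models are available. Under `uniform`, groups are placed
independently and uniformly and move independently. Under `clumped`, clump
centres are uniform, members are scattered around them with an isotropic
Gaussian of sd `clump_spread`, and each clump moves as a rigid block (one
random-walk step per clump, applied to all members; boundary reversal is
decided at the clump centroid). The number of clumps defaults to
`ceiling(n / clump_mean_size)`, so aggregation intensity, not clump count, is
what stays fixed as density varies. The clumped model stands in for loose
aggregations ("herds") on shared prey patches; our presets use mean 4 whales
within ~2 km for Kaikoura sperm whales and mean 10 groups within ~4 km
(Gaussian sd) for Antarctic blue whale aggregations. These are field-informed
choices, not measured quantities, and both are configuration knobs.

Abundance comes either from a Normal draw of the group count (redrawn each
simulated day) or from a fixed density times the area.

### Vocalisation and diving

Each group is vocally capable with probability `p_vocal`, independently.
With the dive cycle disabled (the baleen-whale convention) a capable group
vocalises continuously. With the cycle enabled (sperm whales), dive and
surface phases alternate with truncated-Normal durations (floor 1 min, so a
Normal(9.1, 2.5) surfacing can never be non-positive), and the group
vocalises only during the first `vocal_fraction_of_dive` of each dive — it is
silent for the last part of the dive and at the surface. The same cycle
drives visual availability: a diving sperm whale cannot be sighted. Blue
whale groups are always visually available; availability is subsumed in the
effective strip width and g0.

### Acoustic instruments

Detection is a *hard disc*: every vocalising group within `effective_range`
(a closed disc) of a listening station is detected with certainty, none
beyond. The effective range plays the role of the effective strip half-width
of distance sampling, which is how the empirical values for it were derived.

* **Hand-held directional hydrophone** (small-boat workflow): the vessel
  stops for a timed dwell at listening stations spaced `dip_spacing`
  kilometres apart along its track. Each dip yields one noisy bearing
  (wrapped Normal, sd `bearing_sd`) and one aural distance estimate
  (multiplicative error with CV `distance_sd_frac`, floored at 0.1 km and
  capped at the effective range — a detected whale is by definition within
  range) per audible group.
* **DIFAR sonobuoys** (ship workflow): expendable drifting stations dropped
  at time intervals (`drop_interval_search` while searching,
  `drop_interval_target` while tracking). A buoy provides bearings only
  while younger than `buoy_life` and within `vhf_range` of the vessel; buoys
  are never retrieved and never reactivate. Bearing updates arrive at
  `bearings_per_hour` through a deterministic fractional accumulator; each
  update uses the newest single bearing. When two concurrently active buoys
  hold the same group, the two most recently deployed are intersected into a
  cross-bearing fix; intersections behind either station (diverging rays) or
  parallel rays yield no fix.

### The vessel

The vessel runs a four-mode state machine.

* **Naive search**: steam toward the centre of the nearest unvisited cell of
  a coverage grid (cell side twice the visual half-strip, boustrophedon
  tie-break); the grid resets when fully covered.
* **Targeted**: with only a single bearing available, follow the bearing line
  — run parallel to it inside a 2 km corridor, else close on it
  perpendicular. With a hydrophone fix (bearing + distance) the vessel heads
  for the estimated position, holding there and re-listening at the dwell
  cadence. Successive noisy fixes feed an alpha-beta tracking filter
  (position gains 0.6 within 2 km, 0.5 beyond; velocity gain 0.25; speed cap
  10 km/h) whose dead-reckoned state carries the aim point through the
  whale's silent pre-surfacing minutes. Filter gains were chosen by
  simulation experiment to minimise lost surfacings; they are not biological
  parameters.
* **Direct track**: steam straight at a cross-bearing fix.
* **Marking**: a sighted group is logged as an encounter (once per group per
  replicate — re-encounters are never counted) and then marked. Marking
  requires workable visual conditions and lasts `time_to_mark` hours (blue
  whales, 1.51 h), or until the current surface phase ends — fluke-up —
  for sperm whales. The vessel works *alongside* the group being marked, so
  it drifts with the group rather than anchoring: this keeps it inside a
  drifting aggregation, which is what makes clumped distributions profitable.
  A session interrupted by nightfall or weather restarts (an identification
  session cannot resume against a re-mixed group hours later).

Tracking ends by per-hour abandonment (`1 - (1 - p)^dt` per step), by
`give_up_time` hours since the last acoustic contact with the target (the
clock runs from the *last contact*, also when a queued detection is adopted),
or by `max_tracking_time` since tracking began. Groups detected but not
tracked are queued (FIFO, staleness-capped) and revisited after the current
encounter concludes.

Two team-capability switches matter:

* **Observer model.** The ship-based scenario scans continuously; the strip
  swept each tick is the capsule around that tick's movement segment, so
  coarse time steps do not leave gaps between per-tick detection discs (the
  line-transect mode is validated against the strip-transect closed form
  `2 w v D`). The small-boat scenario searches effectively only when stopped
  or at a listening station — at 37 km/h in an open boat there is no useful
  visual search — except that a team actively tracking a target is on full
  alert.
* **Acoustic identity** (`recognise_marked`). In a long-term study of known
  resident individuals (Kaikoura) the team recognises already-marked whales
  acoustically and never re-targets them. In an open-ocean survey bearings
  carry no identity: already-marked groups are tracked like any other and
  are only recognised — and released without logging anything — once sighted.
  This wasted effort is a real and growing cost as the season's catalogue
  fills, and it is what saturates the acoustic advantage at high density.
  Short-term acoustic continuity is retained either way: a group the team
  just marked (or just recognised) is not re-targeted until contact has been
  stale for the pending-staleness window — a crew always knows "that is the
  singer we just left".

### Environment

Daylight is a half-open window `[dawn, dusk)`. Sea state follows a
persistent Markov chain: each step keeps the current Beaufort level with
probability `transition_persistence` (0.9 per half-hour by default),
otherwise redraws from the stationary weights; sightability is an ordinal
index mapped from sea state (`6 - Beaufort`, floored at 0). Visual work
requires daylight, sightability at or above the team's minimum and sea state
at most Beaufort 5; acoustics operate to `max_sea_state` around the clock
(or only in daylight, for the overnight-acoustics comparison); above
Beaufort 5 the vessel heaves to. At night the vessel moves only when
acoustics are operating — without them there is nothing to do in the dark,
so it drifts and resumes at first light, which is exactly what the
overnight-tracking comparison measures. A user-supplied sea-state series can
replace the synthetic chain via the weather parameters. The synthetic chain
reproduces a chosen marginal distribution and persistence but none of the
diurnal or synoptic structure of a real record, so weather-driven variance
in the outputs should be read as indicative only.

## Scenario presets

`preset_kaikoura()` encodes the small-boat sperm whale study (7.033-h survey
days at a 2-min step, hydrophone acoustics, dive-cycle availability, marking
to fluke-up, weather off, count ~ Normal(13.8, 1.3) in an 18.52 x 37.04 km
rectangle). `preset_antarctic()` encodes the blue-whale ship survey (240 h
at a 0.5-h step, sonobuoys, density 0.000539957 groups/km^2 in a
400 x 400 km area, 60% of groups vocal, marking 1.51 h, abandonment 0.02/h,
synthetic weather on, overnight acoustics on). The 400-km square is our
choice: large enough that boundary reversal is rare on a 10-day track, small
enough to keep replicates cheap; the density-mode results are insensitive to
it. Blue-whale batteries default to a five-point log-spaced density grid
spanning 0.0002–0.002 groups/km^2 around the current density estimate.

## Numerical choices

* Planar coordinates in km, origin at the SW corner; headings in degrees
  clockwise from north; times in hours. No geodesy — areas are at most a few
  hundred km across.
* The tick order is: environment, whale movement and dive update, sonobuoy
  lifecycle and drops, listening/bearing events, tracking time-outs, vessel
  decision and movement, visual detection and encounter logging. Whale
  tracks are simulated up front (they do not depend on the vessel), which
  also fixes the random-number layout: whale draws first, then per-tick
  vessel/acoustics draws.
* One root seed per replicate; batteries and sweeps derive per-replicate
  seeds with a Lehmer-style hash of (root, cell, replicate), so results are
  independent of execution order and every replicate is bit-reproducible.
* Dwell times are quantised to whole ticks (nearest, at least one); at most
  one encounter is logged per tick (the nearest sighted group; the rest stay
  available).
* Degenerate cases: zero groups yield an empty, zero-rate result; a zero
  acoustic range reduces AMR to VMR behaviour; `g0 = 0` disables sighting.

## What the tests do and do not show

The test suite checks the component operations against closed forms and
Monte-Carlo oracles (heading-increment spread, renewal fractions of the dive
cycle, binomial vocal fractions, cross-fix exactness at zero noise, the
strip-transect closed form, abandonment compounding), the bookkeeping
invariants (containment, encounter-source partition, per-group uniqueness,
seeded reproducibility), and scaled-down reproductions of the two study
scenarios (2,000 simulated Kaikoura days; 300 replicates per density cell
for the Antarctic batteries — sizes chosen to keep the whole suite to tens
of minutes on one core while holding Monte-Carlo error well inside the
tolerance bands). Passing them shows the *simulator* behaves as specified
and reproduces the study-scale outputs under these presets; it does not
validate the presets against the ocean. In particular the clump geometry,
movement noise and synthetic weather are plausible stand-ins, and real
surveys add heterogeneity (individual vocal behaviour, spatial density
gradients, responsive movement) that this model deliberately omits —
which is why simulated between-day variance should be expected to
underestimate real-world variance.

## Known limitations

* Sound propagation is collapsed into a hard detection disc; no ambient
  noise, no gradual detection function.
* Group identity is perfectly known to the *bookkeeping* (encounter
  deduplication); the `recognise_marked` switch controls only what the
  simulated team may act on.
* Long-range acoustic detections do not inform broad-scale vessel strategy;
  human judgement beyond the stated decision rules is not modelled.
* The photo/biopsy success probability is not modelled; marking always
  succeeds after its time cost.
* Line-transect mode uses fixed north-south transects spaced at twice the
  visual strip width with no closing mode.

## A worked example

```{r, eval = FALSE}
library(amrsim)

# one 10-day Antarctic replicate
r <- run_survey(preset_antarctic("clumped"), seed = 1)
print(r)

# a small battery over the default density grid
bat <- run_density_grid(preset_antarctic("clumped"),
                        default_density_grid(), n_reps = 50, seed = 1)
print(bat)
plot(bat)

# sensitivity of the encounter rate to the effective acoustic range
sw <- sweep_parameter(preset_antarctic("clumped"), "ac.effective_range",
                      values = c(10, 25, 50, 100), reps_per_cell = 50)
print(sw[, c("value", "mean_rate", "mc_se")])
```
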