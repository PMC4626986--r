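---
title: "Dynamic isochrone coverage for EMS deployment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic isochrone coverage for EMS deployment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

emscover simulates a rural Emergency Medical System — one hub of ambulances
serving a road network of towns — and measures the public-health risk of slow
rescue through indicators built on *isochrones*: the curves joining points at
equal travel time from the first available ambulance. This vignette documents
the model, its assumptions, the tunable parameters, and the design decisions
behind the implementation; the README shows the user-facing workflow.

## The system and its indicators

An ambulance serving an accident runs through six tasks: preparation at the
hub, travel to the scene, on-scene assistance, travel to the nearest
hospital, hospital drop-off, and the return to base. The unit is unavailable
for the whole cycle — by default it can only take a new call once back at the
hub (a `dispatch_from_hospital` flag relaxes this). Accidents are dispatched
FIFO to the closest free unit, ties broken by unit id.

Three indicator families summarise a run:

* **Population coverage** $\phi_k = \mathrm{PopulationCovered}_k /
  \mathrm{Population}$: the share of the (time-varying) population in cells
  whose *rescue time* is at most $k$ minutes. The rescue time of a cell at an
  instant is the travel time from the first available ambulance: for a free
  unit, travel from its current cell; for a busy unit, the remaining time
  until it becomes available plus travel from its availability cell; the
  minimum over units is used. $\phi_k$ is reported as its time-weighted
  average over the horizon, at thresholds $K = \{10, 20, 30, 40, 50, 60\}$
  minutes by default — the 60-minute level is the Golden Hour.
* **Town coverage** $\pi_k = \mathrm{TimeCovered}_k / \mathrm{Timeframe}$:
  the fraction of the horizon during which a given town's cell lies inside
  the $k$-minute isochrone. Each town's population is treated as concentrated
  in its single cell, so at any instant a town is covered or not at once.
* **Occupation**: the partition of each unit's horizon into travelling
  (tasks 2, 4, 6), preparation (task 1), assistance (tasks 3 and 5) and free
  time. The free fraction is the availability, the cost-side indicator.

## Road model and travel times

The region is a rectangular lattice. Road cells carry a base traversal time
in minutes; hub, hospitals and towns sit on road cells; movement is
4-neighbour. Crossing between adjacent cells costs the mean of the two
cells' traversal times — half a cell is traversed on each side of the
boundary — which makes travel times symmetric and gives the natural reading
that the $i$-th cell of a uniform 1-minute road is $i$ minutes out.
Single-source shortest-time fields are computed with Dijkstra's algorithm
over the road subgraph; route ties are broken deterministically by exploring
neighbours in lexicographic `(row, col)` order. Diagonal movement is
disallowed (the simplest consistent metric on a cell grid).

Traversal times are penalised multiplicatively:

* **Weather** events (rain ×2, snow ×3, fog ×3, ice ×4; durations 120, 240,
  120, 240 minutes) cover the whole network. Simultaneous events combine by
  the **maximum** factor, not the product: multi-event composition is not
  otherwise defined, and a product would compound implausibly (snow during
  fog would cost 9×).
* **Congestion**: an accident doubles the traversal time of its cell and the
  8 surrounding cells from its occurrence until 60 minutes
  (`congestion_extra_min`) after the serving unit leaves the scene.
* **Festivities**: on road-closure days the whole network doubles.
* A **stress multiplier** scales everything, including task times
  (sensitivity runs use 2).

A leg's duration is priced with the penalties frozen at its departure
instant: legs are short relative to event durations, and freezing keeps
every leg deterministic given the event calendar.

## Stochastic inputs

* **Accidents**: each rated road segment has a mean monthly count
  $\lambda$; arrivals within a month are a Poisson process (exponential
  inter-arrivals with rate $\lambda$ per month-length), located uniformly on
  the segment's cells. $\lambda = 0$ produces no accidents.
* **Weather**: the per-month event-day counts are Poisson means for the
  number of events in that month; one recorded event-day maps to one event
  of the catalogued duration, starting uniformly within the month. The model
  carries no spatial weather structure. The bundled meteorology table also
  records storm days, but storms have no penalty factor of their own; they
  are ignored unless `storm_as` maps them onto a penalising event type.
* **Service times** (minutes): preparation is lognormal(2.5, 1), read as
  log-scale parameters — the conventional reading, giving a median of
  $e^{2.5} \approx 12.2$ min; the scenario's distribution parameters can be
  changed if a mean/sd reading is preferred. On-scene time is
  uniform(23.2, 37.2) and hospital time triangular(12.7, 13.7, 21.9), read
  as (min, mode, max) — the only assignment consistent with an ascending
  triple.
* **Population**: on weekdays each town holds its static census population.
  Monthly hotel stays are split over towns proportionally to population,
  spread uniformly over that month's weekend and local-event days, and on
  those days the resulting population is raised by 20%
  (`weekend_uplift = 1.2`) for floating population. Monthly festivity-day
  counts are placed on deterministic, evenly spaced days of each month (the
  sources publish counts, not dates). Month lengths and weekends follow the
  scenario's calendar year (2014 by default).

Randomness is organised in four named substreams (accidents, weather,
service, population) whose seeds derive from `(master seed, replication)`.
Runs that differ only in the number of ambulances or the stress multiplier
therefore consume identical random inputs — the common-random-numbers
contract that makes deployment comparisons paired rather than noisy.
Service-time triples are pre-drawn per accident in occurrence order, so they
stay attached to "their" accident whatever the staffing level.

## The event-driven engine and exact time-averaging

The future-event list holds environment changes (day rollovers, weather
starts/ends, closure-day boundaries), congestion expirations, ambulance
stage completions and accident occurrences; simultaneous events execute in
that fixed priority order, then by id. Monthly/daily data updates re-price
rates and populations but never interrupt a leg in progress.

Between consecutive events, every input of the indicators is constant except
the remaining unavailability of busy units, which decreases linearly. The
rescue time of population cell $p$ is $\max(0, a_i - t) + b_{ip}$ minimised
over units $i$ ($a_i$ the unit's estimated availability instant, $b_{ip}$
the scaled travel time from its availability cell), so the time each cell
spends inside the $k$-minute isochrone during an interval has a closed form.
The engine integrates $\phi_k$, $\pi_k$ and the time-averaged rescue field
exactly interval by interval instead of sampling the state on a fixed tick:
the averages are well defined between arbitrarily sparse events, at no
discretisation error and a fraction of the cost. Accidents still being
served when the horizon ends are completed (under end-of-horizon
conditions), but indicator integration and occupation accounting stop at the
horizon.

Shortest-time fields are cached per (source, active congestion pattern);
global factors (weather, closures, stress) scale a cached field without
re-running Dijkstra, since uniform scaling never changes which route is
shortest. Unreachable accident cells are flagged `uncoverable` and warned
about, never silently dropped.

## The bundled Avila scenario

The package reconstructs a desk-scale version of the Avila (Spain) 2014
deployment study. All tabular inputs are the published figures: per-road
monthly accident means for 18 roads, six town populations (the capital's
exact census count, 58,933), monthly province hotel stays, festivity and
road-closure days, monthly weather event-days, and the weather catalogue.

The road network is synthetic: the study's real hub-to-town travel times
came from a commercial routing service and are unpublished. A radial grid
(four straight and four staircase spokes, 5 minutes per cell, hub and
hospital co-located in the capital) reproduces every documented travel-time
band: the capital within 10 minutes of the hub, Navaluenga in (30, 40],
Hoyo de Pinares in (40, 50]. The bands of El Tiemblo, Piedrahita and
El Barraco are not documented; the fixture places them at 15, 45 and 25
minutes as declared choices. The six towns hold 90% of the covered
population; the remaining 10% is assigned to four synthetic settlements at
20, 30, 40 and 50 minutes, so the static coverage curve starts at about 75%
at 10 minutes and reaches 100% at 50. The 18 rated roads partition the 80
non-hub road cells into contiguous runs, and each road's accidents are
spread uniformly over its cells.

Two quirks of the published inputs are worth recording:

* The accident table's monthly TOTAL row is not the sum of its per-road
  rows (January: rows sum to 60 against a printed total of 53; other months
  deviate in both directions). The simulator is calibrated to the per-road
  rows — the only entries usable as rates — so its simulated totals converge
  to the row sums, not to the printed TOTAL row.
* The worked population example in the source rounds differently than its
  own formula; the package implements the formula (proportional split,
  uniform spread, then the 20% uplift) and does not chase the rounded
  total.

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `ambulances` | units | 1 | staffing level c |
| `thresholds` | min | 10,20,...,60 | isochrone levels; 60 = Golden Hour |
| `horizon_days` | days | 365 | one calendar year |
| `replications` | – | 20 | cross-replication averaging |
| `stress_multiplier` | – | 1 | 2 doubles all times and penalties |
| `congestion_factor` | – | 2 | doubling around accident scenes |
| `festivity_factor` | – | 2 | doubling on road-closure days |
| `congestion_extra_min` | min | 60 | congestion outlives scene departure |
| `weekend_uplift` | – | 1.2 | +20% floating population |
| `required_units` | units | 1 | ambulances per accident |
| `dispatch_from_hospital` | – | FALSE | free unit at hospital drop-off |

## Numerical choices and degenerate inputs

Travel-time comparisons and tie-breaks are exact on doubles; occupation
conservation is enforced to $10^{-6}$ minutes over a year and fractions sum
to 1 within $10^{-9}$. Zero accident rates, empty accident tables, zero
event-day months and zero hotel stays are all valid degenerate inputs with
the obvious limits; a zero total population makes $\phi_k$ undefined and is
rejected. Grids must have exactly one hub, at least one hospital, and one
connected road component containing every town and rated cell — violations
are classed validation errors at load time. Indicator CSV exports write
doubles with 17 significant digits so re-loading is bit-exact.

## What the tests do and do not show

The suite verifies the routing against exhaustive path enumeration on small
grids (and against an independent graph library), the generators against
their closed-form summaries and the published monthly tables (1,000
simulated Januaries), hand-computed six-task cycles on toy roads, exact
indicator identities (a quiet system reproduces the static curve; occupation
tiles the horizon), and the deployment experiment at the study's own scale —
20 replications of one year for c = 1, 2, 3 plus a ×2 stress run, all with
common random numbers. Those runs confirm the qualitative deployment
findings on the fixture: mean $\phi_k$ is non-decreasing in c at every
threshold, the Golden-Hour gain from the second ambulance far exceeds that
from the third, availability rises with c, and the stress run never improves
coverage.

Because the network is synthetic, the *dynamic* headline percentages of the
original study (e.g. its Golden-Hour coverage per staffing level) are only
qualitatively, not numerically, reproducible; the static indicators are
reproduced exactly.

## Known limitations

* Weather is spatially uniform and monthly-stationary; accident rates have
  no day-of-week or hour-of-day structure.
* Travel times are time-dependent, so strict per-accident response-time
  dominance in the number of ambulances can fail even under common random
  numbers: a unit dispatched immediately (because a second ambulance was
  free) can drive into a weather window that a delayed dispatch would have
  missed. This is a property of the model, not a sampling artefact — the
  deployment comparisons hold in the aggregate indicators, and the rare
  per-accident reversals are exactly the cases where the faster system met
  worse weather.
* The availability instant of a busy unit (used by the rescue-time field) is
  an estimate priced under current penalties; it is re-estimated at every
  stage transition but not between events.
* With `required_units > 1`, response is recorded at the first unit's
  arrival and congestion follows the first-assigned unit's scene departure.
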