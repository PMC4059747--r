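---
title: "From VMS pings to fishing-pressure indicators: methods and design"
author: "vmstrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From VMS pings to fishing-pressure indicators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmstrack)
```

## The problem

Satellite Vessel Monitoring Systems (VMS) report each fishing vessel's
position, speed and heading every couple of hours; logbooks report, per trip,
the catch in kilograms by FAO 3-alpha species code. Neither source alone
resolves *where and how much fishing pressure* a fleet exerts: VMS pings mix
steaming, drifting and fishing and carry transmission errors, while logbooks
have no positions. `vmstrack` implements the full processing chain that joins
them: cleaning, trip segmentation, trajectory interpolation, métier
(fishing-activity category) identification, VMS–logbook linkage,
fishing-point detection, and spatial pressure indicators.

This vignette documents the models and the design choices, in the order the
pipeline runs.

## Cleaning: warning codes, never silent deletion

Erroneous pings are *flagged*, not deleted; `apply_policy()` is the single
place where removal happens, so any analysis can revisit the raw data. Codes
and rules:

* `DUPLICATE` — same vessel and timestamp; the position is deliberately not
  required to match, because a transponder echo often arrives with metre-level
  jitter and two positions at one instant are physically impossible anyway.
  The first occurrence of a group stays clean.
* `ON_LAND` — strictly inside a coastline polygon (boundary points are kept:
  harbour quays legitimately sit on the coastline).
* `BAD_SPEED` / `BAD_HEADING` — speed negative, missing or above 25 kn
  (inclusive boundary; 25 kn exactly is clean), heading outside the half-open
  compass range [0, 360). The 25 kn ceiling is our default for a mixed
  Mediterranean fleet and is a parameter everywhere it is used.
* `NOT_COHERENT` — the great-circle speed implied by the displacement from
  the previous *retained* ping exceeds 30 kn. The reference ping only
  advances over coherent fixes, so one bad fix does not cascade down the
  track. This check runs after duplicate flagging by construction. The
  30 kn physical ceiling is likewise a package default, not an observed
  constant.
* `IN_HARBOUR` — within 2 km great-circle distance (inclusive) of a harbour
  point; the 2 km buffer is the conventional harbour radius. Ties between
  equidistant harbours break lexicographically by harbour id so results are
  reproducible.

All distances use the haversine formula on a sphere of radius 6371.0088 km
(IUGG mean radius). The default retention policy drops `DUPLICATE`,
`ON_LAND`, `NOT_COHERENT` and `OUT_OF_RANGE` pings and keeps `IN_HARBOUR`
pings, which track cutting needs.

## Track cutting and interpolation

A *track* is one harbour-to-harbour trip. Per vessel, a new track starts
after a maximal run of in-harbour pings or after a temporal gap above
`max_gap_h` (default 12 h, a middle ground between the ~2 h native cadence
and the length of a missed trip). Within a track only the last in-harbour
ping of the preceding dwell and the first of the following dwell survive, so
a track has at most one harbour ping at each end. Fragments with fewer than
three pings are discarded and counted.

Interpolation serves two purposes: densifying ~2 h cadence data to a working
resolution (10 min is typical) and aligning the whole fleet onto one clock.
Output instants are exactly the multiples of the frequency counted from the
Unix epoch (1970-01-01T00:00Z), so two vessels interpolated at the same
frequency share their instants — a fleet-wide snapshot exists at every grid
time, and reruns are reproducible. Native pings pass through unchanged.

Positions come from a cubic Hermite spline per coordinate. The endpoint
tangents are the velocity vectors the vessel itself reported:
`v · (sin h, cos h)` for speed `v` and heading `h`, converted from knots to
degrees per second at the segment's mean latitude. Where speed or heading is
missing or flagged, the segment chord slope replaces that tangent. Speed and
heading of interpolated pings are read off the spline's first derivative.
There is no tuning parameter beyond the frequency. On a straight
constant-velocity course the reported-velocity tangents equal the chord
slope, so the spline degenerates to linear interpolation exactly — a
property the tests pin to 1e-6 degrees. This heading/speed-informed Hermite
scheme is our committed approximation of curvature-aware trajectory
reconstruction; it keeps every stated contract (passthrough, use of course
and speed, parameter-freeness) without reproducing any published formula set.

Interpolation stays inside [first ping, last ping] of each track; endpoints
are labelled with harbours but positions are never fabricated.

## Enrichment

Sea-bottom depth per ping is bilinear interpolation of a regular lon/lat
elevation grid (ESRI ASCII raster or lon,lat,z text; negative below sea
level). Bilinear sampling is exact for planes, which the tests verify to
1e-9 m. Pings outside the grid keep a missing depth and are counted. The
original online-bathymetry retrieval is replaced by local grid files, which
keeps the numerical contract and works offline.

Tracks are assigned to management areas (e.g. GSA rectangles) through their
*focal point* — the arithmetic mean of the track's native ping coordinates —
so the assignment is invariant to ping order and to interpolation frequency.
Overlapping polygons resolve to the first id in increasing order, with a
warning.

## Métier discovery and classification

Métiers are discovered as clusters of logbook *catch profiles* (kg per
species). The compositional dissimilarity is Bray–Curtis,

$$BCD_{ij} = 1 - \frac{2\sum_s \min(x_{is}, x_{js})}{S_i + S_j},$$

with $S_i$ the profile totals: 0 for identical profiles, 1 for disjoint
species supports, invariant to joint rescaling — exactly the behaviour a
catch comparison needs. Euclidean and Manhattan are available alternatives.

Clustering is k-medoids. `pam_medoids()` implements BUILD (greedy seeding:
the first medoid minimises total dissimilarity, each next medoid maximises
the cost reduction) followed by SWAP (the single best medoid/non-medoid
exchange, repeated until none lowers the cost), with all ties broken by
lowest index for determinism. SWAP descends monotonically and terminates; it
reaches a swap-neighbourhood local optimum, which on small instances
coincides with the exhaustive-search optimum most but not all of the time —
that is a property of the algorithm family, shared by the reference
implementation in the `cluster` package, and the tests document it rather
than hide it.

For large logbooks `clara_medoids()` runs PAM on random subsamples
(defaults: 100 samples of 1000 records), scores every candidate medoid set
by the *full-data* average dissimilarity, and keeps the best; after the first
round the current best medoids are always injected into the next subsample.
Everything is seed-deterministic.

The number of métiers is chosen by maximising the average silhouette width
(ASW) over a user range (2–30 is a typical search): for each record,
$s = (b - a)/\max(a, b)$ with $a$ the mean within-cluster dissimilarity and
$b$ the best other-cluster mean; singletons and degenerate $a=b=0$ cases
score 0 by convention. ASW is computed blockwise so no full n×n matrix is
ever held.

Two pre-treatments mirror common practice and default to off: dividing each
profile by trip length in days (catch per day at sea), and outlier removal —
our rule, stated as such: drop records whose nearest-neighbour dissimilarity
exceeds the 99th percentile of all pairwise dissimilarities.

Classification of records against a fitted model is fuzzy: membership in
cluster $c$ is $u_c \propto d_c^{-2/(m-1)}$ with fuzziness $m$ (default 2,
the conventional exponent; the crisp nearest-medoid rule is the $m \to 1^+$
limit, computed in log scale so small $m$ stays stable). A record at zero
distance from a medoid takes full membership there; an all-zero record is
unclassifiable and flagged. Discovered medoids carry generic labels until
`label_metiers()` assigns DCF codes by greedy nearest matching against
reference profiles — the formalised "métier editing" step. No reference
profile values are bundled: users supply their own medoid files
(`read_metier_model()`).

## VMS–logbook linkage, behaviour-based prediction, fishing points

Tracks and logbook records are matched by temporal interval overlap within a
vessel: candidates need the same vessel id and strictly positive overlap;
several tracks may absorb one record; a track overlapping several records
takes the largest overlap, exact ties resolving to the earliest record start
and then the lowest record id. Track intervals use the first/last retained
ping times. Métier and gear propagate from record to track.

Tracks without a logbook match get their métier from a single-hidden-layer
feed-forward network (32 units, seeded initialisation) trained on the
labelled tracks' standardised behaviour descriptors: 11 speed quantiles,
15 one-knot speed-bin occupancies (0–15 kn), trip duration, mean absolute
depth and night-ping fraction — 29 numbers, fixed order, order-invariant.
This architecture and feature set are our interpretation of
behaviour-based métier prediction; a stratified 80/20 split reports held-out
accuracy before the final refit on all labelled tracks. Métiers that differ
only in catch composition but share speed and depth habits (e.g. bottom
otter trawl vs pelagic pair trawl over the same grounds) are genuinely hard
for this classifier; the reported held-out accuracy makes that visible.

A ping is a *fishing set position* when its reported speed lies in its
métier's `[vmin, vmax]` band (inclusive), and — where configured — its
absolute depth lies in `[dmin, dmax]` and its nearest-harbour distance is at
least the minimum. A missing depth fails an active depth rule (conservative:
un-enriched pings never inflate effort). The shipped preset marks towed
gears (OTB/TBB/PTM) at 2.5–4.5 kn; every threshold is a user file.

## Effort grids, DCF indicators 5 and 6, trawled area

Fishing positions are counted per cell of a regular lon/lat grid (or any
polygon partition); a position exactly on a shared boundary goes to the
lowest-id adjacent cell, and counts always reconcile:
Σ cell counts + outside = total fishing positions. Because each interpolated
fishing position stands for one interpolation interval of activity, effort
in hours is `count × interval/60` — the explicit formalisation of mapping
counts to hours. Cell areas use the spherical closed form
`R² · Δλ · |sin φ₂ − sin φ₁|`. Monthly stratification is a group-by on ping
month (`split_by_month()`).

* Indicator 5 (distribution of fishing activities): total area of cells with
  any effort.
* Indicator 6 (aggregation): cells sorted by decreasing effort (ties by id)
  are accumulated until 90% of total effort; the crossing cell is included —
  guaranteeing the accumulated share is at least the target — and the
  accumulated area is returned. Hence indicator 6 ≤ indicator 5, with
  equality at q = 1.

Trawled area per track sums, over consecutive ping pairs that are both
fishing positions, segment length × overall gear width (OWG), the width
evaluated at the segment's mean depth. OWG comes from a small per-vessel
table (`owg_km + owg_per_m · |depth|`); no fleet-register relationship is
bundled because none is portable.

## The synthetic fleet: what it emulates, what it does not

`simulate_fleet()` generates the package's test bed: by default 13 vessels
through June 2012 at a ~2 h cadence — a deliberately small,
sample-dataset-sized fleet — in a rectangular sea bounded eastward by a
rectangular landmass whose edge carries two harbours, with depth increasing
linearly at 5 m per km offshore. Three métier specifications drive
behaviour and catches:

* bottom otter trawl (`OTB_DES`): fishing at U(2.5, 4.5) kn over 80–400 m,
  hake/mullet/shrimp Dirichlet catches;
* purse seine (`PS_SPF`): searching at ≈8 kn and setting/hauling at ≈0.3 kn
  (the fishing state) over 20–100 m, sardine/anchovy catches — together the
  bimodal speed signature typical of seiners;
* pelagic pair trawl (`PTM_SPF`): 2.5–4.5 kn over 100–300 m, blue
  whiting/horse-mackerel catches.

Steaming is N(10, 1) kn truncated to 7–13 for all gears, so fishing and
steaming speed regimes never overlap. Trips alternate harbour dwell (5–10 h,
guaranteeing in-harbour pings between trips at the 2 h cadence), steaming to
a ground drawn from the métier's depth band, a fishing bout, and return.
Logbook records bracket each trip with small margins, catches draw from the
métier's Dirichlet profile scaled by trip length, and interval edges can be
jittered to exercise the matcher. Errors are injected at per-ping Bernoulli
rates (defaults: 2% duplicates, 1% each on-land, bad-speed, bad-heading) at
recorded positions, so cleaning can be scored exactly. Identical seeds give
byte-identical output.

What the generator does **not** emulate — and hence what green tests do not
show about real data: tidal and current drift, position error beyond
isotropic Gaussian noise, irregular transponder outages (beyond the optional
gap injection), multi-harbour fleets with shared grounds, within-trip métier
switching, misreported logbooks, and catch compositions that drift over
seasons. Results on real fleets depend on threshold calibration against
observer data, which no simulation replaces.

## Numerical choices and degenerate inputs

* Boundary conventions: speed/radius/threshold comparisons inclusive;
  heading half-open [0, 360); strictly-inside for on-land; boundary grid
  points to the lowest-id cell.
* The implied-speed comparison carries a 1e-9 kn tolerance so a ping exactly
  at the ceiling is clean under floating-point arithmetic; Bray–Curtis
  values are clamped at 0 against rounding residue.
* Ties everywhere (medoids, harbours, cells, matches) break by lowest
  index/id — determinism over elegance.
* Degenerate inputs are contracts, not crashes: empty files load as empty
  collections, k = 1 medoids are exact, all-identical profiles give ASW 0,
  zero-effort grids refuse indicator 6 explicitly, tracks shorter than two
  pings skip interpolation with a warning.

## Problem sizes used by the test suite

The packaged checks run the discovery on ~500–5000 synthetic trips with
CLARA at 4–5 subsamples of 250–400 records, the end-to-end pipeline on a
20-vessel × 60-day fleet, and the exhaustive k-medoids comparison on 200
instances of up to 10 records — sizes chosen so the whole suite documents
the method's behaviour in minutes on a laptop while still exceeding the
sample-fleet scale the package targets by default.

## Known limitations

* The interpolant is not curvature-adaptive; sharp manoeuvres between pings
  are smoothed.
* SWAP k-medoids is a local optimiser; on adversarial tiny instances it can
  return a cost above the global optimum (as does any PAM implementation).
* The behaviour-based métier classifier cannot separate métiers whose
  kinematics coincide; it is a fallback for unmatched tracks, not a
  replacement for logbooks.
* Spatial layers are read from delimited text (points and polygon rings);
  shapefile conversion is left to external tools.
* Effort hours assume the interpolation interval fully belongs to the
  activity class of its ping — the standard approximation at 10-min
  resolution.
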