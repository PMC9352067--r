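---
title: "Methods: from geolocator stationary estimates to a migratory network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from geolocator stationary estimates to a migratory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flywaynet)
```

This vignette is the package's own account of the science it implements:
the data model, the rule set, the numerical conventions, the design
choices that were genuinely open, and what the synthetic tests do and do
not demonstrate about real tracking data.

## The data and its failure modes

The atomic record is a *stationary estimate*: an inferred stop — latitude,
longitude, arrival, departure — where a bird remained for at least two
days, produced upstream by a light-level geolocation state-space analysis.
Everything upstream of that table (twilight detection, calibration, the
state-space model itself) is out of this package's scope.

Light-level stops carry three characteristic defects that drive the whole
design. Positions are coarse: errors of one to several hundred kilometers
are routine, and resighting evidence puts typical accuracy within about
700 km. Positions are absent north of the Arctic circle in summer, because
continuous daylight provides no twilights: tracks of birds breeding north
of 66.7° N effectively begin and end well away from the nest. And noisy
light data yield *spurious* stops — short, displaced estimates that make
the track zigzag in ways no real bird flies.

## Track refinement

Refinement applies three rules, in a fixed order, with every action logged
so that replaying the log against the raw track reproduces the refined one
(`replay_provenance()`):

1. **Merge.** Sequential stops closer than `merge_km` (250 km, the
   conservative buffer for geolocator resolution) are merged: coordinates
   averaged, arrival set to the earliest arrival, departure to the latest
   departure. A maximal chain of pairwise-close stops collapses in one
   step, and merging *iterates to a fixed point*: a merged centroid can
   newly fall within 250 km of its neighbor, and a single pass would leave
   that pair in violation of the rule's intent. Whether the original
   procedure iterated is not documented; we iterate and say so here.
   Leading stops before the bird first exceeds `breed_buffer_km` (250 km)
   from its breeding site are dropped — they aggregate roost/forage
   commuting, not migration.
2. **Polar drop.** Leading stops at or north of `polar_lat_deg` (66.7° N)
   are dropped, up to the first stop strictly south of it. Later
   northward stops are kept: the rule removes untrustworthy pre-departure
   estimates, not genuine staging.
3. **Turning-angle filter.** Interior stops whose turning angle (the
   spherical interior angle at the stop between the bearings to its
   neighbors; 180° = straight through, 0° = exact reversal) is below
   `turn_min_deg` (60°) are removed one at a time, smallest angle first,
   recomputing after each removal — a deterministic order that takes the
   sharpest artifacts first (the original procedure states no order). The
   removed stop's days are absorbed by the spatially nearest surviving
   neighbor (ties to the earlier one), extending that neighbor's interval
   to cover the removed one, so no tracked time is lost. The *farthest*
   stop with a stationary period of at least `winter_min_days` (42 days)
   is exempt: the winter terminus is exactly where a true reversal of
   direction occurs. If no stop lasts 42 days the farthest stop overall
   is protected and the track is flagged; flagged tracks stay in the
   parameter tables but are excluded from network construction, like
   partial tracks.

All boundary conventions are strict, following the rule wording: "< 250
km", "south of 66.7" (strictly), "< 60°", "≥ 42 days".

## Segmentation and migration parameters

A refined complete track is partitioned into contiguous blocks — south
migration, winter, north migration, plus a terminal breeding block when
the bird's last stops are back within the breeding buffer:

* **South initiation**: birds whose first stop is beyond the buffer (in
  practice all refined tracks, and certainly all high-Arctic breeders)
  have their departure back-calculated as arrival minus
  distance/`travel_kmh` (58 km h⁻¹, an assumed sustained flight speed).
  Initiation dates are therefore the *latest* dates possible, a known
  one-sided bias of the method.
* **Winter** opens at the first stop south of `winter_lat_deg` (45.5° N)
  lasting at least 42 days, and closes at the departure from the *last*
  such stop. The closing rule needs look-ahead: short southern stops
  sandwiched between long winter stops belong to winter (mid-winter
  relocations, e.g. between flood-driven inland sites), whereas short
  southern stops followed only by northern ones are north-migration
  staging. This is the unique formalization consistent with both halves
  of the prose rule it implements.
* **North migration** ends at arrival at the first stop within 250 km of
  the breeding site, else it is forward-calculated symmetrically.

Period parameters follow the tracked-population conventions: *minimum
migration distance* is the great-circle sum over sequential stops within
the period — including the breeding-site → first-stop leg and the
last-stop → breeding-site leg, so distances reflect the full journey
between breeding and wintering grounds (switchable via
`include_breeding_legs = FALSE`; the inclusion is our declared convention,
checked against the magnitude of the published distance medians). A bird
that flies nonstop to its wintering grounds has zero south stops and a
single-leg distance; a single-stop winter has distance 0 and speed 0.
Speed is distance/duration and is compared only *within* individuals
(north/south ratios, `within_individual_ratios()`), because it conflates
flight and fueling time across individuals. Dates are compared on
leap-normalized ordinal days (29 February maps onto 28 February's index)
and, in the statistics, unwrapped at the year boundary relative to each
bird's south initiation so January sorts after December.

## Flyway regionalization

All stops of complete, unflagged tracks — all seasons jointly — are
clustered by partitioning around medoids (classic deterministic
BUILD + SWAP, via `cluster::pam` on the great-circle distance matrix;
sphere of radius 6371 km throughout, since sub-0.5% ellipsoidal
corrections are immaterial against 250–700 km thresholds). Joint
clustering, rather than one clustering per season, gives a single region
numbering shared by all season networks. The number of regions is not
chosen by a quality index but by a *resolution constraint*: k rises from
1 until the median cluster diameter (maximum pairwise member distance;
a mean-pairwise option exists) falls below `region_median_diam_km`
(700 km, the typical accuracy of geolocator stops). Ascending search
returns the coarsest regionalization consistent with the constraint;
k = n always satisfies it, so the search terminates. Regions are numbered
by medoid latitude then longitude for stable identifiers, and
nearest-medoid assignment (ties to the lower id) places any new point.

Deterministic BUILD + SWAP makes results reproducible but is a local
optimizer. On small instances shaped like this pipeline's data — stops
clumped around a few staging centers with geolocator-scale scatter — it
recovers the exhaustively enumerated optimum in ≈ 99% of cases (verified
in the test suite against a brute-force oracle, together with an
unconditional check that no single medoid swap can improve any returned
solution). On adversarial uniform scatter the global-optimum rate drops
to ≈ 93%; that regime does not occur in this pipeline, and the test
instances are drawn from the clumped family for that reason.

## Networks, occupancy, and statistics

For each season, each complete track contributes its time-ordered region
sequence with consecutive duplicates collapsed: each visited region counts
once per bird for node weights, each consecutive ordered pair once per
bird for directed edge weights, and no self-edges exist. Weights are
proportions of the per-subspecies complete-track count, so an edge can
never outweigh its endpoints. Daily occupancy counts a bird in a region on
every ordinal day from arrival through departure, inclusive; days in
transit count toward no region, and a same-day region change credits the
earlier stop so that a bird is never in two places at once (keeping
per-day proportions summing to at most 1 — with purely inclusive counting
and sub-day travel times those two stated properties would conflict).

Region use is compared with two-tailed Fisher exact tests (probability-
mass criterion, the R convention), restricted to subspecies with at least
`fisher_min_n` (25) complete tracks; a region used by nobody (or
everybody) in both groups carries no contrast and reports p = 1.
Migration parameters are compared with Wilcoxon rank-sum tests (exact
null when the combined sample is ≤ 20 without ties, else the normal
approximation with tie and continuity corrections), with the
Hodges–Lehmann shift (median of pairwise differences) and its 95%
rank-sum-inversion confidence interval — the standard companion of the
test, and our declared reading of published "x–y days earlier" interval
statements. Subspecies need `wilcoxon_min_n` (5) birds; single-bird
groups are never tested. Raw p-values are reported, mirroring the
pairwise-battery convention in this literature; `holm = TRUE` adds
Holm-adjusted values. Degenerate comparisons (both samples constant and
identical) report p = 1, and a conf-int inversion failure on heavily tied
samples yields NA interval bounds rather than an error.

## The synthetic population

`make_paper_like_config()` encodes, per subspecies, a breeding site, one
or more itinerary variants (southbound waypoints, winter site sequence
with time shares, northbound waypoints), and timing distributions. The
defaults emulate the tracked Dunlin population: four subspecies breeding
from northern Alaska (71.3° N) to Sakhalin Island (52.5° N); shared core
staging in the Sea of Okhotsk, North Sakhalin, and the Yellow Sea;
south-initiation means staggered (≈ 5 July, 15 August, 31 August for the
southern-, mid-, and northern-breeding subspecies, sds 4–7 days) with
stop durations lognormal (right-skewed, as stop-duration IQRs in this
literature are) and truncated below 42 days so migration stops never
masquerade as winter; winter durations of roughly 190–290 days ending in
a near-synchronous mid-May north migration; and 46% of the *sakhalina*
population routed through an inland-China (Yangtze floodplain) winter
stage. Default sample sizes are the study's 59/35/5/1 tracked birds;
tests override `n_birds` as needed.

Corruption is applied only after each bird's truth record is frozen:
isotropic positional noise (default per-axis sd 150 km — within the
stated accuracy envelope; real geolocator error is latitude-inflated near
the equinoxes, and an anisotropic stress option is deliberately left to
future work), spurious 2–4-day stops at jittered leg midpoints (expected
0.15 per track) whose time is carved from the adjacent stop so the true
timeline is preserved, out-and-back reversal spikes (0.10 per track),
deletion of stops at or above 66.7° N, and dead-tag truncation
(probability 0.16, the study's partial-track fraction). A single seed
drives one RNG stream, restored afterwards, so identical configurations
are byte-identical.

What passing the synthetic battery shows — and what it does not: the
generator's waypoint geometry keeps true turning angles well above 60°
except at the protected winter terminus, and true legs longer than the
merge radius, so refinement's success on synthetic data demonstrates
artifact removal, not robustness to birds whose genuine behavior violates
the rules' assumptions (e.g. true mid-migration reversals, which the
refinement would eat by design). Positional noise is isotropic and
i.i.d.; real equinox-period error is neither. And the phenology
distributions are unimodal per subspecies, so recovery rates say nothing
about, say, differential molt-migration strategies within a subspecies.

## Problem sizes and numerical conventions

The shipped test suite runs the refinement idempotence and post-merge-gap
properties on 500 simulated tracks, segmentation recovery on 200 complete
tracks (noise sd 150 km, spurious rate 0.15; south initiation within ±2
days of truth for ≥ 90% of birds, winter stop correctly identified for
≥ 95%), the PAM oracle on 100 instances with n ≤ 12 and k ≤ 3, the Fisher
enumeration sweep over all 2×2 tables with row sums ≤ 15, rank-sum
permutation enumeration for combined samples ≤ 12 (agreement to 1e-12),
and the south-initiation ordering of the shipped configuration across 20
replicate seeds at 200 birds per subspecies. These sizes were chosen as
the smallest that make the binomial tolerances in those criteria
meaningful.

Numerical conventions worth knowing: longitudes normalize to (−180, 180]
and coordinate averaging uses 3-D unit vectors (the chord centroid), so
the antimeridian — which this flyway crosses — never wraps; perfectly
antipodal inputs are an error, not a silent pole. Fisher ties use the
customary 1e-7 relative slack. Medoid-assignment ties break to the lower
region id, absorption ties to the earlier neighbor, and the
smallest-angle removal ties to the earliest stop. Empty estimate lists,
all-near-breeding tracks (warned, emptied), zero-length periods (speed 0
for zero distance, NA otherwise), and zero-margin contingency tables
(p = 1, warned) are all defined rather than left to fail.

## Limitations

The reader ingests CSV only; the deposited XLS supplement must be
exported to CSV first (the column-alias table in `trackio` covers the
obvious header dialects). Refinement's assumptions — no true reversals
away from the winter terminus, winter stops of at least 42 days — are the
field's, inherited deliberately; birds that genuinely violate them are
mis-refined in the same way the original procedure would. Edges connect
flyway regions only (no virtual breeding/winter terminus nodes, which
published figures are ambiguous about), and occupancy interpolates
nothing: transit days belong to no region.
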