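---
title: "The apiary stocking model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The apiary stocking model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apisite)
```

## The problem

A beekeeper choosing where to put an apiary — and how many hives to put
there — faces a resource-allocation question: within the workers' flight
range, how much nectar can realistically be turned into honey, after
discounting fields that are sprayed, fields that can only be reached by
crossing a road, and forage growing in the polluted band along roads?
`apisite` scores a candidate location on a semantically annotated landscape
and converts the score into a supportable colony count.

## The model

The landscape is a planar map: field polygons, each carrying a
nectar-productivity coefficient $C_1 \in \{0.2, 0.4, 0.6, 0.8, 1.0\}$ and a
pesticide-contamination coefficient $C_2 \in \{-1.0, -0.5, 0.0\}$, and
classified road polylines (highway, railroad, country) carrying a pollution
coefficient $C_4 \in \{-0.5, -0.3, -0.1\}$ and a corridor half-width of
500 / 300 / 100 m respectively.

For a site $(x, y)$ and flight radius $r$ (default 3 km), every field is
clipped to the flight disc, giving segments with area $S_{pot}$. Each
segment is scored:

* combined field coefficient $C_f = \max(0,\; C_1 + C_2)$ — a heavily
  contaminated field contributes nothing no matter how productive;
* availability $C_3$: 1.0 if the straight flight line from the site to the
  segment's representative point crosses no road, 0.5 if it crosses a main
  road (highway or railroad), 0.7 if it crosses only country roads;
* yield $H(i) = C_f \, C_3 \, S_{pot}[\mathrm{ha}] \cdot P \cdot \delta$,
  where $P$ = 100 kg nectar/ha is the offer of a fully productive hectare
  and $\delta = h k$ converts offered nectar to collectible honey
  ($h = 0.4$: five kg of nectar make two kg of honey; $k = 0.35$: the
  fraction of nectar bees actually capture);
* losses $H_{loss}(j) = \sum_r C_f \, C_3 \, (-C_{4,r}) \,
  S_{2,r}[\mathrm{ha}] \cdot P \cdot \delta$, where $S_{2,r}$ is the part
  of the segment inside road $r$'s corridor.

Totals give $H = \sum_i H(i) - \sum_j H_{loss}(j)$ and the colony count

$$N = \left\lfloor \frac{H}{H_{colony} + H_{average}} \right\rfloor,$$

with $H_{colony} = 90$ kg (a colony's own consumption — below this the site
supports no colony at all) and $H_{average} = 60$ kg (the surplus the
beekeeper targets per colony).

### The unit convention

The yield formula is stated in the source material without units for
$S_{pot}$ and without a base productivity. We carry areas in m², convert to
hectares, and multiply by $P = 100$ kg/ha, reading the productivity classes
"nectar production is 20 to 100 kg per hectare" as $C_1 \cdot P$. This is
the only reading under which a ~2800 ha flight disc yields honey totals in
the few-thousand-kg range the model is calibrated to.

### Losses from several roads

Losses are summed per road, so two overlapping corridors both charge the
same square metre. With several main roads crossing one segment the raw sum
could exceed the segment's own yield; we clamp per-segment losses at the
yield so the net contribution is never negative. This keeps the global
invariants ($H \ge 0$, losses $\le$ yield) that the rest of the model
assumes.

## Geometry

No planar-geometry dependency is available in the target environment, and
the geometric operations are the substance of the tool, so the kernel is
implemented here:

* **Flight-disc clipping** — Sutherland–Hodgman against a regular 720-gon
  representation of the circle (relative area error ~1.3e-5, far below
  model precision). Half-planes that do not cut the field's bounding box
  are skipped, so only the arc edges near a field cost anything.
* **Corridor overlap ($S_2$)** — the corridor is the union of flat-capped
  rectangles, one per polyline edge (overlaps at joints counted once; the
  small outer-joint wedges are a documented consequence of flat caps). The
  area of segment ∩ union is computed by a vertical slab sweep with slab
  boundaries at every vertex and pairwise edge crossing; within a slab the
  cross-section is linear in $x$, so a midpoint evaluation integrates
  exactly.
* **Road partition** — roads are extended past the extent along their
  terminal directions (a dangling road separates nothing), all segments
  including the boundary are mutually split at shared intersection points,
  and regions are read off a half-edge face traversal. Region areas sum to
  the extent area to better than 1e-6 relative on every generated map.
* **Representative point** — an approximate pole of inaccessibility from
  horizontal scanlines (best clearance wins). The crossing test is applied
  per segment, not per field: a field straddling a road is partly
  reachable without crossing.

A site within 1e-6 m of a road polyline is flagged `onRoad` and, for
partition purposes, deterministically assigned to the region on the left of
the road's direction.

### Open interpretation choices

Two points the source leaves open are resolved as follows and flagged, not
silently guessed: the pollution band applies on **both** sides of a road
(the physical mechanism — emissions and dust — is two-sided); and the
"active polygon" partition and the straight-line crossing test coexist —
the crossing test drives $C_3$, while the partition drives `onRoad` and
reporting/rendering.

## Synthetic landscapes

`generate_map()` emulates the reference region: a 10 × 10 km extent,
200 convex parcels (4+ vertices, ≥ 1 ha, convex hulls of radial scatters
with circumradius 100–280 m; parcel overlap is permitted and overlapping
areas count in each field independently) and 28 roads crossing the full
extent as noisy straight polylines (vertices every ~900 m, 60 m r.m.s.
perpendicular jitter, endpoints exactly on the boundary). The road-class
mix — 4 highways, 3 railroads, 21 country roads — is our choice for a
rural region dominated by light roads; it is fixed, not tuned.
Coefficients are drawn uniformly from the standard sets (Mersenne–Twister,
explicit seed, draws consumed in field-id sort order so insertion order is
irrelevant); real coefficients supplied in an annotation file are kept and
only missing ones are filled.

What the generator does **not** emulate: parcel tessellation (real fields
tile the land at much higher coverage than the ~20% these scattered
parcels reach), crop rotation structure, road networks with junctions
short of full crossings, and any correlation between crop type and
location. A green property-suite run therefore establishes correctness of
the machinery on landscapes with the stated counts and scales — not
calibration against any real region's totals.

## Numerical choices

* Circle discretisation: 720 vertices, fixed.
* Coordinate round trip: files store input units; `scale` converts to
  metres at load. Round-trip error is a few 1e-12 m, asserted < 1e-9 m.
* Degenerate polygons are rejected at load, never repaired — a repair
  changes areas and hence $H$.
* Node identification in the partition uses exact shared coordinates
  (intersections are computed once and handed to both segments; T-junction
  points snap to the grazed endpoint), so no merge tolerance is needed in
  generic position.
* Crossing tests are strict: grazing a road endpoint does not count as a
  crossing.
* `N` uses `floor`; the survival gate ($H < H_{colony} \Rightarrow N = 0$)
  is implemented explicitly so it stays active for user-supplied
  parameters where $H_{colony} + H_{average} < H_{colony}$ is impossible
  but tight gates are not.

## Limitations

* The flight disc is uniform: no distance decay, wind, or terrain cost.
* One snapshot in time: no bloom phenology, no inter-colony competition
  beyond dividing the same resource pool.
* $C_3$ depends on a single representative point per segment; a very
  large concave segment straddling a road is classified as a whole.
* The end-to-end reproduction of the reference worked example (7688.84 kg
  at its published site) requires that example's exact annotation and
  random coefficient draws, which ship only with the upstream
  supplementary material; the property suite and hand-computed oracles
  stand in for it here.
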