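---
title: "Methods: the threat-degree index and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the threat-degree index and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

threatscape measures the pressure that human expansion — land that is
cropland or artificial surface in the later of two epochs but was neither in
the earlier one — puts on threatened species. The unit of analysis is a
1 km × 1 km grid cell in a planar equal-area frame. For each cell three raw
densities are computed from 30 m pixels: the number of distinct 8-connected
expansion patches touching the cell (*N*), the expansion area in the cell
(*A*, km²), and the number of distinct threatened species whose range
overlaps the expansion footprint in the cell (*T*). Each surface is min–max
normalized to percent over the whole map image, and the threat degree is the
cellwise geometric mean of the three normalized surfaces, a number in
[0, 100] %.

The geometric mean was chosen over the arithmetic mean because the three
components measure necessary facets of one phenomenon: a cell only
threatens biodiversity when expansion *exists* (N, A > 0) *and* touches
species ranges (T > 0). The multiplicative form makes TD exactly zero
wherever any component is zero, so expansion-free cells can never acquire
spurious threat, and it penalizes imbalance between components. Its known
weakness — two cells with opposite component profiles can score alike — is
inherent to any scalar composite.

Assumptions worth keeping in mind:

- The two land-cover epochs are treated as error-free; classification error
  in the sources propagates directly into the change mask.
- Conversion between human classes (cropland → artificial) is *not*
  expansion: human land in the first epoch is excluded from the mask, since
  both classes are pooled as human land and internal conversion would
  double-count it.
- A species "involved" in expansion is one whose mapped range overlaps the
  expansion footprint inside the cell; range maps overstate occupancy, so
  *T* is an upper bound on species actually exposed.

## Overlay semantics

All polygon-versus-grid questions are resolved by centre membership, the
standard raster-overlay rule: a pixel belongs to the unique cell containing
its centre, and a cell belongs to the unique zone containing its centre.
This makes every area accounting exactly additive: the per-cell areas *A*
sum to the total expansion area, per-zone level areas of disjoint zones sum
to their union's, and the protected-area/complement decomposition of the
continental table is exact. A patch is counted once in every cell that
holds at least one of its pixel centres, so patch counts are well defined
without fractional patches. Species involvement is likewise resolved on the
pixel grid: a species overlaps a cell's expansion when at least one
expansion-pixel centre inside the cell falls in its range polygon
(even-odd rule on the range's parts). Exact polygon–polygon intersection is
used only where one operand is convex (species ranges and protected areas
are generated convex; grid cells and pixel squares always are), via
Sutherland–Hodgman clipping; this keeps zone counting exact without a full
polygon-clipping engine.

## Terrain stratification

Slope is derived with Horn's 3 × 3 operator (the common GIS default; the
choice is a convention, not a result) on the metre-scaled grid, with edge
replication at borders. Cells are classified by joint elevation–slope
bands; elevation bands are half-open [lower, upper): below 1,000 m a cell
is hill if slope > 15° (else lowland); 1,000–1,200 m: hill if > 8°;
1,200–1,500 m: hill if ≤ 3°, mountain if > 3°; at and above 1,500 m always
mountain. Highland = hill + mountain. Two boundary conventions are fixed
here because the band wording alone does not decide them: slope thresholds
follow the strict/inclusive wording ("0 to 15°" keeps 15.0 in lowland,
"> 15°" is strict), and exactly 3.0° in the 1,200–1,500 m band stays hill.
Elevations below sea level use the lowest band's rules rather than being
left unclassified. A 1 km cell is called highland when more than half of
its valid sub-pixels are highland; the aggregation rule is a package
convention.

## Classification and zonal statistics

The TD map is cut into Low / Moderate / High at x̄ + 0.5 s and x̄ + 1.5 s,
with the Moderate interval closed on both ends. The statistics x̄ and s are
computed over the *threatened* cells (TD > 0), not all land: the map's
published-style average is a property of the threat map, and this domain
makes the mean and the cut-offs mutually consistent (the cut-offs invert to
the mean via `solve_threshold_stats()`). Zonal means use the same domain,
so a zone's mean TD is the mean over its threatened cells; "threatened
area" is the area of those cells, and per-level proportions are reported
relative to it (they close to 100% by construction). The
highland–lowland difference D is the difference of stratum means within
the zone, reported missing when a stratum is empty. Normalization extremes
are taken over the full map once and never recomputed per zone, so zonal
statistics of one map are mutually comparable.

Protected areas are filtered before aggregation: point features and records
without a status year are dropped, and only polygons established before the
cutoff year (default 2000, matching an assessment window that starts then —
a PA designated later cannot be blamed for earlier expansion) are kept.
Retained polygons overlapping each other, or sharing a name, are dissolved
into one merged feature; merged area is measured by counting fine-subgrid
points inside any member (400 × 400 over the group's bounding box), which
counts overlap exactly once at the cost of a small discretization error —
acceptable because merged areas only feed reporting, never the index.

## Index evaluation

The suitability check samples the TD map at seeded random cell centres
with a minimum spacing (default 3 km) — random thinning of a permutation,
which honours both the randomness and the spacing of the published design,
whose two stated properties (a fixed count and an even 3 km distribution)
cannot hold simultaneously at any fixed extent. By default candidates are
threatened cells; `domain = "all"` widens them to every valid cell.
Pearson correlations of TD with each component, and between components,
use the exact t transform with n − 2 degrees of freedom for two-sided
p-values. The headline statistic is the average correlation degree of the
index with its three components, compared against the component–component
average; on synthetic scenarios the index average is typically several
times larger, but the comparison is data-dependent and is reported, not
asserted.

## The synthetic generator

The generator stands in for continental DEM / land-cover / Red List / PA
sources with landscapes whose ground truth is exact:

- **Terrain**: a bilinearly interpolated coarse Gaussian field (amplitude
  500 m over a 200 m base) plus two sharp ridges (amplitude 1,600 m),
  clamped at sea level — enough relief that every elevation–slope band is
  populated. Flat-terrain configurations exist for degenerate-case tests.
- **Expansion**: patches are grown pixel by pixel from weighted random
  seeds; the per-stratum weight (lowland 1, highland `highland_bias`)
  controls where expansion lands, and `clustering` interpolates between
  compact and straggly growth. A one-pixel halo keeps planted patches
  pairwise 8-disconnected, so the planted count *is* the component count
  and patch recovery can be asserted exactly. Default scale: a 60 km
  square at 30 m resolution with 1% of non-human land converted in
  Poisson-sized patches (mean 150 pixels ≈ 0.14 km²), which yields a few
  hundred patches — large enough for stable map statistics, small enough
  to run end to end in well under a minute.
- **Species**: elliptical ranges with areas log-uniform between 1% and 50%
  of the extent, categories drawn from a CR/EN/VU/NT/LC mix
  (0.10/0.20/0.25/0.15/0.30 by default, threatened-heavy so filtering
  retains a usable set), centres biased toward one corner so the *T*
  surface has spatial structure, plus a 15% share of duplicate-binomial
  records to exercise deduplication.
- **Protected areas**: elliptical polygons with names and status years
  (70% pre-2000 by default), plus missing-year records and point features
  so every exclusion rule of the PA filter fires.
- One root seed feeds fixed-order sub-streams (terrain, land cover,
  species, PAs, zones), so identical configurations are byte-identical
  and adding draws to a later stage never disturbs an earlier one.

What passing tests on these landscapes shows — and what it does not: the
pipeline's bookkeeping (labeling, overlay, normalization, classification,
aggregation) is exact, because every quantity is also recomputed from the
planted truth by independent brute-force code. It does not show robustness
to classification error, misregistered epochs, range maps with holes or
multipart real-world geometry, or non-convex protected areas; real data
carry all of these.

## Numerical choices and degenerate inputs

- A constant density surface normalizes to all zeros with a warning
  (the min–max denominator vanishes); a zero-spread TD domain classifies
  everything Low with a warning.
- Normalization extremes include zero-density cells: the map image, not
  the threatened subset, defines ΔX, which keeps ΔX scale-invariant.
- Integer rasters (land cover, labels, levels, N, T) are stored and
  round-tripped as Int32 with explicit nodata sentinels (255 for codes,
  −1 for counts); float rasters use Float64, so GeoTIFF round trips are
  bit-exact and pipeline reruns are byte-identical.
- Nodata propagates: a cell missing in any input is missing downstream,
  and cells holding no valid pixel centres are reported missing rather
  than zero.
- Grid cells at the map edge are clipped; their areas enter all area
  accounting at clipped size, and the edge column/row of an extent that is
  not a whole number of cells can legitimately hold no pixel centres.

## Problem sizes

The shipped configurations were chosen as the smallest landscapes on which
every behaviour under test still occurs: unit and property tests use 8 km
scenarios (~267 × 267 pixels) and mask sizes up to 50 × 50 for the
labeling oracle (200 random masks); the end-to-end validation and the
acceptance script run the full default 60 km scenario (2,000 × 2,000
pixels, 3,600 grid cells, ~250 patches).

## Known limitations

- The index is relative to its own map: normalization extremes differ
  between maps, so TD values are comparable within one analysis, not
  across analyses. Mean TD on a 60 km synthetic scenario (~37%) is not on
  the scale of a continental map (~9%), where extreme cells stretch the
  normalization range.
- Only mean/SD classification is implemented; quantile or natural-breaks
  alternatives would change level shares substantially on skewed TD
  distributions.
- Two-epoch change only; trajectories and transient reversals are out of
  scope, as are reprojection (inputs must share one equal-area frame) and
  Shapefile input (GeoJSON only).
- Species "involvement" uses range polygons as-is: no area-of-habitat
  refinement, no elevational clipping.
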