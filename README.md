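# threatscape

Quantifying the threat that human expansion — the conversion of natural land
to cropland or artificial surfaces between two land-cover epochs — poses to
threatened species, with explicit attention to whether expansion happens in
lowlands or highlands.

The package is aimed at spatial ecologists and conservation analysts who
work with the standard ingredients of such assessments: a digital elevation
model, two single-band land-cover rasters (Globeland30-style integer
legends), threatened-species range polygons (IUCN Red List-style, with
`binomial` and `category` attributes), protected-area polygons (WDPA-style,
with `name` and `status_year`), and country/zone polygons. All analysis
happens in one planar equal-area frame (coordinates in metres).

## The index

Expansion pixels (human land in epoch 2 that was not any human class in
epoch 1) are grouped into patches under the 8-neighbourhood rule. On a
1 km × 1 km analysis grid, three density surfaces are computed per cell *i*:

- *N*ᵢ — number of distinct expansion patches touching the cell,
- *A*ᵢ — expansion area in the cell (km²),
- *T*ᵢ — number of distinct threatened species (CR/EN/VU, deduplicated by
  binomial) whose range overlaps the expansion footprint in the cell.

Each surface is min–max normalized to percent over the whole map,
ΔX = (X − X_min) / (X_max − X_min) × 100, and the threat degree is their
geometric mean:

    TD_i = (ΔN_i · ΔA_i · ΔT_i)^(1/3)  ∈ [0, 100] %

Cells without expansion always have TD = 0. The TD map is classified into
Low (< x̄ + 0.5 s), Moderate (x̄ + 0.5 s … x̄ + 1.5 s, closed on both ends)
and High (> x̄ + 1.5 s), where x̄ and s are the mean and standard deviation
of TD over the threatened cells (TD > 0). Zonal summaries report per-zone
mean TD (overall and split into highland/lowland strata, with their
difference D = highland mean − lowland mean), per-level areas, and
proportions of the threatened area. Terrain strata come from joint
elevation–slope bands (Horn slope on the DEM): e.g. cells below 1,000 m are
hills when slope > 15°, cells above 1,500 m are always mountain; highland =
hill + mountain.

Because continental source data are far beyond a test suite, the package
ships a seeded synthetic-landscape generator (`scenario_config()`,
`simulate_scenario()`) that emulates the statistical structure of those
inputs — correlated terrain with ridges, clustered expansion planted as
exactly 8-disconnected patches, overlapping elliptical species ranges with
category mixes and duplicate binomials, PA records with pre/post-2000
status years, missing years and point features — and records exact ground
truth for every stage.

## Worked example

```r
library(threatscape)

cfg <- run_config(out_dir = "demo_run", seed = 1)   # 60 km scenario, 30 m pixels
res <- run_pipeline(cfg)
```

The run logs each stage; with seed 1 it prints:

```
[simulate] 252 planted patches, 23 species records, 12 PAs
[detect] 252 patches, 33.7635 km2
threatened species: 12 of 23 records -> 11 binomials (CR:3 EN:4 VU:4)
[index] 311 threatened cells; mean TD 36.75%, cuts 42.89 / 55.17
[zonal] continent mean TD 36.75%, 4 zones, 5 merged PAs
[evaluate] n=105, avg index correlation 0.559 (components 0.068)
```

Reading these numbers: all 252 planted expansion patches were recovered by
8-connected labeling; 311 of the 3,600 grid cells (8.6% of the map) carry
expansion and hence a positive threat degree, averaging 36.75%; the
mean/SD classification cuts the TD map at 42.89 and 55.17; and the index
correlates with its three component densities far more strongly (average
Pearson r ≈ 0.56) than the components correlate with each other (≈ 0.07),
the suitability property a composite index should have. Artifacts
(`td.tif`, `levels.tif`, zonal TSV tables, `correlations.json`, a manifest
with checksums) land in `demo_run/`; re-running the same configuration
reproduces them byte for byte.

A command-line front end wrapping the same stages is installed at
`system.file("scripts/threatscape.R", package = "threatscape")`
(subcommands `simulate`, `terrain`, `detect`, `species`, `index`, `zonal`,
`evaluate`, `run-all`).

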