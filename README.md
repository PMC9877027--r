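# mycorootmap

Global-scale maps of mycorrhizal fungal abundance belowground are scarce,
even though the fine roots colonized by arbuscular (AM) and ectomycorrhizal
(EcM) fungi are where plant carbon meets the fungal partner. `mycorootmap`
is a tested, reusable R implementation of the workflow that produces maps of
**fine-root biomass carbon colonized by AM and EcM fungi** (MgC ha⁻¹): it is
aimed at spatial ecologists and biogeochemists who want to rerun, audit or
extend that workflow on their own layers — or stress-test it end to end on a
synthetic world with known ground truth.

## The model

Estimates are made per *spatial unit* — the intersection of an ecoregion, a
land-cover class and a continent (croplands, urban, bare and water classes
are discarded). For a unit *u* and mycorrhizal type *m*, the colonized
fine-root carbon is

```
C(u, m) = Σ_g  S(u, g) · f_fine(g) · (1 − β_g^30) · p(u, m, g) · I(u, m, g) / 100
```

where the sum runs over growth forms *g* (woody, herbaceous — or a single
growth-form-free pool on tundra units), `S` is belowground biomass C density
(MgC ha⁻¹), `f_fine` the fine-root fraction of root mass (0.141 woody,
0.885 herbaceous), `1 − β^30` the share of roots in the top 30 cm from the
asymptotic vertical root-distribution model (β = 0.974 woody — the mean of
trees 0.970 and shrubs 0.978 — and 0.952 herbaceous), `p` the biomass
fraction of plants associating with type *m*, and `I` the colonization
intensity (%).

The intensity is a community-weighted mean treated as a species trait:
species-level means of filtered colonization records (natural conditions,
growing season; AM % root length and EcM % root tips never pooled) are
weighted by plot relative abundances renormalized over the species that have
data, then averaged over the plots of the unit. Dual-colonized species count
half toward each type. Units without plots are gap-filled with the mean of
their ecoregion × continent group, and three quality-index layers (records
per species, coverage, plot count) accompany each map.

## Worked example

```r
library(mycorootmap)

p <- root_fraction_params()
round(depth_fraction(c(p$beta_woody, p$beta_herb), 30), 4)
#> [1] 0.5463 0.7714        # top-30 cm root share, woody / herbaceous

w <- generate_world(world_config(seed = 42))
w
#> <synthetic_world> 60 x 60 coarse grid, 17 units (14 observed), 68 species, 74 plots, 486 records

res <- run_pipeline(w)
#> filter_records: dropped 30 non-natural or out-of-season records
#> split_dual_abundance: excluded 24 plot records of 4 species with no mycorrhizal type
#> assign_plots_to_units: dropped 4 plots on nodata or excluded pixels

dplyr::filter(res$totals, unit_id %in% 1:3)
#>   unit_id myc_type  total total_filled capable intensity_effective
#> 1       1 AM       NA            0.853   0.389                NA
#> 2       1 EcM      NA            0.613   0.958                NA
#> 3       2 AM        0.853        0.853   1.53                 55.9
#> 4       2 EcM       0.613        0.613   1.19                 51.4
#> 5       3 AM        0.334        0.334   0.634                52.7
#> 6       3 EcM       0.205        0.205   0.456                45.1

res$rasters$AM_roots_colonized
#> <raster_grid> 60 x 60 cells, 0.166667 deg resolution (EPSG:4326)
#>   extent: lon [0.0000, 10.0000], lat [0.0000, 10.0000]
#>   values: [0.0500366, 1.16478], 1500 nodata cells
```

Unit 1 had no vegetation plots: its `total` is missing and `total_filled`
carries the ecoregion × continent mean (0.853 MgC ha⁻¹ for AM). Unit 2 holds
1.53 MgC ha⁻¹ of fine roots capable of AM association, of which 55.9% —
0.853 MgC ha⁻¹ — is colonized. `write_pipeline_outputs()` writes the maps
and unit tables in the deposit-style layout (`AM_roots_colonized`,
`EcM_intensity_colonization`, `AM_plots`, ...), and
`inst/cli/run_pipeline.R` wraps the same chain for shell use.

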