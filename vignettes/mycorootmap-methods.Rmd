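---
title: "Methods: from biomass layers and plot surveys to mycorrhizal root-carbon maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from biomass layers and plot surveys to mycorrhizal root-carbon maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mycorootmap)
library(dplyr)
```

## The estimation problem

Arbuscular mycorrhizal (AM) and ectomycorrhizal (EcM) fungi colonize the fine
roots of most terrestrial plants, but how much root biomass carbon they
actually occupy, and where, is poorly constrained. The quantity this package
maps is the fine-root carbon stock colonized by each mycorrhizal type, in
MgC ha^-1, estimated per *spatial unit* — the intersection of one ecoregion,
one land-cover class and one continent. The estimate for a unit factorizes
into two independent parts:

1. **How much fine root is there that could be colonized?** Belowground
   biomass carbon density, scaled by the fine-root fraction of total root
   mass, the fraction of roots in the depth horizon where colonization
   happens, and the fraction of plant biomass associated with each
   mycorrhizal type.
2. **How intensely is it colonized?** A community-weighted mean of
   species-level colonization intensities (% of root length for AM, % of
   root tips for EcM), weighted by species relative abundances in vegetation
   plots, averaged over the plots of the unit.

The product `stock x intensity / 100` gives colonized root carbon; per-unit
values are painted back onto the raster grid and empty units are borrowed
from their ecoregion x continent neighbours.

## Spatial units

`build_unit_map()` overlays three categorical rasters that must share grid
and registration. Land-cover classes representing croplands, urban areas,
bare areas and water are excluded through the `excluded_classes` argument
(when running on rasters with the real land-cover coding, the set
`{0, 10, 20, 30, 190, 200, 201, 202, 210, 220}` reproduces the 15 retained
natural classes; retaining the cropland-dominated mosaic class 30 would give
16, so it is excluded alongside the pure cropland classes). Only observed
(ecoregion, land cover, continent) triples become units, and unit ids are
assigned by lexicographic sort of the triple so that re-running is stable.
Tundra units are flagged by an ecoregion-code list: which ecoregions are
"tundra" is an input, not something inferable from the codes themselves.

Source layers arrive at different resolutions. Categorical layers are
coarsened with `resample_categorical_nearest()`: each coarse cell takes the
fine cell nearest its center. For even aggregation factors the center is
equidistant from four cells; we take the smallest (row, col) in scan order —
the north-west cell of the central four. Any fixed tie-break is equally
defensible; what matters is that it is deterministic and documented.
Continuous (biomass) layers use `aggregate_mean()`: the mean of valid cells
per block, nodata only when the whole block is nodata.

## From belowground biomass to colonizable fine roots

Three constants per growth form turn a belowground biomass C density into
the fine-root stock available for colonization (`root_fraction_params()`):

| parameter | default | units | meaning |
|---|---|---|---|
| `fine_fraction_woody` | 0.141 | — | fine-root share of woody root mass |
| `fine_fraction_herb` | 0.885 | — | fine-root share of herbaceous root mass |
| `beta_tree`, `beta_shrub`, `beta_herb` | 0.970, 0.978, 0.952 | — | vertical-distribution extinction coefficients |
| `depth_cm` | 30 | cm | depth horizon of mycorrhizal colonization |

The vertical model is the asymptotic form `y = 1 - beta^d`
(`depth_fraction()`): with the defaults, 54.6% of woody and 77.1% of
herbaceous root mass lies in the top 30 cm. The woody coefficient is the
mean of the tree and shrub values (0.974), because the belowground woody
biomass layer does not separate them.

```{r}
p <- root_fraction_params()
c(woody = depth_fraction(p$beta_woody, 30),
  herb  = depth_fraction(p$beta_herb, 30))
```

The fine-root fractions ship as constants because that is how they enter the
workflow, but `fine_fraction_from_ratios()` recomputes them from a
coarse/fine root mass ratio table: ratios are strongly right-skewed, so the
central ratio is the back-transformed mean of log ratios (the geometric
mean; the base of the logarithm is immaterial) and the fine fraction is
`1 / (1 + r)`. Whether the published constants were derived exactly this way
or as direct means of fine fractions is not documented at source; we adopt
the `1/(1+r)` convention because it is the only one in which a single ratio
of 0.13 reproduces the herbaceous constant 0.885.

Mycorrhizal fractions of woody vegetation are the per-pixel sum of the tree
and shrub biomass-fraction layers (`woody_myc_fraction()`). Sums marginally
above 1 can arise from inconsistencies between independently produced source
maps; they are clipped to 1 with a warning rather than treated as errors.

**Tundra.** The tundra biomass layer carries no growth-form split, so tundra
units take a separate path: growth-form-free AM/EcM fraction layers, and —
a choice this package makes explicitly, since none is documented at source —
the *herbaceous* fine-root fraction and extinction coefficient, on the
ground that tundra vegetation is dominated by herbs and small shrubs. On
tundra units the woody and herbaceous paths are skipped entirely.

## Colonization intensity as a community-weighted trait

Colonization intensity is treated as a species-level trait. Records are
first filtered (`filter_records()`): non-natural settings (plantations,
nurseries, greenhouses, pots) and out-of-season observations are dropped;
records with *unknown* naturalness or season are kept, since intensities are
conventionally reported from growing-season surveys in natural habitats.
Categorical report scales are converted to percentages through a
user-supplied mapping (`categorical_to_percent()`); no universal conversion
table exists, so an unmapped label is an error naming the label, never a
silent drop. Species means are then arithmetic means per species *and
measurement kind*: AM (% root length) and EcM (% root tips) are different
measurements and are never pooled — a dual-colonized species needs records
of each kind to contribute to each pool.

Species are matched across tables case-insensitively after whitespace
normalization, with no fuzzy matching: a silent wrong match is worse than a
reported drop. Mycorrhizal types are assigned by genus (the first token of
the species name); facultative AM is folded into AM; species with no
assignment are excluded. Dual-colonized species contribute half their
abundance to each type (`split_dual_abundance()`), which conserves total
abundance by construction.

For each plot and each mycorrhizal-type x growth-form pool,
`plot_weighted_intensity()` renormalizes abundances over the species that
have colonization data and takes the weighted mean of species means. The
share of pool abundance carried by covered species is recorded as
*coverage*. A pool with no covered species is empty — not zero — and is
simply absent from unit averaging. Unit intensity is the unweighted mean
over plots (`unit_intensity()`); weighting by plot size is a conceivable
alternative, but plot sizes are not part of the data contract and the
unweighted mean is the documented convention. Species of unknown growth
form are excluded from the woody/herbaceous pools but retained in the
growth-form-free tundra pools.

## Assembly, gap-filling and quality

`colonized_stock()` multiplies per-pool stock by intensity/100;
`combine_pools()` sums woody + herbaceous per type on ordinary units and
uses only the tundra pool on tundra units. Gap-filling (`gap_fill()`)
assigns empty pools the mean of observed pools among units sharing
ecoregion and continent. Filling operates **per pool, before combination**:
a unit with woody data but no herbaceous data keeps its woody observation
and borrows only the herbaceous pool, which makes maximal use of partial
data (filling combined totals instead would discard it). Observed values
are never altered; groups with no observed member stay missing, and both
map variants — empty units as nodata, and gap-filled — are emitted.

The final maps are piecewise constant per unit: the published products
assign the unit value to every pixel, and `rasterize_units()` followed by
`zonal_mean()` is exactly the identity on per-unit values, which the tests
exploit. The per-type intensity raster reports the *effective* intensity,
`100 x colonized total / colonizable stock`, which collapses the pool
structure into one self-consistent number per unit.

Three quality indices accompany each type (`quality_rasters()`): mean
colonization observations per species, mean coverage, and plot count. They
are computed from observed data only, before gap-filling — borrowed units
carry nodata quality, because their values are copies, not observations.
`compare_rasters()` implements the validation-style comparison against an
independent reference map: reference pixels with standard error above a
threshold (default 20 percentage points) are masked, differences are
`ours - reference`, and the histogram uses 10-point bins over [-100, 100]
(a presentation choice; the bins are configurable).

## The synthetic world and what passing tests mean

`generate_world()` emits every input from scratch: categorical layers in
contiguous bands and strips (ecoregions horizontal, continents vertical,
land-cover strips within each block), biomass layers at finer resolution,
fraction layers, species traits, colonization records and vegetation plots.
One land-cover class plays the role of water: excluded from units and
nodata in every biomass layer, so masking is always exercised. Defaults
draw unit intensities in [40, 60]%, record noise of 5 pp, 6 observations
per species, 5 plots per observed unit, 15% of units without plots, 15%
categorical records, and a 5% within-cell biomass noise that is centered
per coarse block so block means stay exact.

Two constructions make ground truth *exactly* recoverable rather than
approximately:

* Species true means are drawn from a low band [20, 35]% and a high band
  [65, 80]% that bracket the unit targets. Each plot's pool is then a
  two-species mixture whose weights are solved in closed form so the
  community-weighted mean equals the unit's true intensity exactly (dual
  species enter as a three-species system with the 50/50 split accounted
  for). With record noise off, the pipeline must reproduce truth to
  floating precision — a sharp end-to-end correctness test. The bands also
  keep species means ~2 sd away from the [0, 100] clamp at the highest
  noise level used (10 pp), so clamping bias on recovered means is
  negligible (< 0.1 pp).
* Biomass is constant per unit at block level, so zonal means equal the
  per-unit truth exactly.

For the statistical recovery checks the suite uses a 100 x 100 coarse grid
(~20 units): zero-noise recovery with 30 plots/unit must match truth within
1e-9 relative; with 10 pp record noise, 100 plots/unit and 20 observations
per species, unit intensities must land within 2 pp of truth for at least
95% of units. The 20-observations figure follows from a power analysis done
when the generator was designed: the unit-level standard error is roughly
`0.3 x 10/sqrt(20) ~ 0.7 pp`, making 2 pp a ~3-sigma band per unit.
Contaminated records (non-natural, out-of-season, shifted by +/-30 pp) are
always present, so the filtering rules are load-bearing even at zero noise;
the categorical-record fraction is set to zero in the exact-recovery
configuration because class-midpoint conversion is deliberately lossy
(37 becomes 37.5).

What the synthetic world does **not** emulate: the spatial covariance
structure of real land-cover and ecoregion maps (units here are tidy
rectangles), realistic species abundance distributions (plot compositions
are solved, not sampled from communities), intraspecific intensity
variation driven by climate or soil, and registration or projection errors
between source layers. Passing tests therefore demonstrate that the
*computational chain* is correct and statistically well-behaved, not that
the ecological assumptions (intensity as a species trait, aboveground
fractions proxying belowground, root tips ~ biomass) hold in nature.

## Numerical and format choices

* Rasters are an in-memory S3 class (`raster_grid`) with `NA` for missing
  cells; the nodata sentinel exists only on disk. I/O uses the ESRI ASCII
  grid format (`.asc` + `.prj` sidecar): text-based, georeferenced, and
  readable by GDAL/QGIS. Only WGS84 longitude/latitude with square cells is
  supported; there is no reprojection — inputs must already share a grid,
  and misalignment is an error, never a silent resample.
* Cells are half-open: a point on an interior boundary belongs to the cell
  north-east of it; outer edges are inclusive, so every point in the extent
  maps to exactly one cell.
* Degenerate inputs follow one rule: *missing is never zero*. Empty zonal
  footprints, pools without covered species and unfillable groups all stay
  `NA` and are reported, not coerced.
* Worlds are bit-reproducible: one seed drives every draw in
  `generate_world()`, and identical configurations write byte-identical
  files.

## Known limitations

Gap-filling borrows *colonized values*, as the method prescribes, so a
borrowed value is not constrained by the receiving unit's own colonizable
stock: the conservation guarantee (colonized <= stock) holds for observed
units, not for gap-filled ones. Users needing strict per-unit conservation
can instead multiply the unit's own stock by a borrowed intensity, at the
cost of departing from the documented fill rule.

Uncertainty from the source biomass and fraction layers is not propagated —
the quality indices describe only the colonization side, mirroring the
scope of the original products. The conversion from colonization to
extraradical (soil) fungal biomass is out of scope by design. AM and EcM
colonized stocks are not strictly commensurable (root-length vs root-tip
measurements); comparisons between the two types should be qualitative.
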