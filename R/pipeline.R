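#' Run the full mapping workflow on a synthetic (or assembled) world
#'
#' Executes the whole chain on the input layers and tables of a world object:
#' nearest-neighbour aggregation of the categorical layers and construction of
#' the spatial-unit map; block-mean aggregation of the belowground biomass
#' layers and conversion to fine-root C stocks in the top 30 cm; per-unit
#' mycorrhizal stock means; species-level colonization means and
#' community-weighted unit intensities; per-pool colonized stocks with
#' ecoregion-by-continent gap-filling; and final raster assembly with
#' quality-index layers.
#'
#' Tundra units follow the growth-form-free path: their stocks come from the
#' tundra biomass layer (scaled with the herbaceous fine-root constants, as
#' tundra vegetation is predominantly herbs and small shrubs) and the
#' growth-form-free AM/EcM fraction layers, and their intensities pool all
#' growth forms.
#'
#' @param world A `synthetic_world` (see [generate_world()]), or any list with
#'   the same `rasters`, `tables` and `categorical_mapping` structure.
#' @param params A [root_fraction_params()].
#' @return A list with:
#' \describe{
#'   \item{units}{the `spatial_unit_map`}
#'   \item{colonization}{species means, plot intensities and unit
#'     colonization (see [compute_unit_colonization()])}
#'   \item{unit_summary}{long tibble per unit x pool: `stock` (MgC ha^-1),
#'     `intensity` (%), `colonized` (MgC ha^-1), `colonized_filled`,
#'     `fill_status`}
#'   \item{totals}{per unit x mycorrhizal type: `total` (observed pools
#'     only) and `total_filled` (after gap-fill)}
#'   \item{rasters}{final maps: per type, colonized stock with empty units as
#'     nodata and gap-filled, effective intensity, fine-root stock capable of
#'     association}
#'   \item{quality}{per type, the three quality-index rasters}
#' }
#' @export
run_pipeline <- function(world, params = root_fraction_params()) {
  cfg <- world$config
  f <- cfg$fine_factor
  r <- world$rasters

  ## spatial units from nearest-neighbour-aggregated categorical layers
  units <- build_unit_map(
    resample_categorical_nearest(r$ecoregion, f),
    resample_categorical_nearest(r$landcover, f),
    resample_categorical_nearest(r$continent, f),
    excluded_classes = cfg$excluded_landcover,
    tundra_ecoregions = cfg$tundra_ecoregions)

  ## fine-root stocks in the top of the profile, per growth form
  depth_w <- depth_fraction(params$beta_woody, params$depth_cm)
  depth_h <- depth_fraction(params$beta_herb, params$depth_cm)
  fineroot <- list(
    woody = fine_root_stock(aggregate_mean(r$bgb_woody, f),
                            params$fine_fraction_woody, depth_w),
    herbaceous = fine_root_stock(aggregate_mean(r$bgb_herb, f),
                                 params$fine_fraction_herb, depth_h),
    tundra_all = fine_root_stock(aggregate_mean(r$bgb_tundra, f),
                                 params$fine_fraction_herb, depth_h))

  ## mycorrhizal-type stock rasters per pool
  frac <- list(
    AM.woody = woody_myc_fraction(r$frac_am_tree, r$frac_am_shrub),
    EcM.woody = woody_myc_fraction(r$frac_ecm_tree, r$frac_ecm_shrub),
    AM.herbaceous = r$frac_am_herb, EcM.herbaceous = r$frac_ecm_herb,
    AM.tundra_all = r$frac_am_all, EcM.tundra_all = r$frac_ecm_all)
  pools <- tibble::tibble(
    pool = names(frac),
    myc_type = sub("\\..*$", "", names(frac)),
    growth_form = sub("^[^.]*\\.", "", names(frac)))
  stock_rasters <- lapply(stats::setNames(nm = pools$pool), function(p) {
    myc_root_stock(fineroot[[pools$growth_form[pools$pool == p]]], frac[[p]])
  })

  ## per-unit pool stocks: tundra units use only the tundra pool, others only
  ## the growth-form pools
  unit_stocks <- dplyr::bind_rows(lapply(pools$pool, function(p) {
    zonal_mean(stock_rasters[[p]], units) |>
      dplyr::mutate(myc_type = pools$myc_type[pools$pool == p],
                    growth_form = pools$growth_form[pools$pool == p]) |>
      dplyr::rename(stock = "mean")
  })) |>
    dplyr::left_join(dplyr::select(units$units, "unit_id", "is_tundra"),
                     by = "unit_id") |>
    dplyr::filter(ifelse(.data$is_tundra,
                         .data$growth_form == "tundra_all",
                         .data$growth_form != "tundra_all")) |>
    dplyr::select("unit_id", "myc_type", "growth_form", "stock")

  ## colonization intensities per unit
  col <- compute_unit_colonization(
    world$tables$records, world$tables$plots, world$tables$growth_forms,
    world$tables$genus_types, units,
    categorical_mapping = world$categorical_mapping)

  ## colonized stocks per pool, gap-filled by ecoregion x continent mean
  summary_tbl <- unit_stocks |>
    dplyr::left_join(dplyr::select(col$unit_colonization, "unit_id",
                                   "myc_type", "growth_form",
                                   intensity = "mean_intensity"),
                     by = c("unit_id", "myc_type", "growth_form")) |>
    dplyr::mutate(colonized = colonized_stock(.data$stock,
                                              .data$intensity))
  filled <- gap_fill(
    dplyr::select(summary_tbl, "unit_id", "myc_type", "growth_form",
                  value = "colonized"),
    units$units)
  summary_tbl <- summary_tbl |>
    dplyr::left_join(dplyr::rename(filled, colonized_filled = "value"),
                     by = c("unit_id", "myc_type", "growth_form"))

  totals <- dplyr::full_join(
    combine_pools(dplyr::select(summary_tbl, "unit_id", "myc_type",
                                "growth_form", value = "colonized"),
                  units$units),
    combine_pools(dplyr::select(summary_tbl, "unit_id", "myc_type",
                                "growth_form",
                                value = "colonized_filled"),
                  units$units) |>
      dplyr::rename(total_filled = "total"),
    by = c("unit_id", "myc_type"))

  ## per-unit fine-root stock capable of forming each association
  capable <- combine_pools(dplyr::select(unit_stocks |>
                                           dplyr::mutate(value = .data$stock),
                                         "unit_id", "myc_type", "growth_form",
                                         "value"),
                           units$units) |>
    dplyr::rename(capable = "total")
  totals <- dplyr::left_join(totals, capable, by = c("unit_id", "myc_type")) |>
    dplyr::mutate(intensity_effective = ifelse(.data$capable > 0,
                                               .data$total / .data$capable * 100,
                                               NA_real_))

  out_rasters <- list()
  for (ty in c("AM", "EcM")) {
    tt <- dplyr::filter(totals, .data$myc_type == ty)
    out_rasters[[paste0(ty, "_roots_colonized")]] <-
      rasterize_units(dplyr::select(tt, "unit_id", value = "total"), units)
    out_rasters[[paste0(ty, "_roots_colonized_filled")]] <-
      rasterize_units(dplyr::select(tt, "unit_id", value = "total_filled"),
                      units)
    out_rasters[[paste0(ty, "_roots")]] <-
      rasterize_units(dplyr::select(tt, "unit_id", value = "capable"), units)
    out_rasters[[paste0(ty, "_intensity_colonization")]] <-
      rasterize_units(dplyr::select(tt, "unit_id",
                                    value = "intensity_effective"), units)
  }

  quality <- list(AM = quality_rasters(col$unit_colonization, units, "AM"),
                  EcM = quality_rasters(col$unit_colonization, units, "EcM"))

  list(units = units, colonization = col, unit_summary = summary_tbl,
       totals = totals, fineroot = fineroot, stock_rasters = stock_rasters,
       rasters = out_rasters, quality = quality)
}
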