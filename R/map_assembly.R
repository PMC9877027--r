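#' Colonized fine-root carbon stock
#'
#' The fraction of a fine-root carbon stock that is colonized by a
#' mycorrhizal type: `stock * intensity / 100`.
#'
#' @param stock Fine-root C stock in MgC ha^-1 (vectorized, `>= 0`).
#' @param intensity Colonization intensity in percent, in `[0, 100]`
#'   (vectorized).
#' @return Colonized stock in MgC ha^-1.
#' @export
colonized_stock <- function(stock, intensity) {
  if (any(stock < 0, na.rm = TRUE))
    stop("`stock` must be non-negative", call. = FALSE)
  if (any(intensity < 0 | intensity > 100, na.rm = TRUE))
    stop("`intensity` must lie in [0, 100]", call. = FALSE)
  stock * intensity / 100
}

#' Combine per-pool colonized stocks into per-type unit totals
#'
#' On ordinary units the total colonized stock of a mycorrhizal type is the
#' sum of its woody and herbaceous pools; on tundra units only the
#' growth-form-free tundra pool counts, even if woody or herbaceous values
#' exist. A pool that exists nowhere for a type (EcM herbaceous vegetation,
#' say, for which no fine-root biomass exists) contributes zero, not missing;
#' a unit whose every pool of a type is missing stays missing (to be
#' gap-filled).
#'
#' @param pool_values Long tibble with columns `unit_id`, `myc_type`,
#'   `growth_form` (`"woody"`, `"herbaceous"` or `"tundra_all"`) and `value`
#'   (`NA` for missing pools).
#' @param unit_table The `units` tibble of a `spatial_unit_map` (needs
#'   `unit_id`, `is_tundra`).
#' @return A tibble `unit_id`, `myc_type`, `total` with one row per unit x
#'   type present in `pool_values`.
#' @export
combine_pools <- function(pool_values, unit_table) {
  pool_values |>
    dplyr::left_join(dplyr::select(unit_table, "unit_id", "is_tundra"),
                     by = "unit_id") |>
    dplyr::filter(ifelse(.data$is_tundra,
                         .data$growth_form == "tundra_all",
                         .data$growth_form %in% c("woody", "herbaceous"))) |>
    dplyr::summarise(
      total = if (all(is.na(.data$value))) NA_real_
              else sum(.data$value, na.rm = TRUE),
      .by = c("unit_id", "myc_type")) |>
    dplyr::arrange(.data$unit_id, .data$myc_type)
}

#' Gap-fill empty spatial units by ecoregion-by-continent means
#'
#' Units left without a value (no vegetation plots, or no colonization data)
#' receive the arithmetic mean of the observed values among units sharing
#' their ecoregion and continent, independently per pool. Observed units are
#' never altered, fills never cross an ecoregion x continent boundary, and
#' groups with no observed member remain missing (`fill_status =
#' "unfilled"`).
#'
#' @param pool_values Long tibble `unit_id`, `myc_type`, `growth_form`,
#'   `value` covering every unit x pool to consider (`NA` value = empty).
#' @param unit_table The `units` tibble of a `spatial_unit_map` (needs
#'   `unit_id`, `ecoregion`, `continent`).
#' @return `pool_values` with `value` filled where possible and a
#'   `fill_status` column: `"observed"`, `"ecoregion_continent_mean"` or
#'   `"unfilled"`.
#' @export
gap_fill <- function(pool_values, unit_table) {
  pool_values |>
    dplyr::left_join(dplyr::select(unit_table, "unit_id", "ecoregion",
                                   "continent"),
                     by = "unit_id") |>
    dplyr::mutate(
      group_mean = {
        obs <- .data$value[!is.na(.data$value)]
        if (length(obs) > 0) mean(obs) else NA_real_
      },
      .by = c("ecoregion", "continent", "myc_type", "growth_form")) |>
    dplyr::mutate(
      fill_status = dplyr::case_when(
        !is.na(.data$value) ~ "observed",
        !is.na(.data$group_mean) ~ "ecoregion_continent_mean",
        TRUE ~ "unfilled"),
      value = dplyr::coalesce(.data$value, .data$group_mean)) |>
    dplyr::select(-"group_mean", -"ecoregion", -"continent") |>
    dplyr::arrange(.data$unit_id, .data$myc_type, .data$growth_form)
}

#' Paint per-unit values onto the unit raster
#'
#' Every pixel of a unit's footprint takes that unit's value; masked
#' (excluded or nodata) pixels stay nodata, and units with a missing value
#' (e.g. unfilled after gap-filling) become nodata pixels. Every unit present
#' in the raster must appear in `values`.
#'
#' @param values Data frame with columns `unit_id` and `value` (`NA`
#'   allowed).
#' @param units A `spatial_unit_map`.
#' @return A `raster_grid` on the unit grid.
#' @export
rasterize_units <- function(values, units) {
  present <- units$units$unit_id
  missing <- setdiff(present, values$unit_id)
  if (length(missing) > 0)
    stop(sprintf("no value supplied for %d unit(s), e.g. unit_id %d",
                 length(missing), missing[1]), call. = FALSE)
  id <- units$raster$values
  out <- matrix(NA_real_, nrow(id), ncol(id))
  idx <- !is.na(id)
  out[idx] <- values$value[match(id[idx], values$unit_id)]
  raster_grid(out, xll = units$raster$xll, yll = units$raster$yll,
              cellsize = units$raster$cellsize, crs = units$raster$crs,
              nodata = units$raster$nodata)
}
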