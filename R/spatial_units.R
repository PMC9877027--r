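#' Build the spatial-unit map from categorical overlay layers
#'
#' A spatial unit is the intersection of one ecoregion, one land-cover class
#' and one continent: the categorical stratum over which all stocks and
#' colonization intensities are averaged. Pixels carrying nodata in any input
#' layer, or a land-cover class in `excluded_classes` (croplands, urban, bare
#' and water in the real land-cover coding), are masked out. Only observed
#' (ecoregion, land cover, continent) triples become units; unit ids are
#' assigned by lexicographic sort of the triple, so re-running on the same
#' inputs yields identical ids.
#'
#' @param ecoregion,landcover,continent Aligned categorical `raster_grid`s
#'   (integer codes).
#' @param excluded_classes Integer land-cover codes to discard.
#' @param tundra_ecoregions Integer ecoregion codes routed through the tundra
#'   (growth-form-free) workflow.
#' @return An object of class `spatial_unit_map`: a list with `raster` (a
#'   `raster_grid` of integer unit ids, `NA` on masked pixels) and `units`
#'   (a tibble with columns `unit_id`, `ecoregion`, `landcover`, `continent`,
#'   `is_tundra`, `n_pixels`).
#' @examples
#' eco <- raster_grid(matrix(c(1, 1, 2, 2), 2))
#' lc  <- raster_grid(matrix(c(40, 50, 40, 50), 2))
#' con <- raster_grid(matrix(1, 2, 2))
#' build_unit_map(eco, lc, con)$units
#' @export
build_unit_map <- function(ecoregion, landcover, continent,
                           excluded_classes = integer(),
                           tundra_ecoregions = integer()) {
  stop_if_grid_mismatch(ecoregion, landcover, "ecoregion and landcover")
  stop_if_grid_mismatch(ecoregion, continent, "ecoregion and continent")
  e <- ecoregion$values; l <- landcover$values; k <- continent$values
  valid <- !is.na(e) & !is.na(l) & !is.na(k) & !(l %in% excluded_classes)

  units <- tibble::tibble(ecoregion = as.integer(e[valid]),
                          landcover = as.integer(l[valid]),
                          continent = as.integer(k[valid])) |>
    dplyr::count(.data$ecoregion, .data$landcover, .data$continent,
                 name = "n_pixels") |>
    dplyr::arrange(.data$ecoregion, .data$landcover, .data$continent) |>
    dplyr::mutate(unit_id = dplyr::row_number(),
                  is_tundra = .data$ecoregion %in% tundra_ecoregions) |>
    dplyr::select("unit_id", "ecoregion", "landcover", "continent",
                  "is_tundra", "n_pixels")

  ids <- matrix(NA_integer_, nrow(e), ncol(e))
  if (nrow(units) > 0L) {
    key <- paste(e[valid], l[valid], k[valid])
    ids[valid] <- units$unit_id[match(key, paste(units$ecoregion,
                                                 units$landcover,
                                                 units$continent))]
  }
  structure(
    list(raster = raster_grid(ids, xll = ecoregion$xll, yll = ecoregion$yll,
                              cellsize = ecoregion$cellsize,
                              crs = ecoregion$crs, nodata = ecoregion$nodata),
         units = units),
    class = "spatial_unit_map"
  )
}

#' @export
print.spatial_unit_map <- function(x, ...) {
  cat(sprintf("<spatial_unit_map> %d units over a %d x %d grid (%d tundra)\n",
              nrow(x$units), nrow(x$raster$values), ncol(x$raster$values),
              sum(x$units$is_tundra)))
  invisible(x)
}

#' Per-unit mean of a raster layer
#'
#' Arithmetic mean of the valid (non-nodata) pixels of `values` within each
#' spatial-unit footprint. Units whose footprint holds no valid pixel are
#' flagged empty (`NA` mean, `n_pixels = 0`), never zero: missingness is not a
#' stock of zero.
#'
#' @param values A `raster_grid` aligned with `units$raster`.
#' @param units A `spatial_unit_map`.
#' @return A tibble with one row per unit: `unit_id`, `mean`, `n_pixels`.
#' @export
zonal_mean <- function(values, units) {
  stop_if_grid_mismatch(values, units$raster, "value and unit rasters")
  id <- units$raster$values
  v <- values$values
  ok <- !is.na(id) & !is.na(v)
  agg <- tibble::tibble(unit_id = id[ok], v = v[ok]) |>
    dplyr::summarise(mean = mean(.data$v), n_pixels = dplyr::n(),
                     .by = "unit_id")
  units$units |>
    dplyr::select("unit_id") |>
    dplyr::left_join(agg, by = "unit_id") |>
    dplyr::mutate(n_pixels = dplyr::coalesce(.data$n_pixels, 0L)) |>
    dplyr::arrange(.data$unit_id)
}
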