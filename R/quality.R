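#' Quality-index rasters for a mycorrhizal type
#'
#' The colonization side of the workflow carries three per-unit quality
#' indices: the mean number of colonization observations per species (how
#' well intraspecific variation is captured), the mean relative abundance of
#' species with colonization data (how well the dominant species are
#' covered), and the number of vegetation plots (how well the unit's
#' vegetation variability is represented). Each index is painted onto the
#' unit raster; units without observed colonization are nodata — the indices
#' describe observed data only, so they are computed before gap-filling and
#' borrowed (gap-filled) units carry no quality value.
#'
#' @param unit_colonization Output of [unit_intensity()] (or the
#'   `unit_colonization` element of [compute_unit_colonization()]).
#' @param units A `spatial_unit_map`.
#' @param myc_type `"AM"` or `"EcM"`.
#' @return A named list of three `raster_grid`s:
#'   `mean_obs_per_species`, `mean_coverage` (%), `n_plots`.
#' @export
quality_rasters <- function(unit_colonization, units, myc_type = "AM") {
  per_unit <- unit_colonization |>
    dplyr::filter(.data$myc_type == !!myc_type) |>
    dplyr::summarise(
      mean_obs_per_species = stats::weighted.mean(.data$mean_obs_per_species,
                                                  .data$n_plots),
      mean_coverage = stats::weighted.mean(.data$mean_coverage,
                                           .data$n_plots),
      n_plots = max(.data$n_plots),
      .by = "unit_id")
  full <- dplyr::left_join(dplyr::select(units$units, "unit_id"), per_unit,
                           by = "unit_id")
  lapply(stats::setNames(nm = c("mean_obs_per_species", "mean_coverage",
                                "n_plots")),
         function(col) {
           rasterize_units(
             dplyr::tibble(unit_id = full$unit_id, value = full[[col]]),
             units)
         })
}

#' SE-filtered raster comparison with difference histogram
#'
#' Compares two aligned rasters of the same quantity (e.g. an intensity map
#' against an independently modelled reference) after masking reference
#' pixels whose reported standard error exceeds a threshold, so that the
#' comparison is restricted to pixels where the reference is trustworthy.
#' Returns the per-pixel difference `ours - reference` and a binned histogram
#' of the unmasked differences.
#'
#' @param ours,reference Aligned `raster_grid`s.
#' @param reference_se Aligned `raster_grid` of the reference's standard
#'   error, or `NULL` to skip the filter.
#' @param se_threshold Mask reference pixels with SE above this value
#'   (default 20 percentage points).
#' @param breaks Histogram bin edges (default 10-point bins over
#'   `[-100, 100]`).
#' @return A list with `difference` (a `raster_grid`) and `histogram` (a
#'   tibble `bin_low`, `bin_high`, `count`).
#' @export
compare_rasters <- function(ours, reference, reference_se = NULL,
                            se_threshold = 20,
                            breaks = seq(-100, 100, by = 10)) {
  stop_if_grid_mismatch(ours, reference, "compared rasters")
  d <- ours$values - reference$values
  if (!is.null(reference_se)) {
    stop_if_grid_mismatch(ours, reference_se, "raster and SE rasters")
    d[!is.na(reference_se$values) & reference_se$values > se_threshold] <- NA_real_
    d[is.na(reference_se$values)] <- NA_real_
  }
  diffs <- d[!is.na(d)]
  counts <- if (length(diffs) > 0) {
    tab <- table(cut(diffs, breaks = breaks, include.lowest = TRUE,
                     right = FALSE))
    as.integer(tab)
  } else {
    integer(length(breaks) - 1L)
  }
  list(
    difference = raster_grid(d, xll = ours$xll, yll = ours$yll,
                             cellsize = ours$cellsize, crs = ours$crs,
                             nodata = ours$nodata),
    histogram = tibble::tibble(bin_low = utils::head(breaks, -1L),
                               bin_high = utils::tail(breaks, -1L),
                               count = counts)
  )
}
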