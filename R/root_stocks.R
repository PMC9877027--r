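#' Parameters of the fine-root stock derivation
#'
#' Bundles the constants that turn a belowground biomass carbon density map
#' into fine-root carbon in the top 30 cm of soil: the fine-root fraction of
#' total root mass per growth form, and the extinction coefficients of the
#' asymptotic vertical root-distribution model (see [depth_fraction()]).
#' Defaults are the published field estimates: fine-root fractions of 88.5%
#' (herbaceous) and 14.1% (woody) derived from coarse/fine root mass ratio
#' compilations, and beta values of 0.970 (trees), 0.978 (shrubs) and 0.952
#' (herbs); the woody beta is the mean of the tree and shrub values.
#'
#' @param fine_fraction_herb,fine_fraction_woody Fine-root fraction of total
#'   root biomass, in (0, 1).
#' @param beta_tree,beta_shrub,beta_herb Dimensionless extinction coefficients
#'   in (0, 1).
#' @param depth_cm Soil depth of interest in cm.
#' @return A list of class `root_fraction_params` with the above fields plus
#'   `beta_woody = (beta_tree + beta_shrub) / 2`.
#' @export
root_fraction_params <- function(fine_fraction_herb = 0.885,
                                 fine_fraction_woody = 0.141,
                                 beta_tree = 0.970,
                                 beta_shrub = 0.978,
                                 beta_herb = 0.952,
                                 depth_cm = 30) {
  for (p in c(fine_fraction_herb, fine_fraction_woody, beta_tree, beta_shrub,
              beta_herb)) {
    if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
      stop("fractions and beta coefficients must be single numbers in (0, 1)",
           call. = FALSE)
  }
  if (depth_cm < 0) stop("`depth_cm` must be non-negative", call. = FALSE)
  structure(
    list(fine_fraction_herb = fine_fraction_herb,
         fine_fraction_woody = fine_fraction_woody,
         beta_tree = beta_tree, beta_shrub = beta_shrub, beta_herb = beta_herb,
         beta_woody = (beta_tree + beta_shrub) / 2, depth_cm = depth_cm),
    class = "root_fraction_params"
  )
}

#' Cumulative root fraction down to a soil depth
#'
#' The asymptotic vertical root-distribution model `y = 1 - beta^d`, where `y`
#' is the cumulative fraction of root mass between the soil surface and depth
#' `d` (cm) and `beta` is a fitted extinction coefficient. With the default
#' growth-form coefficients, 54.6% of woody and 77.1% of herbaceous live root
#' mass lies in the top 30 cm.
#'
#' @param beta Extinction coefficient in (0, 1) (vectorized).
#' @param depth_cm Depth in cm, `>= 0` (vectorized).
#' @return Cumulative root fraction in `[0, 1]`.
#' @examples
#' depth_fraction(0.974, 30)  # woody vegetation, top 30 cm
#' @export
depth_fraction <- function(beta, depth_cm) {
  if (any(beta <= 0 | beta >= 1))
    stop("`beta` must lie strictly between 0 and 1", call. = FALSE)
  if (any(depth_cm < 0)) stop("`depth_cm` must be non-negative", call. = FALSE)
  1 - beta^depth_cm
}

#' Fine-root fraction from coarse/fine root mass ratios
#'
#' Coarse/fine root mass ratios are strongly right-skewed, so the central
#' ratio is taken as the back-transformed mean of log-transformed ratios (the
#' geometric mean; any log base gives the same result) and converted to the
#' fine fraction of total root mass as `1 / (1 + r)`.
#'
#' @param ratios Data frame with columns `growth_form` and
#'   `coarse_fine_ratio` (positive).
#' @param growth_form Growth form to extract, e.g. `"woody"` or
#'   `"herbaceous"`.
#' @return The fine-root fraction, a single number in (0, 1).
#' @examples
#' tab <- data.frame(growth_form = "woody", coarse_fine_ratio = c(1, 100))
#' fine_fraction_from_ratios(tab, "woody")  # geometric mean 10 -> 1/11
#' @export
fine_fraction_from_ratios <- function(ratios, growth_form) {
  r <- ratios$coarse_fine_ratio[ratios$growth_form == growth_form]
  if (length(r) == 0L)
    stop(sprintf("no coarse/fine root ratios for growth form '%s'",
                 growth_form), call. = FALSE)
  if (any(!is.finite(r) | r <= 0))
    stop("coarse/fine root ratios must be positive", call. = FALSE)
  1 / (1 + exp(mean(log(r))))
}

#' Mycorrhizal fraction of woody vegetation
#'
#' The aboveground biomass fraction maps distinguish trees and shrubs; the
#' belowground woody biomass map does not. The woody fraction of a mycorrhizal
#' type is therefore the per-pixel sum of its tree and shrub fractions.
#' Sums marginally above 1 (inconsistencies between the source maps) are
#' clipped to 1 with a warning; nodata propagates.
#'
#' @param tree_frac,shrub_frac Aligned `raster_grid`s of biomass fractions in
#'   `[0, 1]`.
#' @return A `raster_grid` of summed fractions in `[0, 1]`.
#' @export
woody_myc_fraction <- function(tree_frac, shrub_frac) {
  stop_if_grid_mismatch(tree_frac, shrub_frac, "tree and shrub fraction rasters")
  s <- tree_frac$values + shrub_frac$values
  over <- !is.na(s) & s > 1
  if (any(over)) {
    warning(sprintf("%d pixels with tree + shrub fraction > 1 clipped to 1 (max %.4f)",
                    sum(over), max(s[over])), call. = FALSE)
    s[over] <- 1
  }
  raster_grid(s, xll = tree_frac$xll, yll = tree_frac$yll,
              cellsize = tree_frac$cellsize, crs = tree_frac$crs,
              nodata = tree_frac$nodata)
}

#' Fine-root carbon stock in the top of the soil profile
#'
#' Scales a total belowground biomass carbon density raster (MgC ha^-1) to
#' the fine-root carbon stock within the depth of interest:
#' `stock = total * fine_fraction * depth_fraction`.
#'
#' @param total_bgb `raster_grid` of belowground biomass C density
#'   (MgC ha^-1).
#' @param fine_fraction Fine-root fraction of total root biomass, in
#'   `[0, 1]`.
#' @param depth_frac Cumulative root fraction within the depth of interest,
#'   in `[0, 1]` (see [depth_fraction()]).
#' @return A `raster_grid` in MgC ha^-1; nodata propagates.
#' @export
fine_root_stock <- function(total_bgb, fine_fraction, depth_frac) {
  if (fine_fraction < 0 || fine_fraction > 1 || depth_frac < 0 || depth_frac > 1)
    stop("`fine_fraction` and `depth_frac` must lie in [0, 1]", call. = FALSE)
  raster_grid(total_bgb$values * fine_fraction * depth_frac,
              xll = total_bgb$xll, yll = total_bgb$yll,
              cellsize = total_bgb$cellsize, crs = total_bgb$crs,
              nodata = total_bgb$nodata)
}

#' Fine-root stock attributable to one mycorrhizal type
#'
#' Per-pixel product of a fine-root carbon stock raster and the biomass
#' fraction of the mycorrhizal type (AM or EcM). On tundra units the
#' growth-form-free fraction rasters are supplied instead of the woody or
#' herbaceous ones; the arithmetic is identical.
#'
#' @param fine_root `raster_grid` of fine-root C stock (MgC ha^-1).
#' @param myc_fraction Aligned `raster_grid` of type fractions in `[0, 1]`.
#' @return A `raster_grid` in MgC ha^-1; nodata propagates.
#' @export
myc_root_stock <- function(fine_root, myc_fraction) {
  stop_if_grid_mismatch(fine_root, myc_fraction,
                        "stock and fraction rasters")
  raster_grid(fine_root$values * myc_fraction$values,
              xll = fine_root$xll, yll = fine_root$yll,
              cellsize = fine_root$cellsize, crs = fine_root$crs,
              nodata = fine_root$nodata)
}
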