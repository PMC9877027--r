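#' Configuration of a synthetic mycorrhizal world
#'
#' Describes a complete synthetic input world: categorical layers (ecoregion,
#' land cover, continent) on a coarse grid, finer-resolution belowground
#' biomass layers, mycorrhizal biomass-fraction layers, a species pool with
#' growth forms and mycorrhizal types, colonization records and vegetation
#' plots — all with known ground truth, so the whole pipeline is testable
#' without external downloads.
#'
#' The layout places ecoregions in horizontal bands, continents in vertical
#' bands, and land-cover classes in strips inside each ecoregion x continent
#' block, so unit footprints are contiguous. Class `excluded_landcover[1]`
#' plays the role of water: it is excluded from units and its pixels carry
#' nodata in every biomass layer, exercising masking throughout.
#'
#' Species true colonization means are drawn from a low and a high band that
#' bracket the unit target intensities. This allows plot compositions to be
#' solved in closed form so that each plot's community-weighted mean equals
#' its unit's true intensity exactly; record noise then perturbs species
#' means without ever pushing them near the [0, 100] clamp (which would bias
#' recovered means).
#'
#' @param grid_shape Coarse grid rows x cols (10 arc-minute cells).
#' @param fine_factor Integer ratio of coarse to fine cell size for the
#'   biomass and categorical source layers.
#' @param n_ecoregions,n_landcover_classes,n_continents Numbers of categorical
#'   codes (codes are `1:n`).
#' @param excluded_landcover Land-cover codes excluded from units; the first
#'   is treated as water (nodata in biomass layers). Must not cover all
#'   classes.
#' @param tundra_ecoregions Ecoregion codes routed through the tundra
#'   workflow; default: the last ecoregion.
#' @param landcover_per_block Land-cover strips per ecoregion x continent
#'   block (controls how many units arise).
#' @param species_pool_size Approximate total species count.
#' @param fraction_woody Proportion of woody species.
#' @param fraction_dual_type Proportion of dual-colonized species.
#' @param fraction_unknown_type Proportion of species whose genus has no
#'   mycorrhizal-type assignment (excluded by the pipeline).
#' @param fraction_no_records Proportion of typed species without any
#'   colonization record (they dilute plot coverage below 100%).
#' @param plots_per_unit Plots per observed unit (single count, or
#'   `c(min, max)` for a uniform draw per unit).
#' @param fraction_empty_units Proportion of units left without plots (to be
#'   gap-filled downstream).
#' @param fraction_plots_on_nodata Extra plots dropped on water pixels, as a
#'   proportion of regular plots (exercises the drop rule).
#' @param obs_per_species Colonization observations per species and
#'   measurement kind (single count or `c(min, max)`).
#' @param intensity_noise_sd Standard deviation, in percentage points, of the
#'   record noise around species true means.
#' @param categorical_fraction Proportion of records expressed as categorical
#'   class labels instead of percentages.
#' @param categorical_bounds Increasing class boundaries partitioning
#'   `[0, 100]` for categorical labels.
#' @param flagged_fraction Proportion of recorded species that additionally
#'   get one non-natural and one out-of-season record with shifted values
#'   (must be removed by filtering).
#' @param bgb_noise_cv Coefficient of variation of fine-pixel biomass noise
#'   within a coarse cell (noise is centered per block, so block means are
#'   exact).
#' @param intensity_range Range from which unit true intensities are drawn
#'   (percent).
#' @param species_band_low,species_band_high Ranges of species true mean
#'   colonization for the low and high bands (percent); both must bracket
#'   `intensity_range`.
#' @param true_intensity Optional tibble overriding drawn intensities, with
#'   columns `ecoregion`, `landcover`, `continent`, `myc_type`,
#'   `growth_form`, `intensity`.
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical worlds.
#' @return A validated list of class `world_config`.
#' @export
world_config <- function(grid_shape = c(60, 60),
                         fine_factor = 3,
                         n_ecoregions = 4,
                         n_landcover_classes = 6,
                         excluded_landcover = 1L,
                         n_continents = 2,
                         tundra_ecoregions = NULL,
                         landcover_per_block = 3,
                         species_pool_size = 80,
                         fraction_woody = 0.5,
                         fraction_dual_type = 0.10,
                         fraction_unknown_type = 0.05,
                         fraction_no_records = 0.10,
                         plots_per_unit = 5,
                         fraction_empty_units = 0.15,
                         fraction_plots_on_nodata = 0.05,
                         obs_per_species = 6,
                         intensity_noise_sd = 5,
                         categorical_fraction = 0.15,
                         categorical_bounds = c(0, 25, 50, 75, 100),
                         flagged_fraction = 0.2,
                         bgb_noise_cv = 0.05,
                         intensity_range = c(40, 60),
                         species_band_low = c(20, 35),
                         species_band_high = c(65, 80),
                         true_intensity = NULL,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$tundra_ecoregions)) cfg$tundra_ecoregions <- n_ecoregions
  with(cfg, {
    stopifnot(length(grid_shape) == 2, all(grid_shape >= 4),
              fine_factor >= 1, fine_factor == round(fine_factor),
              n_ecoregions >= 1, n_landcover_classes >= 2, n_continents >= 1)
    for (p in c(fraction_woody, fraction_dual_type, fraction_unknown_type,
                fraction_no_records, fraction_empty_units,
                fraction_plots_on_nodata, categorical_fraction,
                flagged_fraction)) {
      if (p < 0 || p > 1)
        stop("proportions must lie in [0, 1]", call. = FALSE)
    }
    if (length(setdiff(seq_len(n_landcover_classes), excluded_landcover)) == 0)
      stop("excluded land-cover classes cover all classes: no units possible",
           call. = FALSE)
    if (any(intensity_range < 0 | intensity_range > 100))
      stop("intensities must lie in [0, 100]", call. = FALSE)
    if (max(species_band_low) >= min(intensity_range) ||
        max(intensity_range) >= min(species_band_high))
      stop("species mean bands must bracket the intensity range",
           call. = FALSE)
    if (any(plots_per_unit < 1) || any(obs_per_species < 1))
      stop("counts must be >= 1", call. = FALSE)
  })
  structure(cfg, class = "world_config")
}

draw_count <- function(spec, n = 1L) {
  if (length(spec) == 1L) rep(as.integer(spec), n)
  else sample(seq(spec[1], spec[2]), n, replace = TRUE)
}

#' Express a subset of colonization records in categorical levels
#'
#' Mimics sources that report colonization as categorical classes: a random
#' subset of numeric records is relabelled with the class (`"class1"`,
#' `"class2"`, ...) containing its value under `class_bounds`, and the
#' label-to-class-midpoint mapping is returned so the conversion can be
#' round-tripped downstream. Classes are half-open on the right except the
#' last; a value of 0 falls in the lowest class.
#'
#' @param records Records with a numeric `value` column.
#' @param class_bounds Strictly increasing boundaries partitioning
#'   `[0, 100]` (so overlapping classes are impossible by construction).
#' @param fraction Proportion of records to relabel.
#' @return A list with `records` (the `value` column now character, a mix of
#'   numbers and labels) and `mapping` (tibble `label`, `percent` of class
#'   midpoints). With `fraction = 0` or fewer than two bounds, records are
#'   returned unchanged with an empty mapping.
#' @export
generate_categorical_colonization <- function(records, class_bounds,
                                              fraction = 0.15) {
  if (length(class_bounds) >= 2 && any(diff(class_bounds) <= 0))
    stop("`class_bounds` must be strictly increasing (non-overlapping classes)",
         call. = FALSE)
  n_class <- length(class_bounds) - 1L
  if (n_class < 1L || fraction <= 0 || nrow(records) == 0L) {
    return(list(records = records,
                mapping = tibble::tibble(label = character(),
                                         percent = numeric())))
  }
  mapping <- tibble::tibble(
    label = paste0("class", seq_len(n_class)),
    percent = (utils::head(class_bounds, -1L) + utils::tail(class_bounds, -1L)) / 2)
  idx <- sample(nrow(records), size = round(fraction * nrow(records)))
  cls <- findInterval(records$value[idx], class_bounds,
                      rightmost.closed = TRUE)
  cls <- pmin(pmax(cls, 1L), n_class)
  value <- as.character(records$value)
  value[idx] <- mapping$label[cls]
  records$value <- value
  list(records = records, mapping = mapping)
}

# solve pair weights so the pool community-weighted mean equals the target
pair_weight <- function(m_low, m_high, target) (m_high - target) / (m_high - m_low)

#' Generate a synthetic world with known ground truth
#'
#' Emits every input the mapping workflow consumes — categorical layers and
#' belowground biomass carbon layers at fine resolution, mycorrhizal
#' biomass-fraction layers at coarse resolution, colonization records,
#' vegetation plots and trait tables — together with a ground-truth object
#' holding the per-unit stocks, fractions and colonization intensities the
#' pipeline should recover. Plot compositions are solved so that, with zero
#' record noise, every plot's community-weighted intensity equals its unit's
#' true intensity exactly.
#'
#' @param config A [world_config()].
#' @return A list of class `synthetic_world` with elements `rasters` (named
#'   `raster_grid`s: `ecoregion`, `landcover`, `continent` and `bgb_*` at
#'   fine resolution; `frac_*` at coarse resolution), `tables` (tibbles:
#'   `records`, `plots`, `growth_forms`, `genus_types`, `ratios`),
#'   `categorical_mapping`, `truth` (list: `units`, `species`) and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  f <- config$fine_factor
  water <- config$excluded_landcover[1]

  ## --- categorical design on the coarse grid -------------------------------
  eco_band <- as.integer(cut(seq_len(nr), breaks = config$n_ecoregions,
                             labels = FALSE))
  con_band <- as.integer(cut(seq_len(nc), breaks = config$n_continents,
                             labels = FALSE))
  eco <- matrix(eco_band, nr, nc)
  con <- matrix(con_band, nr, nc, byrow = TRUE)
  lc <- matrix(NA_integer_, nr, nc)
  for (e in seq_len(config$n_ecoregions)) {
    for (k in seq_len(config$n_continents)) {
      rows <- which(eco_band == e); cols <- which(con_band == k)
      n_strip <- min(config$landcover_per_block, length(cols))
      codes <- sample(config$n_landcover_classes, n_strip)
      strip <- as.integer(cut(seq_along(cols), breaks = n_strip,
                              labels = FALSE))
      lc[rows, cols] <- matrix(codes[strip], length(rows), length(cols),
                               byrow = TRUE)
    }
  }
  # guarantee at least one water patch so nodata masking is always exercised
  lc[1:2, 1:2] <- water

  retained <- !(lc %in% config$excluded_landcover)
  dim(retained) <- dim(lc)

  ## --- unit table (same ordering rule as build_unit_map) -------------------
  units <- tibble::tibble(ecoregion = eco[retained], landcover = lc[retained],
                          continent = con[retained]) |>
    dplyr::count(.data$ecoregion, .data$landcover, .data$continent,
                 name = "n_pixels") |>
    dplyr::arrange(.data$ecoregion, .data$landcover, .data$continent) |>
    dplyr::mutate(unit_id = dplyr::row_number(),
                  is_tundra = .data$ecoregion %in% config$tundra_ecoregions)
  n_units <- nrow(units)
  unit_of_pixel <- matrix(NA_integer_, nr, nc)
  unit_of_pixel[retained] <- units$unit_id[match(
    paste(eco[retained], lc[retained], con[retained]),
    paste(units$ecoregion, units$landcover, units$continent))]

  ## --- per-unit truth: biomass, fractions, intensities ---------------------
  units <- units |>
    dplyr::mutate(
      bgb_woody = ifelse(.data$is_tundra, NA, stats::runif(n_units, 2, 20)),
      bgb_herb = ifelse(.data$is_tundra, NA, stats::runif(n_units, 1, 10)),
      bgb_tundra = ifelse(.data$is_tundra, stats::runif(n_units, 1, 8), NA))
  fr <- matrix(stats::runif(n_units * 6), n_units, 6)
  fr <- fr / rowSums(fr) * stats::runif(n_units, 0.6, 0.95)
  colnames(fr) <- c("am_tree", "ecm_tree", "am_shrub", "ecm_shrub",
                    "am_herb", "ecm_herb")
  fr_all <- matrix(stats::runif(n_units * 2), n_units, 2)
  fr_all <- fr_all / rowSums(fr_all) * stats::runif(n_units, 0.6, 0.95)
  colnames(fr_all) <- c("am_all", "ecm_all")
  units <- dplyr::bind_cols(units, tibble::as_tibble(fr),
                            tibble::as_tibble(fr_all))

  pools_regular <- tidyr::crossing(myc_type = c("AM", "EcM"),
                                   growth_form = c("woody", "herbaceous"))
  pools_tundra <- tidyr::crossing(myc_type = c("AM", "EcM"),
                                  growth_form = "tundra_all")
  intensities <- dplyr::bind_rows(
    tidyr::crossing(dplyr::filter(units, !.data$is_tundra)["unit_id"],
                    pools_regular),
    tidyr::crossing(dplyr::filter(units, .data$is_tundra)["unit_id"],
                    pools_tundra)) |>
    dplyr::arrange(.data$unit_id, .data$myc_type, .data$growth_form) |>
    dplyr::mutate(intensity = stats::runif(dplyr::n(),
                                           config$intensity_range[1],
                                           config$intensity_range[2]))
  if (!is.null(config$true_intensity)) {
    override <- config$true_intensity |>
      dplyr::left_join(dplyr::select(units, "unit_id", "ecoregion",
                                     "landcover", "continent"),
                       by = c("ecoregion", "landcover", "continent")) |>
      dplyr::select("unit_id", "myc_type", "growth_form",
                    override = "intensity")
    intensities <- intensities |>
      dplyr::left_join(override, by = c("unit_id", "myc_type", "growth_form")) |>
      dplyr::mutate(intensity = dplyr::coalesce(.data$override,
                                                .data$intensity)) |>
      dplyr::select(-"override")
  }

  ## --- species pool --------------------------------------------------------
  species <- build_species_pool(config)

  ## --- colonization records ------------------------------------------------
  rec <- generate_records(species, config)
  records <- rec$records
  categorical_mapping <- rec$mapping

  ## --- plots ----------------------------------------------------------------
  empty_ids <- sort(sample(units$unit_id,
                           size = round(config$fraction_empty_units * n_units)))
  units$observed <- !(units$unit_id %in% empty_ids)
  plots <- generate_plots(units, intensities, species, unit_of_pixel,
                          lc, water, config)

  ## --- rasters --------------------------------------------------------------
  cs_fine <- (1 / 6) / f
  expand <- function(m) m[rep(seq_len(nr), each = f), rep(seq_len(nc), each = f)]
  fine_cat <- function(m) raster_grid(expand(m), cellsize = cs_fine)

  unit_value_matrix <- function(col) {
    v <- matrix(NA_real_, nr, nc)
    idx <- !is.na(unit_of_pixel)
    v[idx] <- units[[col]][unit_of_pixel[idx]]
    v
  }
  fine_bgb <- function(col) {
    v <- expand(unit_value_matrix(col))
    noise <- stats::rnorm(length(v), sd = config$bgb_noise_cv)
    dim(noise) <- dim(v)
    # center the noise within each coarse block so block means stay exact
    ir <- block_index(nrow(v), f); ic <- block_index(ncol(v), f)
    bm <- rowsum(noise, ir) / f
    bm <- t(rowsum(t(bm), ic)) / f
    noise <- noise - bm[cbind(rep(ir, ncol(v)),
                              rep(ic, each = nrow(v)))]
    out <- v * (1 + noise)
    out[expand(matrix(lc == water, nr, nc))] <- NA_real_
    raster_grid(out, cellsize = cs_fine)
  }
  coarse_frac <- function(col) raster_grid(unit_value_matrix(col))

  rasters <- list(
    ecoregion = fine_cat(eco), landcover = fine_cat(lc),
    continent = fine_cat(con),
    bgb_woody = fine_bgb("bgb_woody"), bgb_herb = fine_bgb("bgb_herb"),
    bgb_tundra = fine_bgb("bgb_tundra"),
    frac_am_tree = coarse_frac("am_tree"), frac_ecm_tree = coarse_frac("ecm_tree"),
    frac_am_shrub = coarse_frac("am_shrub"), frac_ecm_shrub = coarse_frac("ecm_shrub"),
    frac_am_herb = coarse_frac("am_herb"), frac_ecm_herb = coarse_frac("ecm_herb"),
    frac_am_all = coarse_frac("am_all"), frac_ecm_all = coarse_frac("ecm_all"))

  ## --- ground truth ---------------------------------------------------------
  params <- root_fraction_params()
  depth_woody <- depth_fraction(params$beta_woody, params$depth_cm)
  depth_herb <- depth_fraction(params$beta_herb, params$depth_cm)
  truth_units <- units |>
    dplyr::mutate(
      fine_root_woody = .data$bgb_woody * params$fine_fraction_woody * depth_woody,
      fine_root_herb = .data$bgb_herb * params$fine_fraction_herb * depth_herb,
      fine_root_tundra = .data$bgb_tundra * params$fine_fraction_herb * depth_herb,
      am_woody = .data$am_tree + .data$am_shrub,
      ecm_woody = .data$ecm_tree + .data$ecm_shrub)
  truth_pools <- intensities |>
    dplyr::left_join(truth_units, by = "unit_id") |>
    dplyr::mutate(
      stock = dplyr::case_when(
        .data$growth_form == "woody" & .data$myc_type == "AM" ~
          .data$fine_root_woody * .data$am_woody,
        .data$growth_form == "woody" & .data$myc_type == "EcM" ~
          .data$fine_root_woody * .data$ecm_woody,
        .data$growth_form == "herbaceous" & .data$myc_type == "AM" ~
          .data$fine_root_herb * .data$am_herb,
        .data$growth_form == "herbaceous" & .data$myc_type == "EcM" ~
          .data$fine_root_herb * .data$ecm_herb,
        .data$growth_form == "tundra_all" & .data$myc_type == "AM" ~
          .data$fine_root_tundra * .data$am_all,
        .data$growth_form == "tundra_all" & .data$myc_type == "EcM" ~
          .data$fine_root_tundra * .data$ecm_all),
      colonized = .data$stock * .data$intensity / 100) |>
    dplyr::select("unit_id", "myc_type", "growth_form", "intensity",
                  "stock", "colonized")
  truth_totals <- truth_pools |>
    dplyr::summarise(colonized_total = sum(.data$colonized),
                     .by = c("unit_id", "myc_type"))

  ## --- coarse/fine root mass ratio table -----------------------------------
  ratios <- dplyr::bind_rows(
    tibble::tibble(growth_form = "woody",
                   coarse_fine_ratio = stats::rlnorm(
                     30, log(1 / params$fine_fraction_woody - 1), 0.5)),
    tibble::tibble(growth_form = "herbaceous",
                   coarse_fine_ratio = stats::rlnorm(
                     30, log(1 / params$fine_fraction_herb - 1), 0.5)))

  structure(
    list(rasters = rasters,
         tables = list(records = records, plots = plots,
                       growth_forms = species$growth_forms,
                       genus_types = species$genus_types,
                       ratios = ratios),
         categorical_mapping = categorical_mapping,
         truth = list(units = truth_units, pools = truth_pools,
                      totals = truth_totals, species = species$truth),
         config = config),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d coarse grid, %d units (%d observed), %d species, %d plots, %d records\n",
              x$config$grid_shape[1], x$config$grid_shape[2],
              nrow(x$truth$units), sum(x$truth$units$observed),
              nrow(x$truth$species |> dplyr::distinct(.data$species)),
              dplyr::n_distinct(x$tables$plots$plot_id),
              nrow(x$tables$records)))
  invisible(x)
}

# Species pool with stratified true means: for every mycorrhizal type x
# growth form, both a low and a high band of species means exist, so any
# target intensity between the bands can be hit by a two-species mixture.
build_species_pool <- function(config) {
  size <- config$species_pool_size
  n_dual <- round(config$fraction_dual_type * size)
  n_unknown <- round(config$fraction_unknown_type * size)
  n_norec <- round(config$fraction_no_records * size)
  n_single <- size - n_dual - n_unknown - n_norec
  n_woody <- round(n_single * config$fraction_woody)
  n_herb <- n_single - n_woody
  if (n_woody < 4 || n_herb < 4)
    stop("species_pool_size too small for the required type/form/band strata",
         call. = FALSE)

  form_strata <- function(form, n_form) {
    strata <- tidyr::crossing(myc_type = c("AM", "EcM"),
                              band = c("low", "high"))
    base <- n_form %/% nrow(strata)
    extra <- n_form %% nrow(strata)
    strata$n <- base + c(rep(1L, extra), rep(0L, nrow(strata) - extra))
    dplyr::mutate(strata, growth_form = form)
  }
  singles <- dplyr::bind_rows(form_strata("woody", n_woody),
                              form_strata("herbaceous", n_herb)) |>
    tidyr::uncount(.data$n) |>
    dplyr::mutate(role = "single")
  duals <- tibble::tibble(
    myc_type = "dual",
    growth_form = rep(c("woody", "herbaceous"), length.out = n_dual),
    band = "low", role = "dual")
  unknowns <- tibble::tibble(
    myc_type = "unknown",
    growth_form = rep(c("woody", "herbaceous"), length.out = n_unknown),
    band = NA_character_, role = "unknown")
  norecs <- tibble::tibble(
    myc_type = rep(c("AM", "EcM"), length.out = n_norec),
    growth_form = rep(c("woody", "herbaceous", "woody", "herbaceous"),
                      length.out = n_norec),
    band = NA_character_, role = "no_records")

  pool <- dplyr::bind_rows(singles, duals, unknowns, norecs) |>
    dplyr::mutate(species_id = dplyr::row_number(),
                  genus = sprintf("Genus%03d", .data$species_id),
                  species = paste0(.data$genus, " sylvestris"))

  draw_band <- function(band, n) {
    lo <- ifelse(band == "low", config$species_band_low[1],
                 config$species_band_high[1])
    hi <- ifelse(band == "low", config$species_band_low[2],
                 config$species_band_high[2])
    stats::runif(n, lo, hi)
  }
  pool$am_mean <- NA_real_
  pool$ecm_mean <- NA_real_
  is_am <- pool$myc_type == "AM" & pool$role == "single"
  is_ecm <- pool$myc_type == "EcM" & pool$role == "single"
  is_dual <- pool$role == "dual"
  pool$am_mean[is_am] <- draw_band(pool$band[is_am], sum(is_am))
  pool$ecm_mean[is_ecm] <- draw_band(pool$band[is_ecm], sum(is_ecm))
  # dual species carry both measurement kinds; keep both in the low band so a
  # high-band single partner always brackets the target
  pool$am_mean[is_dual] <- draw_band("low", sum(is_dual))
  pool$ecm_mean[is_dual] <- draw_band("low", sum(is_dual))

  growth_forms <- dplyr::select(pool, "species", "growth_form")
  genus_types <- pool |>
    dplyr::filter(.data$role != "unknown") |>
    dplyr::mutate(myc_type = dplyr::case_when(
      .data$role == "dual" ~ "dual",
      .data$myc_type == "AM" &
        (.data$species_id %% 5 == 0) ~ "facultative_am",
      .data$myc_type == "AM" ~ "am",
      TRUE ~ "ecm")) |>
    dplyr::select("genus", "myc_type")
  truth <- pool |>
    tidyr::pivot_longer(c("am_mean", "ecm_mean"), names_to = "kind",
                        values_to = "true_mean") |>
    dplyr::filter(!is.na(.data$true_mean)) |>
    dplyr::mutate(myc_kind = ifelse(.data$kind == "am_mean", "AM", "EcM")) |>
    dplyr::select("species", myc_type = "myc_kind", "true_mean")

  list(pool = pool, growth_forms = growth_forms, genus_types = genus_types,
       truth = truth)
}

generate_records <- function(species, config) {
  pool <- species$pool
  has_rec <- pool$role %in% c("single", "dual")
  kinds <- dplyr::bind_rows(
    tibble::tibble(species = pool$species[has_rec & !is.na(pool$am_mean)],
                   myc_type = "AM",
                   true_mean = pool$am_mean[has_rec & !is.na(pool$am_mean)]),
    tibble::tibble(species = pool$species[has_rec & !is.na(pool$ecm_mean)],
                   myc_type = "EcM",
                   true_mean = pool$ecm_mean[has_rec & !is.na(pool$ecm_mean)]))
  n_obs <- draw_count(config$obs_per_species, nrow(kinds))
  records <- kinds[rep(seq_len(nrow(kinds)), n_obs), ] |>
    dplyr::mutate(
      value = pmin(pmax(.data$true_mean +
                          stats::rnorm(dplyr::n(), 0, config$intensity_noise_sd),
                        0), 100),
      naturalness = sample(c("natural", "unknown"), dplyr::n(),
                           replace = TRUE),
      season = sample(c("growing", "unknown"), dplyr::n(), replace = TRUE)) |>
    dplyr::select(-"true_mean")
  # contaminated records that the filter must remove: shifted values under
  # non-natural conditions or outside the growing season
  flagged_sp <- kinds[sample(nrow(kinds),
                             round(config$flagged_fraction * nrow(kinds))), ]
  if (nrow(flagged_sp) > 0) {
    contaminated <- dplyr::bind_rows(
      dplyr::mutate(flagged_sp, value = pmin(.data$true_mean + 30, 100),
                    naturalness = "non_natural", season = "growing"),
      dplyr::mutate(flagged_sp, value = pmax(.data$true_mean - 30, 0),
                    naturalness = "natural", season = "non_growing")) |>
      dplyr::select(-"true_mean")
    records <- dplyr::bind_rows(records, contaminated)
  }
  records <- records[sample(nrow(records)), ]
  cat_out <- generate_categorical_colonization(records,
                                               config$categorical_bounds,
                                               config$categorical_fraction)
  records <- cat_out$records
  records$value <- as.character(records$value)
  list(records = tibble::as_tibble(records), mapping = cat_out$mapping)
}

# For one plot and pool, return species + raw abundances whose renormalized
# community-weighted mean of true species means equals `target` exactly.
pool_members <- function(pool, myc, form, band, target, mean_col) {
  cand_low <- pool[pool$role == "single" & pool$myc_type == myc &
                     pool$growth_form == form & pool$band == "low", ]
  cand_high <- pool[pool$role == "single" & pool$myc_type == myc &
                      pool$growth_form == form & pool$band == "high", ]
  lo <- cand_low[sample(nrow(cand_low), 1L), ]
  hi <- cand_high[sample(nrow(cand_high), 1L), ]
  w <- pair_weight(lo[[mean_col]], hi[[mean_col]], target)
  tibble::tibble(species = c(lo$species, hi$species),
                 rel_abundance = c(w, 1 - w))
}

generate_plots <- function(units, intensities, species, unit_of_pixel,
                           lc, water, config) {
  pool <- species$pool
  norec <- pool[pool$role == "no_records", ]
  unknown <- pool[pool$role == "unknown", ]
  duals <- pool[pool$role == "dual", ]
  target_of <- function(uid, myc, form) {
    intensities$intensity[intensities$unit_id == uid &
                            intensities$myc_type == myc &
                            intensities$growth_form == form]
  }

  plot_rows <- list()
  plot_meta <- list()
  plot_n <- 0L
  obs_units <- units[units$observed, ]
  n_plots <- draw_count(config$plots_per_unit, nrow(obs_units))

  compose_form <- function(uid, form, t_am, t_ecm) {
    use_dual <- nrow(duals[duals$growth_form == form, ]) > 0 &&
      stats::runif(1) < 0.5
    if (use_dual) {
      d <- duals[duals$growth_form == form, ]
      d <- d[sample(nrow(d), 1L), ]
      hi_am <- pool[pool$role == "single" & pool$myc_type == "AM" &
                      pool$growth_form == form & pool$band == "high", ]
      hi_ecm <- pool[pool$role == "single" & pool$myc_type == "EcM" &
                       pool$growth_form == form & pool$band == "high", ]
      a <- hi_am[sample(nrow(hi_am), 1L), ]
      e <- hi_ecm[sample(nrow(hi_ecm), 1L), ]
      # dual raw abundance 1 splits half into each type pool; partners solve
      # each pool's weighted mean to its target
      ab_a <- 0.5 * (t_am - d$am_mean) / (a$am_mean - t_am)
      ab_e <- 0.5 * (t_ecm - d$ecm_mean) / (e$ecm_mean - t_ecm)
      tibble::tibble(species = c(d$species, a$species, e$species),
                     rel_abundance = c(1, ab_a, ab_e))
    } else {
      scale_am <- stats::runif(1, 0.5, 1.5)
      scale_ecm <- stats::runif(1, 0.5, 1.5)
      dplyr::bind_rows(
        dplyr::mutate(pool_members(pool, "AM", form, NULL, t_am, "am_mean"),
                      rel_abundance = .data$rel_abundance * scale_am),
        dplyr::mutate(pool_members(pool, "EcM", form, NULL, t_ecm, "ecm_mean"),
                      rel_abundance = .data$rel_abundance * scale_ecm))
    }
  }

  for (i in seq_len(nrow(obs_units))) {
    u <- obs_units[i, ]
    cells <- which(unit_of_pixel == u$unit_id, arr.ind = TRUE)
    for (p in seq_len(n_plots[i])) {
      plot_n <- plot_n + 1L
      pid <- sprintf("plot%05d", plot_n)
      if (u$is_tundra) {
        comp <- dplyr::bind_rows(
          lapply(c("AM", "EcM"), function(myc) {
            t <- target_of(u$unit_id, myc, "tundra_all")
            form <- sample(c("woody", "herbaceous"), 1L)
            mean_col <- if (myc == "AM") "am_mean" else "ecm_mean"
            dplyr::mutate(pool_members(pool, myc, form, NULL, t, mean_col),
                          rel_abundance = .data$rel_abundance *
                            stats::runif(1, 0.5, 1.5))
          }))
      } else {
        comp <- dplyr::bind_rows(
          compose_form(u$unit_id, "woody",
                       target_of(u$unit_id, "AM", "woody"),
                       target_of(u$unit_id, "EcM", "woody")),
          compose_form(u$unit_id, "herbaceous",
                       target_of(u$unit_id, "AM", "herbaceous"),
                       target_of(u$unit_id, "EcM", "herbaceous")))
      }
      # uncovered and untyped filler species: dilute coverage, never intensity
      if (nrow(norec) > 0 && stats::runif(1) < 0.7) {
        s <- norec[sample(nrow(norec), 1L), ]
        comp <- dplyr::bind_rows(comp,
          tibble::tibble(species = s$species,
                         rel_abundance = stats::runif(1, 0.02, 0.10)))
      }
      if (nrow(unknown) > 0 && stats::runif(1) < 0.3) {
        s <- unknown[sample(nrow(unknown), 1L), ]
        comp <- dplyr::bind_rows(comp,
          tibble::tibble(species = s$species,
                         rel_abundance = stats::runif(1, 0.02, 0.10)))
      }
      comp$rel_abundance <- comp$rel_abundance / sum(comp$rel_abundance)
      cell <- cells[sample(nrow(cells), 1L), , drop = FALSE]
      plot_rows[[plot_n]] <- dplyr::mutate(comp, plot_id = pid)
      plot_meta[[plot_n]] <- tibble::tibble(
        plot_id = pid,
        lon = (as.numeric(cell[1, "col"]) - stats::runif(1)) * (1 / 6),
        lat = (nrow(unit_of_pixel) - as.numeric(cell[1, "row"]) +
                 stats::runif(1)) * (1 / 6))
    }
  }

  plots <- dplyr::bind_rows(plot_rows) |>
    dplyr::left_join(dplyr::bind_rows(plot_meta), by = "plot_id") |>
    dplyr::select("plot_id", "lon", "lat", "species", "rel_abundance")

  # plots dropped on water pixels: copies of real compositions at nodata spots
  n_water_plots <- round(config$fraction_plots_on_nodata * plot_n)
  water_cells <- which(lc == water, arr.ind = TRUE)
  if (n_water_plots > 0 && nrow(water_cells) > 0 && plot_n > 0) {
    for (q in seq_len(n_water_plots)) {
      src <- sprintf("plot%05d", sample(plot_n, 1L))
      cell <- water_cells[sample(nrow(water_cells), 1L), , drop = FALSE]
      wp <- plots[plots$plot_id == src, ] |>
        dplyr::mutate(plot_id = sprintf("waterplot%04d", q),
                      lon = (as.numeric(cell[1, "col"]) - stats::runif(1)) * (1 / 6),
                      lat = (nrow(unit_of_pixel) - as.numeric(cell[1, "row"]) +
                               stats::runif(1)) * (1 / 6))
      plots <- dplyr::bind_rows(plots, wp)
    }
  }
  plots
}
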