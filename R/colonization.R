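#' Filter colonization records to natural, growing-season conditions
#'
#' Colonization intensity is treated as a species trait measured under natural
#' growth conditions, so records from non-natural settings (plantations,
#' nurseries, greenhouses, pots) and records collected outside the growing
#' season are dropped. Records whose naturalness or season is unknown are
#' kept: intensities are generally reported from growing-season surveys of
#' natural habitats.
#'
#' @param records Data frame with columns `species`, `value`, `myc_type`,
#'   `naturalness` (`"natural"`, `"non_natural"` or `"unknown"`) and `season`
#'   (`"growing"`, `"non_growing"` or `"unknown"`).
#' @return The filtered tibble; the number of dropped records is reported via
#'   a message.
#' @export
filter_records <- function(records) {
  out <- dplyr::filter(records,
                       .data$naturalness != "non_natural",
                       .data$season != "non_growing")
  dropped <- nrow(records) - nrow(out)
  if (dropped > 0)
    message(sprintf("filter_records: dropped %d non-natural or out-of-season records",
                    dropped))
  tibble::as_tibble(out)
}

#' Convert categorical colonization records to percentages
#'
#' Some sources report colonization in categorical levels rather than
#' percentages. This converts such labels via a user-supplied mapping (the
#' transformation stated by each original source, e.g. class midpoints);
#' numeric values pass through untouched.
#'
#' @param records Data frame whose `value` column may mix numbers and
#'   categorical labels (character).
#' @param mapping Either a named numeric vector (`label = percent`) or a data
#'   frame with columns `label` and `percent`. May be `NULL` when no
#'   categorical values are present.
#' @return The records tibble with a numeric `value` column in `[0, 100]`.
#' @export
categorical_to_percent <- function(records, mapping = NULL) {
  val <- records$value
  if (is.numeric(val)) {
    records$value <- as.numeric(val)
    return(tibble::as_tibble(records))
  }
  num <- suppressWarnings(as.numeric(val))
  is_label <- is.na(num) & !is.na(val)
  if (any(is_label)) {
    if (is.data.frame(mapping)) {
      map <- stats::setNames(mapping$percent, mapping$label)
    } else {
      map <- mapping
    }
    labels <- val[is_label]
    unknown <- setdiff(unique(labels), names(map))
    if (length(unknown) > 0)
      stop(sprintf("no percentage mapping for categorical label(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    num[is_label] <- unname(map[labels])
  }
  records$value <- num
  tibble::as_tibble(records)
}

#' Species-level mean colonization intensity
#'
#' The intensity of root colonization is treated as a species trait: the
#' arithmetic mean over all retained observations of a species, kept separate
#' per mycorrhizal type since AM (% root length) and EcM (% root tips)
#' colonization are distinct measurement kinds that are never pooled.
#'
#' @param records Filtered, numeric records (see [filter_records()] and
#'   [categorical_to_percent()]).
#' @return A tibble with columns `species`, `myc_type`, `mean_intensity`,
#'   `n_obs`.
#' @export
species_mean_colonization <- function(records) {
  if (!is.numeric(records$value))
    stop("record values must be numeric; run categorical_to_percent() first",
         call. = FALSE)
  records |>
    dplyr::mutate(species_key = normalize_species(.data$species)) |>
    dplyr::summarise(species = dplyr::first(.data$species),
                     mean_intensity = mean(.data$value),
                     n_obs = dplyr::n(),
                     .by = c("species_key", "myc_type")) |>
    dplyr::select("species", "species_key", "myc_type", "mean_intensity",
                  "n_obs")
}

normalize_species <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Assemble a species trait table
#'
#' Combines a species-to-growth-form table with a genus-to-mycorrhizal-type
#' table. The genus is the first whitespace-delimited token of the species
#' name (type assignments are genus-based). Facultative AM species are not
#' distinguished from obligate AM; species whose genus carries no assignment
#' get type `"unknown"` and are excluded downstream.
#'
#' @param growth_forms Data frame with columns `species` and `growth_form`
#'   (`"woody"`, `"herbaceous"` or `"unknown"`).
#' @param genus_types Data frame with columns `genus` and `myc_type` (labels
#'   containing `am`, `ecm`, `dual`, case-insensitive; `facultative_am` is
#'   folded into AM).
#' @return A tibble with `species`, `genus`, `growth_form`, `myc_type`
#'   (`"AM"`, `"EcM"`, `"dual"`, `"other"` or `"unknown"`).
#' @export
species_traits <- function(growth_forms, genus_types) {
  gt <- genus_types |>
    dplyr::mutate(genus_key = normalize_species(.data$genus),
                  myc_type = canonical_myc_type(.data$myc_type)) |>
    dplyr::select("genus_key", "myc_type")
  growth_forms |>
    dplyr::mutate(species_key = normalize_species(.data$species),
                  genus = sub("\\s.*$", "", .data$species),
                  genus_key = normalize_species(.data$genus)) |>
    dplyr::left_join(gt, by = "genus_key") |>
    dplyr::mutate(myc_type = dplyr::coalesce(.data$myc_type, "unknown"),
                  growth_form = dplyr::coalesce(.data$growth_form, "unknown")) |>
    dplyr::select("species", "species_key", "genus", "growth_form",
                  "myc_type")
}

canonical_myc_type <- function(x) {
  y <- tolower(trimws(x))
  dplyr::case_when(
    grepl("dual", y) | grepl("am.*ecm|ecm.*am", y) ~ "dual",
    grepl("ecm|ecto", y) ~ "EcM",
    grepl("am|arbuscular", y) ~ "AM",  # includes facultative AM
    is.na(y) | y == "" ~ "unknown",
    TRUE ~ "other"
  )
}

#' Resolve plot abundances into mycorrhizal-type pools
#'
#' Joins plot composition to species traits and splits each species'
#' relative abundance over mycorrhizal types: single-type species contribute
#' their whole abundance to their type; dual-colonized species contribute 50%
#' to AM and 50% to EcM; species that cannot be assigned to any type are
#' excluded (with a reported count). Abundance is conserved for every
#' retained species: AM share + EcM share = original abundance.
#'
#' @param plot_records Data frame with columns `plot_id`, `species`,
#'   `rel_abundance` (and optionally coordinates, which are carried through
#'   per plot elsewhere).
#' @param traits Output of [species_traits()].
#' @return A tibble with columns `plot_id`, `species`, `species_key`,
#'   `growth_form`, `myc_type` (`"AM"` or `"EcM"`), `type_abundance`.
#' @export
split_dual_abundance <- function(plot_records, traits) {
  joined <- plot_records |>
    dplyr::mutate(species_key = normalize_species(.data$species)) |>
    dplyr::left_join(dplyr::select(traits, "species_key", "growth_form",
                                   "myc_type"),
                     by = "species_key") |>
    dplyr::mutate(myc_type = dplyr::coalesce(.data$myc_type, "unknown"),
                  growth_form = dplyr::coalesce(.data$growth_form, "unknown"))
  excluded <- joined |>
    dplyr::filter(!.data$myc_type %in% c("AM", "EcM", "dual"))
  if (nrow(excluded) > 0)
    message(sprintf("split_dual_abundance: excluded %d plot records of %d species with no mycorrhizal type",
                    nrow(excluded),
                    dplyr::n_distinct(excluded$species_key)))
  kept <- dplyr::filter(joined, .data$myc_type %in% c("AM", "EcM", "dual"))
  single <- kept |>
    dplyr::filter(.data$myc_type != "dual") |>
    dplyr::mutate(type_abundance = .data$rel_abundance)
  dual <- kept |>
    dplyr::filter(.data$myc_type == "dual") |>
    tidyr::crossing(split_type = c("AM", "EcM")) |>
    dplyr::mutate(myc_type = .data$split_type,
                  type_abundance = .data$rel_abundance / 2) |>
    dplyr::select(-"split_type")
  dplyr::bind_rows(single, dual) |>
    dplyr::select("plot_id", "species", "species_key", "growth_form",
                  "myc_type", "type_abundance") |>
    dplyr::arrange(.data$plot_id, .data$myc_type, .data$species_key)
}

#' Choose the plot subset that covers the most spatial units
#'
#' Given several candidate plot subsets (e.g. alternative geographically
#' balanced resamples of a vegetation-plot database), selects the subset whose
#' plots fall in the largest number of spatial units (ties broken by input
#' order, reported via a message), then supplements it with plots from the
#' other subsets that fall in units the chosen subset leaves empty.
#'
#' @param subsets A list of plot data frames, each with columns `plot_id`,
#'   `lon`, `lat` (plus composition columns carried through).
#' @param units A `spatial_unit_map`.
#' @return The chosen subset with supplementary plots appended, as a tibble
#'   with attributes `chosen_subset` (index) and `supplemented_units`
#'   (unit ids filled from other subsets).
#' @export
select_plot_subset <- function(subsets, units) {
  if (length(subsets) == 0L || all(vapply(subsets, nrow, 0L) == 0L))
    stop("no candidate plot subsets with plots", call. = FALSE)
  covered <- lapply(subsets, function(s) {
    a <- assign_plots_to_units(s, units, quiet = TRUE)
    unique(stats::na.omit(a$unit_id))
  })
  n_cov <- lengths(covered)
  best <- which.max(n_cov)  # ties: first by input order
  if (sum(n_cov == n_cov[best]) > 1L)
    message(sprintf("select_plot_subset: tie on unit coverage (%d units); keeping subset %d (first by input order)",
                    n_cov[best], best))
  chosen <- tibble::as_tibble(subsets[[best]])
  missing_units <- setdiff(units$units$unit_id, covered[[best]])
  supplemented <- integer()
  for (j in setdiff(seq_along(subsets), best)) {
    if (length(missing_units) == 0L) break
    a <- assign_plots_to_units(subsets[[j]], units, quiet = TRUE)
    add <- a |>
      dplyr::filter(.data$unit_id %in% missing_units,
                    !.data$plot_id %in% chosen$plot_id)
    if (nrow(add) > 0L) {
      supplemented <- c(supplemented, unique(add$unit_id))
      chosen <- dplyr::bind_rows(
        chosen,
        dplyr::semi_join(tibble::as_tibble(subsets[[j]]), add, by = "plot_id"))
      missing_units <- setdiff(missing_units, add$unit_id)
    }
  }
  attr(chosen, "chosen_subset") <- best
  attr(chosen, "supplemented_units") <- sort(unique(supplemented))
  chosen
}

#' Assign vegetation plots to spatial units
#'
#' Point-in-pixel lookup of each plot's coordinates in the unit raster. Plots
#' falling outside the grid, on nodata pixels or on excluded land cover carry
#' no unit and are dropped with a reported count.
#'
#' @param plots Data frame with columns `plot_id`, `lon`, `lat`.
#' @param units A `spatial_unit_map`.
#' @param quiet Suppress the dropped-plot message.
#' @return A tibble `plot_id`, `unit_id` with one row per plot that landed in
#'   a unit.
#' @export
assign_plots_to_units <- function(plots, units, quiet = FALSE) {
  pts <- dplyr::distinct(plots, .data$plot_id, .data$lon, .data$lat)
  rc <- cell_at(units$raster, pts$lon, pts$lat)
  id <- rep(NA_integer_, nrow(pts))
  ok <- !is.na(rc$row)
  id[ok] <- units$raster$values[cbind(rc$row[ok], rc$col[ok])]
  dropped <- sum(is.na(id))
  if (dropped > 0 && !quiet)
    message(sprintf("assign_plots_to_units: dropped %d plots on nodata or excluded pixels",
                    dropped))
  tibble::tibble(plot_id = pts$plot_id, unit_id = id) |>
    dplyr::filter(!is.na(.data$unit_id))
}

#' Community-weighted colonization intensity of a vegetation plot
#'
#' For each mycorrhizal-type (by growth-form) pool of a plot, the relative
#' abundances are restricted to the species for which colonization data
#' exist, renormalized to sum to one, and used as weights on the species mean
#' intensities. The coverage of each pool is the share of pool abundance
#' carried by species with data; pools with no covered species are empty and
#' are excluded from unit averaging (not zero).
#'
#' @param split_plots Output of [split_dual_abundance()].
#' @param species_means Output of [species_mean_colonization()].
#' @param by_growth_form If `TRUE`, pools are mycorrhizal type x growth form
#'   (woody / herbaceous; species of unknown growth form are left out). If
#'   `FALSE` (the tundra path), one growth-form-free pool per type, retaining
#'   species of unknown growth form.
#' @return A tibble with one row per non-empty plot x pool:
#'   `plot_id`, `myc_type`, `growth_form` (`"tundra_all"` when
#'   `by_growth_form = FALSE`), `intensity` (%), `coverage` (%),
#'   `mean_obs_per_species`, `pool_abundance`.
#' @export
plot_weighted_intensity <- function(split_plots, species_means,
                                    by_growth_form = TRUE) {
  pools <- if (by_growth_form) {
    dplyr::filter(split_plots, .data$growth_form %in% c("woody", "herbaceous"))
  } else {
    dplyr::mutate(split_plots, growth_form = "tundra_all")
  }
  pools |>
    dplyr::left_join(dplyr::select(species_means, "species_key", "myc_type",
                                   "mean_intensity", "n_obs"),
                     by = c("species_key", "myc_type")) |>
    dplyr::summarise(
      pool_abundance = sum(.data$type_abundance),
      covered_abundance = sum(.data$type_abundance[!is.na(.data$mean_intensity)]),
      intensity = if (any(!is.na(.data$mean_intensity) & .data$type_abundance > 0)) {
        stats::weighted.mean(.data$mean_intensity[!is.na(.data$mean_intensity)],
                             .data$type_abundance[!is.na(.data$mean_intensity)])
      } else NA_real_,
      mean_obs_per_species = mean(.data$n_obs[!is.na(.data$mean_intensity)]),
      .by = c("plot_id", "myc_type", "growth_form")
    ) |>
    dplyr::filter(!is.na(.data$intensity), .data$covered_abundance > 0) |>
    dplyr::mutate(coverage = .data$covered_abundance / .data$pool_abundance * 100) |>
    dplyr::select("plot_id", "myc_type", "growth_form", "intensity",
                  "coverage", "mean_obs_per_species", "pool_abundance")
}

#' Per-unit colonization intensity and quality statistics
#'
#' The intensity of colonization of a spatial unit is the unweighted
#' arithmetic mean of the community-weighted plot intensities over all plots
#' in the unit, per mycorrhizal-type x growth-form pool. The quality
#' statistics feeding the quality-index maps are recorded alongside: the
#' number of plots, the mean (over plots) of the per-plot mean number of
#' observations per species, and the mean plot coverage.
#'
#' @param plot_pools Output of [plot_weighted_intensity()] joined to a
#'   `unit_id` column (see [assign_plots_to_units()]).
#' @return A tibble with columns `unit_id`, `myc_type`, `growth_form`,
#'   `mean_intensity`, `n_plots`, `mean_obs_per_species`, `mean_coverage`.
#'   Units without any covered plot are absent (gap-filled downstream).
#' @export
unit_intensity <- function(plot_pools) {
  plot_pools |>
    dplyr::summarise(mean_intensity = mean(.data$intensity),
                     n_plots = dplyr::n(),
                     mean_obs_per_species = mean(.data$mean_obs_per_species),
                     mean_coverage = mean(.data$coverage),
                     .by = c("unit_id", "myc_type", "growth_form")) |>
    dplyr::arrange(.data$unit_id, .data$myc_type, .data$growth_form)
}

#' Unit colonization intensities from raw inputs
#'
#' Orchestrates the colonization workflow: filter records, convert
#' categorical values, compute species means, resolve plot abundances into
#' type pools, assign plots to spatial units, compute community-weighted plot
#' intensities (growth-form-specific on ordinary units, growth-form-free on
#' tundra units) and average them per unit.
#'
#' @param records Colonization records (see [filter_records()]).
#' @param plots Plot composition table: `plot_id`, `lon`, `lat`, `species`,
#'   `rel_abundance`.
#' @param growth_forms,genus_types Trait tables (see [species_traits()]).
#' @param units A `spatial_unit_map`.
#' @param categorical_mapping Label-to-percent mapping for categorical
#'   records, if any (see [categorical_to_percent()]).
#' @return A list with `species_means`, `plot_intensity` (per plot x pool,
#'   with `unit_id`) and `unit_colonization` (see [unit_intensity()]).
#' @export
compute_unit_colonization <- function(records, plots, growth_forms,
                                      genus_types, units,
                                      categorical_mapping = NULL) {
  recs <- filter_records(records)
  recs <- categorical_to_percent(recs, categorical_mapping)
  sp_means <- species_mean_colonization(recs)
  traits <- species_traits(growth_forms, genus_types)
  split <- split_dual_abundance(plots, traits)

  assignment <- assign_plots_to_units(plots, units) |>
    dplyr::left_join(dplyr::select(units$units, "unit_id", "is_tundra"),
                     by = "unit_id")
  split <- dplyr::inner_join(split, assignment, by = "plot_id")

  regular <- plot_weighted_intensity(
    dplyr::filter(split, !.data$is_tundra), sp_means, by_growth_form = TRUE)
  tundra <- plot_weighted_intensity(
    dplyr::filter(split, .data$is_tundra), sp_means, by_growth_form = FALSE)
  plot_int <- dplyr::bind_rows(regular, tundra) |>
    dplyr::left_join(dplyr::distinct(assignment, .data$plot_id, .data$unit_id),
                     by = "plot_id")
  list(species_means = sp_means,
       plot_intensity = plot_int,
       unit_colonization = unit_intensity(plot_int))
}
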