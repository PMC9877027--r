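#' Write a synthetic world to disk
#'
#' Serializes every component of a world in open text formats: rasters as
#' ESRI ASCII grids (`rasters/*.asc` + `.prj`), tables as CSV
#' (`tables/*.csv`; colonization records use the header
#' `species,value,unit_kind,naturalness,season`, where `unit_kind` is the
#' measurement kind AM or EcM), the configuration as YAML (`config.yml`) and
#' the ground truth as JSON (`ground_truth.json`). With a fixed seed and
#' configuration the emitted files are byte-identical across runs.
#'
#' @param world A `synthetic_world` (see [generate_world()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  rdir <- file.path(dir, "rasters"); tdir <- file.path(dir, "tables")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(world$rasters))
    write_ascii_grid(world$rasters[[nm]], file.path(rdir, nm))
  readr::write_csv(
    dplyr::select(world$tables$records, "species", "value",
                  unit_kind = "myc_type", "naturalness", "season"),
    file.path(tdir, "colonization_records.csv"))
  readr::write_csv(world$tables$plots, file.path(tdir, "plots.csv"))
  readr::write_csv(world$tables$growth_forms,
                   file.path(tdir, "growth_forms.csv"))
  readr::write_csv(world$tables$genus_types,
                   file.path(tdir, "genus_types.csv"))
  readr::write_csv(world$tables$ratios,
                   file.path(tdir, "coarse_vs_fine_roots.csv"))
  readr::write_csv(world$categorical_mapping,
                   file.path(tdir, "categorical_mapping.csv"))
  cfg <- unclass(world$config)
  cfg$true_intensity <- NULL  # tabular override is not representable in YAML scalars
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  truth <- list(units = world$truth$units, pools = world$truth$pools,
                totals = world$truth$totals, species = world$truth$species)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA, na = "null")
  invisible(dir)
}

#' Read a synthetic world back from disk
#'
#' Inverse of [write_world()]: reconstructs the rasters, tables, categorical
#' mapping, configuration and ground truth from a world directory.
#'
#' @param dir Directory written by [write_world()].
#' @return A list of class `synthetic_world`.
#' @export
read_world <- function(dir) {
  rdir <- file.path(dir, "rasters"); tdir <- file.path(dir, "tables")
  raster_files <- list.files(rdir, pattern = "\\.asc$", full.names = TRUE)
  rasters <- lapply(stats::setNames(raster_files,
                                    sub("\\.asc$", "", basename(raster_files))),
                    read_ascii_grid)
  records <- readr::read_csv(file.path(tdir, "colonization_records.csv"),
                             col_types = readr::cols(value = "c")) |>
    dplyr::rename(myc_type = "unit_kind")
  cfg <- yaml::read_yaml(file.path(dir, "config.yml"))
  cfg$grid_shape <- as.integer(unlist(cfg$grid_shape))
  config <- do.call(world_config, cfg)
  truth_raw <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                   simplifyVector = TRUE)
  truth <- lapply(truth_raw, tibble::as_tibble)
  structure(
    list(rasters = rasters,
         tables = list(
           records = records,
           plots = readr::read_csv(file.path(tdir, "plots.csv"),
                                   col_types = "cddcd"),
           growth_forms = readr::read_csv(file.path(tdir, "growth_forms.csv"),
                                          col_types = "cc"),
           genus_types = readr::read_csv(file.path(tdir, "genus_types.csv"),
                                         col_types = "cc"),
           ratios = readr::read_csv(file.path(tdir, "coarse_vs_fine_roots.csv"),
                                    col_types = "cd")),
         categorical_mapping = readr::read_csv(
           file.path(tdir, "categorical_mapping.csv"), col_types = "cd"),
         truth = truth,
         config = config),
    class = "synthetic_world"
  )
}

#' Write the principal pipeline outputs
#'
#' Writes the final and intermediate rasters of a [run_pipeline()] result as
#' ESRI ASCII grids, the unit lookup table, the per-unit summary and totals
#' as CSV, and the quality-index rasters, mirroring the deposit layout of the
#' published maps (`AM_roots_colonized`, `EcM_intensity_colonization`,
#' `AM_plots`, ...).
#'
#' @param result Output of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$rasters))
    write_ascii_grid(result$rasters[[nm]], file.path(dir, nm))
  for (ty in names(result$quality)) {
    q <- result$quality[[ty]]
    write_ascii_grid(q$mean_obs_per_species,
                     file.path(dir, paste0(ty, "_occurrences_colonization")))
    write_ascii_grid(q$mean_coverage,
                     file.path(dir, paste0(ty, "_rel.abundance_colonization")))
    write_ascii_grid(q$n_plots, file.path(dir, paste0(ty, "_plots")))
  }
  readr::write_csv(result$units$units, file.path(dir, "spatial_units.csv"))
  readr::write_csv(result$unit_summary, file.path(dir, "unit_summary.csv"))
  readr::write_csv(result$totals, file.path(dir, "unit_totals.csv"))
  invisible(dir)
}
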