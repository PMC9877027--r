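# Shared small world configurations. Worlds are generated once per test run
# and cached, since several test files exercise the same configurations.

tiny_config <- function(seed = 11, ...) {
  world_config(grid_shape = c(24, 24), fine_factor = 2, species_pool_size = 60,
               plots_per_unit = 3, seed = seed, ...)
}

# zero-noise, full-coverage configuration: every stochastic degradation off
exact_config <- function(seed = 5, ...) {
  world_config(grid_shape = c(24, 24), fine_factor = 2, species_pool_size = 60,
               plots_per_unit = 3, intensity_noise_sd = 0,
               categorical_fraction = 0, fraction_no_records = 0,
               seed = seed, ...)
}

local({
  cache <- new.env(parent = emptyenv())
  cached_world <<- function(config) {
    key <- paste(deparse(unclass(config)), collapse = "")
    if (is.null(cache[[key]])) cache[[key]] <- generate_world(config)
    cache[[key]]
  }
})

# join a pipeline result to ground truth on the unit triple
truth_comparison <- function(world, result) {
  tru <- dplyr::left_join(
    world$truth$pools,
    dplyr::select(world$truth$units, "unit_id", "ecoregion", "landcover",
                  "continent", "observed"),
    by = "unit_id")
  est <- dplyr::left_join(result$unit_summary,
                          dplyr::select(result$units$units, "unit_id",
                                        "ecoregion", "landcover", "continent"),
                          by = "unit_id")
  dplyr::inner_join(est, tru,
                    by = c("ecoregion", "landcover", "continent", "myc_type",
                           "growth_form"),
                    suffix = c("", ".true"))
}
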