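test_that("inconsistent configurations are rejected", {
  expect_error(world_config(excluded_landcover = 1:6), "cover all classes")
  expect_error(world_config(fraction_woody = 1.2), "proportions")
  expect_error(world_config(intensity_range = c(40, 120)), "\\[0, 100\\]")
  expect_error(world_config(species_band_low = c(20, 45)), "bracket")
  expect_error(world_config(plots_per_unit = 0), "counts")
  expect_error(generate_world(world_config(species_pool_size = 6)),
               "too small")
})

test_that("the same seed and configuration give identical worlds and files", {
  w1 <- generate_world(tiny_config(seed = 19))
  w2 <- generate_world(tiny_config(seed = 19))
  expect_identical(w1$tables, w2$tables)
  expect_identical(lapply(w1$rasters, `[[`, "values"),
                   lapply(w2$rasters, `[[`, "values"))
  expect_identical(w1$truth, w2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_world(w1, d1); write_world(w2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # a different seed changes the world
  w3 <- generate_world(tiny_config(seed = 20))
  expect_false(identical(w1$tables$plots, w3$tables$plots))
})

test_that("worlds round-trip through their on-disk form", {
  w <- generate_world(tiny_config(seed = 23))
  d <- withr::local_tempdir()
  write_world(w, d)
  back <- read_world(d)
  expect_equal(back$rasters$landcover$values, w$rasters$landcover$values)
  expect_equal(back$rasters$bgb_woody$values, w$rasters$bgb_woody$values)
  expect_equal(back$tables$plots, w$tables$plots, tolerance = 1e-12)
  expect_equal(back$tables$records$value, w$tables$records$value)
  expect_equal(back$config$seed, w$config$seed)
  expect_equal(back$truth$pools$intensity, w$truth$pools$intensity,
               tolerance = 1e-12)
})

test_that("emitted rasters share registration and place nodata over water", {
  w <- cached_world(tiny_config())
  fine <- w$rasters[c("ecoregion", "landcover", "continent", "bgb_woody",
                      "bgb_herb", "bgb_tundra")]
  for (r in fine[-1]) expect_true(same_grid(fine$ecoregion, r))
  coarse <- w$rasters[grep("^frac_", names(w$rasters))]
  for (r in coarse[-1]) expect_true(same_grid(coarse[[1]], r))
  water <- w$config$excluded_landcover[1]
  wet <- w$rasters$landcover$values == water
  expect_gt(sum(wet), 0)
  expect_true(all(is.na(w$rasters$bgb_woody$values[wet])))
  expect_true(all(is.na(w$rasters$bgb_herb$values[wet])))
})

test_that("per-pixel AM + EcM fractions stay within 1 for each growth form", {
  w <- cached_world(tiny_config())
  for (gf in c("tree", "shrub", "herb", "all")) {
    s <- w$rasters[[paste0("frac_am_", gf)]]$values +
      w$rasters[[paste0("frac_ecm_", gf)]]$values
    expect_true(all(s[!is.na(s)] <= 1 + 1e-12), label = gf)
  }
})

test_that("ground truth is recomputable by brute force from the emitted files", {
  w <- cached_world(exact_config())
  # species means: recount from the filtered record table
  recs <- w$tables$records
  recs <- recs[recs$naturalness != "non_natural" &
                 recs$season != "non_growing", ]
  recs$value <- as.numeric(recs$value)
  for (k in seq_len(nrow(w$truth$species))) {
    row <- w$truth$species[k, ]
    obs <- recs$value[recs$species == row$species &
                        recs$myc_type == row$myc_type]
    if (length(obs) > 0)
      expect_equal(mean(obs), row$true_mean, tolerance = 1e-9,
                   label = paste(row$species, row$myc_type))
  }
  # unit stocks: recompute one pool by brute-force raster arithmetic
  f <- w$config$fine_factor
  um <- build_unit_map(resample_categorical_nearest(w$rasters$ecoregion, f),
                       resample_categorical_nearest(w$rasters$landcover, f),
                       resample_categorical_nearest(w$rasters$continent, f),
                       excluded_classes = w$config$excluded_landcover,
                       tundra_ecoregions = w$config$tundra_ecoregions)
  p <- root_fraction_params()
  bgb <- brute_aggregate_mean(w$rasters$bgb_woody, f)
  am_w <- w$rasters$frac_am_tree$values + w$rasters$frac_am_shrub$values
  stock_px <- bgb * p$fine_fraction_woody *
    depth_fraction(p$beta_woody, 30) * am_w
  ref <- brute_zonal_mean(raster_grid(stock_px), um)
  tru <- dplyr::inner_join(
    dplyr::filter(w$truth$pools, .data$myc_type == "AM",
                  .data$growth_form == "woody"),
    dplyr::select(w$truth$units, "unit_id", "ecoregion", "landcover",
                  "continent"),
    by = "unit_id")
  est <- dplyr::inner_join(tru, cbind(um$units, mean = ref$mean),
                           by = c("ecoregion", "landcover", "continent"))
  expect_equal(est$mean, est$stock, tolerance = 1e-9)
})

test_that("with no dual species, type abundances are purely single-type", {
  w <- generate_world(tiny_config(seed = 31, fraction_dual_type = 0))
  traits <- species_traits(w$tables$growth_forms, w$tables$genus_types)
  expect_false(any(traits$myc_type == "dual"))
  split <- suppressMessages(
    split_dual_abundance(w$tables$plots, traits))
  # brute-force recount: per plot, AM + EcM abundance must equal the summed
  # abundance of typed species (nothing was halved)
  plots <- w$tables$plots
  plots$key <- tolower(plots$species)
  typed <- traits$species_key[traits$myc_type %in% c("AM", "EcM")]
  for (pid in unique(plots$plot_id)[1:10]) {
    sub <- plots[plots$plot_id == pid & plots$key %in% typed, ]
    expect_equal(sum(split$type_abundance[split$plot_id == pid]),
                 sum(sub$rel_abundance))
  }
})

test_that("categorical encoding follows the class bounds and round-trips", {
  records <- tibble::tibble(species = "A a", myc_type = "AM",
                            value = c(37, 0, 99),
                            naturalness = "natural", season = "growing")
  set.seed(1)
  out <- generate_categorical_colonization(records,
                                           class_bounds = c(0, 25, 50, 100),
                                           fraction = 1)
  expect_equal(out$records$value, c("class2", "class1", "class3"))
  expect_equal(out$mapping$percent, c(12.5, 37.5, 75))
  # value 37 converts back to the class-2 midpoint 37.5
  conv <- categorical_to_percent(out$records, out$mapping)
  expect_equal(conv$value, c(37.5, 12.5, 75))
  # empty bounds: nothing converted
  none <- generate_categorical_colonization(records, numeric(0), fraction = 1)
  expect_identical(none$records$value, records$value)
  expect_error(
    generate_categorical_colonization(records, c(0, 50, 25, 100), 1),
    "increasing")
})

test_that("zero-noise worlds with many plots recover true intensities exactly", {
  w <- cached_world(exact_config())
  res <- suppressMessages(run_pipeline(w))
  cmp <- truth_comparison(w, res)
  obs <- cmp[cmp$observed, ]
  expect_gt(nrow(obs), 10)
  expect_true(all(!is.na(obs$intensity)))
  expect_equal(obs$intensity, obs$intensity.true, tolerance = 1e-9)
})
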