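unit_table_2x2 <- function() {
  eco <- raster_grid(matrix(c(1, 1, 2, 2), 2), cellsize = 1)
  one <- raster_grid(matrix(1, 2, 2), cellsize = 1)
  build_unit_map(eco, one, one)
}

test_that("colonized stock is stock times intensity over 100", {
  expect_equal(colonized_stock(0.385, 32.5), 0.1251, tolerance = 1e-3)
  expect_equal(colonized_stock(3, 0), 0)
  expect_equal(colonized_stock(3, 100), 3)
  expect_error(colonized_stock(-1, 50), "non-negative")
  expect_error(colonized_stock(1, 130), "\\[0, 100\\]")
})

test_that("pool combination sums growth forms, routes tundra exclusively", {
  units <- tibble::tibble(unit_id = 1:2, is_tundra = c(FALSE, TRUE),
                          ecoregion = 1L, continent = 1L)
  pools <- tibble::tibble(
    unit_id = c(1L, 1L, 1L, 2L, 2L, 2L),
    myc_type = "AM",
    growth_form = c("woody", "herbaceous", "tundra_all",
                    "woody", "herbaceous", "tundra_all"),
    value = c(0.125, 0.050, 99, 99, 99, 0.07))
  out <- combine_pools(pools, units)
  expect_equal(out$total[out$unit_id == 1], 0.175)
  # tundra unit: only the tundra pool counts, even with woody values present
  expect_equal(out$total[out$unit_id == 2], 0.07)
  # a type observed in only one pool: the other contributes 0, not NA
  one_pool <- tibble::tibble(unit_id = 1L, myc_type = "EcM",
                             growth_form = c("woody", "herbaceous"),
                             value = c(0.2, NA))
  expect_equal(combine_pools(one_pool, units)$total, 0.2)
  # all pools missing: stays missing for gap-filling
  empty <- tibble::tibble(unit_id = 1L, myc_type = "EcM",
                          growth_form = c("woody", "herbaceous"),
                          value = c(NA_real_, NA_real_))
  expect_true(is.na(combine_pools(empty, units)$total))
})

test_that("gap-filling borrows the ecoregion x continent mean, nothing else", {
  units <- tibble::tibble(unit_id = 1:5,
                          ecoregion = c(1, 1, 1, 2, 2),
                          continent = c(1, 1, 1, 1, 1),
                          is_tundra = FALSE)
  pools <- tibble::tibble(unit_id = 1:5, myc_type = "AM",
                          growth_form = "woody",
                          value = c(2, 4, NA, 7, NA))
  out <- gap_fill(pools, units)
  expect_equal(out$value[out$unit_id == 3], 3)  # mean of {2, 4}
  expect_equal(out$fill_status[out$unit_id == 3], "ecoregion_continent_mean")
  # observed units are untouched
  expect_equal(out$value[out$unit_id %in% c(1, 2, 4)], c(2, 4, 7))
  expect_true(all(out$fill_status[out$unit_id %in% c(1, 2, 4)] == "observed"))
  # fills never cross the ecoregion boundary: unit 5 borrows only unit 4
  expect_equal(out$value[out$unit_id == 5], 7)
  # a wholly empty group remains unfilled
  pools2 <- dplyr::mutate(pools, value = ifelse(.data$unit_id >= 4, NA, value))
  out2 <- gap_fill(pools2, units)
  expect_true(all(is.na(out2$value[out2$unit_id >= 4])))
  expect_true(all(out2$fill_status[out2$unit_id >= 4] == "unfilled"))
})

test_that("gap-filling is idempotent and fills pools independently", {
  units <- tibble::tibble(unit_id = 1:2, ecoregion = 1, continent = 1,
                          is_tundra = FALSE)
  pools <- tidyr::crossing(unit_id = 1:2, myc_type = c("AM", "EcM"),
                           growth_form = c("woody", "herbaceous")) |>
    dplyr::mutate(value = c(1, 2, 3, 4, NA, 6, 7, 8))
  out <- gap_fill(pools, units)
  # the one empty pool takes its own pool's group mean, not a neighbour pool's
  filled <- dplyr::anti_join(out, dplyr::filter(pools, !is.na(.data$value)),
                             by = c("unit_id", "myc_type", "growth_form"))
  donor <- dplyr::filter(pools, .data$unit_id != filled$unit_id,
                         .data$myc_type == filled$myc_type,
                         .data$growth_form == filled$growth_form)
  expect_equal(filled$value, donor$value)
  again <- gap_fill(dplyr::select(out, -"fill_status"), units)
  expect_equal(again$value, out$value)
})

test_that("gap-filling matches the brute-force oracle on random worlds", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30
    units <- tibble::tibble(unit_id = 1:n,
                            ecoregion = sample(1:3, n, replace = TRUE),
                            continent = sample(1:2, n, replace = TRUE),
                            is_tundra = FALSE)
    pools <- tidyr::crossing(unit_id = 1:n, myc_type = c("AM", "EcM"),
                             growth_form = "woody") |>
      dplyr::mutate(value = ifelse(runif(dplyr::n()) < 0.3, NA,
                                   round(runif(dplyr::n(), 0, 10), 3)))
    got <- gap_fill(pools, units) |>
      dplyr::arrange(.data$unit_id, .data$myc_type)
    ref <- brute_gap_fill(dplyr::arrange(pools, .data$unit_id, .data$myc_type),
                          units)
    expect_equal(got$value, ref$value)
  }
})

test_that("rasterizing paints unit footprints and round-trips with zonal means", {
  um <- unit_table_2x2()
  vals <- tibble::tibble(unit_id = 1:2, value = c(2.5, 7))
  r <- rasterize_units(vals, um)
  expect_equal(sort(unique(as.vector(r$values))), c(2.5, 7))
  # piecewise constant on unit footprints
  expect_true(all(r$values[um$raster$values == 1] == 2.5))
  # inverse property: zonal mean of the painted raster returns the values
  zm <- zonal_mean(r, um)
  expect_equal(zm$mean, vals$value)
  # missing value contract
  expect_error(rasterize_units(vals[1, ], um), "no value supplied")
  # NA value (unfilled unit) becomes nodata pixels
  r2 <- rasterize_units(tibble::tibble(unit_id = 1:2, value = c(NA, 7)), um)
  expect_true(all(is.na(r2$values[um$raster$values == 1])))
})

test_that("rasterize-then-zonal is the identity on random unit maps", {
  for (seed in 1:5) {
    l <- random_world_layers(seed, 20, 20)
    um <- build_unit_map(l$eco, l$lc, l$con, excluded_classes = 1)
    vals <- tibble::tibble(unit_id = um$units$unit_id,
                           value = stats::runif(nrow(um$units), 0, 5))
    zm <- zonal_mean(rasterize_units(vals, um), um)
    expect_equal(zm$mean, vals$value)
  }
})
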