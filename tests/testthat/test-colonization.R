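rec <- function(...) {
  tibble::tibble(...)
}

test_that("record filtering drops non-natural and out-of-season, keeps unknown", {
  records <- rec(
    species = paste("Sp", 1:4), myc_type = "AM", value = c(10, 20, 30, 40),
    naturalness = c("natural", "non_natural", "unknown", "natural"),
    season = c("growing", "growing", "unknown", "non_growing"))
  out <- suppressMessages(filter_records(records))
  expect_equal(out$value, c(10, 30))
})

test_that("categorical labels convert through the mapping; numbers pass through", {
  records <- rec(species = c("A a", "B b", "C c"), myc_type = "AM",
                 value = c("class2", "42", "7.5"),
                 naturalness = "natural", season = "growing")
  mapping <- data.frame(label = c("class1", "class2"), percent = c(12.5, 37.5))
  out <- categorical_to_percent(records, mapping)
  expect_equal(out$value, c(37.5, 42, 7.5))
  # named-vector mapping works too
  out2 <- categorical_to_percent(records, c(class2 = 37.5))
  expect_equal(out2$value[1], 37.5)
  # unmapped label errors, naming the label
  records$value[1] <- "classZ"
  expect_error(categorical_to_percent(records, mapping), "classZ")
})

test_that("species means are per species x measurement kind, never pooled", {
  records <- rec(
    species = c("Acer rubrum", "acer  rubrum", "Acer rubrum", "Pinus alba"),
    myc_type = c("AM", "AM", "EcM", "EcM"),
    value = c(40, 60, 10, 30),
    naturalness = "natural", season = "growing")
  out <- species_mean_colonization(records)
  am <- out[out$myc_type == "AM", ]
  expect_equal(am$mean_intensity, 50)  # case/whitespace-insensitive match
  expect_equal(am$n_obs, 2L)
  expect_equal(out$mean_intensity[out$myc_type == "EcM" &
                                    out$species_key == "acer rubrum"], 10)
  expect_error(species_mean_colonization(rec(species = "A", myc_type = "AM",
                                             value = "class1")),
               "numeric")
})

test_that("species mean recovers a true mean from noisy records", {
  set.seed(9)
  n <- 400; mu <- 35; sd <- 8
  records <- rec(species = "Genus sp", myc_type = "AM",
                 value = pmin(pmax(rnorm(n, mu, sd), 0), 100),
                 naturalness = "natural", season = "growing")
  out <- species_mean_colonization(records)
  expect_lt(abs(out$mean_intensity - mu), 3 * sd / sqrt(n))
})

test_that("genus-based trait assignment handles facultative AM and unknowns", {
  gf <- data.frame(species = c("Quercus robur", "Poa annua", "Festuca ovina",
                               "Rarus unknownii"),
                   growth_form = c("woody", "herbaceous", "herbaceous",
                                   "woody"))
  gt <- data.frame(genus = c("Quercus", "Poa", "Festuca"),
                   myc_type = c("ecm", "facultative_am", "dual"))
  tr <- species_traits(gf, gt)
  expect_equal(tr$genus, c("Quercus", "Poa", "Festuca", "Rarus"))
  expect_equal(tr$myc_type, c("EcM", "AM", "dual", "unknown"))
})

test_that("dual species split 50/50 and abundance is conserved", {
  gf <- data.frame(species = c("A am", "B dual", "C none"),
                   growth_form = c("woody", "woody", "herbaceous"))
  gt <- data.frame(genus = c("A", "B"), myc_type = c("am", "dual"))
  plots <- data.frame(plot_id = "p1", species = c("A am", "B dual", "C none"),
                      rel_abundance = c(0.2, 0.3, 0.5))
  out <- suppressMessages(
    split_dual_abundance(plots, species_traits(gf, gt)))
  # pure AM species: all to AM
  expect_equal(out$type_abundance[out$species == "A am" &
                                    out$myc_type == "AM"], 0.2)
  expect_equal(sum(out$species == "A am" & out$myc_type == "EcM"), 0L)
  # dual: half to each pool
  dual <- out[out$species == "B dual", ]
  expect_setequal(dual$myc_type, c("AM", "EcM"))
  expect_equal(dual$type_abundance, c(0.15, 0.15))
  # untyped species removed from both pools
  expect_false("C none" %in% out$species)
  # conservation over retained species
  expect_equal(sum(out$type_abundance), 0.2 + 0.3)
})

test_that("the community-weighted plot mean renormalizes to covered species", {
  # worked example: A (0.6, 40%), B (0.2, 10%), C (0.2, no data)
  gf <- data.frame(species = c("Aa x", "Bb y", "Cc z"), growth_form = "woody")
  gt <- data.frame(genus = c("Aa", "Bb", "Cc"), myc_type = "am")
  plots <- data.frame(plot_id = "p1", species = c("Aa x", "Bb y", "Cc z"),
                      rel_abundance = c(0.6, 0.2, 0.2))
  split <- split_dual_abundance(plots, species_traits(gf, gt))
  means <- rec(species = c("Aa x", "Bb y"), species_key = c("aa x", "bb y"),
               myc_type = "AM", mean_intensity = c(40, 10), n_obs = c(4L, 2L))
  out <- plot_weighted_intensity(split, means)
  expect_equal(nrow(out), 1L)
  expect_equal(out$intensity, 32.5)  # weights 0.75/0.25 on 40/10
  expect_equal(out$coverage, 80)
  expect_equal(out$mean_obs_per_species, 3)
  # single covered species: its mean regardless of abundance
  one <- plot_weighted_intensity(split[split$species == "Aa x", ], means)
  expect_equal(one$intensity, 40)
  # no covered species: pool is empty, not zero
  none <- plot_weighted_intensity(split[split$species == "Cc z", ], means)
  expect_equal(nrow(none), 0L)
})

test_that("weighted means are bounded by pool species means and weights sum to 1", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    sp <- sprintf("Gen%02d sp", seq_len(n))
    gf <- data.frame(species = sp, growth_form = "herbaceous")
    gt <- data.frame(genus = sub(" sp", "", sp), myc_type = "am")
    plots <- data.frame(plot_id = "p", species = sp,
                        rel_abundance = runif(n))
    m <- runif(n, 0, 100)
    means <- rec(species = sp, species_key = tolower(sp), myc_type = "AM",
                 mean_intensity = m, n_obs = 3L)
    out <- plot_weighted_intensity(split_dual_abundance(plots,
                                                        species_traits(gf, gt)),
                                   means)
    expect_gte(out$intensity, min(m) - 1e-12)
    expect_lte(out$intensity, max(m) + 1e-12)
  }
})

test_that("unit intensity is the unweighted mean over plots", {
  pools <- rec(plot_id = c("p1", "p2"), myc_type = "AM",
               growth_form = "woody", intensity = c(30, 50),
               coverage = c(80, 100), mean_obs_per_species = c(2, 4),
               pool_abundance = c(0.5, 0.7), unit_id = 1L)
  out <- unit_intensity(pools)
  expect_equal(out$mean_intensity, 40)
  expect_equal(out$n_plots, 2L)
  expect_equal(out$mean_obs_per_species, 3)
  expect_equal(out$mean_coverage, 90)
})

test_that("plot subset selection maximizes unit coverage, then supplements", {
  eco <- raster_grid(matrix(c(1, 2, 3, 4), 2), cellsize = 1)
  one <- raster_grid(matrix(1, 2, 2), cellsize = 1)
  um <- build_unit_map(eco, one, one)
  # unit footprints: unit k at the pixel with ecoregion k
  plot_at <- function(id, lon, lat) {
    data.frame(plot_id = id, lon = lon, lat = lat, species = "X y",
               rel_abundance = 1)
  }
  sub1 <- rbind(plot_at("a", 0.5, 1.5), plot_at("b", 0.5, 0.5))   # units A, B
  sub2 <- rbind(plot_at("c", 0.5, 1.5), plot_at("d", 0.5, 0.5),
                plot_at("e", 1.5, 1.5))                           # units A, B, C
  out <- select_plot_subset(list(sub1, sub2), um)
  expect_equal(attr(out, "chosen_subset"), 2L)
  # supplementation: chosen covers {A, B}; another subset reaches C
  sub3 <- plot_at("f", 1.5, 1.5)
  out2 <- select_plot_subset(list(sub1, sub3), um)
  expect_equal(attr(out2, "chosen_subset"), 1L)
  expect_true("f" %in% out2$plot_id)
  covered <- unique(assign_plots_to_units(out2, um)$unit_id)
  expect_equal(length(covered), 3L)
  expect_equal(attr(out2, "supplemented_units"),
               setdiff(covered, unique(assign_plots_to_units(sub1, um)$unit_id)))
  # tie: first subset by input order wins, with a message
  expect_message(out3 <- select_plot_subset(list(sub1, sub1), um), "tie")
  expect_equal(attr(out3, "chosen_subset"), 1L)
  expect_error(select_plot_subset(list(), um), "no candidate")
})

test_that("plots on nodata or excluded pixels are dropped from unit assignment", {
  eco <- raster_grid(matrix(c(1, 1, 2, 2), 2), cellsize = 1)
  lc <- raster_grid(matrix(c(40, 40, 10, 40), 2), cellsize = 1)
  one <- raster_grid(matrix(1, 2, 2), cellsize = 1)
  um <- build_unit_map(eco, lc, one, excluded_classes = 10)
  plots <- data.frame(plot_id = c("in", "out", "off"),
                      lon = c(0.5, 1.5, 5), lat = c(0.5, 1.5, 0.5))
  expect_message(a <- assign_plots_to_units(plots, um), "dropped 2")
  expect_equal(a$plot_id, "in")
})
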