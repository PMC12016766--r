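small_cfg <- function(..., n_species = 6) {
  synthetic_config(baseline_years = 1961:1965, recent_years = 1991:1995,
                   grid_rows = 4, grid_cols = 4, n_species = n_species, ...)
}

test_that("configuration validation rejects inconsistent settings", {
  expect_error(synthetic_config(baseline_years = 1961:1990,
                                recent_years = 1980:2010), "overlap")
  expect_error(synthetic_config(baseline_years = 1961), "at least 2 years")
  expect_error(small_cfg(interannual_sd = list(tmean = 0)), "must be > 0")
  expect_error(small_cfg(occupancy = list(fill_prob = 1.5)), "fill_prob")
})

test_that("generators are pure functions of configuration and seed", {
  cfg <- synthetic_config(seed = 42, grid_rows = 2, grid_cols = 2,
                          baseline_years = 2000:2001,
                          recent_years = 2010:2011, n_species = 4)
  expect_identical(generate_climate(cfg), generate_climate(cfg))
  expect_identical(generate_occurrences(cfg), generate_occurrences(cfg))
  expect_identical(generate_traits(cfg), generate_traits(cfg))
  tr <- generate_traits(cfg)
  expect_identical(generate_surveillance(cfg, tr),
                   generate_surveillance(cfg, tr))
  # a different seed changes the draw
  cfg2 <- synthetic_config(seed = 43, grid_rows = 2, grid_cols = 2,
                           baseline_years = 2000:2001,
                           recent_years = 2010:2011, n_species = 4)
  expect_false(identical(generate_climate(cfg), generate_climate(cfg2)))
})

test_that("generated climate respects physical invariants", {
  cfg <- small_cfg(seed = 9)
  cl <- generate_climate(cfg)
  expect_true(all(cl$tmin <= cl$tmean))
  expect_true(all(cl$tmean <= cl$tmax))
  expect_true(all(cl$prcp >= 0))
  # one record per cell x year x month over both periods
  expect_equal(nrow(cl), 16 * 10 * 12)
})

test_that("zero-trend climate yields SED near the pure-noise level", {
  cfg <- synthetic_config(seed = 5, grid_rows = 6, grid_cols = 6,
                          trend = list(tmean = 0, tmax = 0, tmin = 0, prcp = 0))
  sed <- climate_novelty(generate_climate(cfg), cfg$baseline_years,
                         cfg$recent_years)
  # with no trend each of the 6 standardized terms has expectation ~2/30
  expect_gt(mean(sed$sed), 0.2)
  expect_lt(mean(sed$sed), 0.7)
})

test_that("an east-edge trend raises eastern SED, by direct recomputation", {
  cfg <- synthetic_config(seed = 6, grid_rows = 3, grid_cols = 6,
                          trend_gradient = "east",
                          trend = list(tmean = 2, tmax = 2, tmin = 2,
                                       prcp = 10))
  cl <- generate_climate(cfg)
  sed <- brute_sed(cl, cfg$baseline_years, cfg$recent_years)
  col <- cell_to_rowcol(sed$cell_id, cfg$grid_cols)$col
  expect_gt(mean(sed$sed[col == 5]), mean(sed$sed[col == 0]))
})

test_that("occupancy generation covers the stated geometries", {
  # fill probability 1 and a radius covering the grid occupies every cell
  cfg <- small_cfg(seed = 2, n_species = 3,
                   occupancy = list(fill_prob = 1, radius_range = c(10, 10)))
  occ <- generate_occurrences(cfg)
  expect_equal(unname(table(occ$species)), rep(16L, 3), ignore_attr = TRUE)

  # disjoint cluster centers with non-overlapping radii -> disjoint occupancy
  centers <- data.frame(species = c("sp001", "sp002"),
                        row = c(0, 9), col = c(0, 9),
                        radius = 2, fill_prob = 1)
  cfg2 <- synthetic_config(seed = 2, grid_rows = 10, grid_cols = 10,
                           baseline_years = 1961:1965,
                           recent_years = 1991:1995, n_species = 2,
                           occupancy = list(centers = centers))
  occ2 <- generate_occurrences(cfg2)
  a <- occ2$cell_id[occ2$species == "sp001"]
  b <- occ2$cell_id[occ2$species == "sp002"]
  expect_length(intersect(a, b), 0)
  expect_gt(length(a), 0)
  expect_gt(length(b), 0)
})

test_that("generated traits span all score levels and honor the bat contract", {
  cfg <- small_cfg(seed = 3, n_species = 40)
  tr <- generate_traits(cfg)
  expect_equal(nrow(tr), 40)
  expect_setequal(unique(score_habitat(tr$habitat_breadth)), 0:2)
  batlike <- is.na(tr$dispersal_km)
  expect_gt(sum(batlike), 0)
  expect_true(all(!is.na(tr$migration_class[batlike])))
  expect_true(all(is.na(tr$migration_class[!batlike])))
  expect_true(all(tr$l_max > tr$l_1r))
  rc <- reproductive_capacity(tr$l_max, tr$l_1r, tr$litter_size,
                              tr$litters_per_year)
  expect_true(all(rc > 0))
  expect_error(generate_traits(small_cfg(
    trait_ranges = list(body_mass_g = c(10, 10)))), "degenerate range")
})

test_that("surveillance fractions drive the filter outcome", {
  cfg <- small_cfg(seed = 4, n_surveillance_records = 120,
                   surveillance = list(missing_coords = 1))
  tr <- generate_traits(cfg)
  sv <- generate_surveillance(cfg, tr)
  kept <- filter_records(sv)
  expect_equal(nrow(kept$included), 0)
  expect_true(all(kept$excluded$reason %in% c("level", "coords")))
})

test_that("equal order weights give near-equal per-order record shares", {
  cfg <- synthetic_config(seed = 10, grid_rows = 4, grid_cols = 4,
                          baseline_years = 1961:1965,
                          recent_years = 1991:1995,
                          n_species = 12, frac_batlike = 0,
                          n_surveillance_records = 3000,
                          order_weights = c(Chiroptera = 1, Rodentia = 1,
                                            Carnivora = 1, Eulipotyphla = 1,
                                            Cetartiodactyla = 1,
                                            Lagomorpha = 1),
                          surveillance = list(missing_coords = 0,
                                              targeted = 0,
                                              macroscopic_only = 0,
                                              organs_missing = 0,
                                              other_level = 0))
  tr <- generate_traits(cfg)
  sv <- generate_surveillance(cfg, tr)
  # with equal weights each record is a uniform draw over species, so order
  # shares follow the species counts per order; compare with a binomial CI
  share <- table(tr$order[match(sv$species, tr$species)]) / nrow(sv)
  expected <- table(tr$order) / nrow(tr)
  for (o in names(expected)) {
    p <- expected[[o]]
    se <- sqrt(p * (1 - p) / nrow(sv))
    expect_lt(abs(share[[o]] - p), 4 * se + 1e-9)
  }
})

test_that("the packaged reference table passes its integrity checks", {
  fx <- load_reference_categories()
  expect_equal(nrow(fx), 59)
  expect_equal(as.vector(table(factor(fx$category, levels = 1:8))),
               c(2, 5, 3, 2, 8, 4, 4, 31))
  expect_equal(sum(table(fx$order)), 59)

  lookup <- function(sp) fx[fx$species == sp, ]
  expect_equal(lookup("Whiskered myotis")$order, "Chiroptera")
  expect_equal(lookup("Whiskered myotis")$category, 1)
  expect_equal(lookup("Garden dormouse")$order, "Rodentia")
  expect_equal(lookup("Garden dormouse")$category, 1)
  expect_equal(lookup("Fallow deer")$category, 7)
})

test_that("configurations round-trip through YAML", {
  cfg <- small_cfg(seed = 12)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 12, grid_rows = 4, grid_cols = 4,
                        baseline_years = c(1961, 1965),
                        recent_years = c(1991, 1995), n_species = 6),
                   path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$baseline_years, cfg$baseline_years)
  expect_identical(generate_climate(cfg2), generate_climate(cfg))
})
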