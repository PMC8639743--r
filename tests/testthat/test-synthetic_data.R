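test_that("generated life tables follow the configured cohort trend", {
  # constant table
  lt <- generate_life_table(c(1900, 1950), base_leb = 80, annual_gain = 0)
  expect_true(all(lt$leb_years == 80))
  expect_equal(nrow(lt), 51 * 2)

  # linear construction: +0.1/year means +1 after 10 cohorts
  lt <- generate_life_table(c(1900, 1950), base_leb = c(F = 70, M = 70),
                            annual_gain = 0.1)
  l1900 <- lt$leb_years[lt$birth_year == 1900 & lt$gender == "M"]
  l1910 <- lt$leb_years[lt$birth_year == 1910 & lt$gender == "M"]
  expect_equal(l1900, 70)
  expect_equal(l1910, 71)

  # configured gender offset holds at every birth year
  lt <- generate_life_table(c(1900, 1980), base_leb = c(F = 74, M = 70),
                            annual_gain = 0.08)
  wide <- merge(lt[lt$gender == "F", c("birth_year", "leb_years")],
                lt[lt$gender == "M", c("birth_year", "leb_years")],
                by = "birth_year")
  expect_true(all(abs(wide$leb_years.x - wide$leb_years.y - 4) < 1e-12))

  expect_error(generate_life_table(c(2000, 1990)), "non-empty")
  expect_error(generate_life_table(c(1900, 1950), annual_gain = -1), ">= 0")
})

test_that("with effects and noise off every generated lifespan deviation is exactly zero", {
  cfg <- synthetic_config(n_individuals = 400, cluster_effect_years = 0,
                          skew_params = list(mean = 0, sd = 0, median = 0),
                          covariate_effects = list(swiss = 0,
                                                   income_per_1000 = 0,
                                                   neighborhood_age = 0),
                          seed = 11)
  pop <- generate_population(cfg)
  expect_identical(max(abs(pop$records$ypllg_true)), 0)
  expect_true(all(pop$records$age_years == pop$records$leb_years))
})

test_that("planted high clusters shift in-cluster lifespans by the configured effect", {
  # Monte-Carlo recovery over >= 1000 in-cluster draws, Gaussian noise sd 2
  cfg <- synthetic_config(n_individuals = 6000,
                          region_extent = c(0, 8000, 0, 8000),
                          n_high_clusters = 1, n_low_clusters = 0,
                          cluster_radius_m = 2500, cluster_effect_years = 15,
                          skew_params = list(mean = 0, sd = 2, median = 0),
                          covariate_effects = list(swiss = 0,
                                                   income_per_1000 = 0,
                                                   neighborhood_age = 0),
                          seed = 21)
  pop <- generate_population(cfg)
  inside <- pop$truth$cluster > 0
  expect_gt(sum(inside), 1000)
  se <- 2 / sqrt(sum(inside))
  expect_lt(abs(mean(pop$records$ypllg_true[inside]) - 15), 3 * se)
  # truth labels partition the records and recover the planted contrast
  expect_true(all(pop$truth$cluster %in% c(0L, 1L)))
  contrast <- mean(pop$records$ypllg_true[inside]) -
    mean(pop$records$ypllg_true[!inside])
  se_c <- sqrt(2^2 / sum(inside) + 2^2 / sum(!inside))
  expect_lt(abs(contrast - 15), 3 * se_c)
})

test_that("the generator is deterministic in its seed", {
  cfg <- synthetic_config(n_individuals = 300, seed = 33)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$records, p2$records)
  expect_identical(p1$truth, p2$truth)
  expect_identical(as.data.frame(p1$panel), as.data.frame(p2$panel))
  p3 <- generate_population(synthetic_config(n_individuals = 300, seed = 34))
  expect_false(identical(p1$records, p3$records))
})

test_that("default lifespan-deviation noise is negatively skewed with the calibrated moments", {
  dev <- ypllg:::rdev_noise(200000, list(mean = 5.19, sd = 20.12,
                                         median = 9.3))
  expect_lt(sample_skewness(dev), -0.5)
  expect_lt(abs(mean(dev) - 5.19), 0.2)
  expect_lt(abs(sd(dev) - 20.12), 0.2)
  expect_lt(abs(median(dev) - 9.3), 0.2)

  # and the generated population inherits the negative skew (n >= 5000)
  cfg <- synthetic_config(n_individuals = 5000, n_high_clusters = 0,
                          n_low_clusters = 0, seed = 5)
  pop <- generate_population(cfg)
  expect_lt(sample_skewness(pop$records$ypllg_true), 0)
})

test_that("neighborhood panels have valid bins, centroids, and optional missing cells", {
  cfg <- synthetic_config(n_individuals = 10, n_subsectors = 40, seed = 7)
  panel <- generate_neighborhood_panel(cfg)
  count_cols <- grep("^c_", names(panel), value = TRUE)
  expect_length(count_cols, 21)  # [0,5) ... [100,105)
  expect_true(all(as.matrix(panel[count_cols]) >= 0))
  expect_true(all(panel$median_income > 0))
  ext <- cfg$region_extent
  expect_true(all(panel$centroid_x_m >= ext[1] & panel$centroid_x_m <= ext[2]))
  expect_true(all(panel$centroid_y_m >= ext[3] & panel$centroid_y_m <= ext[4]))
  expect_identical(as.data.frame(panel),
                   as.data.frame(generate_neighborhood_panel(cfg)))

  # no missing cells -> attaching covariates never falls back
  pop <- generate_population(synthetic_config(n_individuals = 200, seed = 8,
                                              missing_cell_frac = 0))
  rec <- attach_covariates(pop$records, pop$panel)
  expect_false(any(rec$covariate_fallback))

  # blanked cells exist but every year keeps at least one donor
  cfgm <- synthetic_config(n_individuals = 10, n_subsectors = 30, seed = 9,
                           missing_cell_frac = 0.3)
  pm <- generate_neighborhood_panel(cfgm)
  expect_gt(sum(is.na(pm$median_income)), 0)
  donors <- tapply(!is.na(pm$median_income), pm$year, any)
  expect_true(all(donors))
})

test_that("synthetic files round-trip through the plain-text writers", {
  dir <- withr::local_tempdir()
  pop <- generate_population(synthetic_config(n_individuals = 50, seed = 2))
  paths <- write_synthetic(pop, dir)
  expect_true(all(file.exists(paths)))
  back <- load_records(paths[["records"]])
  expect_equal(nrow(back), 50)
  expect_identical(back$gender, pop$records$gender)
  expect_identical(back$birth_date, pop$records$birth_date)
  gj <- jsonlite::read_json(paths[["centroids"]])
  expect_identical(gj$type, "FeatureCollection")
  expect_length(gj$features, nrow(unique(pop$panel["subsector_id"])))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_individuals = 0), "at least 1")
  expect_error(synthetic_config(frac_women = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(cluster_radius_m = -5), "positive")
  expect_error(synthetic_config(skew_params = list(mean = 5, sd = 2,
                                                   median = 1)),
               "left-skewed")
  # planted centers must fit inside the region
  expect_error(generate_population(
    synthetic_config(n_individuals = 10, region_extent = c(0, 1000, 0, 1000),
                     cluster_radius_m = 900)), "too small")
})
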