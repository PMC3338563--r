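test_that("the generator is deterministic in its seed", {
  cfg <- world_config(n_countries = 5, n_crops = 5, n_staples = 1,
                      seed = 77, cells_per_country = 16, years = 1998:2002,
                      map_year = 2000)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  for (nm in c("dependency", "production", "prices", "corrections", "macro")) {
    expect_identical(w1[[nm]], w2[[nm]])
  }
  r1 <- generate_rasters(w1)
  r2 <- generate_rasters(w2)
  expect_identical(r1$stack$yield, r2$stack$yield)
  expect_identical(r1$temperature$values, r2$temperature$values)

  # identical text payloads on disk too
  f1 <- withr::local_tempfile(fileext = ".asc")
  f2 <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r1$stack$yield[[3]], f1)
  write_ascii_grid(r2$stack$yield[[3]], f2)
  expect_identical(readLines(f1), readLines(f2))

  w3 <- generate_world(world_config(n_countries = 5, n_crops = 5,
                                    n_staples = 1, seed = 78,
                                    cells_per_country = 16,
                                    years = 1998:2002, map_year = 2000))
  expect_false(identical(w1$production$quantity, w3$production$quantity))
})

test_that("every generated panel passes validation unmodified", {
  w <- generate_world(world_config(n_countries = 6, n_crops = 7,
                                   n_staples = 2, seed = 5))
  expect_silent(validate_panel(w$dependency, "dependency"))
  expect_silent(validate_panel(w$production, "production"))
  expect_silent(validate_panel(w$prices, "price"))
  expect_silent(validate_panel(w$corrections, "corrections"))
  expect_silent(validate_panel(w$macro, "macro"))
  # reference country and reference year conventions
  ref_year <- max(w$corrections$year)
  expect_true(all(w$corrections$inflation_factor[
    w$corrections$year == ref_year] == 1))
  expect_true(all(w$corrections$ppp_factor[
    w$corrections$country_id == "C001"] == 1))
})

test_that("an all-staple world produces zero benefit everywhere", {
  w <- generate_world(world_config(n_countries = 3, n_crops = 3,
                                   n_staples = 3, seed = 2,
                                   years = 1995:1999))
  aligned <- align_panels(w$production, w$prices, w$corrections,
                          w$dependency)
  expect_true(all(pollination_benefit(aligned, "upper", "global")$value == 0))
  expect_error(
    generate_world(world_config(n_countries = 3, n_crops = 3, n_staples = 3,
                                seed = 2, years = 1995:1999,
                                target_ag_dependency = 0.1)),
    "infeasible")
})

test_that("a target dependency share is recovered exactly by the pipeline", {
  w <- generate_world(world_config(n_countries = 8, n_crops = 6,
                                   n_staples = 2, seed = 31,
                                   target_ag_dependency = 0.10))
  aligned <- align_panels(w$production, w$prices, w$corrections,
                          w$dependency)
  bc <- pollination_benefit(aligned, "median", "country")
  vt <- vulnerability_table(bc, w$macro)
  national <- vt[vt$country_id != "GLOBAL", ]
  expect_equal(national$ag_gdp_dependency,
               rep(0.10, nrow(national)), tolerance = 1e-12)
  glob <- vt[vt$country_id == "GLOBAL", ]
  expect_equal(glob$ag_gdp_dependency, rep(0.10, nrow(glob)),
               tolerance = 1e-12)
})

test_that("crop rasters re-aggregate to national panel quantities", {
  cfg <- world_config(n_countries = 6, n_crops = 5, n_staples = 1,
                      seed = 13, cells_per_country = 36,
                      years = 1998:2002, map_year = 2000)
  w <- generate_world(cfg)
  r <- generate_rasters(w)
  lats <- raster_lats(r$stack$zones)
  area <- matrix(cell_area(lats, cfg$resolution),
                 length(lats), ncol(r$stack$zones$values))
  zi <- r$stack$zones$values
  for (crop in names(r$stack$yield)) {
    y <- r$stack$yield[[crop]]$values
    f <- r$stack$area_fraction[[crop]]$values
    prod <- ifelse(is.na(y) | is.na(f), 0, y * f * area)
    for (k in seq_along(r$stack$country_ids)) {
      co <- r$stack$country_ids[k]
      truth <- r$truth$national_quantity[co, crop]
      expect_equal(sum(prod[zi == k]), truth, tolerance = 1e-9)
    }
  }
})

test_that("area fractions are proper and never over-allocate a cell", {
  cfg <- world_config(n_countries = 4, n_crops = 6, n_staples = 1,
                      seed = 19, cells_per_country = 25,
                      years = 1999:2001, map_year = 2000)
  r <- generate_rasters(generate_world(cfg))
  total <- 0
  for (f in r$stack$area_fraction) {
    v <- f$values
    expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
    total <- total + ifelse(is.na(v), 0, v)
  }
  expect_true(all(total <= 1 + 1e-9))
  expect_equal(r$stack$n_overallocated, 0)
  # cropland tracks the cultivated fraction
  expect_gt(raster_correlation(r$cropland,
                               pv_raster(total, r$cropland$xll,
                                         r$cropland$yll, r$cropland$res))$r,
            0.5)
})

test_that("temperature falls away from the equator on a wide lattice", {
  # ~17 degrees of latitude so the gradient dominates the local noise
  cfg <- world_config(n_countries = 20, n_crops = 4, n_staples = 1,
                      seed = 29, cells_per_country = 100,
                      years = 1999:2001, map_year = 2000)
  r <- generate_rasters(generate_world(cfg))
  lat_m <- matrix(raster_lats(r$temperature),
                  nrow(r$temperature$values), ncol(r$temperature$values))
  expect_lt(stats::cor(abs(as.vector(lat_m)),
                       as.vector(r$temperature$values)), -0.3)
})

test_that("infeasible grids and configs are rejected", {
  expect_error(world_config(n_countries = 2, n_crops = 3, n_staples = 4),
               "n_staples")
  expect_error(world_config(beehive_trend_correlation = 1.5), "\\[-1, 1\\]")
  expect_error(world_config(target_ag_dependency = 0), "\\(0, 1\\]")
  expect_error(world_config(map_year = 1980), "map_year")
  big <- world_config(n_countries = 300, cells_per_country = 10000,
                      seed = 1)
  w <- list(production = tibble::tibble(
    country_id = sprintf("C%03d", rep(1:300, 2)),
    crop_id = "crop_01", year = 2000L, quantity = 1))
  expect_error(generate_rasters(w, big), "insufficient")
})
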