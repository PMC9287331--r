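test_that("station tables are parsed and bad rows quarantined", {
  syn <- synth_station_table(fixture_spec(seed = 5, nrow = 6, ncol = 6),
                             n_stations = 10)
  p <- file.path(tempdir(), "stations.csv")
  write.csv(syn$stations, p, row.names = FALSE)
  parsed <- read_station_table(p)
  expect_equal(nrow(parsed$stations), 10)
  expect_equal(nrow(parsed$quarantined), 0)

  # corrupt two rows: invalid latitude, missing wind month
  bad <- syn$stations
  bad$latitude[2] <- 95
  bad$wind_06[4] <- NA
  write.csv(bad, p, row.names = FALSE)
  expect_warning(parsed2 <- read_station_table(p), "quarantined")
  expect_equal(nrow(parsed2$stations), 8)
  expect_setequal(parsed2$quarantined$reason,
                  c("latitude out of range", "missing month in wind"))

  # sunshine columns are rejected outright
  sun <- cbind(syn$stations, sunshine_01 = 5)
  write.csv(sun, p, row.names = FALSE)
  expect_error(read_station_table(p), "sunshine")
})

test_that("station ET0 equals the scalar chain on the same drivers", {
  rec <- monthly_climate(latitude = 35, elev = 150,
                         tmin = rep(12, 12), tmax = rep(26, 12),
                         srad = rep(17, 12), wind = rep(2.5, 12),
                         rh = rep(55, 12))
  direct <- et0_location(rec)
  row <- data.frame(station_id = "S1", latitude = 35, longitude = 10,
                    altitude = 150)
  for (v in list(c("tmin", 12), c("tmax", 26), c("rh", 55), c("wind", 2.5),
                 c("srad", 17), c("prec", 40), c("et0", 100))) {
    vals <- matrix(as.numeric(v[2]), 1, 12)
    colnames(vals) <- paste0(v[1], "_", sprintf("%02d", 1:12))
    row <- cbind(row, vals)
  }
  row$tmin_01 <- 12; row$tmax_01 <- 26  # already set; keep the frame tidy
  via_station <- station_et0(row)
  expect_equal(via_station$et0_monthly, direct$et0_monthly)
  expect_equal(via_station$et0_annual, direct$et0_annual)
})

test_that("regression statistics match hand-computed OLS", {
  perfect <- regression_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$se, 0)
  expect_equal(perfect$bias, 0)

  offset <- regression_stats(c(11, 12, 13), c(1, 2, 3))
  expect_equal(offset$r2, 1)
  expect_equal(offset$se, 0)
  expect_equal(offset$bias, 10)

  doubled <- regression_stats(2 * c(1, 2, 3), c(1, 2, 3))
  expect_equal(doubled$slope, 2)
  expect_equal(doubled$r2, 1)
  expect_equal(doubled$bias, 2)

  # permutation invariance and bias antisymmetry
  set.seed(3)
  x <- runif(30); y <- x + rnorm(30, 0, 0.1)
  a <- regression_stats(y, x)
  perm <- sample(30)
  b <- regression_stats(y[perm], x[perm])
  expect_equal(a$r2, b$r2)
  expect_equal(a$se, b$se)
  expect_equal(a$bias, -regression_stats(x, y)$bias)

  expect_error(regression_stats(1, 1), "at least 2")
  expect_error(regression_stats(c(1, 2), c(5, 5)), "zero variance")
})

test_that("point sampling uses the containing-cell convention", {
  m <- matrix(1:12, 3, 4, byrow = TRUE)
  g <- geo_raster(m, xll = 0, yll = 0, cellsize = 1)  # top edge at 3
  # cell centres
  expect_equal(sample_grid_at_points(g, 0.5, 2.5), 1)
  expect_equal(sample_grid_at_points(g, 3.5, 0.5), 12)
  # boundary point belongs to the cell on its right ([left, right))
  expect_equal(sample_grid_at_points(g, 1, 2.5), 2)
  # nodata cell and out-of-extent point
  g$values[1, 1] <- NA
  expect_true(is.na(sample_grid_at_points(g, 0.5, 2.5)))
  expect_warning(out <- sample_grid_at_points(g, 10, 10), "outside")
  expect_true(is.na(out))
})

test_that("closed-loop validation on noise-free stations is exact", {
  syn <- synth_station_table(toy_tile_spec(), n_stations = 12)
  rep <- validate_stations(syn$stations, syn$et0$annual)
  expect_equal(rep$r2, 1)
  expect_lt(rep$se, 1e-8)
  expect_lt(abs(rep$bias), 1e-9)
  expect_equal(rep$n, 12)
})

test_that("r2 degrades monotonically as station noise grows", {
  r2_at <- function(noise) {
    syn <- synth_station_table(fixture_spec(seed = 11, nrow = 8, ncol = 8),
                               n_stations = 30, et0_noise_sd = noise)
    validate_stations(syn$stations, syn$et0$annual)$r2
  }
  r2 <- vapply(c(0, 5, 50), r2_at, 0)
  expect_true(all(diff(r2) < 0))
  expect_equal(r2[1], 1)
})

test_that("validation reports round-trip to delimited text", {
  syn <- synth_station_table(fixture_spec(seed = 2, nrow = 5, ncol = 5),
                             n_stations = 8)
  rep <- validate_stations(syn$stations, syn$et0$annual)
  p <- file.path(tempdir(), "report.csv")
  write_validation_report(rep, p)
  lines <- readLines(p)
  expect_match(lines[1], "r2=1")
  pairs <- read.csv(p, skip = 1)
  expect_equal(nrow(pairs), 8)
})
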