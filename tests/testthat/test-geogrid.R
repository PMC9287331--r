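test_that("latitude grid gives cell-centre latitudes per row", {
  g <- geo_raster(matrix(0, 4, 3), xll = 0, yll = 88, cellsize = 0.5)
  lat <- latitude_grid(g)
  expect_equal(lat[1], 89.75)
  expect_equal(diff(lat), rep(-0.5, 3))
  # an equator-crossing grid has a row centre within half a cell of 0
  eq <- geo_raster(matrix(0, 8, 2), xll = 0, yll = -2, cellsize = 0.5)
  expect_true(min(abs(latitude_grid(eq))) < 0.25 + 1e-12)
})

test_that("ascii grid I/O round-trips values and geotransform", {
  m <- matrix(runif(12), 3, 4)
  m[2, 3] <- NA
  g <- geo_raster(m, xll = -10.25, yll = 42.5, cellsize = 0.25)
  p <- file.path(tempdir(), "roundtrip.asc")
  write_ascii_grid(g, p, digits = 15)
  back <- read_ascii_grid(p)
  expect_equal(back$values, m, tolerance = 1e-12)
  expect_equal(back$xll, g$xll)
  expect_equal(back$yll, g$yll)
  expect_equal(back$cellsize, g$cellsize)
  expect_error(read_ascii_grid(file.path(tempdir(), "missing.asc")),
               "no such")
})

test_that("grid engine equals the per-cell scalar oracle bit for bit", {
  stack <- synth_climate_stack(toy_tile_spec())
  et0 <- compute_et0_grid(stack)
  oracle <- scalar_cell_oracle(stack)
  for (m in 1:12) {
    expect_identical(et0$monthly[[m]]$values, oracle[[m]])
  }
  expect_identical(et0$annual$values, Reduce(`+`, oracle))
})

test_that("blocked execution is identical to whole-array execution", {
  stack <- synth_climate_stack(toy_tile_spec())
  whole <- compute_et0_grid(stack)
  for (bs in c(1, 3, 5)) {
    blocked <- compute_et0_grid(stack, block_size = bs)
    expect_identical(blocked$annual$values, whole$annual$values)
    expect_identical(blocked$monthly[[7]]$values, whole$monthly[[7]]$values)
  }
})

test_that("nodata propagates from any input variable to all outputs", {
  stack <- synth_climate_stack(toy_tile_spec())
  stack$wind[[4]][2, 5] <- NA      # one month of wind missing
  stack$elev[6, 1] <- NA           # static layer missing
  et0 <- compute_et0_grid(stack)
  expect_true(is.na(et0$monthly[[4]]$values[2, 5]))
  expect_true(is.na(et0$annual$values[2, 5]))
  expect_true(is.na(et0$annual_sd$values[2, 5]))
  expect_true(all(is.na(vapply(1:12, function(m)
    et0$monthly[[m]]$values[6, 1], 0))))
  # other months of the wind-gap cell unaffected
  expect_false(is.na(et0$monthly[[5]]$values[2, 5]))
  expect_equal(et0$report$cells_nodata, 2)
})

test_that("uniform inputs give latitude-only structure", {
  spec <- fixture_spec(seed = 1, nrow = 6, ncol = 4, cellsize = 1,
                       yll = 30)
  stack <- synth_climate_stack(spec)
  flat <- function(x) matrix(x, 6, 4)
  uni <- climate_stack(
    tmin = rep(list(flat(10)), 12), tmax = rep(list(flat(24)), 12),
    tavg = rep(list(flat(17)), 12), srad = rep(list(flat(15)), 12),
    wind = rep(list(flat(2)), 12), vapr = rep(list(flat(1.2)), 12),
    elev = flat(100), xll = 0, yll = 30, cellsize = 1)
  et0 <- compute_et0_grid(uni)
  ann <- et0$annual$values
  # constant along rows, varying across rows (Ra depends on latitude only)
  expect_true(all(apply(ann, 1, function(r) diff(range(r))) == 0))
  expect_gt(diff(range(ann[, 1])), 0)
})

test_that("climate stacks read back from disk reproduce in-memory runs", {
  spec <- fixture_spec(seed = 9, nrow = 5, ncol = 5, cellsize = 0.5)
  stack <- synth_climate_stack(spec)
  d <- file.path(tempdir(), "fixture_stack")
  write_climate_stack(stack, d)
  back <- read_climate_stack(
    tmin = monthly_paths(d, "tmin"), tmax = monthly_paths(d, "tmax"),
    tavg = monthly_paths(d, "tavg"), srad = monthly_paths(d, "srad"),
    wind = monthly_paths(d, "wind"), vapr = monthly_paths(d, "vapr"),
    prec = monthly_paths(d, "prec"), elev = file.path(d, "elev.asc"),
    srad_unit = "kJ")
  # srad written in kJ and divided by 1000 at ingest
  expect_equal(back$srad[[6]], stack$srad[[6]], tolerance = 1e-6)
  a <- compute_et0_grid(stack)$annual$values
  b <- compute_et0_grid(back)$annual$values
  expect_equal(b, a, tolerance = 1e-5)
  # missing month is a descriptive error
  expect_error(read_climate_stack(
    tmin = monthly_paths(d, "tmin")[-3], tmax = monthly_paths(d, "tmax"),
    tavg = monthly_paths(d, "tavg"), srad = monthly_paths(d, "srad"),
    wind = monthly_paths(d, "wind"), vapr = monthly_paths(d, "vapr"),
    elev = file.path(d, "elev.asc")), "tmin.*12 monthly files")
})

test_that("aridity grids follow the nodata and encoding conventions", {
  stack <- synth_climate_stack(toy_tile_spec())
  et0 <- compute_et0_grid(stack)
  # precipitation equal to ET0 gives AI exactly 1 everywhere
  ai_one <- compute_ai_grid(lapply(et0$monthly, `[[`, "values"), et0)
  expect_true(all(ai_one$annual$values == 1))
  ai <- compute_ai_grid(stack, et0, encode = TRUE)
  expect_equal(dim(ai$annual$values), dim(stack$elev))
  ok <- !is.na(ai$annual$values)
  expect_identical(ai$annual_encoded$values[ok],
                   encode_ai(ai$annual$values[ok]))
  # zero-ET0 months become nodata in monthly AI
  et0$monthly[[1]]$values[1, 1] <- 0
  ai2 <- compute_ai_grid(stack, et0)
  expect_true(is.na(ai2$monthly[[1]]$values[1, 1]))
})

test_that("outputs are written under the distribution naming scheme", {
  stack <- synth_climate_stack(fixture_spec(seed = 3, nrow = 4, ncol = 4))
  et0 <- compute_et0_grid(stack)
  ai <- compute_ai_grid(stack, et0, encode = TRUE)
  d <- file.path(tempdir(), "dist_outputs")
  p1 <- write_outputs(et0, d)
  p2 <- write_outputs(ai, d, encoded = TRUE)
  expect_true(file.exists(file.path(d, "et0_v3_yr.asc")))
  expect_true(file.exists(file.path(d, "et0_v3_yr_sd.asc")))
  expect_true(file.exists(file.path(d, "et0_v3_02.asc")))
  expect_true(file.exists(file.path(d, "ai_v3_02.asc")))
  expect_length(p1, 14)
  expect_length(p2, 13)
  # round-trip of a written layer preserves array and geotransform
  back <- read_ascii_grid(file.path(d, "et0_v3_yr.asc"))
  expect_equal(back$values, et0$annual$values, tolerance = 1e-6)
  expect_equal(back$cellsize, stack$cellsize)
  # encoded AI is integer-valued with the integer sentinel
  enc <- read_ascii_grid(file.path(d, "ai_v3_yr.asc"))
  expect_true(all(enc$values == round(enc$values), na.rm = TRUE))
})
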