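test_that("bulk surface resistance: formula and reference override", {
  expect_equal(bulk_surface_resistance(0.12), 70)
  expect_equal(bulk_surface_resistance(0.12, reference_override = FALSE),
               100 / 1.44, tolerance = 1e-6)
  # inverse proportionality to crop height in the raw formula
  expect_equal(bulk_surface_resistance(0.24, reference_override = FALSE),
               bulk_surface_resistance(0.12, reference_override = FALSE) / 2)
  expect_error(bulk_surface_resistance(0), "> 0")
})

test_that("aerodynamic resistance is 208/u2 with a calm-wind floor", {
  expect_equal(as.numeric(aerodynamic_resistance(1)), 208)
  expect_equal(as.numeric(aerodynamic_resistance(2)), 104)
  floored <- aerodynamic_resistance(0)
  expect_equal(as.numeric(floored), 416)   # floored to 0.5 m/s
  expect_identical(attr(floored, "floored"), 1L)
  expect_error(aerodynamic_resistance(-1), ">= 0")
})

test_that("general log-profile resistance reduces to 208/u2 at reference", {
  # reference geometry: within 0.5% of the simplified constant
  expect_equal(aerodynamic_resistance_general(1, 2, 2, 0.12), 208,
               tolerance = 0.005)
  # inverse proportionality in wind speed
  expect_equal(aerodynamic_resistance_general(2, 2, 2, 0.12),
               aerodynamic_resistance_general(1, 2, 2, 0.12) / 2)
  # 10 m measurement heights (hand-evaluated log profile)
  expect_equal(aerodynamic_resistance_general(1, 10, 10, 0.12), 341.32,
               tolerance = 1e-4)
  expect_error(aerodynamic_resistance_general(1, 0.05, 0.05, 0.12),
               "displacement")
})

test_that("wind profile adjustment from 10 m matches the log factor", {
  expect_equal(wind_to_2m(3, 10), 3 * 4.87 / log(67.8 * 10 - 5.42))
  expect_equal(wind_to_2m(3, 2), 3)
})

test_that("daily ET0 reproduces the combination-equation worked value", {
  expect_equal(as.numeric(
    et0_daily(20, 2, 2.338, 1.4, 13, 0, 0.145, 0.0673)),
    4.4830, tolerance = 1e-4)
  # both numerator terms vanish
  expect_equal(as.numeric(et0_daily(20, 2, 2.0, 2.0, 0, 0, 0.145, 0.0673)),
               0)
  # strictly increasing in net radiation
  rn <- seq(0, 20, 2)
  v <- as.numeric(et0_daily(20, 2, 2.338, 1.4, rn, 0, 0.145, 0.0673))
  expect_true(all(diff(v) > 0))
  # negative raw value clamped and counted
  clamped <- et0_daily(20, 2, 2.0, 2.0, -5, 0, 0.145, 0.0673)
  expect_equal(as.numeric(clamped), 0)
  expect_identical(attr(clamped, "clamped"), 1L)
})

test_that("energy-balance form agrees with the simplified form within 2%", {
  expect_equal(et0_general(20, 2.338, 1.4, 13, 0, 0.145, 0.0673,
                           rs = 70, ra = 104),
               4.48, tolerance = 0.02)
  expect_equal(et0_general(20, 2.0, 2.0, 5, 5, 0.145, 0.0673,
                           rs = 70, ra = 104), 0)
  # decreasing in surface resistance
  v <- vapply(c(50, 70, 120, 500, 5000), function(rs)
    et0_general(20, 2.338, 1.4, 13, 0, 0.145, 0.0673, rs = rs, ra = 104), 0)
  expect_true(all(diff(v) < 0))

  # random sweep across realistic conditions
  set.seed(101)
  n <- 1000
  tavg <- runif(n, 0, 35)
  u2 <- runif(n, 0.5, 6)
  rh <- runif(n, 20, 95)
  rn <- runif(n, 0, 20)
  es <- saturation_vapour_pressure(tavg)
  ea <- rh / 100 * es
  delta <- svp_slope(tavg)
  gamma <- psychrometric_constant(101.3)
  simple <- as.numeric(et0_daily(tavg, u2, es, ea, rn, 0, delta, gamma))
  general <- et0_general(tavg, es, ea, rn, 0, delta, gamma,
                         rs = 70, ra = 208 / u2)
  keep <- simple > 0.1   # relative comparison needs a non-trivial scale
  rel <- abs(general[keep] - simple[keep]) / simple[keep]
  expect_lt(max(rel), 0.02)
})

test_that("monthly and annual aggregation conserve totals", {
  expect_equal(et0_monthly(4.48, 7), 138.88)
  expect_equal(et0_monthly(0, 2), 0)
  expect_equal(sum(et0_monthly(rep(3, 12), 1:12)), 3 * 365)
  ann <- et0_annual(rep(100, 12))
  expect_equal(ann$annual, 1200)
  expect_equal(ann$sd, 0)
  spike <- c(rep(0, 11), 1200)
  ann2 <- et0_annual(spike)
  expect_equal(ann2$annual, 1200)
  expect_equal(ann2$sd, sqrt(mean((spike - 100)^2)))
  # permutation invariance of the dispersion
  expect_equal(et0_annual(rev(spike))$sd, ann2$sd)
  # missing month propagates as nodata
  expect_true(is.na(et0_annual(c(NA, rep(100, 11)))$annual))
})

test_that("location chain aggregates the monthly scalar chain", {
  rec <- monthly_climate(latitude = 40, elev = 200,
                         tmin = rep(10, 12), tmax = rep(24, 12),
                         srad = rep(18, 12), wind = rep(2, 12),
                         rh = rep(60, 12))
  res <- et0_location(rec)
  expect_s3_class(res, "et0_result")
  expect_equal(res$et0_annual, sum(res$et0_monthly))
  expect_equal(res$et0_monthly, res$et0_daily * c(31, 28, 31, 30, 31, 30,
                                                  31, 31, 30, 31, 30, 31))
  expect_true(all(res$et0_daily >= 0))
  # saturated air all year: aerodynamic term zero, ET0 driven by Rn only
  sat <- monthly_climate(latitude = 40, elev = 200,
                         tmin = rep(10, 12), tmax = rep(24, 12),
                         srad = rep(18, 12), wind = rep(2, 12),
                         rh = rep(100, 12))
  res_sat <- et0_location(sat)
  expect_true(all(res_sat$et0_daily <= res$et0_daily))
})
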