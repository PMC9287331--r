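## Reference-crop resistances and the Penman-Monteith combination equation:
## daily ET0, monthly totals, annual aggregate.

DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Reference crop configuration
#'
#' The hypothetical well-watered grass reference surface: crop height
#' 0.12 m, albedo 0.23, bulk surface resistance fixed at 70 s m-1,
#' measurements at 2 m, soil heat flux ignored (G = 0 for monthly
#' climatology).
#'
#' @param crop_height Crop height (m).
#' @param albedo Surface albedo (fraction).
#' @param rs_bulk Bulk surface resistance (s m-1).
#' @param measurement_height Wind/humidity measurement height (m).
#' @param soil_heat_flux Soil heat flux density G (MJ m-2 day-1).
#' @return An object of class `reference_crop`.
#' @examples
#' reference_crop()
#' @export
reference_crop <- function(crop_height = 0.12, albedo = 0.23, rs_bulk = 70,
                           measurement_height = 2, soil_heat_flux = 0) {
  stopifnot(crop_height > 0, albedo >= 0, albedo <= 1, rs_bulk > 0,
            measurement_height > 0)
  structure(list(crop_height = crop_height, albedo = albedo,
                 rs_bulk = rs_bulk, measurement_height = measurement_height,
                 soil_heat_flux = soil_heat_flux),
            class = "reference_crop")
}

#' @export
print.reference_crop <- function(x, ...) {
  cat("Reference crop surface\n")
  cat(sprintf("  crop height        : %.2f m\n", x$crop_height))
  cat(sprintf("  albedo             : %.2f\n", x$albedo))
  cat(sprintf("  surface resistance : %g s/m\n", x$rs_bulk))
  cat(sprintf("  measurement height : %g m\n", x$measurement_height))
  cat(sprintf("  soil heat flux G   : %g MJ/m2/day\n", x$soil_heat_flux))
  invisible(x)
}

#' Bulk surface resistance of a short crop
#'
#' Ratio of single-leaf stomatal resistance to the active (sunlit) leaf
#' area, with LAI = 24 h for short crops and half the LAI active:
#' \deqn{r_s = \frac{r_l}{0.5 \times 24\,h}}
#' For the 0.12 m reference crop the conventional fixed value 70 s m-1 is
#' returned (the combination equation's 0.34 wind coefficient presumes it);
#' set `reference_override = FALSE` for the raw formula (69.44 at 0.12 m).
#'
#' @param crop_height Crop height h (m), positive.
#' @param stomatal_resistance Well-illuminated single-leaf stomatal
#'   resistance (s m-1), about 100 under well-watered conditions.
#' @param reference_override Return the fixed 70 s m-1 when `crop_height`
#'   is 0.12 m.
#' @return Bulk surface resistance (s m-1).
#' @examples
#' bulk_surface_resistance(0.12)                             # 70
#' bulk_surface_resistance(0.12, reference_override = FALSE) # ~69.44
#' @export
bulk_surface_resistance <- function(crop_height, stomatal_resistance = 100,
                                    reference_override = TRUE) {
  if (any(crop_height <= 0)) stop("`crop_height` must be > 0", call. = FALSE)
  rs <- stomatal_resistance / (0.5 * 24 * crop_height)
  if (reference_override) {
    rs[crop_height == 0.12 & stomatal_resistance == 100] <- 70
  }
  rs
}

#' Aerodynamic resistance for the reference surface
#'
#' For the 0.12 m grass reference with measurements at 2 m the log-profile
#' resistance collapses to \eqn{r_a = 208 / u_2}. Calm conditions are
#' floored at `u2 >= 0.5` m s-1 (the simplified form is singular at zero
#' wind); the number of floored values is returned in the `"floored"`
#' attribute.
#'
#' @param u2 Wind speed at 2 m (m s-1).
#' @param wind_floor Minimum wind speed applied before division (m s-1).
#' @return Aerodynamic resistance (s m-1) with attribute `floored`.
#' @examples
#' aerodynamic_resistance(2)  # 104
#' aerodynamic_resistance(0)  # floored to 0.5 -> 416
#' @export
aerodynamic_resistance <- function(u2, wind_floor = 0.5) {
  if (any(u2 < 0, na.rm = TRUE)) stop("`u2` must be >= 0", call. = FALSE)
  low <- !is.na(u2) & u2 < wind_floor
  u2[low] <- wind_floor
  structure(208 / u2, floored = sum(low))
}

#' Aerodynamic resistance, general log-profile form
#'
#' \deqn{r_a = \frac{\ln\!\frac{z_m - d}{z_{om}} \ln\!\frac{z_h - d}{z_{oh}}}{k^2 u_z}}
#' with zero-plane displacement \eqn{d = 2h/3}, momentum roughness length
#' \eqn{z_{om} = 0.123\,h}, heat/vapour roughness \eqn{z_{oh} = 0.1 z_{om}}
#' and von Karman's constant \eqn{k = 0.41}. At reference geometry
#' (h = 0.12 m, 2 m measurements) this reduces to 208/u2 within 0.5%.
#'
#' @param uz Wind speed at measurement height (m s-1), positive.
#' @param zm Wind measurement height (m).
#' @param zh Humidity measurement height (m).
#' @param crop_height Crop height h (m).
#' @return Aerodynamic resistance (s m-1).
#' @examples
#' aerodynamic_resistance_general(1, 2, 2, 0.12)  # ~207.7
#' @export
aerodynamic_resistance_general <- function(uz, zm = 2, zh = 2,
                                           crop_height = 0.12) {
  d <- 2 / 3 * crop_height
  zom <- 0.123 * crop_height
  zoh <- 0.1 * zom
  if (any(zm <= d) || any(zh <= d)) {
    stop("measurement heights must exceed the zero-plane displacement ",
         signif(d, 3), " m", call. = FALSE)
  }
  if (any(uz <= 0, na.rm = TRUE)) stop("`uz` must be > 0", call. = FALSE)
  k <- physical_constants()$karman
  log((zm - d) / zom) * log((zh - d) / zoh) / (k^2 * uz)
}

#' Wind speed profile adjustment to 2 m
#'
#' Converts wind measured at height z to the 2 m standard via the
#' logarithmic profile factor \eqn{u_2 = u_z\, 4.87 / \ln(67.8 z - 5.42)}.
#'
#' @param uz Wind speed at height `z` (m s-1).
#' @param z Measurement height (m), > 0.08.
#' @return Wind speed at 2 m (m s-1).
#' @examples
#' wind_to_2m(3, 10)
#' @export
wind_to_2m <- function(uz, z) {
  if (any(z <= 5.42 / 67.8)) stop("`z` too small for the log profile",
                                  call. = FALSE)
  if (isTRUE(all.equal(z, 2))) return(uz)
  uz * 4.87 / log(67.8 * z - 5.42)
}

#' Daily reference evapotranspiration (simplified combination equation)
#'
#' The reference-crop form of the Penman-Monteith combination equation:
#' \deqn{ET_0 = \frac{0.408\,\Delta (R_n - G) +
#'   \gamma \frac{900}{T_{avg} + 273} u_2 (e_s - e_a)}
#'   {\Delta + \gamma (1 + 0.34\,u_2)}}
#' where the 0.34 coefficient realises the fixed surface resistance
#' (70 s m-1) over the 208/u2 aerodynamic resistance. Negative raw values
#' (possible under net radiative loss with saturated air) are clamped to
#' zero; the count is in the `"clamped"` attribute.
#'
#' @param tavg Mean air temperature (degC).
#' @param u2 Wind speed at 2 m (m s-1), after any flooring.
#' @param es,ea Mean saturation and actual vapour pressure (kPa).
#' @param rn Net radiation (MJ m-2 day-1).
#' @param g Soil heat flux (MJ m-2 day-1), 0 for monthly climatology.
#' @param delta Slope of the saturation vapour pressure curve (kPa degC-1).
#' @param gamma Psychrometric constant (kPa degC-1).
#' @return Reference evapotranspiration (mm day-1), non-negative, with
#'   attribute `clamped` counting negatives set to zero.
#' @examples
#' et0_daily(20, 2, 2.338, 1.4, 13, 0, 0.145, 0.0673)  # ~4.48
#' @export
et0_daily <- function(tavg, u2, es, ea, rn, g = 0, delta, gamma) {
  if (any(delta <= 0, na.rm = TRUE) || any(gamma <= 0, na.rm = TRUE)) {
    stop("`delta` and `gamma` must be > 0", call. = FALSE)
  }
  num <- 0.408 * delta * (rn - g) +
    gamma * (900 / (tavg + 273)) * u2 * (es - ea)
  den <- delta + gamma * (1 + 0.34 * u2)
  raw <- num / den
  neg <- !is.na(raw) & raw < 0
  raw[neg] <- 0
  structure(raw, clamped = sum(neg))
}

#' Daily reference evapotranspiration, energy-balance form
#'
#' The full combination equation with explicit resistances and air
#' properties:
#' \deqn{ET_0 = \frac{1}{\lambda}\,
#'   \frac{\Delta (R_n - G) + 86400\,\rho_a c_p (e_s - e_a)/r_a}
#'        {\Delta + \gamma (1 + r_s / r_a)}}
#' (the 86400 converts the per-second aerodynamic flux to a daily total).
#' With the reference constants (rs = 70 s m-1, ra = 208/u2, G = 0) it
#' agrees with [et0_daily()] to within 2% — the 900/(T+273) coefficient of
#' the simplified form is a rounding of \eqn{86400\,\epsilon /
#' (1.01 R \times 208) \approx 891}.
#'
#' @inheritParams et0_daily
#' @param rs Bulk surface resistance (s m-1).
#' @param ra Aerodynamic resistance (s m-1), positive.
#' @param pressure Atmospheric pressure (kPa), used for air density.
#' @return Reference evapotranspiration (mm day-1), clamped at zero.
#' @examples
#' et0_general(20, 2.338, 1.4, 13, 0, 0.145, 0.0673, rs = 70, ra = 104)
#' @export
et0_general <- function(tavg, es, ea, rn, g = 0, delta, gamma,
                        rs = 70, ra, pressure = 101.3) {
  if (any(ra <= 0, na.rm = TRUE)) stop("`ra` must be > 0", call. = FALSE)
  if (any(rs < 0, na.rm = TRUE)) stop("`rs` must be >= 0", call. = FALSE)
  k <- physical_constants()
  rho <- air_density(pressure, tavg)
  num <- delta * (rn - g) + 86400 * rho * k$cp * (es - ea) / ra
  den <- delta + gamma * (1 + rs / ra)
  raw <- num / den / k$lambda_lh
  pmax(raw, 0)
}

#' Monthly total from a daily rate
#'
#' Multiplies a mean daily rate by the (non-leap) month length
#' `31,28,31,30,31,30,31,31,30,31,30,31`.
#'
#' @param daily Mean daily ET0 (mm day-1).
#' @param month Month number (1..12); recycled against `daily`.
#' @return Monthly total (mm month-1).
#' @examples
#' et0_monthly(4.48, 7)  # 138.88
#' @export
et0_monthly <- function(daily, month) {
  if (any(month < 1 | month > 12 | month != round(month), na.rm = TRUE)) {
    stop("`month` must be an integer in 1..12", call. = FALSE)
  }
  if (any(daily < 0, na.rm = TRUE)) stop("`daily` must be >= 0", call. = FALSE)
  daily * DAYS_IN_MONTH[month]
}

#' Annual total and dispersion of monthly totals
#'
#' Sums twelve monthly totals to the annual value and reports the
#' population standard deviation of the twelve monthly totals (the only
#' dispersion computable from 1970-2000 normals, which carry no
#' year-to-year replication).
#'
#' @param monthly Numeric vector of 12 monthly totals (mm month-1).
#' @return List with `annual` (mm yr-1) and `sd` (mm).
#' @examples
#' et0_annual(rep(100, 12))  # annual 1200, sd 0
#' @export
et0_annual <- function(monthly) {
  stopifnot(length(monthly) == 12)
  if (anyNA(monthly)) return(list(annual = NA_real_, sd = NA_real_))
  if (any(monthly < 0)) stop("monthly totals must be >= 0", call. = FALSE)
  mu <- mean(monthly)
  list(annual = sum(monthly), sd = sqrt(mean((monthly - mu)^2)))
}
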