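## The full scalar chain from monthly climate drivers to ET0. One code path
## serves scalars, station records and raster blocks: every step is
## elementwise, so grid results equal per-cell scalar results exactly.

#' One month of the ET0 scalar chain
#'
#' Applies the complete chain — atmospheric pressure, psychrometrics,
#' vapour pressures, solar geometry at the representative mid-month day,
#' radiation budget, combination equation — elementwise over its inputs
#' (scalars or equal-shape arrays).
#'
#' @param tmin,tmax,tavg Monthly minimum / maximum / mean temperature (degC).
#' @param srad Solar radiation (MJ m-2 day-1; convert kJ inputs at ingest).
#' @param wind Wind speed (m s-1) at `wind_height`.
#' @param elev Elevation (m).
#' @param latitude Latitude (decimal degrees).
#' @param month Month number (1..12), scalar.
#' @param vapr Water vapour pressure (kPa); supply exactly one of
#'   `vapr` / `rh`.
#' @param rh Relative humidity (percent).
#' @param crop A [reference_crop()] configuration.
#' @param wind_height Height of the wind measurement (m); 10 m input is
#'   converted to 2 m by the log profile.
#' @return List with `et0` (mm day-1) and the intermediate quantities
#'   (`pressure`, `gamma`, `es`, `ea`, `delta`, `ra_ext`, `rso`, `rns`,
#'   `rnl`, `rn`, `u2`), plus counters `clipped` (supersaturation),
#'   `floored` (calm wind) and `clamped` (negative ET0).
#' @export
et0_month_fields <- function(tmin, tmax, tavg, srad, wind, elev, latitude,
                             month, vapr = NULL, rh = NULL,
                             crop = reference_crop(), wind_height = 2) {
  stopifnot(length(month) == 1)
  pressure <- atmospheric_pressure(elev)
  gamma <- psychrometric_constant(pressure)
  vap <- vapour_state(tmin, tmax, tavg, rh = rh, vapr = vapr)

  u2 <- wind_to_2m(wind, wind_height)
  ra_res <- aerodynamic_resistance(u2)
  floored <- attr(ra_res, "floored")
  u2 <- pmax(u2, 0.5)

  ra_ext <- extraterrestrial_radiation(latitude, representative_day(month))
  rso <- clear_sky_radiation(ra_ext, elev)
  rns <- net_shortwave(srad, crop$albedo)
  rnl <- net_longwave(tmin, tmax, vap$ea, srad, rso)
  rn <- net_radiation(rns, rnl)

  et0 <- et0_daily(tavg, u2, vap$es, vap$ea, rn, crop$soil_heat_flux,
                   vap$delta, gamma)
  clamped <- attr(et0, "clamped")
  attributes(et0) <- attributes(tmin)   # keep matrix shape if any

  list(et0 = et0, pressure = pressure, gamma = gamma,
       es = vap$es, ea = vap$ea, delta = vap$delta,
       ra_ext = ra_ext, rso = rso, rns = rns, rnl = rnl, rn = rn, u2 = u2,
       clipped = vap$clipped, floored = floored, clamped = clamped)
}

#' Monthly climate record for one location
#'
#' Bundles the monthly climate drivers of a single location. Each monthly
#' field must have 12 values; supply exactly one of `vapr` (vapour
#' pressure, kPa) or `rh` (relative humidity, percent).
#'
#' @param latitude Latitude (decimal degrees).
#' @param elev Elevation (m).
#' @param tmin,tmax Monthly extreme temperatures (degC), length 12.
#' @param tavg Monthly mean temperature (degC); defaults to
#'   `(tmin + tmax)/2` (logged via the `tavg_fallback` field).
#' @param srad Monthly solar radiation (MJ m-2 day-1), length 12.
#' @param wind Monthly wind speed (m s-1), length 12.
#' @param vapr,rh Monthly humidity driver, length 12.
#' @param prec Monthly precipitation (mm), length 12; optional, needed for
#'   the aridity index.
#' @param wind_height Wind measurement height (m), 2 or 10.
#' @param station_id Optional identifier.
#' @return An object of class `monthly_climate`.
#' @export
monthly_climate <- function(latitude, elev, tmin, tmax, tavg = NULL,
                            srad, wind, vapr = NULL, rh = NULL,
                            prec = NULL, wind_height = 2,
                            station_id = NULL) {
  for (f in list(tmin, tmax, srad, wind)) stopifnot(length(f) == 12)
  if (is.null(vapr) == is.null(rh)) {
    stop("supply exactly one of `vapr` or `rh`", call. = FALSE)
  }
  if (abs(latitude) > 90) stop("invalid latitude", call. = FALSE)
  tavg_fallback <- is.null(tavg)
  if (tavg_fallback) tavg <- (tmin + tmax) / 2
  structure(list(latitude = latitude, elev = elev, tmin = tmin, tmax = tmax,
                 tavg = tavg, srad = srad, wind = wind, vapr = vapr, rh = rh,
                 prec = prec, wind_height = wind_height,
                 tavg_fallback = tavg_fallback, station_id = station_id),
            class = "monthly_climate")
}

#' Reference evapotranspiration for one location, all months
#'
#' Runs the scalar chain for each month of a [monthly_climate()] record and
#' aggregates: mean daily ET0 per month, monthly totals, annual total and
#' the standard deviation of the monthly totals.
#'
#' @param record A [monthly_climate()] record.
#' @param crop A [reference_crop()] configuration.
#' @return An object of class `et0_result`: list with `et0_daily` (12,
#'   mm day-1), `et0_monthly` (12, mm month-1), `et0_annual` (mm yr-1),
#'   `et0_monthly_sd` (mm) and a `report` of event counters.
#' @examples
#' rec <- monthly_climate(latitude = 40, elev = 200,
#'   tmin = rep(10, 12), tmax = rep(24, 12), srad = rep(18, 12),
#'   wind = rep(2, 12), rh = rep(60, 12))
#' et0_location(rec)
#' @export
et0_location <- function(record, crop = reference_crop()) {
  stopifnot(inherits(record, "monthly_climate"))
  daily <- numeric(12)
  counters <- c(clipped = 0L, floored = 0L, clamped = 0L)
  for (m in 1:12) {
    res <- et0_month_fields(
      tmin = record$tmin[m], tmax = record$tmax[m], tavg = record$tavg[m],
      srad = record$srad[m], wind = record$wind[m],
      elev = record$elev, latitude = record$latitude, month = m,
      vapr = if (!is.null(record$vapr)) record$vapr[m],
      rh = if (!is.null(record$rh)) record$rh[m],
      crop = crop, wind_height = record$wind_height)
    daily[m] <- res$et0
    counters <- counters +
      c(res$clipped, res$floored, res$clamped)
  }
  monthly <- et0_monthly(daily, 1:12)
  ann <- et0_annual(monthly)
  structure(list(et0_daily = daily, et0_monthly = monthly,
                 et0_annual = ann$annual, et0_monthly_sd = ann$sd,
                 report = as.list(counters),
                 station_id = record$station_id),
            class = "et0_result")
}

#' @export
print.et0_result <- function(x, ...) {
  cat("Reference evapotranspiration (FAO-56 Penman-Monteith)\n")
  if (!is.null(x$station_id)) cat("  station:", x$station_id, "\n")
  cat("  monthly totals (mm):",
      paste(sprintf("%.1f", x$et0_monthly), collapse = " "), "\n")
  cat(sprintf("  annual: %.1f mm/yr (sd of monthly totals %.1f mm)\n",
              x$et0_annual, x$et0_monthly_sd))
  ev <- unlist(x$report)
  if (any(ev > 0)) cat("  events:", paste(names(ev)[ev > 0],
                                          ev[ev > 0], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.et0_result <- function(object, ...) {
  cat(sprintf("annual ET0 %.1f mm; daily range %.2f-%.2f mm/day\n",
              object$et0_annual, min(object$et0_daily),
              max(object$et0_daily)))
  invisible(object)
}
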