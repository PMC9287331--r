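## Scalar/elementwise psychrometric primitives. All functions are vectorised
## and recycle arguments with base arithmetic, so the raster engine applies
## exactly the same arithmetic path as scalar calls.

#' Physical constants used throughout the package
#'
#' Returns the fixed physical constants of the reference-evapotranspiration
#' formulation: specific heat of moist air at constant pressure \eqn{c_p}
#' (MJ kg-1 degC-1), latent heat of vaporization \eqn{\lambda} (MJ kg-1),
#' molecular weight ratio of water vapour to dry air \eqn{\epsilon},
#' specific gas constant \eqn{R} (kJ kg-1 K-1), the Stefan-Boltzmann
#' constant \eqn{\sigma} (MJ K-4 m-2 day-1) and von Karman's constant.
#'
#' @return A named list with components `cp`, `lambda_lh`, `epsilon`,
#'   `R_spec`, `sigma`, `karman`.
#' @examples
#' physical_constants()$sigma
#' @export
physical_constants <- function() {
  list(
    cp        = 1.013e-3,
    lambda_lh = 2.45,
    epsilon   = 0.622,
    R_spec    = 0.287,
    sigma     = 4.903e-9,
    karman    = 0.41
  )
}

#' Atmospheric pressure from elevation
#'
#' Barometric formula for mean atmospheric pressure,
#' \deqn{P = 101.3 \left(\frac{293 - 0.0065\,z}{293}\right)^{5.26}}
#' with elevation \eqn{z} in metres. Strictly decreasing in elevation.
#'
#' @param elev Elevation above sea level (m). Vectorised; `NA` propagates.
#' @return Atmospheric pressure (kPa).
#' @examples
#' atmospheric_pressure(0)     # 101.3
#' atmospheric_pressure(1000)  # ~90.02
#' @export
atmospheric_pressure <- function(elev) {
  if (!is.numeric(elev)) stop("`elev` must be numeric", call. = FALSE)
  bad <- is.infinite(elev)
  if (any(bad, na.rm = TRUE)) stop("`elev` must be finite", call. = FALSE)
  out_of_range <- !is.na(elev) & (elev < -500 | elev > 9000)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " elevation value(s) outside [-500, 9000] m",
            call. = FALSE)
  }
  101.3 * ((293 - 0.0065 * elev) / 293)^5.26
}

#' Psychrometric constant
#'
#' \deqn{\gamma = \frac{c_p P}{\epsilon \lambda} = \frac{0.001013\,P}{0.622 \times 2.45}}
#' Linear in pressure, hence decreasing with elevation.
#'
#' @param pressure Atmospheric pressure (kPa), non-negative.
#' @return Psychrometric constant (kPa degC-1).
#' @examples
#' psychrometric_constant(101.3)  # ~0.0673
#' @export
psychrometric_constant <- function(pressure) {
  if (!is.numeric(pressure)) stop("`pressure` must be numeric", call. = FALSE)
  if (any(pressure < 0, na.rm = TRUE)) {
    stop("`pressure` must be >= 0 kPa", call. = FALSE)
  }
  k <- physical_constants()
  (k$cp * pressure) / (k$epsilon * k$lambda_lh)
}

#' Mean air density at constant pressure
#'
#' \deqn{\rho_a = \frac{P}{T_{Kv} R}, \qquad T_{Kv} = 1.01\,(T_{avg} + 273)}
#' with \eqn{R = 0.287} kJ kg-1 K-1. The 273 offset (not 273.15) is the
#' printed form of the virtual-temperature approximation and is kept as is.
#'
#' @param pressure Atmospheric pressure (kPa).
#' @param tavg Mean air temperature (degC), above -273.
#' @return Air density (kg m-3).
#' @examples
#' air_density(101.3, 20)  # ~1.193
#' @export
air_density <- function(pressure, tavg) {
  if (any(pressure < 0, na.rm = TRUE)) {
    stop("`pressure` must be >= 0 kPa", call. = FALSE)
  }
  if (any(tavg <= -273, na.rm = TRUE)) {
    stop("`tavg` must be > -273 degC", call. = FALSE)
  }
  k <- physical_constants()
  pressure / (1.01 * (tavg + 273) * k$R_spec)
}

#' Saturation vapour pressure at a temperature
#'
#' Tetens-type form
#' \deqn{e^\circ(T) = 0.6108 \exp\!\left(\frac{17.27\,T}{T + 237.3}\right)}
#' strictly increasing in temperature.
#'
#' @param t Air temperature (degC), above the -237.3 singularity.
#' @return Saturation vapour pressure (kPa).
#' @examples
#' saturation_vapour_pressure(0)   # 0.6108
#' saturation_vapour_pressure(20)  # ~2.338
#' @export
saturation_vapour_pressure <- function(t) {
  if (!is.numeric(t)) stop("`t` must be numeric", call. = FALSE)
  if (any(t <= -237.3, na.rm = TRUE)) {
    stop("temperature at or below the -237.3 degC singularity", call. = FALSE)
  }
  warn_temperature_range(t)
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Mean saturation vapour pressure from daily extremes
#'
#' Because the saturation curve is convex, the mean saturation vapour
#' pressure is the average of its values at the minimum and maximum
#' temperature, not its value at the mean temperature:
#' \deqn{e_s = \frac{e^\circ(T_{max}) + e^\circ(T_{min})}{2}}
#'
#' @param tmin,tmax Daily minimum and maximum temperature (degC), `tmin <= tmax`.
#' @return Mean saturation vapour pressure (kPa).
#' @examples
#' mean_saturation_vp(15, 25)  # ~2.437
#' @export
mean_saturation_vp <- function(tmin, tmax) {
  if (any(tmin > tmax, na.rm = TRUE)) {
    stop("`tmin` must not exceed `tmax`", call. = FALSE)
  }
  (saturation_vapour_pressure(tmax) + saturation_vapour_pressure(tmin)) / 2
}

#' Actual vapour pressure from relative humidity or a vapour-pressure input
#'
#' With relative humidity, \eqn{e_a = RH/100 \cdot e_s}; with a directly
#' measured/gridded water vapour pressure, the value is passed through.
#' Either way the result is clipped to at most \eqn{e_s}, so the vapour
#' pressure deficit stays non-negative even when independently interpolated
#' vapour-pressure and temperature grids disagree; the number of clipped
#' values is returned in the `"clipped"` attribute.
#'
#' @param es Mean saturation vapour pressure (kPa).
#' @param rh Relative humidity (percent, 0-100). Supply exactly one of
#'   `rh` / `vapr`.
#' @param vapr Actual water vapour pressure (kPa).
#' @return Actual vapour pressure (kPa), `<= es`, with attribute `clipped`
#'   counting supersaturated inputs that were clipped.
#' @examples
#' actual_vapour_pressure(2.338, rh = 50)
#' actual_vapour_pressure(2.0, vapr = 2.4)  # clipped to 2.0
#' @export
actual_vapour_pressure <- function(es, rh = NULL, vapr = NULL) {
  if (is.null(rh) == is.null(vapr)) {
    stop("supply exactly one of `rh` or `vapr`", call. = FALSE)
  }
  if (!is.null(rh)) {
    if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
      stop("`rh` must lie in [0, 100] percent", call. = FALSE)
    }
    ea <- rh / 100 * es
  } else {
    if (any(vapr < 0, na.rm = TRUE)) {
      stop("`vapr` must be >= 0 kPa", call. = FALSE)
    }
    ea <- vapr + 0 * es   # recycle to common shape
  }
  over <- !is.na(ea) & !is.na(es) & ea > es
  ea[over] <- es[over]
  structure(ea, clipped = sum(over))
}

#' Slope of the saturation vapour pressure curve
#'
#' Analytic derivative of the saturation curve at the mean temperature:
#' \deqn{\Delta = \frac{4098 \times 0.6108 \exp\!\left(\frac{17.27\,T}{T+237.3}\right)}{(T + 237.3)^2}}
#'
#' @param tavg Mean air temperature (degC).
#' @return Slope \eqn{\Delta} (kPa degC-1), strictly positive.
#' @examples
#' svp_slope(20)  # ~0.1447
#' @export
svp_slope <- function(tavg) {
  if (any(tavg <= -237.3, na.rm = TRUE)) {
    stop("temperature at or below the -237.3 degC singularity", call. = FALSE)
  }
  4098 * 0.6108 * exp(17.27 * tavg / (tavg + 237.3)) / (tavg + 237.3)^2
}

#' Vapour state (es, ea, deficit, slope) for one set of drivers
#'
#' Convenience bundle of the four vapour-pressure quantities the combination
#' equation needs.
#'
#' @inheritParams mean_saturation_vp
#' @param tavg Mean air temperature (degC); defaults to `(tmin + tmax)/2`.
#' @inheritParams actual_vapour_pressure
#' @return List with `es`, `ea`, `vpd`, `delta` and a `clipped` count.
#' @export
vapour_state <- function(tmin, tmax, tavg = (tmin + tmax) / 2,
                         rh = NULL, vapr = NULL) {
  es <- mean_saturation_vp(tmin, tmax)
  ea <- actual_vapour_pressure(es, rh = rh, vapr = vapr)
  clipped <- attr(ea, "clipped")
  attributes(ea) <- NULL
  list(es = es, ea = ea, vpd = es - ea, delta = svp_slope(tavg),
       clipped = clipped)
}

# warn (once per call) for temperatures far outside the climatological range
warn_temperature_range <- function(t) {
  out <- !is.na(t) & (t < -60 | t > 60)
  if (any(out)) {
    warning(sum(out), " temperature value(s) outside [-60, 60] degC",
            call. = FALSE)
  }
  invisible(NULL)
}
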