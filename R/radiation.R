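## Daily radiation budget: extraterrestrial and clear-sky solar radiation,
## net shortwave/longwave balance. Vectorised over locations.

#' Extraterrestrial radiation for a day of year and latitude
#'
#' Daily solar radiation at the top of the atmosphere from the solar
#' constant, inverse relative Earth-Sun distance, solar declination and
#' sunset hour angle:
#' \deqn{R_a = \frac{24 \times 60}{\pi} G_{sc} d_r
#'   \left[\omega_s \sin\varphi \sin\delta +
#'         \cos\varphi \cos\delta \sin\omega_s\right]}
#' with \eqn{G_{sc} = 0.0820} MJ m-2 min-1,
#' \eqn{d_r = 1 + 0.033\cos(2\pi J/365)},
#' \eqn{\delta = 0.409\sin(2\pi J/365 - 1.39)} and
#' \eqn{\omega_s = \arccos(-\tan\varphi\tan\delta)} with the argument
#' clamped to \eqn{[-1, 1]} so polar day and polar night are handled
#' (polar night gives \eqn{R_a = 0}).
#'
#' @param latitude Latitude (decimal degrees, -90..90). Vectorised.
#' @param day_of_year Julian day (1..366).
#' @return Extraterrestrial radiation (MJ m-2 day-1), non-negative.
#' @examples
#' extraterrestrial_radiation(0, 80)    # ~37.8 at the equator near equinox
#' extraterrestrial_radiation(80, 355)  # 0 (polar night)
#' @export
extraterrestrial_radiation <- function(latitude, day_of_year) {
  if (any(latitude < -90 | latitude > 90, na.rm = TRUE)) {
    stop("`latitude` must lie in [-90, 90] degrees", call. = FALSE)
  }
  if (any(day_of_year < 1 | day_of_year > 366, na.rm = TRUE)) {
    stop("`day_of_year` must lie in 1..366", call. = FALSE)
  }
  gsc <- 0.0820                       # MJ m-2 min-1
  phi <- latitude * pi / 180
  j <- 2 * pi * day_of_year / 365
  dr <- 1 + 0.033 * cos(j)
  delta <- 0.409 * sin(j - 1.39)
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  ws <- acos(x)
  ra <- (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  pmax(ra, 0)
}

#' Representative day of year for a month
#'
#' Monthly climatologies need one Julian day per month at which to evaluate
#' the solar geometry; the standard mid-month day is
#' \eqn{J = \mathrm{round}(30.4\,m - 15)}.
#'
#' @param month Month number (1..12).
#' @return Integer day of year, strictly increasing in month.
#' @examples
#' representative_day(1)   # 15
#' representative_day(7)   # 198
#' @export
representative_day <- function(month) {
  if (any(month < 1 | month > 12 | month != round(month), na.rm = TRUE)) {
    stop("`month` must be an integer in 1..12", call. = FALSE)
  }
  as.integer(round(30.4 * month - 15))
}

#' Clear-sky solar radiation
#'
#' \deqn{R_{so} = R_a (0.75 + 2\times 10^{-5}\, z)}
#' with elevation \eqn{z} in metres.
#'
#' @param ra Extraterrestrial radiation (MJ m-2 day-1), non-negative.
#' @param elev Elevation (m).
#' @return Clear-sky radiation (MJ m-2 day-1).
#' @examples
#' clear_sky_radiation(30, 0)     # 22.5
#' clear_sky_radiation(30, 2000)  # 23.7
#' @export
clear_sky_radiation <- function(ra, elev) {
  if (any(ra < 0, na.rm = TRUE)) stop("`ra` must be >= 0", call. = FALSE)
  ra * (0.75 + 2e-5 * elev)
}

#' Net shortwave radiation
#'
#' Fraction of incoming solar radiation not reflected by the surface:
#' \deqn{R_{ns} = (1 - \alpha) R_s} with albedo \eqn{\alpha = 0.23} for the
#' green grass reference crop.
#'
#' @param rs Incoming solar radiation (MJ m-2 day-1).
#' @param albedo Surface albedo (fraction in [0, 1]).
#' @return Net shortwave radiation (MJ m-2 day-1).
#' @examples
#' net_shortwave(20)  # 15.4
#' @export
net_shortwave <- function(rs, albedo = 0.23) {
  if (any(rs < 0, na.rm = TRUE)) stop("`rs` must be >= 0", call. = FALSE)
  if (any(albedo < 0 | albedo > 1, na.rm = TRUE)) {
    stop("`albedo` must lie in [0, 1]", call. = FALSE)
  }
  rs * (1 - albedo)
}

#' Net longwave radiation
#'
#' Stefan-Boltzmann emission at the mean fourth power of the daily extreme
#' temperatures, modulated by humidity and cloudiness:
#' \deqn{R_{nl} = \sigma\,\frac{T_{max,K}^4 + T_{min,K}^4}{2}
#'   \,(0.34 - 0.14\sqrt{e_a})
#'   \,\left(1.35\,\frac{R_s}{R_{so}} - 0.35\right)}
#' with temperatures in Kelvin (K = degC + 273.16). The relative shortwave
#' ratio \eqn{R_s/R_{so}} is clamped to at most 1 (no super-clear-sky) and,
#' where both \eqn{R_s} and \eqn{R_{so}} are zero (polar night), replaced by
#' 0.5, the conventional mid value for unobservable cloudiness. \eqn{R_{so}=0}
#' with \eqn{R_s>0} is physically inconsistent and yields `NA`.
#'
#' @param tmin,tmax Daily extreme temperatures (degC).
#' @param ea Actual vapour pressure (kPa).
#' @param rs Measured solar radiation (MJ m-2 day-1).
#' @param rso Clear-sky radiation (MJ m-2 day-1).
#' @return Net longwave radiation (MJ m-2 day-1); positive values are an
#'   energy loss from the surface.
#' @examples
#' net_longwave(20, 30, 2.0, 25, 30)  # ~4.27
#' @export
net_longwave <- function(tmin, tmax, ea, rs, rso) {
  if (any(tmin > tmax, na.rm = TRUE)) {
    stop("`tmin` must not exceed `tmax`", call. = FALSE)
  }
  if (any(ea < 0, na.rm = TRUE)) stop("`ea` must be >= 0", call. = FALSE)
  sigma <- physical_constants()$sigma
  tkx <- tmax + 273.16
  tkn <- tmin + 273.16
  ratio <- rs / rso
  both_zero <- !is.na(rs) & !is.na(rso) & rso <= 0 & rs <= 0
  ratio[both_zero] <- 0.5
  invalid <- !is.na(rs) & !is.na(rso) & rso <= 0 & rs > 0
  ratio[invalid] <- NA_real_
  ratio <- pmin(ratio, 1)
  sigma * ((tkx^4 + tkn^4) / 2) * (0.34 - 0.14 * sqrt(ea)) *
    (1.35 * ratio - 0.35)
}

#' Net radiation at the crop surface
#'
#' \deqn{R_n = R_{ns} - R_{nl}}; may be negative (net energy loss), in which
#' case the downstream reference evapotranspiration is clamped, not the
#' radiation itself.
#'
#' @param rns Net shortwave radiation (MJ m-2 day-1).
#' @param rnl Net longwave radiation (MJ m-2 day-1).
#' @return Net radiation (MJ m-2 day-1).
#' @export
net_radiation <- function(rns, rnl) rns - rnl

#' Monthly radiation budget for a location
#'
#' Computes the full radiation chain for a single location and all 12
#' months: extraterrestrial radiation at the representative mid-month day,
#' clear-sky radiation, net shortwave and net longwave, and net radiation.
#'
#' @param latitude Latitude (decimal degrees).
#' @param elev Elevation (m).
#' @param tmin,tmax Length-12 monthly extreme temperatures (degC).
#' @param ea Length-12 actual vapour pressure (kPa).
#' @param rs Length-12 solar radiation (MJ m-2 day-1).
#' @param albedo Reference surface albedo.
#' @return A `radiation_budget` data frame with one row per month and
#'   columns `month`, `ra`, `rso`, `rs`, `rns`, `rnl`, `rn`.
#' @export
radiation_budget <- function(latitude, elev, tmin, tmax, ea, rs,
                             albedo = 0.23) {
  stopifnot(length(tmin) == 12, length(tmax) == 12,
            length(ea) == 12, length(rs) == 12)
  m <- 1:12
  ra <- extraterrestrial_radiation(latitude, representative_day(m))
  rso <- clear_sky_radiation(ra, elev)
  rns <- net_shortwave(rs, albedo)
  rnl <- net_longwave(tmin, tmax, ea, rs, rso)
  out <- data.frame(month = m, ra = ra, rso = rso, rs = rs,
                    rns = rns, rnl = rnl, rn = net_radiation(rns, rnl))
  class(out) <- c("radiation_budget", "data.frame")
  out
}
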