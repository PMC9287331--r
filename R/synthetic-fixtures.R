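## Deterministic synthetic climate fixtures: physically plausible monthly
## climate stacks and station tables, so the whole pipeline is testable
## without any data download. Same (seed, spec) -> identical output.

#' Specification of a synthetic climate fixture
#'
#' Parameters of the synthetic climate generator. The climate profile is a
#' smooth latitudinal model: mean annual temperature falls with latitude
#' (0.6 degC per degree) and elevation (6.5 degC km-1 lapse), the seasonal
#' cycle grows with latitude and is phase-shifted six months between
#' hemispheres, solar radiation is a cloudiness fraction of the module's
#' own clear-sky radiation, vapour pressure is a humidity fraction of
#' saturation at the minimum temperature (so no supersaturation at zero
#' noise), and precipitation follows a wet-equator/dry-subtropics profile.
#' `noise_sd` adds Gaussian perturbations per variable.
#'
#' @param seed Integer seed; the generator is a deterministic function of
#'   `(seed, spec)`.
#' @param nrow,ncol Grid shape.
#' @param cellsize Cell size (decimal degrees).
#' @param xll,yll Lower-left grid corner (decimal degrees).
#' @param cloud_range Range of the solar-radiation fraction of clear-sky
#'   radiation; keep the upper end at or below 1 unless deliberately
#'   stressing the cloudiness-ratio clamp.
#' @param humidity_range Range of the vapour-pressure fraction of
#'   saturation at `tmin`.
#' @param wind_range Range of mean wind speeds (m s-1).
#' @param diurnal_range Mean diurnal temperature range (degC).
#' @param noise_sd Named numeric vector of perturbation scales for
#'   `tavg` (degC), `wind` (m s-1), `vapr` (kPa), `prec` (mm).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42, nrow = 8, ncol = 8, cellsize = 0.5,
                         xll = 5, yll = 38,
                         cloud_range = c(0.3, 0.8),
                         humidity_range = c(0.45, 0.95),
                         wind_range = c(1, 5),
                         diurnal_range = 10,
                         noise_sd = c(tavg = 0, wind = 0, vapr = 0,
                                      prec = 0)) {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  ns <- c(tavg = 0, wind = 0, vapr = 0, prec = 0)
  ns[names(noise_sd)] <- noise_sd
  structure(list(seed = seed, nrow = nrow, ncol = ncol,
                 cellsize = cellsize, xll = xll, yll = yll,
                 cloud_range = cloud_range,
                 humidity_range = humidity_range,
                 wind_range = wind_range, diurnal_range = diurnal_range,
                 noise_sd = ns),
            class = "fixture_spec")
}

#' The canonical 8 x 8 toy tile
#'
#' The documented fixture used across the test-suite: 8 x 8 cells of 0.5
#' degrees, seed 42, mid-latitude northern-hemisphere corner.
#'
#' @return A [fixture_spec()].
#' @export
toy_tile_spec <- function() fixture_spec(seed = 42, nrow = 8, ncol = 8,
                                         cellsize = 0.5, xll = 5, yll = 38)

#' Generate a synthetic monthly climate stack
#'
#' Deterministically builds a [climate_stack()] from a [fixture_spec()].
#' At zero noise the stack satisfies every precondition of the raster
#' engine by construction: `tmax >= tavg >= tmin` everywhere, solar
#' radiation within the clear-sky envelope, no supersaturation, wind
#' non-negative, and seasonal cycles phase-shifted across hemispheres.
#'
#' @param spec A [fixture_spec()].
#' @return A [climate_stack()] including precipitation.
#' @examples
#' stack <- synth_climate_stack(toy_tile_spec())
#' @export
synth_climate_stack <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  nr <- spec$nrow; nc <- spec$ncol
  top <- spec$yll + nr * spec$cellsize
  lat <- top - (seq_len(nr) - 0.5) * spec$cellsize
  latm <- matrix(lat, nr, nc)
  lon <- spec$xll + (seq_len(nc) - 0.5) * spec$cellsize
  lonm <- matrix(lon, nr, nc, byrow = TRUE)

  # smooth elevation: gentle ridge, always non-negative
  elev <- 300 + 250 * sin(lonm / 7) * cos(latm / 9) +
    matrix(stats::runif(nr * nc, 0, 150), nr, nc)
  elev <- pmax(elev, 0)

  base_t <- 28 - 0.6 * abs(latm) - 0.0065 * elev
  amp <- 2 + 0.35 * abs(latm)
  peak <- ifelse(latm >= 0, 7, 1)          # warmest month by hemisphere
  cloud <- matrix(stats::runif(nr * nc, spec$cloud_range[1],
                               spec$cloud_range[2]), nr, nc)
  humid <- matrix(stats::runif(nr * nc, spec$humidity_range[1],
                               spec$humidity_range[2]), nr, nc)
  wind_mean <- matrix(stats::runif(nr * nc, spec$wind_range[1],
                                   spec$wind_range[2]), nr, nc)
  prec_base <- pmax(1200 * exp(-((abs(latm) - 0) / 40)^2) -
                      500 * exp(-((abs(latm) - 25) / 12)^2), 30) / 12

  mk <- function() vector("list", 12)
  tmin <- mk(); tmax <- mk(); tavg <- mk(); srad <- mk()
  wind <- mk(); vapr <- mk(); prec <- mk()
  ns <- spec$noise_sd
  for (m in 1:12) {
    season <- cos(2 * pi * (m - peak) / 12)
    ta <- base_t + amp * season +
      matrix(stats::rnorm(nr * nc, 0, ns[["tavg"]]), nr, nc)
    half <- spec$diurnal_range / 2
    tavg[[m]] <- ta
    tmin[[m]] <- ta - half
    tmax[[m]] <- ta + half

    ra <- extraterrestrial_radiation(latm, representative_day(m))
    rso <- clear_sky_radiation(ra, elev)
    srad[[m]] <- cloud * rso

    w <- wind_mean + matrix(stats::rnorm(nr * nc, 0, ns[["wind"]]), nr, nc)
    wind[[m]] <- pmax(w, 0)

    vp <- humid * saturation_vapour_pressure(tmin[[m]]) +
      matrix(stats::rnorm(nr * nc, 0, ns[["vapr"]]), nr, nc)
    vapr[[m]] <- pmax(vp, 0)

    pr <- prec_base * (1 + 0.5 * season) +
      matrix(stats::rnorm(nr * nc, 0, ns[["prec"]]), nr, nc)
    prec[[m]] <- pmax(pr, 0)
  }
  climate_stack(tmin = tmin, tmax = tmax, tavg = tavg, srad = srad,
                wind = wind, vapr = vapr, prec = prec, elev = elev,
                xll = spec$xll, yll = spec$yll, cellsize = spec$cellsize)
}

#' Generate a synthetic station table with known ET0 truth
#'
#' Samples `n_stations` distinct cell centres of the synthetic stack of
#' `spec`, runs the ET0 grid over the stack, and emits a station table in
#' the [read_station_table()] schema whose reported monthly ET0 columns
#' hold the scalar-chain values for those cells (perturbed by
#' `et0_noise_sd` if requested). Relative humidity is back-derived from the
#' stack's vapour pressure so the humidity route reproduces the gridded
#' vapour pressure. Closed-loop validation of the grid against these
#' stations at zero noise is therefore exact by construction.
#'
#' @param spec A [fixture_spec()].
#' @param n_stations Number of stations (at most the number of grid cells).
#' @param et0_noise_sd Gaussian perturbation (mm month-1) added to the
#'   reported monthly ET0 columns.
#' @return List with `stations` (data frame), `truth` (the unperturbed
#'   monthly ET0 matrix, stations x 12) and `stack` / `et0` (the
#'   underlying stack and `et0_grid`).
#' @export
synth_station_table <- function(spec, n_stations = 10, et0_noise_sd = 0) {
  stopifnot(n_stations >= 1)
  stack <- synth_climate_stack(spec)
  if (n_stations > spec$nrow * spec$ncol) {
    stop("n_stations exceeds the number of grid cells", call. = FALSE)
  }
  et0 <- compute_et0_grid(stack)
  set.seed(spec$seed + 1L)
  cells <- sample(spec$nrow * spec$ncol, n_stations)
  row <- ((cells - 1) %% spec$nrow) + 1
  col <- ((cells - 1) %/% spec$nrow) + 1
  top <- spec$yll + spec$nrow * spec$cellsize
  lat <- top - (row - 0.5) * spec$cellsize
  lon <- spec$xll + (col - 0.5) * spec$cellsize

  at <- function(layers) {
    out <- sapply(1:12, function(m) layers[[m]][cbind(row, col)])
    matrix(out, nrow = n_stations, ncol = 12)
  }
  es <- (saturation_vapour_pressure(at(stack$tmax)) +
           saturation_vapour_pressure(at(stack$tmin))) / 2
  rh <- pmin(100 * at(stack$vapr) / es, 100)
  truth <- at(lapply(et0$monthly, `[[`, "values"))
  reported <- truth
  if (et0_noise_sd > 0) {
    reported <- reported +
      matrix(stats::rnorm(length(truth), 0, et0_noise_sd), nrow(truth))
    reported <- pmax(reported, 0)
  }
  df <- data.frame(station_id = sprintf("SYN%03d", seq_len(n_stations)),
                   latitude = lat, longitude = lon,
                   altitude = stack$elev[cbind(row, col)])
  put <- function(var, vals) {
    colnames(vals) <- station_monthly_cols(var)
    cbind(df, vals)
  }
  df <- put("tmin", at(stack$tmin))
  df <- put("tmax", at(stack$tmax))
  df <- put("rh", rh)
  df <- put("wind", at(stack$wind))
  df <- put("srad", at(stack$srad))
  df <- put("prec", at(stack$prec))
  df <- put("et0", reported)
  list(stations = df, truth = truth, stack = stack, et0 = et0)
}

#' Write a climate stack as raster fixture files
#'
#' Writes the stack under the on-disk layout [read_climate_stack()]
#' expects: `<var>_01.asc` ... `<var>_12.asc` per variable plus
#' `elev.asc`. Solar radiation is written in kJ m-2 day-1 (the
#' WorldClim convention), i.e. multiplied by 1000 on the way out.
#'
#' @param stack A [climate_stack()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_climate_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mk <- function(v) geo_raster(v, stack$xll, stack$yll, stack$cellsize)
  for (var in c("tmin", "tmax", "tavg", "srad", "wind", "vapr", "prec")) {
    if (is.null(stack[[var]])) next
    for (m in 1:12) {
      v <- stack[[var]][[m]]
      if (var == "srad") v <- v * 1000
      write_ascii_grid(mk(v), file.path(dir, sprintf("%s_%02d.asc", var, m)))
    }
  }
  write_ascii_grid(mk(stack$elev), file.path(dir, "elev.asc"))
  invisible(dir)
}
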