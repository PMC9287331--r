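# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Daily extraterrestrial radiation by brute-force minute-by-minute
# integration of the instantaneous top-of-atmosphere flux.
ra_integration_oracle <- function(latitude, day_of_year) {
  gsc <- 0.0820                       # MJ m-2 min-1
  phi <- latitude * pi / 180
  j <- 2 * pi * day_of_year / 365
  dr <- 1 + 0.033 * cos(j)
  delta <- 0.409 * sin(j - 1.39)
  minutes <- seq(0.5, 1439.5, by = 1)
  omega <- pi / 720 * (minutes - 720)   # hour angle, solar noon at 720 min
  cosz <- sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(omega)
  gsc * dr * sum(pmax(cosz, 0))
}

# Per-cell scalar evaluation of a climate stack: loops cells one by one
# through the scalar chain (the grid engine must match this exactly).
scalar_cell_oracle <- function(stack, crop = reference_crop()) {
  shape <- dim(stack$elev)
  lat <- latitude_grid(geo_raster(stack$elev, stack$xll, stack$yll,
                                  stack$cellsize))
  monthly <- lapply(1:12, function(m) matrix(NA_real_, shape[1], shape[2]))
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      for (m in 1:12) {
        res <- et0_month_fields(
          tmin = stack$tmin[[m]][i, j], tmax = stack$tmax[[m]][i, j],
          tavg = stack$tavg[[m]][i, j], srad = stack$srad[[m]][i, j],
          wind = stack$wind[[m]][i, j], elev = stack$elev[i, j],
          latitude = lat[i], month = m, vapr = stack$vapr[[m]][i, j],
          crop = crop, wind_height = stack$wind_height)
        monthly[[m]][i, j] <- res$et0 * c(31, 28, 31, 30, 31, 30,
                                          31, 31, 30, 31, 30, 31)[m]
      }
    }
  }
  monthly
}
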