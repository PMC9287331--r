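## Station-table ingestion, per-station ET0, and grid-versus-station
## validation statistics (r2, standard error of estimate, bias).

STATION_MONTHLY_VARS <- c("tmin", "tmax", "rh", "wind", "srad", "prec",
                          "et0")

station_monthly_cols <- function(var) paste0(var, "_", MONTH_SUFFIX)

#' Read a station table
#'
#' Parses a delimited table of long-term monthly station normals, one row
#' per station: `station_id`, `latitude`, `longitude`, `altitude`, then
#' twelve monthly columns per variable (`tmin_01..tmin_12`, `tmax_*`,
#' `rh_*` (percent), `wind_*` (m s-1), `srad_*` (MJ m-2 day-1), `prec_*`
#' (mm) and the station-reported `et0_*` (mm month-1)). Rows failing range
#' checks (coordinates, RH bounds, tmin > tmax) or with missing monthly
#' values are quarantined with reasons rather than dropped silently.
#' Sunshine-hours columns are rejected: converting sunshine duration to
#' solar radiation is out of scope, supply radiation directly.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default comma).
#' @return List with `stations` (data frame of valid rows) and
#'   `quarantined` (data frame with a `reason` column). A warning reports
#'   quarantined rows.
#' @export
read_station_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  if (any(grepl("^sunshine", names(df)))) {
    stop("table carries sunshine-hours columns; supply solar radiation ",
         "(srad_01..srad_12, MJ m-2 day-1) instead", call. = FALSE)
  }
  need <- c("station_id", "latitude", "longitude", "altitude",
            unlist(lapply(STATION_MONTHLY_VARS, station_monthly_cols)))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("station table missing column(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...", call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    reason[bad & is.na(reason)] <<- why
  }
  flag(is.na(df$latitude) | abs(df$latitude) > 90, "latitude out of range")
  flag(is.na(df$longitude) | abs(df$longitude) > 180,
       "longitude out of range")
  flag(is.na(df$altitude) | df$altitude < -500 | df$altitude > 9000,
       "altitude out of range")
  for (v in STATION_MONTHLY_VARS) {
    cols <- station_monthly_cols(v)
    flag(rowSums(is.na(df[cols])) > 0, paste0("missing month in ", v))
  }
  rh <- as.matrix(df[station_monthly_cols("rh")])
  flag(rowSums(rh < 0 | rh > 100, na.rm = TRUE) > 0 & is.na(reason),
       "relative humidity outside [0, 100]")
  tn <- as.matrix(df[station_monthly_cols("tmin")])
  tx <- as.matrix(df[station_monthly_cols("tmax")])
  flag(rowSums(tn > tx, na.rm = TRUE) > 0, "tmin exceeds tmax")
  bad <- !is.na(reason)
  if (any(bad)) {
    warning(sum(bad), " station row(s) quarantined (",
            paste(unique(reason[bad]), collapse = "; "), ")",
            call. = FALSE)
  }
  list(stations = df[!bad, , drop = FALSE],
       quarantined = cbind(df[bad, , drop = FALSE],
                           reason = reason[bad]))
}

# one station row -> monthly_climate record
station_record <- function(row) {
  g <- function(v) as.numeric(unlist(row[station_monthly_cols(v)]))
  monthly_climate(latitude = as.numeric(row[["latitude"]]),
                  elev = as.numeric(row[["altitude"]]),
                  tmin = g("tmin"), tmax = g("tmax"),
                  srad = g("srad"), wind = g("wind"), rh = g("rh"),
                  prec = g("prec"),
                  station_id = as.character(row[["station_id"]]))
}

#' Reference evapotranspiration at a station
#'
#' Runs the same scalar chain used by the raster engine on one station row
#' (as returned by [read_station_table()]), with actual vapour pressure
#' derived from relative humidity and extraterrestrial radiation from the
#' station latitude.
#'
#' @param row One-row data frame (or list) with the station-table columns.
#' @param crop A [reference_crop()] configuration.
#' @return An `et0_result` (see [et0_location()]).
#' @export
station_et0 <- function(row, crop = reference_crop()) {
  et0_location(station_record(row), crop = crop)
}

#' Regression statistics between two paired samples
#'
#' Ordinary least squares of `model` on `reference`, reporting the fitted
#' slope and intercept, the coefficient of determination r2 (squared
#' Pearson correlation), the standard error of estimate
#' \eqn{\sqrt{\sum e_i^2 / (n-2)}}, and the bias
#' `mean(model - reference)`.
#'
#' @param model Model-derived values (e.g. grid-sampled ET0).
#' @param reference Reference values (e.g. station-reported ET0).
#' @return An object of class `validation_report`: list with `n`, `slope`,
#'   `intercept`, `r2`, `se`, `bias`.
#' @examples
#' regression_stats(c(1, 2, 3) * 2, c(1, 2, 3))
#' @export
regression_stats <- function(model, reference) {
  ok <- is.finite(model) & is.finite(reference)
  model <- model[ok]; reference <- reference[ok]
  n <- length(model)
  if (n < 2) stop("need at least 2 paired finite values", call. = FALSE)
  if (stats::var(reference) == 0) {
    stop("reference values have zero variance", call. = FALSE)
  }
  fit <- stats::lm(model ~ reference)
  resid <- stats::residuals(fit)
  r <- stats::cor(model, reference)
  structure(list(n = n,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r^2,
                 se = sqrt(sum(resid^2) / (n - 2)),
                 bias = mean(model - reference)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation regression (model ~ reference)\n")
  cat(sprintf("  n = %d\n", x$n))
  cat(sprintf("  slope %.4f, intercept %.4f\n", x$slope, x$intercept))
  cat(sprintf("  r2 = %.4f, SE = %.4f, bias = %.4f\n",
              x$r2, x$se, x$bias))
  invisible(x)
}

#' Validate a gridded product against station values
#'
#' Samples an annual (or monthly) raster at the station coordinates and
#' regresses the sampled values against a station-reported column. The
#' default compares annual grid ET0 with the sum of the stations' reported
#' monthly ET0.
#'
#' @param stations Data frame of valid station rows
#'   (see [read_station_table()]).
#' @param grid A [geo_raster()] to sample (e.g. `et0_grid$annual`).
#' @param reference Reference values per station; defaults to the row sums
#'   of the `et0_01..et0_12` columns.
#' @return A `validation_report` with an added `pairs` data frame
#'   (`station_id`, `model`, `reference`).
#' @export
validate_stations <- function(stations, grid, reference = NULL) {
  if (is.null(reference)) {
    reference <- rowSums(stations[station_monthly_cols("et0")])
  }
  model <- sample_grid_at_points(grid, stations$longitude,
                                 stations$latitude)
  rep <- regression_stats(model, reference)
  rep$pairs <- data.frame(station_id = stations$station_id,
                          model = model, reference = reference)
  rep
}

#' Write a validation report as delimited text
#'
#' @param report A `validation_report` from [validate_stations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# n=%d slope=%.6g intercept=%.6g r2=%.6g se=%.6g bias=%.6g",
                 report$n, report$slope, report$intercept, report$r2,
                 report$se, report$bias)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(report$pairs, con, row.names = FALSE)
  invisible(path)
}
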