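## Raster engine: monthly climate stacks in, ET0 / AI rasters out.
## Processing is block-streamed over rows; because every step of the scalar
## chain is elementwise, blocked and whole-array runs are identical and each
## cell equals the scalar chain applied to that cell's values.

MONTH_SUFFIX <- sprintf("%02d", 1:12)

#' Monthly climate raster stack
#'
#' Bundles the seven climate drivers as aligned monthly rasters plus a
#' static elevation layer. Monthly variables are lists of 12 matrices
#' (row 1 north); all layers must share shape and geotransform. `NA` marks
#' nodata; the effective mask of any computation is the per-cell union of
#' nodata across the variables involved.
#'
#' @param tmin,tmax,tavg Lists of 12 temperature matrices (degC).
#' @param srad List of 12 solar radiation matrices (MJ m-2 day-1).
#' @param wind List of 12 wind speed matrices (m s-1).
#' @param vapr List of 12 water vapour pressure matrices (kPa).
#' @param prec Optional list of 12 precipitation matrices (mm).
#' @param elev Elevation matrix (m).
#' @param xll,yll Lower-left grid corner (decimal degrees).
#' @param cellsize Cell size (decimal degrees).
#' @param wind_height Wind measurement height (m), 2 or 10.
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(tmin, tmax, tavg, srad, wind, vapr, prec = NULL,
                          elev, xll, yll, cellsize, wind_height = 2) {
  monthly <- list(tmin = tmin, tmax = tmax, tavg = tavg, srad = srad,
                  wind = wind, vapr = vapr)
  if (!is.null(prec)) monthly$prec <- prec
  shape <- dim(elev)
  for (nm in names(monthly)) {
    v <- monthly[[nm]]
    if (length(v) != 12) {
      stop("variable `", nm, "` needs 12 monthly layers, got ", length(v),
           call. = FALSE)
    }
    for (m in 1:12) {
      if (!identical(dim(v[[m]]), shape)) {
        stop("layer ", nm, " month ", m, " shape ",
             paste(dim(v[[m]]), collapse = "x"),
             " does not match elevation ", paste(shape, collapse = "x"),
             call. = FALSE)
      }
    }
  }
  structure(c(monthly,
              list(elev = elev, xll = xll, yll = yll, cellsize = cellsize,
                   crs = "WGS84", wind_height = wind_height)),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack %d x %d @ %g deg, ll corner (%g, %g)\n",
              nrow(x$elev), ncol(x$elev), x$cellsize, x$xll, x$yll))
  cat("  variables:", paste(intersect(names(x),
      c("tmin", "tmax", "tavg", "srad", "wind", "vapr", "prec")),
      collapse = ", "), "\n")
  invisible(x)
}

# template geo_raster sharing the stack's geotransform
stack_raster <- function(stack, values, nodata = -9999) {
  geo_raster(values, stack$xll, stack$yll, stack$cellsize, nodata)
}

#' Paths of the 12 monthly raster files of a variable
#'
#' File-naming helper for directory layouts with one `.asc` file per month,
#' `<var>_01.asc` ... `<var>_12.asc`.
#'
#' @param dir Directory.
#' @param var Variable name used as the filename prefix.
#' @return Character vector of 12 paths.
#' @export
monthly_paths <- function(dir, var) {
  file.path(dir, paste0(var, "_", MONTH_SUFFIX, ".asc"))
}

#' Read a monthly climate stack from raster files
#'
#' Reads 12 ESRI ASCII grids per monthly variable plus a static elevation
#' grid, checks alignment (shape, corner, cell size), and normalises solar
#' radiation units: WorldClim-shaped inputs carry kJ m-2 day-1 and are
#' divided by 1000 to MJ m-2 day-1 at ingest.
#'
#' @param tmin,tmax,tavg,srad,wind,vapr Character vectors of 12 file paths
#'   each, in month order (see [monthly_paths()]).
#' @param prec Optional 12 precipitation paths.
#' @param elev Path to the elevation raster.
#' @param srad_unit `"kJ"` (divide by 1000 at ingest) or `"MJ"`
#'   (passthrough).
#' @param wind_height Wind measurement height (m).
#' @return A [climate_stack()].
#' @export
read_climate_stack <- function(tmin, tmax, tavg, srad, wind, vapr,
                               prec = NULL, elev,
                               srad_unit = c("kJ", "MJ"), wind_height = 2) {
  srad_unit <- match.arg(srad_unit)
  elev_grid <- read_ascii_grid(elev)
  read_var <- function(paths, var) {
    if (length(paths) != 12) {
      missing_m <- setdiff(MONTH_SUFFIX,
                           regmatches(paths, regexpr("[0-9]{2}", paths)))
      stop("variable `", var, "` needs 12 monthly files, got ",
           length(paths),
           if (length(missing_m)) paste0(" (missing month ",
                                         paste(missing_m, collapse = ", "),
                                         ")"),
           call. = FALSE)
    }
    lapply(seq_along(paths), function(m) {
      g <- read_ascii_grid(paths[m])
      if (!identical(dim(g$values), dim(elev_grid$values))) {
        stop("`", var, "` month ", m, ": shape mismatch with elevation grid",
             call. = FALSE)
      }
      if (abs(g$xll - elev_grid$xll) > 1e-9 ||
          abs(g$yll - elev_grid$yll) > 1e-9 ||
          abs(g$cellsize - elev_grid$cellsize) > 1e-9) {
        stop("`", var, "` month ", m, ": geotransform mismatch",
             call. = FALSE)
      }
      g$values
    })
  }
  srad_layers <- read_var(srad, "srad")
  if (srad_unit == "kJ") srad_layers <- lapply(srad_layers, function(m) m / 1000)
  climate_stack(
    tmin = read_var(tmin, "tmin"), tmax = read_var(tmax, "tmax"),
    tavg = read_var(tavg, "tavg"), srad = srad_layers,
    wind = read_var(wind, "wind"), vapr = read_var(vapr, "vapr"),
    prec = if (!is.null(prec)) read_var(prec, "prec"),
    elev = elev_grid$values,
    xll = elev_grid$xll, yll = elev_grid$yll,
    cellsize = elev_grid$cellsize, wind_height = wind_height)
}

#' Reference evapotranspiration over a climate stack
#'
#' Applies the scalar chain to every cell and month of a stack: 12 monthly
#' total rasters (mm month-1), the annual total (mm yr-1) and the
#' population standard deviation of the 12 monthly totals, plus a run
#' report counting nodata cells and the clamping/flooring/clipping events.
#' Processing streams over row blocks; results are independent of
#' `block_size`.
#'
#' @param stack A [climate_stack()].
#' @param crop A [reference_crop()] configuration.
#' @param block_size Rows per processing block (`NULL` = whole grid).
#' @return An object of class `et0_grid`: list with `monthly` (12
#'   [geo_raster()]s), `annual`, `annual_sd`, and `report` (class
#'   `run_report`).
#' @export
compute_et0_grid <- function(stack, crop = reference_crop(),
                             block_size = NULL) {
  stopifnot(inherits(stack, "climate_stack"))
  shape <- dim(stack$elev)
  if (all(is.na(stack$elev))) {
    warning("all-nodata elevation layer: output will be all nodata",
            call. = FALSE)
  }
  lat_rows <- latitude_grid(stack_raster(stack, stack$elev))
  if (is.null(block_size)) block_size <- shape[1]
  block_starts <- seq(1, shape[1], by = block_size)

  daily <- lapply(1:12, function(m) matrix(NA_real_, shape[1], shape[2]))
  counters <- c(clipped = 0L, floored = 0L, clamped = 0L)
  for (start in block_starts) {
    rows <- start:min(start + block_size - 1, shape[1])
    latm <- matrix(lat_rows[rows], nrow = length(rows), ncol = shape[2])
    elev_b <- stack$elev[rows, , drop = FALSE]
    for (m in 1:12) {
      res <- et0_month_fields(
        tmin = stack$tmin[[m]][rows, , drop = FALSE],
        tmax = stack$tmax[[m]][rows, , drop = FALSE],
        tavg = stack$tavg[[m]][rows, , drop = FALSE],
        srad = stack$srad[[m]][rows, , drop = FALSE],
        wind = stack$wind[[m]][rows, , drop = FALSE],
        elev = elev_b, latitude = latm, month = m,
        vapr = stack$vapr[[m]][rows, , drop = FALSE],
        crop = crop, wind_height = stack$wind_height)
      daily[[m]][rows, ] <- res$et0
      counters <- counters + c(res$clipped, res$floored, res$clamped)
    }
  }
  monthly <- lapply(1:12, function(m) daily[[m]] * DAYS_IN_MONTH[m])
  annual <- Reduce(`+`, monthly)
  mu <- annual / 12
  annual_sd <- sqrt(Reduce(`+`, lapply(monthly,
                                       function(x) (x - mu)^2)) / 12)
  report <- structure(list(
    cells_total = prod(shape),
    cells_nodata = sum(is.na(annual)),
    clamped_et0_count = counters[["clamped"]],
    supersaturation_count = counters[["clipped"]],
    wind_floor_count = counters[["floored"]],
    runtime_metadata = list(blocks = length(block_starts),
                            block_size = block_size,
                            timestamp = format(Sys.time(), tz = "UTC"))),
    class = "run_report")
  structure(list(
    monthly = lapply(monthly, function(m) stack_raster(stack, m)),
    annual = stack_raster(stack, annual),
    annual_sd = stack_raster(stack, annual_sd),
    report = report),
    class = "et0_grid")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Run report\n")
  cat(sprintf("  cells: %d (%d nodata)\n", x$cells_total, x$cells_nodata))
  cat(sprintf("  ET0 clamped to 0 : %d cell-months\n", x$clamped_et0_count))
  cat(sprintf("  ea clipped to es : %d cell-months\n",
              x$supersaturation_count))
  cat(sprintf("  wind floored     : %d cell-months\n", x$wind_floor_count))
  cat(sprintf("  blocks: %d (block size %d)\n",
              x$runtime_metadata$blocks, x$runtime_metadata$block_size))
  invisible(x)
}

#' @export
print.et0_grid <- function(x, ...) {
  cat("ET0 grid:", nrow(x$annual$values), "x", ncol(x$annual$values),
      "cells; annual mean",
      sprintf("%.1f mm/yr\n", mean(x$annual$values, na.rm = TRUE)))
  print(x$report)
  invisible(x)
}

#' Aridity index over a grid
#'
#' Monthly and annual aridity index rasters from monthly precipitation and
#' an [compute_et0_grid()] result. Cells or months with zero ET0 become
#' nodata (annual AI is still computed wherever annual ET0 is positive).
#'
#' @param prec List of 12 precipitation matrices (mm), or a
#'   [climate_stack()] carrying `prec`.
#' @param et0 An `et0_grid`.
#' @param encode Also produce the x10,000 integer-encoded variants.
#' @return An object of class `ai_grid`: `monthly` (12 rasters), `annual`,
#'   and with `encode = TRUE` also `monthly_encoded` / `annual_encoded`
#'   integer rasters (nodata sentinel -32768).
#' @export
compute_ai_grid <- function(prec, et0, encode = FALSE) {
  stopifnot(inherits(et0, "et0_grid"))
  if (inherits(prec, "climate_stack")) {
    if (is.null(prec$prec)) stop("stack carries no precipitation layers",
                                 call. = FALSE)
    prec <- prec$prec
  }
  stopifnot(length(prec) == 12)
  shape <- dim(et0$annual$values)
  for (m in 1:12) {
    if (!identical(dim(prec[[m]]), shape)) {
      stop("precipitation month ", m, " not aligned with ET0 grid",
           call. = FALSE)
    }
  }
  tmpl <- et0$annual
  ai_m <- lapply(1:12, function(m) {
    aridity_index(prec[[m]], et0$monthly[[m]]$values)
  })
  ai_yr <- aridity_index(Reduce(`+`, prec), et0$annual$values)
  mk <- function(v) geo_raster(v, tmpl$xll, tmpl$yll, tmpl$cellsize,
                               tmpl$nodata)
  out <- list(monthly = lapply(ai_m, mk), annual = mk(ai_yr))
  if (encode) {
    enc <- function(v) {
      e <- matrix(NA_integer_, nrow(v), ncol(v))
      ok <- !is.na(v)
      e[ok] <- encode_ai(v[ok])
      geo_raster(e, tmpl$xll, tmpl$yll, tmpl$cellsize, nodata = -32768)
    }
    out$monthly_encoded <- lapply(ai_m, enc)
    out$annual_encoded <- enc(ai_yr)
  }
  structure(out, class = "ai_grid")
}

#' Write ET0 / AI rasters under the distribution naming scheme
#'
#' Writes the layers of an `et0_grid` or `ai_grid` to
#' `{prefix}_{suffix}.asc` with prefixes `et0_v3` / `ai_v3` and suffixes
#' `01`..`12`, `yr` and (ET0 only) `yr_sd`. AI can be written as the
#' x10,000 integer-encoded product (requires `encode = TRUE` at
#' [compute_ai_grid()] time).
#'
#' @param x An `et0_grid` or `ai_grid`.
#' @param out_dir Output directory (created if needed).
#' @param prefix Filename prefix; defaults to `et0_v3` / `ai_v3`.
#' @param encoded Write the integer-encoded AI variant.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(x, out_dir, prefix = NULL, encoded = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(grid, name) {
    p <- file.path(out_dir, paste0(name, ".asc"))
    write_ascii_grid(grid, p)
    paths <<- c(paths, p)
  }
  if (inherits(x, "et0_grid")) {
    if (is.null(prefix)) prefix <- "et0_v3"
    for (m in 1:12) put(x$monthly[[m]], paste0(prefix, "_", MONTH_SUFFIX[m]))
    put(x$annual, paste0(prefix, "_yr"))
    put(x$annual_sd, paste0(prefix, "_yr_sd"))
  } else if (inherits(x, "ai_grid")) {
    if (is.null(prefix)) prefix <- "ai_v3"
    monthly <- if (encoded) x$monthly_encoded else x$monthly
    annual <- if (encoded) x$annual_encoded else x$annual
    if (encoded && is.null(monthly)) {
      stop("no encoded layers: run compute_ai_grid(..., encode = TRUE)",
           call. = FALSE)
    }
    for (m in 1:12) put(monthly[[m]], paste0(prefix, "_", MONTH_SUFFIX[m]))
    put(annual, paste0(prefix, "_yr"))
  } else {
    stop("`x` must be an et0_grid or ai_grid", call. = FALSE)
  }
  invisible(paths)
}
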