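## Minimal georeferenced raster container + ESRI ASCII Grid (.asc) I/O.
## Geographic (WGS84) coordinates, corner-registered geotransform, single
## nodata sentinel — the conventions of the distributed ET0/AI products.

#' Construct a georeferenced raster layer
#'
#' A light container for a single 2-D raster in geographic coordinates:
#' a numeric matrix (row 1 = northernmost row, columns west to east), the
#' lower-left corner of the grid, the square cell size in decimal degrees,
#' and a nodata sentinel. `NA` entries in `values` mark nodata.
#'
#' @param values Numeric matrix, row 1 north.
#' @param xll,yll Longitude/latitude of the lower-left grid corner
#'   (decimal degrees).
#' @param cellsize Cell size (decimal degrees), positive.
#' @param nodata Sentinel written for `NA` cells on output.
#' @return An object of class `geo_raster`.
#' @export
geo_raster <- function(values, xll, yll, cellsize, nodata = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  lat_top <- yll + nrow(values) * cellsize
  if (lat_top > 90 + 1e-9 || yll < -90 - 1e-9) {
    stop("grid extends outside [-90, 90] latitude", call. = FALSE)
  }
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata, crs = "WGS84"),
            class = "geo_raster")
}

#' @export
print.geo_raster <- function(x, ...) {
  cat(sprintf("geo_raster %d x %d @ %g deg, ll corner (%g, %g), %s\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              x$crs))
  cat(sprintf("  nodata cells: %d / %d\n", sum(is.na(x$values)),
              length(x$values)))
  invisible(x)
}

#' Latitudes of cell centres, per row
#'
#' Row 1 is the northernmost row; its centre sits half a cell below the top
#' edge of the grid.
#'
#' @param grid A [geo_raster()].
#' @return Numeric vector of length `nrow(grid$values)`, decreasing.
#' @examples
#' g <- geo_raster(matrix(0, 2, 2), xll = 0, yll = 89, cellsize = 0.5)
#' latitude_grid(g)  # 89.75 89.25
#' @export
latitude_grid <- function(grid) {
  top <- grid$yll + nrow(grid$values) * grid$cellsize
  top - (seq_len(nrow(grid$values)) - 0.5) * grid$cellsize
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line AAIGrid header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`) followed by
#' `nrows` rows of values, north first. Nodata values become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @return A [geo_raster()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path, call. = FALSE)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1)
    if (!length(line)) stop("truncated ASCII grid: ", path, call. = FALSE)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop("ASCII grid header missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(con, what = double(), n = hdr$ncols * hdr$nrows, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  geo_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param grid A [geo_raster()].
#' @param path Output path (conventionally `.asc`).
#' @param digits Significant digits for floating output; integer matrices
#'   are written without a decimal point.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, digits = 7) {
  stopifnot(inherits(grid, "geo_raster"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  v <- grid$values
  is_int <- is.integer(v) || isTRUE(all(v == round(v), na.rm = TRUE))
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("nodata_value %.10g", grid$nodata))
  body <- apply(v, 1, function(row) {
    row[is.na(row)] <- grid$nodata
    paste(formatC(row, digits = if (is_int) NULL else digits,
                  format = if (is_int) "d" else "g"), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Sample raster values at point coordinates
#'
#' Nearest-cell (containing-cell) lookup: a point belongs to the cell whose
#' half-open extent `[left, right) x (bottom, top]` contains it. Points
#' outside the grid extent return `NA` with a warning.
#'
#' @param grid A [geo_raster()].
#' @param lon,lat Point coordinates (decimal degrees), equal length.
#' @return Numeric vector of sampled values (`NA` for nodata cells and
#'   out-of-extent points).
#' @export
sample_grid_at_points <- function(grid, lon, lat) {
  stopifnot(length(lon) == length(lat))
  v <- grid$values
  top <- grid$yll + nrow(v) * grid$cellsize
  col <- floor((lon - grid$xll) / grid$cellsize) + 1
  row <- floor((top - lat) / grid$cellsize) + 1
  # the top edge itself belongs to row 1
  row[!is.na(lat) & lat == top] <- 1
  inside <- !is.na(row) & !is.na(col) &
    row >= 1 & row <= nrow(v) & col >= 1 & col <= ncol(v)
  if (any(!inside)) {
    warning(sum(!inside), " point(s) outside raster extent -> NA",
            call. = FALSE)
  }
  out <- rep(NA_real_, length(lon))
  out[inside] <- v[cbind(row[inside], col[inside])]
  out
}
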