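#' Georeferenced raster grid
#'
#' Lightweight in-memory container for a single-band raster in geographic
#' (longitude/latitude) coordinates: a numeric matrix whose first row is the
#' northernmost row of cells, plus the lower-left corner of the grid, a square
#' cell size in degrees, and a nodata sentinel used only on disk. In memory,
#' missing cells are `NA`. Values are cell means referenced to cell centers;
#' the origin follows the lower-left corner convention of the ESRI ASCII grid
#' format used for I/O (see [write_ascii_grid()]).
#'
#' @param values Numeric or integer matrix; `NA` marks nodata cells. Row 1 is
#'   the top (northernmost) row.
#' @param xll,yll Longitude/latitude of the lower-left corner of the grid, in
#'   degrees.
#' @param cellsize Cell edge length in degrees (square cells). The default,
#'   1/6 degree, is 10 arc-minutes.
#' @param crs Coordinate reference system label; only WGS84 longitude/latitude
#'   is supported.
#' @param nodata Sentinel written for `NA` cells on disk.
#' @return An object of class `raster_grid`.
#' @examples
#' r <- raster_grid(matrix(1:12, nrow = 3), xll = -10, yll = 40)
#' dim(r)
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1 / 6,
                        crs = "EPSG:4326", nodata = -9999) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), crs = crs,
         nodata = as.numeric(nodata)),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, %.6g deg resolution (%s)\n",
              nrow(v), ncol(v), x$cellsize, x$crs))
  cat(sprintf("  extent: lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
              x$xll, x$xll + ncol(v) * x$cellsize,
              x$yll, x$yll + nrow(v) * x$cellsize))
  ok <- !is.na(v)
  if (any(ok)) {
    cat(sprintf("  values: [%.6g, %.6g], %d nodata cells\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Test whether two rasters share grid and registration
#'
#' @param a,b `raster_grid` objects.
#' @param tol Numeric tolerance on origin and cell size, in degrees.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not aligned: grids differ in shape or registration",
                 what), call. = FALSE)
  invisible(TRUE)
}

#' Locate the cell containing a point
#'
#' @param r A `raster_grid`.
#' @param lon,lat Point coordinates in degrees (vectorized).
#' @return A data frame with columns `row` and `col`; `NA` for points outside
#'   the grid extent. Points on an interior cell boundary belong to the cell
#'   to the north-east of the boundary (half-open cells); the extent's outer
#'   edges are inclusive.
#' @export
cell_at <- function(r, lon, lat) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cellsize
  col <- floor((lon - r$xll) / cs) + 1
  row <- nr - floor((lat - r$yll) / cs)
  # points exactly on the top/right edge fall in the outermost cell
  col[lon == r$xll + nc * cs] <- nc
  row[lat == r$yll + nr * cs] <- 1L
  bad <- col < 1 | col > nc | row < 1 | row > nr | is.na(lon) | is.na(lat)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

block_index <- function(n, factor) rep(seq_len(n %/% factor), each = factor)

check_divisible <- function(r, factor) {
  if (factor < 1 || factor != round(factor))
    stop("`factor` must be a positive integer", call. = FALSE)
  d <- dim(r$values)
  if (any(d %% factor != 0))
    stop(sprintf("raster dimensions %d x %d are not divisible by factor %d",
                 d[1], d[2], factor), call. = FALSE)
  invisible(TRUE)
}

coarsen_meta <- function(fine, factor, values) {
  raster_grid(values, xll = fine$xll, yll = fine$yll,
              cellsize = fine$cellsize * factor, crs = fine$crs,
              nodata = fine$nodata)
}

#' Nearest-neighbour aggregation of a categorical raster
#'
#' Coarsens a categorical raster by an integer factor: each coarse cell takes
#' the value of the fine cell whose center is nearest the coarse-cell center.
#' For even factors the center is equidistant from four fine cells; the tie is
#' broken by taking the cell with the smallest (row, col) in scan order, i.e.
#' the north-west cell of the central four. Nodata propagates when the
#' selected fine cell is nodata.
#'
#' @param fine A `raster_grid` whose dimensions are divisible by `factor`.
#' @param factor Positive integer ratio of coarse to fine cell size.
#' @return A `raster_grid` with dimensions `dim(fine) / factor`.
#' @export
resample_categorical_nearest <- function(fine, factor) {
  check_divisible(fine, factor)
  if (factor == 1) return(fine)
  pick <- ceiling(factor / 2)  # local index nearest the block center
  rows <- seq(pick, nrow(fine$values), by = factor)
  cols <- seq(pick, ncol(fine$values), by = factor)
  coarsen_meta(fine, factor, fine$values[rows, cols, drop = FALSE])
}

#' Block-mean aggregation of a continuous raster
#'
#' Coarsens a continuous raster by an integer factor: each coarse cell is the
#' arithmetic mean of the valid (non-nodata) fine cells in its factor-by-factor
#' block, or nodata when the whole block is nodata.
#'
#' @inheritParams resample_categorical_nearest
#' @return A `raster_grid` with dimensions `dim(fine) / factor`.
#' @export
aggregate_mean <- function(fine, factor) {
  check_divisible(fine, factor)
  if (factor == 1) return(fine)
  v <- fine$values
  ir <- block_index(nrow(v), factor)
  ic <- block_index(ncol(v), factor)
  sums <- rowsum(ifelse(is.na(v), 0, v), ir)
  cnts <- rowsum((!is.na(v)) + 0, ir)
  sums <- t(rowsum(t(sums), ic))
  cnts <- t(rowsum(t(cnts), ic))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  dimnames(out) <- NULL
  coarsen_meta(fine, factor, out)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Writes the standard text-based georeferenced raster format (`.asc`:
#' six-line header of `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`, then rows of values north to south) together with a `.prj`
#' sidecar holding the WGS84 well-known text, so the file opens georeferenced
#' in GDAL/QGIS.
#'
#' @param r A `raster_grid`.
#' @param path Output path; `.asc` is appended if absent.
#' @return The `.asc` path, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(is_raster_grid(r))
  if (!grepl("\\.asc$", path)) path <- paste0(path, ".asc")
  v <- r$values
  v[is.na(v)] <- r$nodata
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", r$nodata)
  )
  body <- apply(v, 1L, function(row) paste(format(row, trim = TRUE, digits = 15),
                                           collapse = " "))
  writeLines(c(header, body), path)
  writeLines(wgs84_wkt(), sub("\\.asc$", ".prj", path))
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to an `.asc` file written by [write_ascii_grid()] or any
#'   conforming producer.
#' @return A `raster_grid`; cells equal to the declared nodata value become
#'   `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  header <- lines[1:6]
  kv <- strsplit(trimws(header), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  body <- lines[-(1:6)]
  v <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (!identical(dim(v), c(as.integer(vals["nrows"]), as.integer(vals["ncols"]))))
    stop("ASCII grid body does not match declared dimensions in ", path,
         call. = FALSE)
  v[v == vals["nodata_value"]] <- NA_real_
  raster_grid(v, xll = vals["xllcorner"], yll = vals["yllcorner"],
              cellsize = vals["cellsize"], nodata = vals["nodata_value"])
}

wgs84_wkt <- function() {
  paste0('GEOGCS["WGS 84",DATUM["WGS_1984",SPHEROID["WGS 84",6378137,',
         '298.257223563]],PRIMEM["Greenwich",0],UNIT["degree",',
         '0.0174532925199433]]')
}
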