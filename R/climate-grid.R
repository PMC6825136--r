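#' Gridded climate field with matching elevation
#'
#' A lightweight raster container: strictly monotone cell-centre coordinate
#' vectors plus a climate value field and an elevation field of matching
#' shape. Typically built from a pair of ESRI ASCII grids via
#' [read_climate_grid()].
#'
#' @param lon_coords,lat_coords strictly increasing cell-centre coordinates.
#' @param value numeric matrix `(length(lat_coords), length(lon_coords))`,
#'   row 1 = southernmost latitude.
#' @param elev elevation matrix (metres) of the same shape.
#' @param nodata sentinel value marking missing cells.
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(lon_coords, lat_coords, value, elev,
                         nodata = -9999) {
  lon_coords <- as.numeric(lon_coords)
  lat_coords <- as.numeric(lat_coords)
  if (any(diff(lon_coords) <= 0) || any(diff(lat_coords) <= 0))
    stop("coordinate vectors must be strictly increasing")
  value <- as.matrix(value); elev <- as.matrix(elev)
  shape <- c(length(lat_coords), length(lon_coords))
  if (!identical(dim(value), as.integer(shape)))
    stop("value field shape must be (length(lat_coords), length(lon_coords))")
  if (!identical(dim(elev), dim(value)))
    stop("value and elev fields must share the same shape")
  structure(list(lon = lon_coords, lat = lat_coords, value = value,
                 elev = elev, nodata = nodata),
            class = "climate_grid")
}

#' Read an ESRI ASCII grid (.asc)
#'
#' Parses the 6-line header (ncols, nrows, xllcorner/xllcenter,
#' yllcorner/yllcenter, cellsize, nodata_value) and the row-major data block
#' (first data row = northernmost). Returns cell-centre coordinates and a
#' matrix oriented south-to-north to match [climate_grid()].
#'
#' @param path path to the .asc file.
#' @return List with `lon`, `lat` (cell centres, increasing), `values`
#'   matrix and `nodata`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("invalid ESRI ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  cs <- hdr$cellsize
  x0 <- if (!is.null(hdr$xllcenter)) hdr$xllcenter else hdr$xllcorner + cs / 2
  y0 <- if (!is.null(hdr$yllcenter)) hdr$yllcenter else hdr$yllcorner + cs / 2
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ESRI ASCII grid data block has wrong length in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[hdr$nrows:1, , drop = FALSE]  # flip to south-to-north
  list(lon = x0 + (seq_len(hdr$ncols) - 1) * cs,
       lat = y0 + (seq_len(hdr$nrows) - 1) * cs,
       values = m, nodata = nodata)
}

#' Read a climate grid from a pair of ESRI ASCII files
#'
#' @param value_path .asc file with the climate variable.
#' @param elev_path .asc file with elevation (metres), same grid geometry.
#' @return A [climate_grid].
#' @export
read_climate_grid <- function(value_path, elev_path) {
  v <- read_asc(value_path)
  e <- read_asc(elev_path)
  if (!isTRUE(all.equal(v$lon, e$lon)) || !isTRUE(all.equal(v$lat, e$lat)))
    stop("value and elevation grids have different geometries")
  climate_grid(v$lon, v$lat, v$values, e$values, nodata = v$nodata)
}

#' Extract a climate value at a site by bilinear interpolation
#'
#' Interpolates the climate field and the grid elevation from the four
#' nearest cell centres (nodata cells dropped with weight renormalization).
#' With `apply_lapse = TRUE` a lapse-rate correction is applied based on the
#' difference between the site elevation and the interpolated grid
#' elevation: `value - lapse_rate * (site_elev - grid_elev) / 1000`. The
#' default rate of 6.4 degC/km is the standard environmental lapse rate for
#' air temperature; leave `apply_lapse = FALSE` for non-temperature fields.
#'
#' @param grid a [climate_grid].
#' @param site single-row data frame (or list) with `lon`, `lat`,
#'   `elevation`.
#' @param lapse_rate lapse rate in degC per km of elevation.
#' @param apply_lapse logical; apply the elevation correction?
#' @return The interpolated (and optionally corrected) value, or `NA` if
#'   all four surrounding cells are nodata.
#' @export
extract_climate <- function(grid, site, lapse_rate = 6.4, apply_lapse = TRUE) {
  stopifnot(inherits(grid, "climate_grid"))
  lon <- as.numeric(site$lon); lat <- as.numeric(site$lat)
  half_x <- mean(diff(grid$lon)) / 2
  half_y <- mean(diff(grid$lat)) / 2
  if (lon < min(grid$lon) - half_x || lon > max(grid$lon) + half_x ||
      lat < min(grid$lat) - half_y || lat > max(grid$lat) + half_y)
    stop(sprintf("site (%g, %g) lies outside the grid", lon, lat))
  ix <- bracket(grid$lon, lon)
  iy <- bracket(grid$lat, lat)
  wx <- interp_weight(grid$lon, lon, ix)
  wy <- interp_weight(grid$lat, lat, iy)
  cells <- rbind(
    c(iy[1], ix[1], (1 - wy) * (1 - wx)),
    c(iy[1], ix[2], (1 - wy) * wx),
    c(iy[2], ix[1], wy * (1 - wx)),
    c(iy[2], ix[2], wy * wx)
  )
  v <- grid$value[cells[, 1:2, drop = FALSE]]
  e <- grid$elev[cells[, 1:2, drop = FALSE]]
  ok <- v != grid$nodata & e != grid$nodata & cells[, 3] > 0
  if (!any(ok)) return(NA_real_)
  w <- cells[ok, 3] / sum(cells[ok, 3])
  value <- sum(w * v[ok])
  grid_elev <- sum(w * e[ok])
  if (apply_lapse) {
    site_elev <- as.numeric(site$elevation)
    value <- value - lapse_rate * (site_elev - grid_elev) / 1000
  }
  value
}

# Indices of the two cell centres bracketing x (clamped at the edges).
bracket <- function(coords, x) {
  n <- length(coords)
  i <- findInterval(x, coords, all.inside = TRUE)
  if (n == 1) c(1L, 1L) else c(i, i + 1L)
}

interp_weight <- function(coords, x, idx) {
  if (idx[1] == idx[2]) return(0)
  w <- (x - coords[idx[1]]) / (coords[idx[2]] - coords[idx[1]])
  min(1, max(0, w))
}
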