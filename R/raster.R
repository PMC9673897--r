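# Gridded data. A raster is a matrix with square cells plus georeferencing:
# values[i, j] with row 1 the northernmost row, column 1 the westernmost
# column; (xll, yll) the lower-left corner of the grid; cellsize the cell
# width in CRS units (degrees for geographic, metres for local).

#' Construct a raster
#'
#' @param values numeric matrix; row 1 is the top (northern) row.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell width/height in CRS units (square cells).
#' @param crs an [sdi_crs()].
#' @param nodata nodata marker stored in `values` (default -99).
#' @return object of class `sdi_raster`.
#' @export
sdi_raster <- function(values, xll, yll, cellsize, crs, nodata = -99) {
  stopifnot(is.matrix(values), cellsize > 0, inherits(crs, "sdi_crs"))
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, crs = crs, nodata = nodata),
            class = "sdi_raster")
}

#' @export
print.sdi_raster <- function(x, ...) {
  cat(sprintf("sdi_raster: %d rows x %d cols, cellsize %g (%s), origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$crs$type,
              x$xll, x$yll))
  invisible(x)
}

raster_same_grid <- function(a, b) {
  nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values) &&
    isTRUE(all.equal(a$xll, b$xll)) && isTRUE(all.equal(a$yll, b$yll)) &&
    isTRUE(all.equal(a$cellsize, b$cellsize)) && crs_equal(a$crs, b$crs)
}

# cell-centre coordinates; returns list(x = col centres, y = row centres with
# y[1] the top row, matching values[i, j])
raster_centres <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xll + (seq_len(nc) - 0.5) * r$cellsize,
       y = r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize)
}

raster_mask <- function(r) {
  m <- r$values
  !is.na(m) & m != r$nodata
}

#' Per-cell population density from count and surface-area rasters
#'
#' Divides the population-count raster by the matching grid-cell surface-area
#' raster (km^2 per cell), preserving the grid resolution. Nodata counts
#' propagate to nodata densities.
#'
#' @param pop population counts per cell (`sdi_raster`).
#' @param area surface area of each cell in km^2 (`sdi_raster`, same grid).
#' @return density `sdi_raster` in persons per km^2.
#' @export
density_raster <- function(pop, area) {
  stopifnot(inherits(pop, "sdi_raster"), inherits(area, "sdi_raster"))
  if (!raster_same_grid(pop, area))
    stop("population and surface-area rasters are not on the same grid")
  ok <- raster_mask(pop) & raster_mask(area)
  if (any(area$values[ok] <= 0))
    stop("surface-area raster must be strictly positive where population is defined")
  d <- pop$values
  d[ok] <- pop$values[ok] / area$values[ok]
  d[!ok] <- pop$nodata
  sdi_raster(d, pop$xll, pop$yll, pop$cellsize, pop$crs, nodata = pop$nodata)
}

#' Read a raster from an ESRI ASCII grid
#'
#' Reads `path` (.asc). CRS and nodata metadata are taken from a JSON sidecar
#' `<path>.aux.json` when present (written by [write_raster()]), otherwise
#' from the `crs` argument.
#'
#' @param path file path.
#' @param crs fallback [sdi_crs()] when no sidecar exists.
#' @return an `sdi_raster`.
#' @export
read_raster <- function(path, crs = NULL) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  if (!grepl("\\.asc$", path, ignore.case = TRUE))
    stop("unsupported raster format (expected an ESRI ASCII grid .asc): ", path)
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header in ", path)
  if (!is.null(hdr$xllcenter)) hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
  if (!is.null(hdr$yllcenter)) hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body does not match header dimensions in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -99
  aux_path <- paste0(path, ".aux.json")
  if (file.exists(aux_path)) {
    aux <- jsonlite::read_json(aux_path, simplifyVector = TRUE)
    crs <- sdi_crs(aux$crs_type,
                   lon0 = if (is.null(aux$lon0)) NA_real_ else aux$lon0,
                   lat0 = if (is.null(aux$lat0)) NA_real_ else aux$lat0)
  } else if (is.null(crs)) {
    stop("no CRS sidecar for ", path, " and no `crs` supplied")
  }
  sdi_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, crs, nodata)
}

#' Write a raster as an ESRI ASCII grid with a CRS sidecar
#'
#' @param r an `sdi_raster`.
#' @param path output path (.asc); a `<path>.aux.json` sidecar records the
#'   CRS and nodata marker.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "sdi_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(r$values)),
    paste("nrows", nrow(r$values)),
    paste("xllcorner", format(r$xll, digits = 15)),
    paste("yllcorner", format(r$yll, digits = 15)),
    paste("cellsize", format(r$cellsize, digits = 15)),
    paste("NODATA_value", format(r$nodata, digits = 15))), con)
  utils::write.table(format(r$values, digits = 15, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(crs_type = r$crs$type, lon0 = r$crs$lon0,
                            lat0 = r$crs$lat0, nodata = r$nodata),
                       paste0(path, ".aux.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
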