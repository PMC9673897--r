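# Per-unit metrics and index scores.

#' Mean population density of a spatial unit (zonal mean)
#'
#' Averages the density raster over the cells whose centroids fall inside the
#' unit (nodata cells dropped). When no usable cell centroid falls inside -
#' typically a unit smaller or thinner than one raster cell - the density is
#' interpolated bilinearly at the unit centroid from the 4 nearest cell
#' centres, dropping nodata neighbours with weight renormalisation. If that
#' also fails (all neighbours nodata or the unit lies off the raster), the
#' nodata marker -99 is returned.
#'
#' @param region unit region in the raster CRS.
#' @param dens density `sdi_raster` (persons per km^2).
#' @return mean density, or -99.
#' @export
zonal_mean_density <- function(region, dens) {
  stopifnot(inherits(dens, "sdi_raster"))
  region <- as_region(region)
  bb <- region_bbox(region)
  ctr <- raster_centres(dens)
  jx <- which(ctr$x >= bb["xmin"] & ctr$x <= bb["xmax"])
  iy <- which(ctr$y >= bb["ymin"] & ctr$y <= bb["ymax"])
  vals <- numeric(0)
  if (length(jx) > 0L && length(iy) > 0L) {
    gx <- rep(ctr$x[jx], times = length(iy))
    gy <- rep(ctr$y[iy], each = length(jx))
    inside <- points_in_region(gx, gy, region)
    if (any(inside)) {
      ii <- rep(iy, each = length(jx))[inside]
      jj <- rep(jx, times = length(iy))[inside]
      v <- dens$values[cbind(ii, jj)]
      vals <- v[!is.na(v) & v != dens$nodata]
    }
  }
  if (length(vals) > 0L) return(mean(vals))
  bilinear_density(region_centroid(region), dens)
}

# bilinear interpolation at a point from the 4 nearest cell centres,
# nodata-aware; -99 when impossible
bilinear_density <- function(pt, dens) {
  nr <- nrow(dens$values); nc <- ncol(dens$values)
  cs <- dens$cellsize
  # fractional column/row position in cell-centre coordinates
  fx <- (pt[1] - dens$xll) / cs + 0.5
  fy <- (pt[2] - dens$yll) / cs + 0.5   # from bottom
  j0 <- floor(fx); i0b <- floor(fy)     # left col / bottom row (1-based below)
  wts <- c((j0 + 1 - fx) * (i0b + 1 - fy),  # (j0,  i0b)
           (fx - j0) * (i0b + 1 - fy),      # (j0+1,i0b)
           (j0 + 1 - fx) * (fy - i0b),      # (j0,  i0b+1)
           (fx - j0) * (fy - i0b))          # (j0+1,i0b+1)
  cols <- c(j0, j0 + 1, j0, j0 + 1)
  rows_b <- c(i0b, i0b, i0b + 1, i0b + 1)   # bottom-based row index
  v <- numeric(4); ok <- logical(4)
  for (k in 1:4) {
    jj <- cols[k]; ib <- rows_b[k]
    if (jj >= 1 && jj <= nc && ib >= 1 && ib <= nr) {
      val <- dens$values[nr - ib + 1L, jj]
      if (!is.na(val) && val != dens$nodata) { v[k] <- val; ok[k] <- TRUE }
    }
  }
  ok <- ok & wts > 0
  if (!any(ok)) return(-99)
  sum(v[ok] * wts[ok]) / sum(wts[ok])
}

#' Built area and built proportion of a spatial unit
#'
#' Building footprints are dissolved (overlaps unioned) and clipped to the
#' unit, so a footprint straddling a unit boundary contributes exactly its
#' clipped share to each side. Areas are computed in a metric frame centred
#' on the unit.
#'
#' @param region unit region (unit CRS).
#' @param footprints list of building-footprint regions (same CRS).
#' @param crs the shared [sdi_crs()].
#' @param unit_area_m2 unit area in m^2 (defaults to the region's planar
#'   area).
#' @return `list(built_area_m2, built_prop)` with `built_prop` in [0, 1].
#' @export
built_metrics <- function(region, footprints, crs, unit_area_m2 = NULL) {
  region <- as_region(region)
  fr <- local_frame(crs, region_centroid(region))
  unit_m <- frame_region(region, fr$to_m)
  if (is.null(unit_area_m2)) unit_area_m2 <- region_area(unit_m)
  bb <- region_bbox(region)
  near <- Filter(function(f) {
    fb <- region_bbox(as_region(f))
    !(fb["xmin"] > bb["xmax"] || bb["xmin"] > fb["xmax"] ||
        fb["ymin"] > bb["ymax"] || bb["ymin"] > fb["ymax"])
  }, footprints)
  if (length(near) == 0L)
    return(list(built_area_m2 = 0, built_prop = 0))
  near_m <- lapply(near, function(f) frame_region(as_region(f), fr$to_m))
  ok <- vapply(near_m, function(f) all(vapply(f, ring_is_valid, logical(1))),
               logical(1))
  if (!all(ok)) {
    warning("skipping ", sum(!ok), " invalid building footprint(s)")
    near_m <- near_m[ok]
  }
  dissolved <- rc_union(near_m)
  clipped <- rc_intersect(dissolved, unit_m)
  built <- if (length(clipped) > 0L) region_area(clipped) else 0
  prop <- built / unit_area_m2
  list(built_area_m2 = built, built_prop = min(max(prop, 0), 1))
}

#' Classify built proportion into a 0-10 built score
#'
#' 0 when no building is present; otherwise decile bins with closed upper
#' bounds: (0, 0.10] scores 1, (0.10, 0.20] scores 2, ..., (0.90, 1] scores
#' 10.
#'
#' @param prop built proportion in [0, 1]; vectorised.
#' @return integer score(s) 0-10.
#' @export
classify_built <- function(prop) {
  if (any(!is.finite(prop)) || any(prop < 0) || any(prop > 1 + 1e-12))
    stop("built proportion must lie in [0, 1]")
  prop <- pmin(prop, 1)
  ifelse(prop == 0, 0L, pmin(10L, as.integer(ceiling(prop * 10))))
}

#' Classify mean population density into a 0-10 population score
#'
#' Densities at or above the tightest-spacing threshold (32,075 per km^2 for
#' the default 3 m apothem) score 10; bands `[T(d), T(d - step))` score the
#' table's value for apothem `d`; positive densities below the loosest
#' threshold (2,386 per km^2 at 11 m) score 1; zero scores 0; the nodata
#' marker -99 passes through. Comparisons use the unrounded thresholds.
#'
#' @param density mean density in persons per km^2, or -99; vectorised.
#' @param table a [build_threshold_table()] result.
#' @return integer score(s) 0-10, or -99.
#' @export
classify_pop <- function(density, table = build_threshold_table()) {
  stopifnot(inherits(table, "spacing_thresholds"))
  vapply(density, function(d) {
    if (is.na(d)) return(NA_integer_)
    if (d == -99) return(-99L)
    if (!is.finite(d) || d < 0) stop("population density must be non-negative")
    if (d == 0) return(0L)
    hit <- which(d >= table$max_density_km2)
    if (length(hit) == 0L) return(1L)
    as.integer(table$pop_score[min(hit)])
  }, integer(1))
}

#' Combine built and population scores into the index value
#'
#' The ease-of-social-distancing index is the mean of the two scores, in
#' {0, 0.5, ..., 10}; a nodata population score (-99) yields -99.
#'
#' @param built_score integer 0-10; vectorised.
#' @param pop_score integer 0-10 or -99.
#' @return index value(s).
#' @export
compute_index <- function(built_score, pop_score) {
  n <- max(length(built_score), length(pop_score))
  built_score <- rep_len(built_score, n); pop_score <- rep_len(pop_score, n)
  if (any(built_score < 0 | built_score > 10))
    stop("built score out of range 0-10")
  if (any(pop_score != -99 & (pop_score < 0 | pop_score > 10)))
    stop("population score out of range")
  ifelse(pop_score == -99, -99, (built_score + pop_score) / 2)
}

#' Score every spatial unit
#'
#' Computes the full attribute record for each unit: area, built area and
#' proportion, mean population density, both scores and the index value.
#' Records are ordered by (`uext_ID`, `unit_ID`).
#'
#' @param units a `spatial_units` collection.
#' @param footprints list of building-footprint regions (unit CRS).
#' @param pop population-count `sdi_raster`.
#' @param area surface-area `sdi_raster` (km^2 per cell, same grid).
#' @param table population-score threshold table.
#' @param iso3 country code stamped on the records.
#' @return object of class `score_records`: `data` (the published attribute
#'   schema), `geometry`, `unit_ID`, `crs`.
#' @export
score_units <- function(units, footprints, pop, area,
                        table = build_threshold_table(), iso3 = "XXX") {
  stopifnot(inherits(units, "spatial_units"))
  if (!crs_equal(units$crs, pop$crs))
    stop("units and population raster are in different CRS")
  dens <- density_raster(pop, area)
  ord <- order(units$uext_ID, units$unit_ID)
  units <- subset_units(units, ord)
  n <- length(units$unit_ID)
  ua <- ba <- bp <- pd <- numeric(n)
  for (i in seq_len(n)) {
    ua[i] <- units$area_m2[i]
    bm <- built_metrics(units$geometry[[i]], footprints, units$crs,
                        unit_area_m2 = ua[i])
    ba[i] <- bm$built_area_m2; bp[i] <- bm$built_prop
    pd[i] <- zonal_mean_density(units$geometry[[i]], dens)
  }
  bscore <- classify_built(bp)
  pscore <- classify_pop(pd, table)
  idx <- compute_index(bscore, pscore)
  df <- data.frame(uext_ID = units$uext_ID,
                   adm0_ISO3 = rep(iso3, n),
                   UNIT_AREA = ua,
                   BUILT_AREA = ba,
                   BUILT_PROP = bp,
                   NBUILTPROP = 1 - bp,
                   POP_DENS = pd,
                   BUILTscore = bscore,
                   POPscore = pscore,
                   INDEXvalue = idx,
                   stringsAsFactors = FALSE)
  structure(list(data = df, geometry = units$geometry,
                 unit_ID = units$unit_ID, crs = units$crs),
            class = "score_records")
}

#' @export
print.score_records <- function(x, ...) {
  cat(sprintf("score_records: %d unit(s), %d with data\n",
              nrow(x$data), sum(x$data$POPscore != -99)))
  ok <- x$data$INDEXvalue != -99
  if (any(ok)) {
    cat(sprintf("  index range %.1f-%.1f, median %.1f\n",
                min(x$data$INDEXvalue[ok]), max(x$data$INDEXvalue[ok]),
                stats::median(x$data$INDEXvalue[ok])))
  }
  invisible(x)
}
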