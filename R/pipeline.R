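# Pipeline orchestration.

#' Pipeline configuration
#'
#' Houses every tunable constant of the processing chain; the defaults
#' reproduce the published parameters (3 km component buffer, urban classes
#' 21-30, 100,000 m^2 fringe threshold, 1 ha minimum unit, 30-unit extent
#' filter, quality flag 1, 3-11 m apothem sweep, -99 nodata).
#'
#' @param buffer_m urban-component buffer in metres.
#' @param smod_urban_classes settlement classes treated as urban.
#' @param fringe_area_m2 fringe-flagging area threshold.
#' @param min_unit_area_m2 minimum spatial-unit area.
#' @param min_units_per_extent minimum unit count per kept extent.
#' @param d_min,d_max,d_step spacing-model apothem sweep (metres).
#' @param nodata nodata marker for attributes.
#' @param qa_required urban-centre quality-flag value selected.
#' @param seed optional integer seed (synthetic data only).
#' @return object of class `sdi_config`.
#' @export
sdi_config <- function(buffer_m = 3000, smod_urban_classes = 21:30,
                       fringe_area_m2 = 1e5, min_unit_area_m2 = 1e4,
                       min_units_per_extent = 30,
                       d_min = 3, d_max = 11, d_step = 1,
                       nodata = -99, qa_required = 1, seed = NULL) {
  stopifnot(buffer_m >= 0, fringe_area_m2 > 0, min_unit_area_m2 > 0,
            min_units_per_extent >= 0)
  structure(list(buffer_m = buffer_m, smod_urban_classes = smod_urban_classes,
                 fringe_area_m2 = fringe_area_m2,
                 min_unit_area_m2 = min_unit_area_m2,
                 min_units_per_extent = min_units_per_extent,
                 d_min = d_min, d_max = d_max, d_step = d_step,
                 nodata = nodata, qa_required = qa_required, seed = seed),
            class = "sdi_config")
}

#' Run the ease-of-social-distancing pipeline
#'
#' Executes the five stages in order: (1) delineate urban extents, (2) build
#' street-block spatial units and drop under-populated extents, (3) compute
#' built metrics, (4) compute population densities, and (5) classify scores
#' and the index. Deterministic for fixed inputs.
#'
#' @param x a `city_bundle` (synthetic inputs), or the settlement raster when
#'   calling the long-form method.
#' @param ... passed on between methods.
#' @return an `sdi_result`: `records` (a `score_records`), `units`,
#'   `extents`, `points` (urban-points attribute table), `report` (stage
#'   counts) and `config`.
#' @export
sdi_pipeline <- function(x, ...) UseMethod("sdi_pipeline")

#' @rdname sdi_pipeline
#' @param config an [sdi_config()].
#' @export
sdi_pipeline.city_bundle <- function(x, config = sdi_config(), ...) {
  sdi_pipeline_run(smod = x$smod, centres = x$centres,
                   features = x$features, settlements = x$settlements,
                   footprints = x$footprints, pop = x$pop,
                   surface = x$surface, admin = x$admin, water = x$water,
                   iso3 = x$iso3, config = config, ...)
}

#' @rdname sdi_pipeline
#' @export
sdi_pipeline.default <- function(x, ...) sdi_pipeline_run(smod = x, ...)

#' @rdname sdi_pipeline
#' @param smod settlement-class `sdi_raster`.
#' @param centres an [urban_centres()] record set.
#' @param features a [feature_set()].
#' @param settlements a [settlement_extents()] layer (or `NULL`).
#' @param footprints list of building-footprint regions.
#' @param pop,surface population-count and surface-area rasters (same grid).
#' @param admin,water optional national boundary / water regions.
#' @param iso3 country code.
#' @param adm0_name country name for the urban-points layer.
#' @export
sdi_pipeline_run <- function(smod, centres, features, settlements, footprints,
                             pop, surface, admin = NULL, water = NULL,
                             iso3 = "XXX", adm0_name = iso3,
                             config = sdi_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  table <- build_threshold_table(
    spacing_model(config$d_min, config$d_max, config$d_step))
  extents <- stage("extents", delineate_urban_extents(
    smod, centres, admin = admin, water = water,
    buffer_m = config$buffer_m, iso3 = iso3,
    urban_classes = config$smod_urban_classes,
    qa_value = config$qa_required))
  n_extents_found <- length(extents$uext_ID)
  units <- stage("units", build_spatial_units(
    extents, features, settlements,
    min_area = config$min_unit_area_m2,
    fringe_area = config$fringe_area_m2))
  n_units_built <- length(units$unit_ID)
  flt <- stage("filter", filter_small_extents(
    units, extents, config$min_units_per_extent))
  records <- stage("score", score_units(
    flt$units, footprints, pop, surface, table = table, iso3 = iso3))
  cen <- extents$centres
  keep <- !is.na(extents$centre_uext) &
    extents$centre_uext %in% flt$extents$uext_ID
  pts_ll <- t(vapply(which(keep), function(i)
    point_to_lonlat(cen$x[i], cen$y[i], cen$crs), numeric(2)))
  points <- data.frame(
    PNT_LAT = if (any(keep)) pts_ll[, 2] else numeric(0),
    PNT_LON = if (any(keep)) pts_ll[, 1] else numeric(0),
    adm0_NAME = rep(adm0_name, sum(keep)),
    adm0_ISO3 = rep(iso3, sum(keep)),
    urb_NAME = cen$name[keep],
    uext_ID = extents$centre_uext[keep],
    stringsAsFactors = FALSE)
  report <- list(
    extents_found = n_extents_found,
    extents_excluded = length(flt$dropped),
    extents_kept = length(flt$extents$uext_ID),
    units_built = n_units_built,
    units_scored = nrow(records$data),
    units_nodata = sum(records$data$POPscore == -99))
  structure(list(records = records, units = flt$units,
                 extents = flt$extents, points = points,
                 report = report, config = config, thresholds = table,
                 geometry_points = cen, crs = smod$crs),
            class = "sdi_result")
}

#' @export
print.sdi_result <- function(x, ...) {
  r <- x$report
  cat("Ease-of-social-distancing pipeline result\n")
  cat(sprintf("  urban extents: %d found, %d excluded (<%d units), %d kept\n",
              r$extents_found, r$extents_excluded,
              x$config$min_units_per_extent, r$extents_kept))
  cat(sprintf("  spatial units: %d built, %d scored, %d nodata\n",
              r$units_built, r$units_scored, r$units_nodata))
  ok <- x$records$data$INDEXvalue != -99
  if (any(ok))
    cat(sprintf("  index values: %.1f-%.1f (median %.1f)\n",
                min(x$records$data$INDEXvalue[ok]),
                max(x$records$data$INDEXvalue[ok]),
                stats::median(x$records$data$INDEXvalue[ok])))
  invisible(x)
}

#' @export
summary.sdi_result <- function(object, ...) {
  print(object)
  d <- object$records$data
  ok <- d$INDEXvalue != -99
  if (any(ok)) {
    cat("\n  score distribution (units with data):\n")
    print(table(BUILTscore = d$BUILTscore[ok], POPscore = d$POPscore[ok]))
  }
  invisible(object)
}

#' Map the index values of a pipeline result
#'
#' Draws the spatial units shaded by index value (grey for nodata) with the
#' urban-extent outlines, using base graphics.
#'
#' @param x an `sdi_result`.
#' @param y unused.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sdi_result <- function(x, y, ...) {
  geoms <- x$records$geometry
  if (length(geoms) == 0L) {
    warning("nothing to plot")
    return(invisible(x))
  }
  bb <- Reduce(function(a, b) c(min(a[1], b[1]), min(a[2], b[2]),
                                max(a[3], b[3]), max(a[4], b[4])),
               lapply(geoms, function(g) region_bbox(g)[c(1, 2, 3, 4)]))
  graphics::plot(NA, xlim = bb[c(1, 3)], ylim = bb[c(2, 4)], asp = 1,
                 xlab = "", ylab = "", main = "Ease of social distancing index",
                 ...)
  pal <- grDevices::hcl.colors(21, "YlOrRd", rev = TRUE)
  vals <- x$records$data$INDEXvalue
  for (i in seq_along(geoms)) {
    col <- if (vals[i] == -99) "grey80" else pal[round(vals[i] * 2) + 1]
    for (r in as_region(geoms[[i]]))
      graphics::polygon(r$x, r$y, col = col, border = "grey40", lwd = 0.3)
  }
  for (e in x$extents$geometry)
    for (r in as_region(e))
      graphics::polygon(r$x, r$y, border = "black", lwd = 1)
  invisible(x)
}
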