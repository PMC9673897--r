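# Published output layers.
#
# Three layers per country, with the published field names and file stems:
#   {ISO3}_SocialDistancing_v1_0_index         spatial units + scores
#   {ISO3}_SocialDistancing_v1_0_urban_extents extent polygons
#   {ISO3}_SocialDistancing_v1_0_urban_points  urban-centre points

INDEX_FIELDS <- c("uext_ID", "adm0_ISO3", "UNIT_AREA", "BUILT_AREA",
                  "BUILT_PROP", "NBUILTPROP", "POP_DENS", "BUILTscore",
                  "POPscore", "INDEXvalue")
POINTS_FIELDS <- c("PNT_LAT", "PNT_LON", "adm0_NAME", "adm0_ISO3",
                   "urb_NAME", "uext_ID")
EXTENTS_FIELDS <- c("uext_ID", "adm0_ISO3")

#' Write the published output layers
#'
#' Validates the bundle schema (exact field names, index extents being a
#' subset of the extents layer, numeric -99 for nodata) and writes the three
#' GeoJSON layers under the published file stems. Schema violations are
#' refused with field-level diagnostics.
#'
#' @param result an `sdi_result` from [sdi_pipeline()].
#' @param dir output directory (created if needed).
#' @param iso3 country code used in the file stems (defaults to the
#'   result's).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_outputs <- function(result, dir, iso3 = NULL) {
  stopifnot(inherits(result, "sdi_result"))
  if (is.null(iso3)) iso3 <- result$records$data$adm0_ISO3[1]
  if (is.null(iso3) || is.na(iso3)) iso3 <- "XXX"
  d <- result$records$data
  missing_idx <- setdiff(INDEX_FIELDS, names(d))
  if (length(missing_idx) > 0L)
    stop("index layer schema violation; missing field(s): ",
         paste(missing_idx, collapse = ", "))
  if (!all(d$uext_ID %in% result$extents$uext_ID))
    stop("index layer references uext_ID values absent from the extents layer")
  if (any(!is.finite(d$POP_DENS)))
    stop("POP_DENS must be numeric (-99 for nodata, never null)")
  missing_pts <- setdiff(POINTS_FIELDS, names(result$points))
  if (length(missing_pts) > 0L)
    stop("urban-points layer schema violation; missing field(s): ",
         paste(missing_pts, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- function(layer)
    file.path(dir, sprintf("%s_SocialDistancing_v1_0_%s.geojson", iso3, layer))
  crs <- result$crs
  p_index <- write_vector(
    sdi_features(result$records$geometry, d[, INDEX_FIELDS], "polygon", crs),
    stem("index"))
  p_ext <- write_vector(
    sdi_features(result$extents$geometry,
                 data.frame(uext_ID = result$extents$uext_ID,
                            adm0_ISO3 = result$extents$adm0_ISO3,
                            stringsAsFactors = FALSE),
                 "polygon", crs),
    stem("urban_extents"))
  keep <- result$points$uext_ID
  cen <- result$geometry_points
  pt_geom <- lapply(seq_len(nrow(result$points)), function(i)
    c(result$points$PNT_LON[i], result$points$PNT_LAT[i]))
  p_pts <- write_vector(
    sdi_features(pt_geom, result$points[, POINTS_FIELDS], "point",
                 sdi_crs("geographic")),
    stem("urban_points"))
  invisible(c(index = p_index, urban_extents = p_ext, urban_points = p_pts))
}
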