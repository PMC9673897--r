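# Vector feature collections and GeoJSON I/O.
#
# An `sdi_features` collection holds parallel geometry and attribute tables:
#   geometry - list of geoms: point = c(x, y); line = list of paths
#              (each list(x, y)); polygon = region (list of rings, even-odd)
#   data     - data.frame of attributes (one row per geometry)
#   type     - "point" | "line" | "polygon"
#   crs      - an sdi_crs
# GeoJSON is the on-disk format; a local metric CRS is recorded in a
# foreign "crs_local" member so fixtures survive a round trip.

#' Construct a feature collection
#'
#' @param geometry list of geometries (see Details in the package vignette).
#' @param data data.frame of attributes, one row per geometry.
#' @param type geometry type: "point", "line" or "polygon".
#' @param crs an [sdi_crs()].
#' @return object of class `sdi_features`.
#' @export
sdi_features <- function(geometry, data = NULL,
                         type = c("point", "line", "polygon"), crs) {
  type <- match.arg(type)
  if (is.null(data)) data <- data.frame(row.names = seq_along(geometry))
  stopifnot(nrow(data) == length(geometry), inherits(crs, "sdi_crs"))
  structure(list(geometry = geometry, data = data, type = type, crs = crs),
            class = "sdi_features")
}

#' @export
print.sdi_features <- function(x, ...) {
  cat(sprintf("sdi_features: %d %s feature(s), crs %s; fields: %s\n",
              length(x$geometry), x$type, x$crs$type,
              if (ncol(x$data)) paste(names(x$data), collapse = ", ") else "(none)"))
  invisible(x)
}

#' @export
length.sdi_features <- function(x) length(x$geometry)

subset_features <- function(x, idx) {
  sdi_features(x$geometry[idx], x$data[idx, , drop = FALSE], x$type, x$crs)
}

# ring validity: >= 3 distinct vertices, finite coords
ring_is_valid <- function(r) {
  length(r$x) >= 3L && all(is.finite(r$x)) && all(is.finite(r$y)) &&
    abs(ring_area_signed(r)) > 0
}

validate_features <- function(x, repair = TRUE) {
  if (x$type != "polygon") return(x)
  for (i in seq_along(x$geometry)) {
    reg <- as_region(x$geometry[[i]])
    ok <- vapply(reg, ring_is_valid, logical(1))
    if (!all(ok)) {
      if (!repair) stop("invalid polygon geometry in feature ", i)
      warning("dropping ", sum(!ok), " degenerate ring(s) in feature ", i)
      reg <- reg[ok]
    }
    x$geometry[[i]] <- reg
  }
  x
}

# --- GeoJSON conversion ----------------------------------------------------

close_ring <- function(r) {
  lapply(seq_along(r$x), function(i) c(r$x[i], r$y[i])) |>
    c(list(c(r$x[1L], r$y[1L])))
}

coords_to_path <- function(cc) {
  list(x = vapply(cc, function(p) as.numeric(p[[1]]), numeric(1)),
       y = vapply(cc, function(p) as.numeric(p[[2]]), numeric(1)))
}

coords_to_ring <- function(cc) {
  p <- coords_to_path(cc)
  n <- length(p$x)
  if (n > 1L && p$x[1L] == p$x[n] && p$y[1L] == p$y[n]) {
    p$x <- p$x[-n]; p$y <- p$y[-n]
  }
  p
}

geom_to_geojson <- function(g, type) {
  switch(type,
    point = list(type = "Point", coordinates = c(g[1], g[2])),
    line = {
      paths <- lapply(g, function(p) lapply(seq_along(p$x), function(i)
        c(p$x[i], p$y[i])))
      if (length(paths) == 1L)
        list(type = "LineString", coordinates = paths[[1]])
      else list(type = "MultiLineString", coordinates = paths)
    },
    polygon = {
      reg <- as_region(g)
      a <- vapply(reg, ring_area_signed, numeric(1))
      outers <- which(a > 0); holes <- which(a <= 0)
      if (length(outers) == 0L) { outers <- seq_along(reg); holes <- integer(0) }
      polys <- lapply(outers, function(o) list(close_ring(reg[[o]])))
      for (h in holes) {
        cand <- which(vapply(outers, function(o)
          point_in_ring(reg[[h]]$x[1L], reg[[h]]$y[1L], reg[[o]]), logical(1)))
        tgt <- if (length(cand)) cand[which.min(a[outers[cand]])] else 1L
        polys[[tgt]] <- c(polys[[tgt]], list(close_ring(reg[[h]])))
      }
      if (length(polys) == 1L)
        list(type = "Polygon", coordinates = polys[[1]])
      else list(type = "MultiPolygon", coordinates = polys)
    })
}

geojson_to_geom <- function(gj) {
  ty <- gj$type
  cc <- gj$coordinates
  switch(ty,
    Point = c(as.numeric(cc[[1]]), as.numeric(cc[[2]])),
    LineString = list(coords_to_path(cc)),
    MultiLineString = lapply(cc, coords_to_path),
    Polygon = lapply(cc, coords_to_ring),
    MultiPolygon = unlist(lapply(cc, function(poly)
      lapply(poly, coords_to_ring)), recursive = FALSE),
    stop("unsupported GeoJSON geometry type: ", ty))
}

geojson_geom_type <- function(ty) {
  switch(ty, Point = "point", MultiPoint = "point",
         LineString = "line", MultiLineString = "line",
         Polygon = "polygon", MultiPolygon = "polygon",
         stop("unsupported GeoJSON geometry type: ", ty))
}

#' Read a vector layer (GeoJSON)
#'
#' Geometries are validated on read; degenerate rings are repaired (dropped
#' with a warning) unless `repair = FALSE`, in which case they raise an
#' error. A collection without any CRS information is refused.
#'
#' @param path a `.geojson`/`.json` file.
#' @param repair drop degenerate rings with a warning instead of erroring.
#' @return an [sdi_features()] collection.
#' @export
read_vector <- function(path, repair = TRUE) {
  if (!file.exists(path)) stop("no such vector file: ", path)
  if (!grepl("\\.(geo)?json$", path, ignore.case = TRUE))
    stop("unsupported vector format (expected GeoJSON): ", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  crs <- if (!is.null(gj$crs_local)) {
    sdi_crs("local", lon0 = gj$crs_local$lon0, lat0 = gj$crs_local$lat0)
  } else sdi_crs("geographic")
  feats <- gj$features
  if (length(feats) == 0L)
    return(sdi_features(list(), data.frame(), "polygon", crs))
  geoms <- lapply(feats, function(f) geojson_to_geom(f$geometry))
  type <- geojson_geom_type(feats[[1]]$geometry$type)
  props <- lapply(feats, function(f)
    lapply(f$properties, function(v) if (is.null(v)) NA else v))
  keys <- unique(unlist(lapply(props, names)))
  data <- as.data.frame(
    stats::setNames(lapply(keys, function(k)
      unlist(lapply(props, function(p) if (is.null(p[[k]])) NA else p[[k]]))),
      keys), optional = TRUE)
  if (length(keys) == 0L) data <- data.frame(row.names = seq_along(geoms))
  validate_features(sdi_features(geoms, data, type, crs), repair = repair)
}

#' Write a vector layer (GeoJSON)
#'
#' @param x an [sdi_features()] collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vector <- function(x, path) {
  stopifnot(inherits(x, "sdi_features"))
  feats <- lapply(seq_along(x$geometry), function(i) {
    props <- as.list(x$data[i, , drop = FALSE])
    names(props) <- names(x$data)
    list(type = "Feature",
         properties = props,
         geometry = geom_to_geojson(x$geometry[[i]], x$type))
  })
  out <- list(type = "FeatureCollection", features = feats)
  if (x$crs$type == "local")
    out$crs_local <- list(lon0 = x$crs$lon0, lat0 = x$crs$lat0)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
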