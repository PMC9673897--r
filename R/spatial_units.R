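# Street-block spatial units.
#
# Within each urban extent, linear features (roads, railways, waterways),
# land-use boundary outlines and the extent boundary are noded and
# polygonised into faces. Large faces on the urban fringe (crossing a
# built-up-area or small-settled-area boundary) are further subdivided with
# residential land-use outlines, sub-hectare faces are merged into
# neighbours, and extents ending up with fewer than 30 units are discarded.

#' Linear and boundary features used to cut spatial units
#'
#' @param lines list of polylines (`list(x, y)` each): roads, railways,
#'   waterways, coastlines.
#' @param boundary list of land-use regions whose outlines act as unit
#'   boundaries (industrial, cemetery, military, golf, park, wetland, water,
#'   quarry, university, hospital grounds, reservoir, mine, airport,
#'   landfill, basin).
#' @param residential list of residential land-use regions (used only to
#'   subdivide flagged fringe polygons).
#' @param crs an [sdi_crs()] shared by all layers.
#' @return object of class `feature_set`.
#' @export
feature_set <- function(lines = list(), boundary = list(),
                        residential = list(), crs) {
  stopifnot(inherits(crs, "sdi_crs"))
  structure(list(lines = lines, boundary = lapply(boundary, as_region),
                 residential = lapply(residential, as_region), crs = crs),
            class = "feature_set")
}

#' Settlement extents classified BUA / SSA / hamlet
#'
#' @param regions list of settlement-extent regions.
#' @param stype character vector: `"BUA"`, `"SSA"` or `"hamlet"`.
#' @param crs an [sdi_crs()].
#' @return object of class `settlement_extents`.
#' @export
settlement_extents <- function(regions, stype, crs) {
  stype <- as.character(stype)
  stopifnot(length(regions) == length(stype),
            all(stype %in% c("BUA", "SSA", "hamlet")))
  structure(list(regions = lapply(regions, as_region), stype = stype,
                 crs = crs), class = "settlement_extents")
}

# ring -> closed path for polyline clipping (repeat first vertex)
ring_as_path <- function(r) list(x = c(r$x, r$x[1L]), y = c(r$y, r$y[1L]))

region_outline_paths <- function(reg) lapply(as_region(reg), ring_as_path)

# Collect the noding segment soup for one extent, in metric coordinates.
unit_segments <- function(extent_m, lines_m = list(), outline_regions_m = list()) {
  segs <- segs_from_region(extent_m)
  if (length(lines_m) > 0L) {
    clipped <- clip_lines_to_region(lines_m, extent_m)
    segs <- rbind(segs, segs_from_lines(clipped))
  }
  for (reg in outline_regions_m) {
    clipped <- clip_lines_to_region(region_outline_paths(reg), extent_m)
    segs <- rbind(segs, segs_from_lines(clipped))
  }
  segs
}

#' Polygonise features into candidate spatial units
#'
#' Nodes the line network (lines, land-use outlines, extent boundary) and
#' extracts the faces of the arrangement. The faces partition the extent.
#'
#' @param features a [feature_set()].
#' @param extent extent region (in `features$crs` units).
#' @param tol noding snap tolerance in metres (default 1e-3, i.e. 1 mm).
#' @return an `sdi_faces` object (regions, areas in m^2, adjacency), with the
#'   metric frame used attached as attribute `"frame"`.
#' @export
polygonize_features <- function(features, extent, tol = 1e-3) {
  stopifnot(inherits(features, "feature_set"))
  extent <- as_region(extent)
  fr <- local_frame(features$crs, region_centroid(extent))
  extent_m <- frame_region(extent, fr$to_m)
  lines_m <- lapply(features$lines, frame_ring, fun = fr$to_m)
  outlines_m <- lapply(features$boundary, frame_region, fun = fr$to_m)
  segs <- unit_segments(extent_m, lines_m, outlines_m)
  faces <- extract_faces(node_segments(segs, tol))
  keep_faces_in_region(faces, extent_m, attach_frame = fr)
}

keep_faces_in_region <- function(faces, region_m, attach_frame = NULL) {
  keep <- vapply(seq_len(n_faces(faces)), function(i) {
    p <- region_interior_point(faces$regions[[i]])
    isTRUE(points_in_region(p[1], p[2], region_m))
  }, logical(1))
  out <- structure(list(regions = faces$regions[keep],
                        areas = faces$areas[keep],
                        edge_sets = faces$edge_sets[keep],
                        edges = faces$edges), class = "sdi_faces")
  if (!is.null(attach_frame)) attr(out, "frame") <- attach_frame
  out
}

#' Flag large polygons on the urban fringe
#'
#' A face is flagged when its area exceeds `min_area` (default 100,000 m^2)
#' AND it intersects the boundary curve of a BUA or SSA settlement extent
#' (hamlets excluded). Faces strictly inside a settlement extent do not touch
#' the boundary curve and are not flagged.
#'
#' @param faces `sdi_faces` in metric coordinates (from
#'   [polygonize_features()]).
#' @param settlements_m list of BUA/SSA regions in the same metric frame.
#' @param min_area area threshold in m^2.
#' @return integer indices of flagged faces.
#' @export
flag_fringe_polygons <- function(faces, settlements_m, min_area = 1e5) {
  if (n_faces(faces) == 0L || length(settlements_m) == 0L) return(integer(0))
  big <- which(faces$areas > min_area)
  out <- integer(0)
  for (i in big) {
    for (s in settlements_m) {
      cl <- clip_lines_to_region(region_outline_paths(s), faces$regions[[i]])
      if (total_line_length(cl) > 1e-6) { out <- c(out, i); break }
    }
  }
  out
}

#' Subdivide a fringe polygon with residential outlines
#'
#' Re-polygonises a single face with residential land-use outlines as
#' additional edges. When no residential region intersects the face it is
#' returned unchanged.
#'
#' @param region face region (metric).
#' @param residential_m list of residential regions (metric).
#' @param tol noding tolerance.
#' @return list of face regions partitioning the input.
#' @export
subdivide_with_residential <- function(region, residential_m, tol = 1e-3) {
  region <- as_region(region)
  touching <- Filter(function(r) regions_overlap(region, r), residential_m)
  if (length(touching) == 0L) return(list(region))
  segs <- unit_segments(region, outline_regions_m = touching)
  faces <- extract_faces(node_segments(segs, tol))
  faces <- keep_faces_in_region(faces, region)
  faces$regions
}

#' Merge sub-threshold units into neighbours
#'
#' Iteratively dissolves the smallest face below `min_area` into a
#' neighbouring face until every face meets the constraint or one face
#' remains. The neighbour sharing the longest common boundary is chosen;
#' ties go to the larger neighbour, then the lowest stable face ID. An
#' isolated sub-threshold face with no neighbour is retained with a warning.
#'
#' @param faces `sdi_faces` with a shared edge table.
#' @param min_area minimum unit area in m^2 (default 10,000 = 1 ha).
#' @return `sdi_faces` with all areas >= `min_area` (up to retained
#'   isolates); attribute `"ids"` carries the surviving stable IDs.
#' @export
merge_small_units <- function(faces, min_area = 1e4) {
  ids <- attr(faces, "ids")
  if (is.null(ids)) ids <- seq_len(n_faces(faces))
  regions <- faces$regions; areas <- faces$areas; esets <- faces$edge_sets
  unmergeable <- rep(FALSE, length(areas))
  repeat {
    small <- which(areas < min_area & !unmergeable)
    if (length(small) == 0L || length(areas) <= 1L) break
    i <- small[which.min(areas[small])]
    nbr <- integer(0); shlen <- numeric(0)
    for (j in seq_along(areas)) {
      if (j == i) next
      sh <- intersect(esets[[i]], esets[[j]])
      if (length(sh) > 0L) {
        len <- sum(faces$edges$length[sh])
        if (len > 0) { nbr <- c(nbr, j); shlen <- c(shlen, len) }
      }
    }
    if (length(nbr) == 0L) {
      warning("retaining isolated sub-threshold unit (", round(areas[i]),
              " m^2): no neighbour to merge with")
      unmergeable[i] <- TRUE
      next
    }
    ord <- order(-shlen, -areas[nbr], ids[nbr])
    j <- nbr[ord[1L]]
    regions[[j]] <- rc_union2(regions[[j]], regions[[i]])
    areas[j] <- areas[j] + areas[i]          # exact conservation
    shared <- intersect(esets[[i]], esets[[j]])
    esets[[j]] <- setdiff(union(esets[[j]], esets[[i]]), shared)
    regions <- regions[-i]; areas <- areas[-i]
    esets <- esets[-i]; ids <- ids[-i]; unmergeable <- unmergeable[-i]
  }
  structure(list(regions = regions, areas = areas, edge_sets = esets,
                 edges = faces$edges),
            class = "sdi_faces", ids = ids, frame = attr(faces, "frame"))
}

#' Build spatial units for every urban extent
#'
#' Runs the unit stage per extent: polygonise features, flag and subdivide
#' fringe faces with residential outlines (re-noding the whole arrangement so
#' adjacency stays consistent), and merge sub-hectare faces.
#'
#' @param extents an `urban_extents` object.
#' @param features a [feature_set()].
#' @param settlements a [settlement_extents()] layer (may be empty).
#' @param min_area minimum unit area, m^2 (default 10,000).
#' @param fringe_area fringe-flagging threshold, m^2 (default 100,000).
#' @param tol noding tolerance, metres.
#' @return object of class `spatial_units`: per-unit `uext_ID`, `unit_ID`,
#'   `geometry` (regions in the input CRS), `area_m2`.
#' @export
build_spatial_units <- function(extents, features, settlements = NULL,
                                min_area = 1e4, fringe_area = 1e5,
                                tol = 1e-3) {
  stopifnot(inherits(extents, "urban_extents"))
  all_uext <- character(0); all_geom <- list(); all_area <- numeric(0)
  all_unit <- character(0)
  for (e in seq_along(extents$uext_ID)) {
    extent <- extents$geometry[[e]]
    fr <- local_frame(features$crs, region_centroid(as_region(extent)))
    extent_m <- frame_region(extent, fr$to_m)
    lines_m <- lapply(features$lines, frame_ring, fun = fr$to_m)
    outlines_m <- lapply(features$boundary, frame_region, fun = fr$to_m)
    segs <- unit_segments(extent_m, lines_m, outlines_m)
    faces <- keep_faces_in_region(extract_faces(node_segments(segs, tol)),
                                  extent_m)
    if (!is.null(settlements) && length(settlements$regions) > 0L) {
      keepers <- settlements$stype %in% c("BUA", "SSA")
      setts_m <- lapply(settlements$regions[keepers], frame_region,
                        fun = fr$to_m)
      flagged <- flag_fringe_polygons(faces, setts_m, fringe_area)
      if (length(flagged) > 0L && length(features$residential) > 0L) {
        resid_m <- lapply(features$residential, frame_region, fun = fr$to_m)
        flag_union <- rc_union(faces$regions[flagged])
        extra <- Filter(function(r) regions_overlap(flag_union, r), resid_m)
        if (length(extra) > 0L) {
          add <- do.call(rbind, lapply(extra, function(r)
            segs_from_lines(clip_lines_to_region(region_outline_paths(r),
                                                 flag_union))))
          segs <- rbind(segs, add)
          faces <- keep_faces_in_region(
            extract_faces(node_segments(segs, tol)), extent_m)
        }
      }
    }
    attr(faces, "ids") <- seq_len(n_faces(faces))
    merged <- merge_small_units(faces, min_area)
    if (n_faces(merged) > 0L) {
      geom <- lapply(merged$regions, frame_region, fun = fr$from_m)
      ids <- sprintf("%s_u%04d", extents$uext_ID[e], seq_len(n_faces(merged)))
      all_uext <- c(all_uext, rep(extents$uext_ID[e], n_faces(merged)))
      all_unit <- c(all_unit, ids)
      all_geom <- c(all_geom, geom)
      all_area <- c(all_area, merged$areas)
    }
  }
  structure(list(uext_ID = all_uext, unit_ID = all_unit, geometry = all_geom,
                 area_m2 = all_area, crs = features$crs),
            class = "spatial_units")
}

#' @export
print.spatial_units <- function(x, ...) {
  cat(sprintf("spatial_units: %d unit(s) in %d extent(s); area %.1f-%.1f ha\n",
              length(x$unit_ID), length(unique(x$uext_ID)),
              if (length(x$area_m2)) min(x$area_m2) / 1e4 else NA,
              if (length(x$area_m2)) max(x$area_m2) / 1e4 else NA))
  invisible(x)
}

#' @export
length.spatial_units <- function(x) length(x$unit_ID)

subset_units <- function(units, idx) {
  structure(list(uext_ID = units$uext_ID[idx], unit_ID = units$unit_ID[idx],
                 geometry = units$geometry[idx], area_m2 = units$area_m2[idx],
                 crs = units$crs), class = "spatial_units")
}

#' Drop urban extents with too few spatial units
#'
#' Extents with fewer than `min_units` units are removed together with their
#' units (such extents typically straddle a national boundary or lack enough
#' mapped features to be meaningfully subdivided).
#'
#' @param units a `spatial_units` collection.
#' @param extents the matching `urban_extents`.
#' @param min_units minimum unit count per extent (default 30; an extent with
#'   exactly `min_units` is kept).
#' @return `list(units, extents, dropped)` where `dropped` names the removed
#'   extents.
#' @export
filter_small_extents <- function(units, extents, min_units = 30) {
  counts <- table(factor(units$uext_ID, levels = extents$uext_ID))
  keep_ids <- names(counts)[counts >= min_units]
  dropped <- setdiff(extents$uext_ID, keep_ids)
  if (length(dropped) > 0L)
    message("excluding ", length(dropped), " urban extent(s) with < ",
            min_units, " spatial units: ", paste(dropped, collapse = ", "))
  keep_e <- extents$uext_ID %in% keep_ids
  new_ext <- structure(list(uext_ID = extents$uext_ID[keep_e],
                            geometry = extents$geometry[keep_e],
                            adm0_ISO3 = extents$adm0_ISO3[keep_e],
                            crs = extents$crs, centres = extents$centres,
                            centre_uext = ifelse(extents$centre_uext %in% keep_ids,
                                                 extents$centre_uext,
                                                 NA_character_)),
                       class = "urban_extents")
  list(units = subset_units(units, units$uext_ID %in% keep_ids),
       extents = new_ext, dropped = dropped)
}
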