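# Urban-extent delineation.
#
# From a settlement-model raster (classes: 10 water, 11-13 rural, 21-23
# peri-urban/clusters, 30 urban centre) and quality-flagged urban-centre
# records: reclassify classes 21-30 to a binary urban grid, keep connected
# urban components touching a true-positive centre, buffer each component by
# 3 km, take the convex hull, merge overlapping hulls to a fixpoint, and clip
# to the national land polygon.

#' Urban-centre records
#'
#' @param x,y point coordinates (CRS units).
#' @param qa_flag integer quality flag; 1 marks a true positive.
#' @param name urban-centre names.
#' @param iso3 country ISO-3166 alpha-3 code(s).
#' @param polygons optional list of centre footprint regions (one per centre);
#'   when absent the point is used for contiguity tests.
#' @param crs an [sdi_crs()].
#' @return object of class `urban_centres`.
#' @export
urban_centres <- function(x, y, qa_flag, name = NULL, iso3 = NA_character_,
                          polygons = NULL, crs) {
  n <- length(x)
  if (is.null(name)) name <- sprintf("centre_%d", seq_len(n))
  stopifnot(length(y) == n, length(qa_flag) == n, length(name) == n)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 qa_flag = qa_flag, name = as.character(name),
                 iso3 = rep_len(as.character(iso3), n),
                 polygons = polygons, crs = crs),
            class = "urban_centres")
}

#' @export
length.urban_centres <- function(x) length(x$x)

subset_centres <- function(cen, idx) {
  urban_centres(cen$x[idx], cen$y[idx], cen$qa_flag[idx], cen$name[idx],
                cen$iso3[idx],
                if (!is.null(cen$polygons)) cen$polygons[idx], cen$crs)
}

#' Select true-positive urban centres
#'
#' Keeps exactly the centres whose quality flag equals `qa_value`
#' (the database's true-positive marker), preserving input order.
#'
#' @param centres an [urban_centres()] record set.
#' @param qa_value flag value to keep (default 1).
#' @return the selected subset, same class.
#' @export
select_centres <- function(centres, qa_value = 1) {
  stopifnot(inherits(centres, "urban_centres"))
  if (length(centres) == 0L) return(centres)
  if (any(is.na(centres$qa_flag)))
    stop("quality flag missing for ", sum(is.na(centres$qa_flag)), " centre(s)")
  subset_centres(centres, which(centres$qa_flag == qa_value))
}

#' Reclassify a settlement-model raster to binary urban / not urban
#'
#' Cells with class in `urban_classes` (default 21-30: peri-urban through
#' urban centre) become 1, everything else (including nodata) 0.
#'
#' @param grid settlement-class `sdi_raster`.
#' @param urban_classes integer classes treated as urban.
#' @return binary `sdi_raster`.
#' @export
reclassify_urban <- function(grid, urban_classes = 21:30) {
  stopifnot(inherits(grid, "sdi_raster"))
  v <- grid$values
  b <- matrix(0L, nrow(v), ncol(v))
  b[!is.na(v) & v != grid$nodata & v %in% urban_classes] <- 1L
  sdi_raster(b, grid$xll, grid$yll, grid$cellsize, grid$crs, nodata = -1)
}

# Connected-component labelling of a binary matrix, two-pass with union-find.
label_components <- function(m, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  nxt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (m[i, j] != 1L) next
    nb <- integer(0)
    if (i > 1L && lab[i - 1L, j]) nb <- c(nb, lab[i - 1L, j])
    if (j > 1L && lab[i, j - 1L]) nb <- c(nb, lab[i, j - 1L])
    if (connectivity == 8) {
      if (i > 1L && j > 1L && lab[i - 1L, j - 1L]) nb <- c(nb, lab[i - 1L, j - 1L])
      if (i > 1L && j < nc && lab[i - 1L, j + 1L]) nb <- c(nb, lab[i - 1L, j + 1L])
    }
    if (length(nb) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else {
      roots <- vapply(nb, find, integer(1))
      r0 <- min(roots)
      lab[i, j] <- r0
      for (r in roots) parent[r] <- r0
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    dense <- match(roots, sort(unique(roots)))
    nz <- lab > 0L
    lab[nz] <- dense[lab[nz]]
  }
  lab
}

# union region of a component's cells (rectangles merged row-wise then unioned)
mask_region <- function(mask, raster) {
  cs <- raster$cellsize
  nr <- nrow(mask)
  rows <- list()
  for (i in seq_len(nr)) {
    js <- which(mask[i, ])
    if (length(js) == 0L) next
    runs <- split(js, cumsum(c(1L, diff(js) != 1L)))
    y1 <- raster$yll + (nr - i) * cs
    for (run in runs) {
      x0 <- raster$xll + (min(run) - 1L) * cs
      x1 <- raster$xll + max(run) * cs
      rows[[length(rows) + 1L]] <- list(rect_ring(x0, y1, x1, y1 + cs))
    }
  }
  rc_union(rows)
}

#' Connected urban components contiguous with a selected centre
#'
#' Labels the 1-cells of the binary urban grid (8-connectivity by default)
#' and keeps the components that spatially intersect at least one centre
#' polygon (or contain a centre point when no polygon is supplied).
#'
#' @param binary binary urban `sdi_raster` (from [reclassify_urban()]).
#' @param centres selected [urban_centres()].
#' @param connectivity 4 or 8 (default 8, so diagonal settlement strings are
#'   not split).
#' @return list of components, each `list(mask, region, centre_idx)`; empty
#'   list when no component qualifies.
#' @export
contiguous_urban_components <- function(binary, centres, connectivity = 8) {
  stopifnot(inherits(binary, "sdi_raster"), inherits(centres, "urban_centres"))
  lab <- label_components(binary$values == 1L, connectivity)
  nlab <- max(lab)
  if (nlab == 0L || length(centres) == 0L) return(list())
  out <- list()
  for (k in seq_len(nlab)) {
    mask <- lab == k
    reg <- mask_region(mask, binary)
    touching <- integer(0)
    for (ci in seq_along(centres$x)) {
      hit <- if (!is.null(centres$polygons) && !is.null(centres$polygons[[ci]])) {
        regions_overlap(reg, centres$polygons[[ci]])
      } else {
        points_in_region(centres$x[ci], centres$y[ci], reg)
      }
      if (isTRUE(hit)) touching <- c(touching, ci)
    }
    if (length(touching) > 0L)
      out[[length(out) + 1L]] <- list(mask = mask, region = reg,
                                      centre_idx = touching)
  }
  out
}

#' Buffer an urban component and take its convex hull
#'
#' The component's cell polygons are buffered by `buffer_m` metres (round
#' joins) and replaced by the convex hull of the buffered shape, giving a
#' smooth extent boundary. For geographic data the buffering is done in an
#' azimuthal equidistant frame centred on the component centroid.
#'
#' @param region component region in CRS units.
#' @param crs the component's [sdi_crs()].
#' @param buffer_m buffer distance in metres (default 3000; must be >= 0).
#' @return hull region (single CCW ring) in CRS units.
#' @export
buffer_and_hull <- function(region, crs, buffer_m = 3000) {
  if (buffer_m < 0) stop("buffer distance must be non-negative")
  region <- as_region(region)
  stopifnot(length(region) > 0L)
  fr <- local_frame(crs, region_centroid(region))
  reg_m <- frame_region(region, fr$to_m)
  buf <- if (buffer_m > 0) {
    polyclip::polyoffset(reg_m, buffer_m, jointype = "round",
                         arctol = buffer_m / 200, eps = 1e-6)
  } else reg_m
  xs <- unlist(lapply(buf, `[[`, "x")); ys <- unlist(lapply(buf, `[[`, "y"))
  hull <- convex_hull_ring(xs, ys)
  frame_region(list(hull), fr$from_m)
}

# buffered shape without the hull (used for geometric monotonicity checks)
buffer_component <- function(region, crs, buffer_m = 3000) {
  region <- as_region(region)
  fr <- local_frame(crs, region_centroid(region))
  reg_m <- frame_region(region, fr$to_m)
  buf <- if (buffer_m > 0) {
    polyclip::polyoffset(reg_m, buffer_m, jointype = "round",
                         arctol = buffer_m / 200, eps = 1e-6)
  } else reg_m
  frame_region(buf, fr$from_m)
}

#' Merge overlapping convex hulls into combined urban areas
#'
#' Groups hulls by transitive overlap, replaces each group by the convex hull
#' of the combined vertices, and repeats until no two outputs overlap.
#'
#' @param hulls list of hull regions.
#' @return `list(hulls = merged hull regions, groups = list of input indices
#'   contributing to each output)`.
#' @export
merge_overlapping_hulls <- function(hulls) {
  n <- length(hulls)
  if (n == 0L) return(list(hulls = list(), groups = list()))
  groups <- as.list(seq_len(n))
  cur <- hulls
  repeat {
    k <- length(cur)
    if (k <= 1L) break
    parent <- seq_len(k)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    merged_any <- FALSE
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (regions_overlap(cur[[i]], cur[[j]])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) { parent[max(ri, rj)] <- min(ri, rj); merged_any <- TRUE }
      }
    }
    if (!merged_any) break
    roots <- vapply(seq_len(k), find, integer(1))
    newc <- list(); newg <- list()
    for (r in unique(roots)) {
      idx <- which(roots == r)
      if (length(idx) == 1L) {
        newc <- c(newc, cur[idx]); newg <- c(newg, groups[idx])
      } else {
        xs <- unlist(lapply(idx, function(i)
          unlist(lapply(as_region(cur[[i]]), `[[`, "x"))))
        ys <- unlist(lapply(idx, function(i)
          unlist(lapply(as_region(cur[[i]]), `[[`, "y"))))
        newc <- c(newc, list(list(convex_hull_ring(xs, ys))))
        newg <- c(newg, list(sort(unique(unlist(groups[idx])))))
      }
    }
    cur <- newc; groups <- newg
  }
  list(hulls = cur, groups = groups)
}

#' Clip urban extents to the national land polygon
#'
#' Each extent is intersected with the administrative boundary polygon; when
#' water polygons (derived from the coastline) are supplied they are
#' subtracted first, so coastal extents stop at the shore. Extents left empty
#' are dropped.
#'
#' @param extents list of extent regions.
#' @param admin national boundary region.
#' @param water optional region of sea/water to subtract from the land.
#' @return `list(extents = clipped regions, kept = indices of survivors)`.
#' @export
clip_extents <- function(extents, admin, water = NULL) {
  admin <- as_region(admin)
  land <- if (!is.null(water)) rc_diff(admin, water) else admin
  out <- list(); kept <- integer(0)
  for (i in seq_along(extents)) {
    clipped <- rc_intersect(extents[[i]], land)
    if (length(clipped) > 0L && region_area(clipped) > 0) {
      ok <- vapply(clipped, ring_is_valid, logical(1))
      if (!all(ok)) {
        warning("extent ", i, ": dropping degenerate ring(s) after clipping")
        clipped <- clipped[ok]
        if (length(clipped) == 0L) next
      }
      out[[length(out) + 1L]] <- clipped
      kept <- c(kept, i)
    }
  }
  list(extents = out, kept = kept)
}

#' Delineate urban extents from a settlement raster and urban centres
#'
#' Full extent stage: select true-positive centres, reclassify the settlement
#' grid, keep urban components contiguous with a centre, buffer + hull each,
#' merge overlapping hulls, clip to the land polygon, and assign stable
#' extent IDs (`ISO3_NNNN`, ordered south-to-north then west-to-east by
#' centroid).
#'
#' @param smod settlement-class `sdi_raster`.
#' @param centres [urban_centres()].
#' @param admin optional national boundary region (CRS units).
#' @param water optional water region subtracted from the land.
#' @param buffer_m buffer distance in metres (default 3000).
#' @param iso3 country code stamped on outputs.
#' @param urban_classes classes treated as urban (default 21:30).
#' @param qa_value quality-flag value selecting centres (default 1).
#' @return object of class `urban_extents`: `uext_ID`, `geometry` (list of
#'   regions), `adm0_ISO3`, `crs`, plus the selected-centre table with their
#'   extent assignment.
#' @export
delineate_urban_extents <- function(smod, centres, admin = NULL, water = NULL,
                                    buffer_m = 3000, iso3 = "XXX",
                                    urban_classes = 21:30, qa_value = 1) {
  sel <- select_centres(centres, qa_value)
  binary <- reclassify_urban(smod, urban_classes)
  comps <- contiguous_urban_components(binary, sel)
  hulls <- lapply(comps, function(cm)
    buffer_and_hull(cm$region, smod$crs, buffer_m))
  mg <- merge_overlapping_hulls(hulls)
  geoms <- mg$hulls
  groups <- mg$groups
  if (!is.null(admin)) {
    cl <- clip_extents(geoms, admin, water)
    geoms <- cl$extents
    groups <- groups[cl$kept]
  }
  # stable ordering by centroid latitude then longitude
  if (length(geoms) > 0L) {
    ctr <- t(vapply(geoms, region_centroid, numeric(2)))
    # round out boolean-op jitter so coordinate ties order stably
    ord <- order(round(ctr[, 2], 6), round(ctr[, 1], 6))
    geoms <- geoms[ord]; groups <- groups[ord]
  }
  ids <- sprintf("%s_%04d", iso3, seq_along(geoms))
  # map each selected centre to the extent containing it
  centre_uext <- rep(NA_character_, length(sel))
  for (e in seq_along(geoms)) {
    cidx <- sort(unique(unlist(lapply(groups[[e]], function(g)
      comps[[g]]$centre_idx))))
    centre_uext[cidx] <- ids[e]
  }
  structure(list(uext_ID = ids, geometry = geoms,
                 adm0_ISO3 = rep(iso3, length(ids)), crs = smod$crs,
                 centres = sel, centre_uext = centre_uext),
            class = "urban_extents")
}

#' @export
print.urban_extents <- function(x, ...) {
  cat(sprintf("urban_extents: %d extent(s) [%s]\n",
              length(x$uext_ID), paste(x$uext_ID, collapse = ", ")))
  invisible(x)
}
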