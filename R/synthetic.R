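# Synthetic toy country with planted ground truth.
#
# The generator emulates every production input at toy scale: a 1 km
# settlement-class grid, quality-flagged urban centres, a national boundary,
# street/land-use features, BUA settlement extents, building footprints and a
# 100 m population-count raster with its surface-area companion. Cities are
# regular street-block grids; each block carries a planted built-proportion
# and population-density target, realised exactly: buildings are squares
# centred (with seeded jitter) in a k x k subcell lattice so the realised
# coverage equals the target, and population counts are density x cell area
# for cells whose centre falls in the block, so the zonal mean density equals
# the target for any subset of covered cells.

#' Configuration of a synthetic city
#'
#' @param n_blocks_x,n_blocks_y street-block grid dimensions (default 6 x 6,
#'   so one city clears the 30-unit extent filter on its own).
#' @param block_size block edge length in metres (default 300; must be a
#'   multiple of the 100 m population-grid cell so cell centres never fall on
#'   block boundaries).
#' @param built_prop_field per-block built-proportion targets in [0, 0.98]
#'   (vector of length `n_blocks_x * n_blocks_y`, row-major from the
#'   south-west block); `NULL` for the default score-sweeping pattern.
#' @param density_field per-block density targets in persons per km^2;
#'   `NA` plants a nodata block (population raster nodata there). `NULL` for
#'   the default pattern.
#' @param river add a diagonal waterway that subdivides the blocks it
#'   crosses (those blocks are excluded from the planted truth table).
#' @param fringe_blocks optional integer block indices forming a contiguous
#'   group whose interior street edges are omitted, creating a large fringe
#'   polygon that is flagged and subdivided with residential outlines.
#' @param seed integer seed fixing all randomness (building jitter).
#' @return object of class `city_config`.
#' @export
city_config <- function(n_blocks_x = 6, n_blocks_y = 6, block_size = 300,
                        built_prop_field = NULL, density_field = NULL,
                        river = FALSE, fringe_blocks = NULL, seed = 1L) {
  nb <- n_blocks_x * n_blocks_y
  stopifnot(n_blocks_x >= 1, n_blocks_y >= 1, block_size >= 100,
            block_size %% 100 == 0)
  if (is.null(built_prop_field) || is.null(density_field)) {
    dflt <- default_city_fields(nb)
    if (is.null(built_prop_field)) built_prop_field <- dflt$built
    if (is.null(density_field)) density_field <- dflt$density
  }
  stopifnot(length(built_prop_field) == nb, length(density_field) == nb)
  if (any(built_prop_field < 0 | built_prop_field > 0.98))
    stop("built-proportion targets must lie in [0, 0.98] (packable limit)")
  if (any(density_field[!is.na(density_field)] < 0))
    stop("density targets must be non-negative")
  structure(list(n_blocks_x = n_blocks_x, n_blocks_y = n_blocks_y,
                 block_size = block_size,
                 built_prop_field = built_prop_field,
                 density_field = density_field,
                 river = isTRUE(river), fringe_blocks = fringe_blocks,
                 seed = as.integer(seed)),
            class = "city_config")
}

# Default planted fields: block 1 has no buildings and no population, block 2
# is the extreme (10, 10) case, block 3 is a nodata block; the rest sweep
# built scores 1-10 and population scores 0-10. Density values sit
# mid-band so classification is insensitive to floating-point noise, and
# blocks with people always have buildings (population rasters are
# constrained to settled cells).
default_city_fields <- function(nb) {
  dens_by_score <- c(0, 1200, 2600, 3200, 4000, 5200, 7000, 9500,
                     15000, 25000, 35000)
  built <- numeric(nb); dens <- numeric(nb)
  for (b in seq_len(nb)) {
    if (b == 1L) { built[b] <- 0; dens[b] <- 0 }
    else if (b == 2L) { built[b] <- 0.95; dens[b] <- 35000 }
    else if (b == 3L) { built[b] <- 0.35; dens[b] <- NA }
    else {
      k <- b - 4L
      bscore <- 1L + (k %% 10L)
      pscore <- (k + 5L) %% 11L
      built[b] <- (bscore - 0.5) / 10
      dens[b] <- if (pscore > 0L && built[b] == 0) dens_by_score[2L]
                 else dens_by_score[pscore + 1L]
    }
  }
  list(built = built, density = dens)
}

# block lower-left corners, row-major from the SW block
block_origin <- function(cfg, b, offset) {
  i <- (b - 1L) %% cfg$n_blocks_x          # column, 0-based
  j <- (b - 1L) %/% cfg$n_blocks_x         # row, 0-based
  c(offset[1] + i * cfg$block_size, offset[2] + j * cfg$block_size)
}

block_ring <- function(cfg, b, offset) {
  o <- block_origin(cfg, b, offset)
  rect_ring(o[1], o[2], o[1] + cfg$block_size, o[2] + cfg$block_size)
}

# interior street edges of the block grid as short per-edge segments,
# omitting edges interior to the fringe group
city_street_lines <- function(cfg, offset) {
  bs <- cfg$block_size
  nbx <- cfg$n_blocks_x; nby <- cfg$n_blocks_y
  fringe <- cfg$fringe_blocks
  in_fringe <- function(i, j) {            # 0-based block column/row
    if (is.null(fringe)) return(FALSE)
    b <- j * nbx + i + 1L
    b >= 1L && b <= nbx * nby && b %in% fringe
  }
  lines <- list()
  for (i in 0:nbx) for (j in seq_len(nby) - 1L) {      # vertical edges
    if (i > 0 && i < nbx && in_fringe(i - 1L, j) && in_fringe(i, j)) next
    x <- offset[1] + i * bs
    lines[[length(lines) + 1L]] <-
      list(x = c(x, x), y = offset[2] + c(j, j + 1L) * bs)
  }
  for (j in 0:nby) for (i in seq_len(nbx) - 1L) {      # horizontal edges
    if (j > 0 && j < nby && in_fringe(i, j - 1L) && in_fringe(i, j)) next
    y <- offset[2] + j * bs
    lines[[length(lines) + 1L]] <-
      list(x = offset[1] + c(i, i + 1L) * bs, y = c(y, y))
  }
  lines
}

# square buildings on a k x k subcell lattice realising the coverage target
# exactly; jitter keeps each building strictly inside its subcell
city_buildings <- function(cfg, offset, k = 5L) {
  out <- list(); out_block <- integer(0)
  bs <- cfg$block_size; sub <- bs / k
  for (b in seq_along(cfg$built_prop_field)) {
    target <- cfg$built_prop_field[b]
    if (target <= 0) next
    s <- sqrt(target) * sub
    slack <- (sub - s) / 2
    o <- block_origin(cfg, b, offset)
    for (ii in seq_len(k) - 1L) for (jj in seq_len(k) - 1L) {
      jx <- stats::runif(1, -0.45, 0.45) * 2 * slack
      jy <- stats::runif(1, -0.45, 0.45) * 2 * slack
      cx <- o[1] + (ii + 0.5) * sub + jx
      cy <- o[2] + (jj + 0.5) * sub + jy
      out[[length(out) + 1L]] <-
        list(rect_ring(cx - s / 2, cy - s / 2, cx + s / 2, cy + s / 2))
      out_block <- c(out_block, b)
    }
  }
  list(regions = out, block = out_block)
}

river_path <- function(cfg, offset) {
  w <- cfg$n_blocks_x * cfg$block_size
  h <- cfg$n_blocks_y * cfg$block_size
  list(x = offset[1] + c(-10, w + 10),
       y = offset[2] + c(0.37, 0.63) * h)
}

blocks_crossed_by_river <- function(cfg, offset) {
  rp <- river_path(cfg, offset)
  tt <- seq(0, 1, length.out = 400)
  sx <- rp$x[1] + tt * diff(rp$x); sy <- rp$y[1] + tt * diff(rp$y)
  bs <- cfg$block_size
  i <- floor((sx - offset[1]) / bs); j <- floor((sy - offset[2]) / bs)
  ok <- i >= 0 & i < cfg$n_blocks_x & j >= 0 & j < cfg$n_blocks_y
  sort(unique(j[ok] * cfg$n_blocks_x + i[ok] + 1L))
}

densify_ring <- function(r, step = 100) {
  n <- length(r$x)
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    len <- sqrt((r$x[j] - r$x[i])^2 + (r$y[j] - r$y[i])^2)
    k <- max(1L, ceiling(len / step))
    tt <- (seq_len(k) - 1L) / k
    xs <- c(xs, r$x[i] + tt * (r$x[j] - r$x[i]))
    ys <- c(ys, r$y[i] + tt * (r$y[j] - r$y[i]))
  }
  list(x = xs, y = ys)
}

# truth-table row for one block
block_truth <- function(cfg, b, offset, extra_built_m2 = 0, planted = TRUE,
                        table = build_threshold_table()) {
  o <- block_origin(cfg, b, offset)
  a <- cfg$block_size^2
  bp <- cfg$built_prop_field[b] + extra_built_m2 / a
  dv <- cfg$density_field[b]
  pd <- if (is.na(dv)) -99 else dv
  bscore <- classify_built(min(bp, 1))
  pscore <- classify_pop(pd, table)
  data.frame(block = b,
             cx = o[1] + cfg$block_size / 2, cy = o[2] + cfg$block_size / 2,
             BUILT_PROP = bp, POP_DENS = pd,
             BUILTscore = bscore, POPscore = pscore,
             INDEXvalue = compute_index(bscore, pscore),
             planted = planted)
}

# ---------------------------------------------------------------------------

#' Generate a synthetic city bundle
#'
#' Builds a complete input bundle for one city: settlement grid, urban
#' centre, national boundary, street/land-use features, BUA settlement
#' extent, building footprints, population and surface-area rasters, plus
#' the planted truth table. Deterministic for a fixed seed.
#'
#' @param config a [city_config()].
#' @param crs_type `"local"` (metric plane) or `"geographic"` (the same city
#'   expressed in lon/lat with arc-second rasters).
#' @param iso3 country code used in outputs.
#' @return object of class `city_bundle`; see the package vignette for the
#'   layer inventory.
#' @export
generate_city <- function(config = city_config(),
                          crs_type = c("local", "geographic"),
                          iso3 = "SYN") {
  crs_type <- match.arg(crs_type)
  generate_country(list(list(cfg = config, offset = c(0, 0))),
                   crs_type = crs_type, iso3 = iso3)
}

# Multi-city builder shared by generate_city() and generate_edge_cases().
# Each element of `cities` is list(cfg, offset, extras) where extras may
# contain strip_block, sliver_block, straddle_pair, split_block.
generate_country <- function(cities, crs_type = "local", iso3 = "SYN",
                             lon0 = 30, lat0 = -10) {
  crs_local <- sdi_crs("local", lon0 = lon0, lat0 = lat0)
  geographic <- crs_type == "geographic"
  crs_out <- if (geographic) sdi_crs("geographic") else crs_local
  proj <- if (geographic) aeqd_projection(lon0, lat0) else NULL
  to_out_ring <- function(r) {
    if (!geographic) return(r)
    d <- densify_ring(r, 100)
    p <- proj$inv(d$x, d$y)
    list(x = p$lon, y = p$lat)
  }
  to_out_region <- function(reg) lapply(as_region(reg), to_out_ring)
  to_out_path <- function(l) {
    if (!geographic) return(l)
    p <- proj$inv(l$x, l$y)
    list(x = p$lon, y = p$lat)
  }
  seed <- cities[[1]]$cfg$seed
  set.seed(seed)

  # metric layout -----------------------------------------------------------
  rects <- lapply(cities, function(ci) {
    w <- ci$cfg$n_blocks_x * ci$cfg$block_size
    h <- ci$cfg$n_blocks_y * ci$cfg$block_size
    c(ci$offset[1], ci$offset[2], ci$offset[1] + w, ci$offset[2] + h)
  })
  margin <- 6000
  ax0 <- floor((min(vapply(rects, `[`, 0, 1)) - margin) / 1000) * 1000
  ay0 <- floor((min(vapply(rects, `[`, 0, 2)) - margin) / 1000) * 1000
  ax1 <- ceiling((max(vapply(rects, `[`, 0, 3)) + margin) / 1000) * 1000
  ay1 <- ceiling((max(vapply(rects, `[`, 0, 4)) + margin) / 1000) * 1000
  admin_m <- rect_ring(ax0, ay0, ax1, ay1)

  # features, footprints, settlements, truth --------------------------------
  lines_m <- list(); resid_m <- list(); setts_m <- list(); setts_type <- character(0)
  foot_m <- list(); truth <- list()
  for (cix in seq_along(cities)) {
    ci <- cities[[cix]]
    cfg <- ci$cfg; off <- ci$offset
    lines_m <- c(lines_m, city_street_lines(cfg, off))
    ex <- ci$extras
    planted_off <- integer(0)
    bs <- cfg$block_size
    if (!is.null(ex$strip_block)) {
      o <- block_origin(cfg, ex$strip_block, off)
      lines_m <- c(lines_m,
                   list(list(x = o[1] + c(0, bs), y = rep(o[2] + 90, 2)),
                        list(x = o[1] + c(0, bs), y = rep(o[2] + 130, 2))))
    }
    if (!is.null(ex$sliver_block)) {
      o <- block_origin(cfg, ex$sliver_block, off)
      lines_m <- c(lines_m, list(list(x = rep(o[1] + 20, 2), y = o[2] + c(0, bs))))
    }
    if (!is.null(ex$split_block)) {
      o <- block_origin(cfg, ex$split_block, off)
      lines_m <- c(lines_m, list(list(x = rep(o[1] + bs / 2, 2), y = o[2] + c(0, bs))))
      planted_off <- c(planted_off, ex$split_block)
    }
    if (cfg$river) {
      lines_m <- c(lines_m, list(river_path(cfg, off)))
      planted_off <- c(planted_off, blocks_crossed_by_river(cfg, off))
    }
    if (!is.null(cfg$fringe_blocks)) {
      planted_off <- c(planted_off, cfg$fringe_blocks)
      # residential areas inside the fringe group, to re-subdivide it
      for (b in cfg$fringe_blocks) {
        o <- block_origin(cfg, b, off)
        resid_m[[length(resid_m) + 1L]] <-
          list(rect_ring(o[1] + 40, o[2] + 40, o[1] + bs - 40, o[2] + bs - 40))
      }
    }
    rect <- rects[[cix]]
    # BUA settlement extent: the city slightly expanded, unless the fringe
    # group needs the boundary to cross it (then the BUA stops mid-group)
    bua <- if (is.null(cfg$fringe_blocks)) {
      rect_ring(rect[1] - 150, rect[2] - 150, rect[3] + 150, rect[4] + 150)
    } else {
      fo <- block_origin(cfg, min(cfg$fringe_blocks), off)
      rect_ring(rect[1] - 150, rect[2] - 150, fo[1] + bs / 2, fo[2] + bs / 2)
    }
    setts_m <- c(setts_m, list(list(bua)))
    setts_type <- c(setts_type, "BUA")
    bld <- city_buildings(cfg, off)
    foot_m <- c(foot_m, bld$regions)
    extra_built <- numeric(length(cfg$built_prop_field))
    if (!is.null(ex$straddle_pair)) {
      # one 20 x 20 m building centred on the shared vertical edge
      b1 <- ex$straddle_pair[1]; b2 <- ex$straddle_pair[2]
      o2 <- block_origin(cfg, b2, off)
      foot_m <- c(foot_m, list(list(rect_ring(o2[1] - 10, o2[2] + 140,
                                              o2[1] + 10, o2[2] + 160))))
      extra_built[c(b1, b2)] <- 200
    }
    for (b in seq_along(cfg$built_prop_field)) {
      truth[[length(truth) + 1L]] <-
        cbind(city = cix,
              block_truth(cfg, b, off, extra_built_m2 = extra_built[b],
                          planted = !(b %in% planted_off)))
    }
  }
  truth <- do.call(rbind, truth)

  # settlement-model raster --------------------------------------------------
  if (!geographic) {
    smod_cs <- 1000
    nc <- (ax1 - ax0) / smod_cs; nr <- (ay1 - ay0) / smod_cs
    cx <- ax0 + (seq_len(nc) - 0.5) * smod_cs
    cyv <- ay0 + (nr - seq_len(nr) + 0.5) * smod_cs
    smod_vals <- matrix(11, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      for (rect in rects) {
        if (cx[j] > rect[1] && cx[j] < rect[3] &&
            cyv[i] > rect[2] && cyv[i] < rect[4]) {
          smod_vals[i, j] <- 30; break
        }
        if (cx[j] > rect[1] - smod_cs && cx[j] < rect[3] + smod_cs &&
            cyv[i] > rect[2] - smod_cs && cyv[i] < rect[4] + smod_cs &&
            smod_vals[i, j] < 21) {
          smod_vals[i, j] <- 22
        }
      }
    }
    smod_vals[1, 1] <- 10   # a water corner
    smod <- sdi_raster(smod_vals, ax0, ay0, smod_cs, crs_local)
  } else {
    smod_cs <- 1 / 120      # 30 arc seconds
    smod <- geographic_class_raster(proj, ax0, ay0, ax1, ay1, smod_cs,
                                    rects, crs_out)
  }

  # population + surface-area rasters ---------------------------------------
  blocks_out <- list()   # per city: list of block regions in output coords
  for (cix in seq_along(cities)) {
    cfg <- cities[[cix]]$cfg; off <- cities[[cix]]$offset
    blocks_out[[cix]] <- lapply(seq_along(cfg$built_prop_field), function(b)
      to_out_ring(block_ring(cfg, b, off)))
  }
  if (!geographic) {
    pop_cs <- 100
    nc <- (ax1 - ax0) / pop_cs; nr <- (ay1 - ay0) / pop_cs
    cellarea <- matrix((pop_cs / 1000)^2, nr, nc)
    cx <- ax0 + (seq_len(nc) - 0.5) * pop_cs
    cyv <- ay0 + (nr - seq_len(nr) + 0.5) * pop_cs
  } else {
    pop_cs <- 1 / 1200      # 3 arc seconds
    ll <- proj$inv(c(ax0, ax1), c(ay0, ay1))
    x0 <- floor(ll$lon[1] / pop_cs) * pop_cs
    y0 <- floor(ll$lat[1] / pop_cs) * pop_cs
    nc <- ceiling((ll$lon[2] - x0) / pop_cs); nr <- ceiling((ll$lat[2] - y0) / pop_cs)
    ax0 <- x0; ay0 <- y0
    R_auth <- 6371007.181
    lat_top <- y0 + (nr - seq_len(nr) + 1L) * pop_cs
    lat_bot <- lat_top - pop_cs
    band <- (R_auth / 1000)^2 * (pop_cs * pi / 180) *
      (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
    cellarea <- matrix(rep(band, nc), nr, nc)
    cx <- x0 + (seq_len(nc) - 0.5) * pop_cs
    cyv <- y0 + (nr - seq_len(nr) + 0.5) * pop_cs
  }
  dens_vals <- matrix(0, nr, nc)
  for (cix in seq_along(cities)) {
    cfg <- cities[[cix]]$cfg
    for (b in seq_along(cfg$built_prop_field)) {
      reg <- list(blocks_out[[cix]][[b]])
      bb <- region_bbox(reg)
      jx <- which(cx > bb["xmin"] & cx < bb["xmax"])
      iy <- which(cyv > bb["ymin"] & cyv < bb["ymax"])
      if (length(jx) == 0L || length(iy) == 0L) next
      gx <- rep(cx[jx], times = length(iy))
      gy <- rep(cyv[iy], each = length(jx))
      inside <- points_in_region(gx, gy, reg)
      if (!any(inside)) next
      ii <- rep(iy, each = length(jx))[inside]
      jj <- rep(jx, times = length(iy))[inside]
      dv <- cfg$density_field[b]
      dens_vals[cbind(ii, jj)] <- if (is.na(dv)) NA else dv
    }
  }
  pop_vals <- dens_vals * cellarea
  pop_vals[is.na(pop_vals)] <- -99
  pop <- sdi_raster(pop_vals, ax0, ay0, pop_cs, crs_out, nodata = -99)
  surf <- sdi_raster(cellarea, ax0, ay0, pop_cs, crs_out, nodata = -99)

  # vectors in output coordinates -------------------------------------------
  centre_pts_m <- t(vapply(rects, function(r)
    c((r[1] + r[3]) / 2, (r[2] + r[4]) / 2), numeric(2)))
  decoy <- c(ax0 + 1500, ay0 + 1500)
  pts_m <- rbind(centre_pts_m, decoy)
  if (geographic) {
    p <- proj$inv(pts_m[, 1], pts_m[, 2])
    pts <- cbind(p$lon, p$lat)
  } else pts <- pts_m
  centres <- urban_centres(pts[, 1], pts[, 2],
                           qa_flag = c(rep(1L, length(cities)), 0L),
                           name = c(sprintf("SynthCity%02d", seq_along(cities)),
                                    "FalsePositive"),
                           iso3 = iso3,
                           polygons = c(lapply(rects, function(r)
                             to_out_region(list(rect_ring(r[1], r[2], r[3], r[4])))),
                             list(NULL)),
                           crs = crs_out)
  features <- feature_set(lines = lapply(lines_m, to_out_path),
                          residential = lapply(resid_m, to_out_region),
                          crs = crs_out)
  setts <- settlement_extents(lapply(setts_m, to_out_region), setts_type,
                              crs_out)
  footprints <- lapply(foot_m, to_out_region)
  admin <- to_out_region(list(admin_m))
  if (geographic) {
    tp <- proj$inv(truth$cx, truth$cy)
    truth$cx <- tp$lon; truth$cy <- tp$lat
  }
  structure(list(config = lapply(cities, `[[`, "cfg"), crs = crs_out,
                 iso3 = iso3, smod = smod, centres = centres, admin = admin,
                 water = NULL, features = features, settlements = setts,
                 footprints = footprints, pop = pop, surface = surf,
                 truth = truth),
            class = "city_bundle")
}

geographic_class_raster <- function(proj, ax0, ay0, ax1, ay1, cs, rects, crs_out) {
  ll <- proj$inv(c(ax0, ax1), c(ay0, ay1))
  x0 <- floor(ll$lon[1] / cs) * cs
  y0 <- floor(ll$lat[1] / cs) * cs
  nc <- ceiling((ll$lon[2] - x0) / cs); nr <- ceiling((ll$lat[2] - y0) / cs)
  cx <- x0 + (seq_len(nc) - 0.5) * cs
  cyv <- y0 + (nr - seq_len(nr) + 0.5) * cs
  gx <- rep(cx, times = nr); gy <- rep(cyv, each = nc)
  pm <- proj$fwd(gx, gy)
  vals <- matrix(11, nr, nc, byrow = FALSE)
  v <- rep(11, length(gx))
  for (rect in rects) {
    inside <- pm$x > rect[1] & pm$x < rect[3] & pm$y > rect[2] & pm$y < rect[4]
    near <- pm$x > rect[1] - 1000 & pm$x < rect[3] + 1000 &
      pm$y > rect[2] - 1000 & pm$y < rect[4] + 1000
    v[near & v < 21] <- 22
    v[inside] <- 30
  }
  vals[] <- matrix(v, nr, nc, byrow = TRUE)
  vals[1, 1] <- 10
  sdi_raster(vals, x0, y0, cs, crs_out)
}

#' @export
print.city_bundle <- function(x, ...) {
  cat(sprintf("city_bundle: %d city(ies), %s CRS, %d footprint(s), %d planted block(s)\n",
              length(x$config), x$crs$type, length(x$footprints),
              sum(x$truth$planted)))
  invisible(x)
}

#' Generate the edge-case bundle
#'
#' A three-city country exercising the pipeline's corner cases: a unit with
#' no buildings; a nodata-population block; a 40 m strip unit with no raster
#' cell centroid (forcing the interpolation fallback); a footprint straddling
#' two units; a sub-hectare sliver merged away; a fringe group subdivided by
#' residential outlines; a 29-unit extent (excluded by the 30-unit filter)
#' next to a 30-unit extent (kept).
#'
#' @param seed integer seed.
#' @param crs_type `"local"` or `"geographic"`.
#' @return a `city_bundle`.
#' @export
generate_edge_cases <- function(seed = 1L, crs_type = "local") {
  main <- city_config(seed = seed, fringe_blocks = c(29L, 30L, 35L, 36L))
  cityB <- city_config(n_blocks_x = 4, n_blocks_y = 7, seed = seed)
  cityC <- city_config(n_blocks_x = 4, n_blocks_y = 7, seed = seed)
  cities <- list(
    list(cfg = main, offset = c(0, 0),
         extras = list(strip_block = 4L, sliver_block = 19L,
                       straddle_pair = c(5L, 6L))),
    list(cfg = cityB, offset = c(30000, 0), extras = list()),
    list(cfg = cityC, offset = c(0, 30000), extras = list(split_block = 14L)))
  # the straddle pair and sliver/strip hosts must carry no planted buildings
  for (i in c(4L, 5L, 6L)) cities[[1]]$cfg$built_prop_field[i] <- 0
  cities[[1]]$cfg$built_prop_field[19L] <- 0
  generate_country(cities, crs_type = crs_type, iso3 = "SYN")
}

#' Write a bundle's layers to a fixture directory
#'
#' Persists every layer in plain text: GeoJSON vectors, ASCII-grid rasters,
#' CSV truth table and a JSON manifest. The bundle can be rebuilt
#' deterministically from its config instead; fixtures exist for external
#' tools and round-trip tests.
#'
#' @param bundle a `city_bundle`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  crs <- bundle$crs
  paths <- c(
    smod = write_raster(bundle$smod, file.path(dir, "smod.asc")),
    pop = write_raster(bundle$pop, file.path(dir, "population.asc")),
    surface = write_raster(bundle$surface, file.path(dir, "surface_area.asc")))
  cen <- bundle$centres
  paths["centres"] <- write_vector(
    sdi_features(lapply(seq_along(cen$x), function(i) c(cen$x[i], cen$y[i])),
                 data.frame(qa_flag = cen$qa_flag, name = cen$name,
                            iso3 = cen$iso3),
                 "point", crs),
    file.path(dir, "urban_centres.geojson"))
  paths["admin"] <- write_vector(
    sdi_features(list(bundle$admin), data.frame(iso3 = bundle$iso3),
                 "polygon", crs),
    file.path(dir, "admin.geojson"))
  paths["lines"] <- write_vector(
    sdi_features(lapply(bundle$features$lines, list),
                 data.frame(kind = rep("road", length(bundle$features$lines))),
                 "line", crs),
    file.path(dir, "features_lines.geojson"))
  if (length(bundle$features$residential) > 0L)
    paths["residential"] <- write_vector(
      sdi_features(bundle$features$residential, type = "polygon", crs = crs),
      file.path(dir, "residential.geojson"))
  paths["settlements"] <- write_vector(
    sdi_features(bundle$settlements$regions,
                 data.frame(type = bundle$settlements$stype), "polygon", crs),
    file.path(dir, "settlement_extents.geojson"))
  paths["footprints"] <- write_vector(
    sdi_features(bundle$footprints, type = "polygon", crs = crs),
    file.path(dir, "footprints.geojson"))
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  paths["truth"] <- file.path(dir, "truth.csv")
  invisible(paths)
}

#' Read a fixture directory back into an input bundle
#'
#' Reconstructs the pipeline inputs written by [write_fixture()]. Urban-centre
#' footprint polygons are not persisted, so component contiguity falls back
#' to the centre points (which the synthetic layout places inside their
#' settlements).
#'
#' @param dir fixture directory.
#' @return a `city_bundle` ready for [sdi_pipeline()].
#' @export
read_fixture <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("fixture is missing ", f)
    p
  }
  smod <- read_raster(need("smod.asc"))
  pop <- read_raster(need("population.asc"))
  surf <- read_raster(need("surface_area.asc"))
  cen_v <- read_vector(need("urban_centres.geojson"))
  centres <- urban_centres(
    vapply(cen_v$geometry, `[`, 0, 1), vapply(cen_v$geometry, `[`, 0, 2),
    qa_flag = cen_v$data$qa_flag, name = cen_v$data$name,
    iso3 = cen_v$data$iso3, crs = cen_v$crs)
  admin_v <- read_vector(need("admin.geojson"))
  lines_v <- read_vector(need("features_lines.geojson"))
  resid_path <- file.path(dir, "residential.geojson")
  resid <- if (file.exists(resid_path)) read_vector(resid_path)$geometry
           else list()
  setts_v <- read_vector(need("settlement_extents.geojson"))
  foot_v <- read_vector(need("footprints.geojson"))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) utils::read.csv(truth_path) else NULL
  structure(list(config = NULL, crs = smod$crs,
                 iso3 = if (!is.null(admin_v$data$iso3)) admin_v$data$iso3[1]
                        else "XXX",
                 smod = smod, centres = centres,
                 admin = admin_v$geometry[[1]], water = NULL,
                 features = feature_set(
                   lines = unlist(lines_v$geometry, recursive = FALSE),
                   residential = resid, crs = lines_v$crs),
                 settlements = settlement_extents(setts_v$geometry,
                                                  setts_v$data$type,
                                                  setts_v$crs),
                 footprints = foot_v$geometry, pop = pop, surface = surf,
                 truth = truth),
            class = "city_bundle")
}
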