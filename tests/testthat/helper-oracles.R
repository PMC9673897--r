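# Independent oracles used to cross-check the implementation.

# Shoelace area over the explicit vertices of a regular hexagon with the
# given apothem (circumradius 2a/sqrt(3), vertices every 60 degrees).
oracle_hexagon_area <- function(apothem) {
  R <- 2 * apothem / sqrt(3)
  th <- pi / 6 + (0:5) * pi / 3
  x <- R * cos(th); y <- R * sin(th)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(0.5 * sum(x * yn - xn * y))
}

# Count of hexagonal-lattice points (centre spacing 2d) inside a half-open
# square window; an enumeration upper bound for the packing density.
oracle_packing_count <- function(d, window = 1000) {
  s <- 2 * d
  dy <- s * sqrt(3) / 2
  count <- 0L
  row <- 0L
  repeat {
    y <- row * dy
    if (y >= window) break
    xoff <- if (row %% 2L == 1L) s / 2 else 0
    count <- count + length(seq(xoff, window - 1e-9, by = s))
    row <- row + 1L
  }
  count
}

# Recursive (stack-based) flood fill labelling of a binary matrix.
oracle_flood_components <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (si in seq_len(nr)) for (sj in seq_len(nc)) {
    if (m[si, sj] != 1L || lab[si, sj] != 0L) next
    cur <- cur + 1L
    stack <- list(c(si, sj))
    lab[si, sj] <- cur
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        ii <- p[1] + nb[k, 1]; jj <- p[2] + nb[k, 2]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
            m[ii, jj] == 1L && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# canonical form of a labelling: group cells by label, sorted
canonical_components <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  comps <- lapply(ids, function(k) sort(which(lab == k)))
  comps[order(vapply(comps, `[`, 0L, 1L))]
}

# region -> spatstat owin (outer rings anticlockwise, holes clockwise);
# orientation normalised by containment parity
region_to_owin <- function(reg) {
  reg <- sdindex:::as_region(reg)
  n <- length(reg)
  bdry <- lapply(seq_len(n), function(i) {
    depth <- sum(vapply(seq_len(n), function(j) {
      j != i && sdindex:::point_in_ring(reg[[i]]$x[1], reg[[i]]$y[1],
                                        reg[[j]])
    }, logical(1)))
    want_ccw <- depth %% 2L == 0L
    is_ccw <- sdindex:::ring_area_signed(reg[[i]]) > 0
    r <- if (want_ccw == is_ccw) reg[[i]] else sdindex:::ring_reverse(reg[[i]])
    list(x = r$x, y = r$y)
  })
  spatstat.geom::owin(poly = bdry, check = FALSE)
}

# intersection area oracle (spatstat.geom)
oracle_intersection_area <- function(A, B) {
  spatstat.geom::overlap.owin(region_to_owin(A), region_to_owin(B))
}

# even-odd point-in-region using sp::point.in.polygon as the primitive
oracle_points_in_region <- function(px, py, reg) {
  reg <- sdindex:::as_region(reg)
  inside <- rep(FALSE, length(px))
  for (r in reg) {
    hit <- sp::point.in.polygon(px, py, r$x, r$y) == 1
    inside <- xor(inside, hit)
  }
  inside
}

# Exhaustive zonal-mean oracle: loop over every raster cell, test its centre
# with the sp primitive, average the non-nodata values.
oracle_zonal_mean <- function(region, dens) {
  nr <- nrow(dens$values); nc <- ncol(dens$values)
  cs <- dens$cellsize
  vals <- numeric(0)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cx <- dens$xll + (j - 0.5) * cs
    cy <- dens$yll + (nr - i + 0.5) * cs
    if (oracle_points_in_region(cx, cy, region)) {
      v <- dens$values[i, j]
      if (!is.na(v) && v != dens$nodata) vals <- c(vals, v)
    }
  }
  if (length(vals) == 0L) return(NULL)
  mean(vals)
}

# Transitive-closure merge oracle: igraph components over the pairwise
# overlap graph (overlap measured by spatstat), hulls rebuilt with chull,
# iterated to a fixpoint.
oracle_merge_hulls <- function(hulls) {
  cur <- hulls
  groups <- as.list(seq_along(hulls))
  repeat {
    k <- length(cur)
    if (k <= 1L) break
    adj <- matrix(FALSE, k, k)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      # the spatstat overlap can return ~1e-16 for merely touching hulls
      if (oracle_intersection_area(cur[[i]], cur[[j]]) > 1e-9) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    mem <- igraph::components(g)$membership
    if (max(mem) == k) break
    newc <- list(); newg <- list()
    for (cl in seq_len(max(mem))) {
      idx <- which(mem == cl)
      if (length(idx) == 1L) {
        newc <- c(newc, cur[idx]); newg <- c(newg, groups[idx])
      } else {
        xs <- unlist(lapply(idx, function(i)
          unlist(lapply(sdindex:::as_region(cur[[i]]), `[[`, "x"))))
        ys <- unlist(lapply(idx, function(i)
          unlist(lapply(sdindex:::as_region(cur[[i]]), `[[`, "y"))))
        ch <- grDevices::chull(xs, ys)
        newc <- c(newc, list(list(list(x = xs[ch], y = ys[ch]))))
        newg <- c(newg, list(sort(unique(unlist(groups[idx])))))
      }
    }
    cur <- newc; groups <- newg
  }
  groups[order(vapply(groups, `[`, 0L, 1L))]
}

# random convex hull around points in a box (anticlockwise ring)
random_hull <- function(cx, cy, spread = 1) {
  x <- cx + stats::runif(8, -spread, spread)
  y <- cy + stats::runif(8, -spread, spread)
  ch <- rev(grDevices::chull(x, y))   # chull returns clockwise order
  list(list(x = x[ch], y = y[ch]))
}
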