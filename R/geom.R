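# Planar geometry primitives.
#
# A "ring" is a list(x =, y =) of vertices, not closed (the last vertex is
# not repeated). A "region" is a list of rings interpreted with the even-odd
# rule; rings we construct ourselves follow the convention outer = CCW
# (positive shoelace area), hole = CW (negative), which polyclip's Clipper
# backend also emits.

ring <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  list(x = as.numeric(x), y = as.numeric(y))
}

#' @noRd
ring_area_signed <- function(r) {
  x <- r$x; y <- r$y
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

ring_length <- function(r) {
  x <- r$x; y <- r$y
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(sqrt((xn - x)^2 + (yn - y)^2))
}

ring_reverse <- function(r) list(x = rev(r$x), y = rev(r$y))

# force a ring to a given orientation (+1 CCW, -1 CW)
ring_orient <- function(r, dir = 1) {
  if (sign(ring_area_signed(r)) == sign(dir) || ring_area_signed(r) == 0) r
  else ring_reverse(r)
}

rect_ring <- function(xmin, ymin, xmax, ymax) {
  ring(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

is_region <- function(p) {
  is.list(p) && length(p) > 0L && all(vapply(p, function(r)
    is.list(r) && !is.null(r$x) && !is.null(r$y), logical(1)))
}

as_region <- function(p) {
  if (is.null(p) || length(p) == 0L) return(list())
  if (!is.null(p$x)) list(p) else p
}

# Region area under the even-odd rule. Robust to ring orientation: each
# ring's contribution sign is set by its containment parity.
region_area <- function(reg) {
  reg <- as_region(reg)
  n <- length(reg)
  if (n == 0L) return(0)
  a <- vapply(reg, ring_area_signed, numeric(1))
  if (n == 1L) return(abs(a))
  total <- 0
  for (i in seq_len(n)) {
    depth <- 0L
    for (j in seq_len(n)) {
      if (i != j && point_in_ring(reg[[i]]$x[1L], reg[[i]]$y[1L], reg[[j]]))
        depth <- depth + 1L
    }
    total <- total + (if (depth %% 2L == 0L) abs(a[i]) else -abs(a[i]))
  }
  total
}

region_bbox <- function(reg) {
  reg <- as_region(reg)
  xs <- unlist(lapply(reg, `[[`, "x")); ys <- unlist(lapply(reg, `[[`, "y"))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Area-weighted centroid (outer rings minus holes, via signed shoelace).
region_centroid <- function(reg) {
  reg <- as_region(reg)
  cx <- 0; cy <- 0; atot <- 0
  for (r in reg) {
    x <- r$x; y <- r$y
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    cr <- x * yn - xn * y
    a <- 0.5 * sum(cr)
    if (abs(a) < .Machine$double.eps) next
    cx <- cx + sum((x + xn) * cr) / 6
    cy <- cy + sum((y + yn) * cr) / 6
    atot <- atot + a
  }
  if (abs(atot) < .Machine$double.eps) {
    xs <- unlist(lapply(reg, `[[`, "x")); ys <- unlist(lapply(reg, `[[`, "y"))
    return(c(mean(xs), mean(ys)))
  }
  c(cx / atot, cy / atot)
}

# Crossing-number test for one point against one ring.
point_in_ring <- function(px, py, r) {
  x <- r$x; y <- r$y
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  crosses <- ((y > py) != (yn > py))
  if (!any(crosses)) return(FALSE)
  xi <- x[crosses] + (py - y[crosses]) * (xn[crosses] - x[crosses]) /
    (yn[crosses] - y[crosses])
  sum(xi > px) %% 2L == 1L
}

# Vectorised even-odd test of many points against a region.
points_in_region <- function(px, py, reg) {
  reg <- as_region(reg)
  inside <- rep(FALSE, length(px))
  for (r in reg) {
    x <- r$x; y <- r$y
    m <- length(x)
    ins <- rep(FALSE, length(px))
    j <- m
    for (i in seq_len(m)) {
      x1 <- x[j]; y1 <- y[j]; x2 <- x[i]; y2 <- y[i]
      cond <- ((y1 > py) != (y2 > py))
      if (any(cond)) {
        xi <- x1 + (py[cond] - y1) * (x2 - x1) / (y2 - y1)
        hit <- cond
        hit[cond] <- xi > px[cond]
        ins <- xor(ins, hit)
      }
      j <- i
    }
    inside <- xor(inside, ins)
  }
  inside
}

# polyclip wrappers (even-odd fill on both operands) ------------------------

rc_op <- function(A, B, op) {
  # eps fixes the Clipper integer-scaling resolution (nanometre-scale here)
  # so boolean-op jitter stays far below the noding snap tolerance
  polyclip::polyclip(as_region(A), as_region(B), op = op,
                     fillA = "evenodd", fillB = "evenodd", eps = 1e-9)
}

rc_intersect <- function(A, B) rc_op(A, B, "intersection")
rc_diff      <- function(A, B) rc_op(A, B, "minus")
rc_union2    <- function(A, B) rc_op(A, B, "union")

# union of a list of regions
rc_union <- function(regions) {
  regions <- Filter(function(r) length(as_region(r)) > 0L, regions)
  if (length(regions) == 0L) return(list())
  Reduce(function(a, b) rc_union2(a, b), lapply(regions, as_region))
}

# do two regions share positive interior area?
regions_overlap <- function(A, B, min_area = 0) {
  ba <- region_bbox(as_region(A)); bb <- region_bbox(as_region(B))
  if (ba["xmin"] > bb["xmax"] || bb["xmin"] > ba["xmax"] ||
      ba["ymin"] > bb["ymax"] || bb["ymin"] > ba["ymax"]) return(FALSE)
  inter <- rc_intersect(A, B)
  length(inter) > 0L && region_area(inter) > min_area
}

# clip polylines (list of rings treated as open paths) to a region
clip_lines_to_region <- function(lines, reg) {
  if (length(lines) == 0L) return(list())
  polyclip::polyclip(lines, as_region(reg), op = "intersection",
                     closed = FALSE, fillB = "evenodd", eps = 1e-9)
}

total_line_length <- function(lines) {
  if (length(lines) == 0L) return(0)
  sum(vapply(lines, function(l) {
    if (length(l$x) < 2L) return(0)
    sum(sqrt(diff(l$x)^2 + diff(l$y)^2))
  }, numeric(1)))
}

# convex hull of a point set, returned as a CCW ring
convex_hull_ring <- function(x, y) {
  idx <- grDevices::chull(x, y)
  r <- ring(x[idx], y[idx])
  ring_orient(r, 1)
}

# A representative interior point of a region: scan a horizontal line through
# the widest vertical gap between vertex ordinates and take the midpoint of
# the first even-odd inside interval. Avoids vertices, so crossings are
# unambiguous.
region_interior_point <- function(reg) {
  reg <- as_region(reg)
  ys <- sort(unique(unlist(lapply(reg, `[[`, "y"))))
  cand_y <- if (length(ys) >= 2L) {
    gaps <- diff(ys)
    ord <- order(gaps, decreasing = TRUE)
    (ys[ord] + ys[ord + 1L]) / 2
  } else ys
  for (y0 in cand_y) {
    xs <- numeric(0)
    for (r in reg) {
      x <- r$x; y <- r$y
      xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
      cr <- (y > y0) != (yn > y0)
      if (any(cr))
        xs <- c(xs, x[cr] + (y0 - y[cr]) * (xn[cr] - x[cr]) / (yn[cr] - y[cr]))
    }
    xs <- sort(xs)
    if (length(xs) >= 2L) {
      widths <- xs[seq(2, length(xs), by = 2)] - xs[seq(1, length(xs) - 1, by = 2)]
      k <- which.max(widths)
      return(c((xs[2 * k - 1] + xs[2 * k]) / 2, y0))
    }
  }
  region_centroid(reg)
}
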