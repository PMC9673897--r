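# Planar arrangement: noding of a segment soup and face extraction.
#
# Street-block units are the faces of the arrangement induced by all linear
# features (roads, rails, waterways, land-use outlines) plus the urban-extent
# boundary. Faces are extracted by the classic half-edge walk: at each vertex
# the outgoing edges are sorted by angle and every directed edge is followed
# into the next face edge, producing one CCW cycle per bounded face and CW
# contour cycles that either bound the unbounded face or become holes.

snap_to <- function(v, tol) round(v / tol) * tol

# segments as a 4-column matrix (x1, y1, x2, y2)
segs_from_path <- function(x, y, closed = FALSE) {
  if (closed) { x <- c(x, x[1L]); y <- c(y, y[1L]) }
  n <- length(x)
  if (n < 2L) return(matrix(numeric(0), ncol = 4))
  cbind(x[-n], y[-n], x[-1L], y[-1L])
}

segs_from_lines <- function(lines) {
  do.call(rbind, c(list(matrix(numeric(0), ncol = 4)),
                   lapply(lines, function(l) segs_from_path(l$x, l$y))))
}

segs_from_region <- function(reg) {
  do.call(rbind, c(list(matrix(numeric(0), ncol = 4)),
                   lapply(as_region(reg), function(r)
                     segs_from_path(r$x, r$y, closed = TRUE))))
}

# Split all segments at mutual intersections (including collinear overlap and
# endpoint-on-interior contacts); snap coordinates to `tol`; deduplicate.
node_segments <- function(segs, tol = 1e-3) {
  if (is.null(segs) || nrow(segs) == 0L) return(matrix(numeric(0), ncol = 4))
  segs[] <- snap_to(segs, tol)
  len2 <- (segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2
  segs <- segs[len2 > (2 * tol)^2, , drop = FALSE]
  n <- nrow(segs)
  if (n == 0L) return(segs)
  cuts <- vector("list", n)
  ax <- segs[, 1]; ay <- segs[, 2]; bx <- segs[, 3]; by <- segs[, 4]
  rx <- bx - ax; ry <- by - ay
  lens <- sqrt(rx^2 + ry^2)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    qx <- ax[j] - ax[i]; qy <- ay[j] - ay[i]
    denom <- rx[i] * ry[j] - ry[i] * rx[j]
    thr <- 1e-9 * lens[i] * lens[j]
    tN <- qx * ry[j] - qy * rx[j]
    uN <- qx * ry[i] - qy * rx[i]
    cross_ok <- abs(denom) > thr
    t <- ifelse(cross_ok, tN / denom, NA_real_)
    u <- ifelse(cross_ok, uN / denom, NA_real_)
    hit <- cross_ok & t >= -1e-9 & t <= 1 + 1e-9 & u >= -1e-9 & u <= 1 + 1e-9
    if (any(hit)) {
      px <- snap_to(ax[i] + t[hit] * rx[i], tol)
      py <- snap_to(ay[i] + t[hit] * ry[i], tol)
      cuts[[i]] <- rbind(cuts[[i]], cbind(px, py))
      for (k in seq_along(which(hit))) {
        jj <- j[hit][k]
        cuts[[jj]] <- rbind(cuts[[jj]], cbind(px[k], py[k]))
      }
    }
    col <- !cross_ok & abs(tN) <= thr  # collinear pairs
    for (jj in j[col]) {
      for (pt in list(c(ax[jj], ay[jj]), c(bx[jj], by[jj]))) {
        t0 <- ((pt[1] - ax[i]) * rx[i] + (pt[2] - ay[i]) * ry[i]) / lens[i]^2
        if (t0 > 1e-9 && t0 < 1 - 1e-9)
          cuts[[i]] <- rbind(cuts[[i]], cbind(pt[1], pt[2]))
      }
      for (pt in list(c(ax[i], ay[i]), c(bx[i], by[i]))) {
        t0 <- ((pt[1] - ax[jj]) * (bx[jj] - ax[jj]) +
                 (pt[2] - ay[jj]) * (by[jj] - ay[jj])) / lens[jj]^2
        if (t0 > 1e-9 && t0 < 1 - 1e-9)
          cuts[[jj]] <- rbind(cuts[[jj]], cbind(pt[1], pt[2]))
      }
    }
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pts <- rbind(c(ax[i], ay[i]), cuts[[i]], c(bx[i], by[i]))
    tpar <- ((pts[, 1] - ax[i]) * rx[i] + (pts[, 2] - ay[i]) * ry[i]) / lens[i]^2
    ord <- order(tpar)
    pts <- pts[ord, , drop = FALSE]
    keep <- c(TRUE, rowSums(abs(diff(pts))) > tol / 2)
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) >= 2L)
      out[[i]] <- cbind(pts[-nrow(pts), 1], pts[-nrow(pts), 2],
                        pts[-1L, 1], pts[-1L, 2])
  }
  segs <- do.call(rbind, c(list(matrix(numeric(0), ncol = 4)), out))
  if (nrow(segs) == 0L) return(segs)
  # canonical undirected key for dedup
  swap <- segs[, 1] > segs[, 3] | (segs[, 1] == segs[, 3] & segs[, 2] > segs[, 4])
  canon <- segs
  canon[swap, ] <- segs[swap, c(3, 4, 1, 2)]
  key <- paste(canon[, 1], canon[, 2], canon[, 3], canon[, 4])
  canon[!duplicated(key), , drop = FALSE]
}

# Extract the faces of the arrangement of (already noded) segments.
# Returns an object of class "sdi_faces": parallel lists of face regions,
# areas and boundary-edge-id sets, plus the edge table (for adjacency).
extract_faces <- function(segs) {
  empty <- structure(list(regions = list(), areas = numeric(0),
                          edge_sets = list(),
                          edges = data.frame(v1 = integer(0), v2 = integer(0),
                                             length = numeric(0))),
                     class = "sdi_faces")
  if (is.null(segs) || nrow(segs) == 0L) return(empty)
  # coordinates are snapped, so equal vertices are bitwise-equal doubles
  vkey <- function(x, y) sprintf("%.15g %.15g", x, y)
  pkeys <- c(vkey(segs[, 1], segs[, 2]), vkey(segs[, 3], segs[, 4]))
  px <- c(segs[, 1], segs[, 3]); py <- c(segs[, 2], segs[, 4])
  uk <- !duplicated(pkeys)
  vx <- px[uk]; vy <- py[uk]; ukeys <- pkeys[uk]
  v1 <- match(pkeys[seq_len(nrow(segs))], ukeys)
  v2 <- match(pkeys[nrow(segs) + seq_len(nrow(segs))], ukeys)
  keep <- v1 != v2
  v1 <- v1[keep]; v2 <- v2[keep]
  m <- length(v1)
  if (m == 0L) return(empty)
  elen <- sqrt((vx[v2] - vx[v1])^2 + (vy[v2] - vy[v1])^2)
  # directed edges: 1..m are v1->v2, m+1..2m are v2->v1
  org <- c(v1, v2); tgt <- c(v2, v1)
  eid <- c(seq_len(m), seq_len(m))
  ang <- atan2(vy[tgt] - vy[org], vx[tgt] - vx[org])
  nxt <- integer(2 * m)
  ord <- order(org, ang)
  # for each vertex, CCW-sorted outgoing edges; next(de) = predecessor of
  # rev(de) in that cyclic order
  starts <- c(which(!duplicated(org[ord])), length(ord) + 1L)
  rev_of <- function(de) if (de <= m) de + m else de - m
  pos_in <- integer(2 * m)  # position of each directed edge in its vertex list
  vert_list <- vector("list", length(vx))
  for (b in seq_len(length(starts) - 1L)) {
    idx <- ord[starts[b]:(starts[b + 1L] - 1L)]
    vert_list[[org[idx[1L]]]] <- idx
    pos_in[idx] <- seq_along(idx)
  }
  for (de in seq_len(2L * m)) {
    rv <- rev_of(de)
    lst <- vert_list[[org[rv]]]
    k <- pos_in[rv]
    nxt[de] <- lst[if (k == 1L) length(lst) else k - 1L]
  }
  visited <- logical(2 * m)
  cycles <- list()
  for (s in seq_len(2L * m)) {
    if (visited[s]) next
    de <- s; verts <- integer(0); eids <- integer(0)
    repeat {
      visited[de] <- TRUE
      verts <- c(verts, org[de]); eids <- c(eids, eid[de])
      de <- nxt[de]
      if (de == s) break
    }
    cycles[[length(cycles) + 1L]] <-
      list(ring = list(x = vx[verts], y = vy[verts]),
           vids = verts, eids = eids)
  }
  careas <- vapply(cycles, function(cy) ring_area_signed(cy$ring), numeric(1))
  pos <- which(careas > 0); neg <- which(careas <= 0)
  faces_regions <- lapply(pos, function(i) list(cycles[[i]]$ring))
  faces_edges <- lapply(pos, function(i) unique(cycles[[i]]$eids))
  faces_area <- careas[pos]
  if (length(neg) > 0L && length(pos) > 0L) {
    pos_bbox <- lapply(pos, function(i) {
      r <- cycles[[i]]$ring
      c(min(r$x), min(r$y), max(r$x), max(r$y))
    })
    for (ni in neg) {
      tvx <- vx[cycles[[ni]]$vids[1L]]; tvy <- vy[cycles[[ni]]$vids[1L]]
      best <- 0L; best_area <- Inf
      for (k in seq_along(pos)) {
        bb <- pos_bbox[[k]]
        if (tvx < bb[1] || tvx > bb[3] || tvy < bb[2] || tvy > bb[4]) next
        if (careas[pos[k]] >= best_area) next
        if (any(cycles[[ni]]$vids %in% cycles[[pos[k]]]$vids)) next
        if (point_in_ring(tvx, tvy, cycles[[pos[k]]]$ring)) {
          best <- k; best_area <- careas[pos[k]]
        }
      }
      if (best > 0L) {
        faces_regions[[best]] <- c(faces_regions[[best]], list(cycles[[ni]]$ring))
        faces_edges[[best]] <- unique(c(faces_edges[[best]], cycles[[ni]]$eids))
        faces_area[best] <- faces_area[best] + careas[ni]
      }
    }
  }
  structure(list(regions = faces_regions,
                 areas = faces_area,
                 edge_sets = faces_edges,
                 edges = data.frame(v1 = v1, v2 = v2, length = elen)),
            class = "sdi_faces")
}

n_faces <- function(f) length(f$regions)

# shared-boundary length between two faces (sum of shared arrangement edges)
shared_edge_length <- function(faces, i, j) {
  sh <- intersect(faces$edge_sets[[i]], faces$edge_sets[[j]])
  if (length(sh) == 0L) return(0)
  sum(faces$edges$length[sh])
}

face_neighbours <- function(faces, i) {
  out <- integer(0)
  for (j in seq_len(n_faces(faces))) {
    if (j == i) next
    if (length(intersect(faces$edge_sets[[i]], faces$edge_sets[[j]])) > 0L)
      out <- c(out, j)
  }
  out
}
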