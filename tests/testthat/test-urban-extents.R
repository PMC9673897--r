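make_centres <- function(qa, crs = local_crs()) {
  urban_centres(x = seq_along(qa) * 1000, y = rep(500, length(qa)),
                qa_flag = qa, crs = crs)
}

test_that("centre selection keeps exactly the true positives, in order", {
  cen <- make_centres(c(1, 0, 1, 2))
  sel <- select_centres(cen)
  expect_equal(length(sel), 2L)
  expect_equal(sel$x, c(1000, 3000))
  expect_equal(length(select_centres(make_centres(integer(0)))), 0L)
  allq <- make_centres(c(1, 1, 1))
  expect_equal(select_centres(allq)$x, allq$x)
  expect_error(select_centres(make_centres(c(1, NA))), "flag missing")
})

test_that("settlement classes 21-30 reclassify to urban, others to zero", {
  vals <- matrix(c(30, 21, 23, 13, 11, 10, -99, 22, 30), 3, 3)
  r <- sdi_raster(vals, 0, 0, 1000, local_crs(), nodata = -99)
  b <- reclassify_urban(r)
  expect_equal(as.vector(b$values),
               as.integer(c(1, 1, 1, 0, 0, 0, 0, 1, 1)))
})

test_that("connected components agree with a flood-fill oracle", {
  set.seed(99)
  for (conn in c(8, 4)) {
    for (rep in 1:10) {
      m <- matrix(rbinom(15 * 12, 1, 0.4), 15, 12)
      got <- sdindex:::label_components(m == 1L, conn)
      want <- oracle_flood_components(m, conn)
      expect_equal(canonical_components(got), canonical_components(want))
    }
  }
})

test_that("only components contiguous with a selected centre are kept", {
  vals <- matrix(0, 8, 8)
  vals[2:3, 2:3] <- 30       # blob with a centre
  vals[6:7, 6:7] <- 23       # blob without
  r <- sdi_raster(vals, 0, 0, 1000, local_crs(), nodata = -99)
  cen <- urban_centres(2500, 5500, qa_flag = 1, crs = local_crs())
  # y: row 2-3 of 8 rows -> y in (5000, 7000)
  comps <- contiguous_urban_components(reclassify_urban(r), cen)
  expect_length(comps, 1L)
  expect_equal(comps[[1]]$centre_idx, 1L)
  expect_true(sdindex:::points_in_region(2500, 5500, comps[[1]]$region))
})

test_that("buffering then hulling is monotone and contains the component", {
  crs <- local_crs()
  cell <- list(sdindex:::rect_ring(0, 0, 1000, 1000))
  hull <- buffer_and_hull(cell, crs, 3000)
  buf <- sdindex:::buffer_component(cell, crs, 3000)
  a_cell <- sdindex:::region_area(cell)
  a_buf <- sdindex:::region_area(buf)
  a_hull <- sdindex:::region_area(hull)
  expect_gte(a_buf, a_cell)
  expect_gte(a_hull, a_buf - 1e-6)
  # hull contains every corner of the cell
  expect_true(all(sdindex:::points_in_region(
    c(1, 999, 1, 999), c(1, 1, 999, 999), hull)))
  # convex component, zero buffer: hull equals the outline
  h0 <- buffer_and_hull(cell, crs, 0)
  expect_equal(sdindex:::region_area(h0), a_cell, tolerance = 1e-9)
  expect_error(buffer_and_hull(cell, crs, -1), "non-negative")
})

test_that("overlapping hulls merge transitively to disjoint extents", {
  sq <- function(x0, y0, w = 2)
    list(sdindex:::rect_ring(x0, y0, x0 + w, y0 + w))
  # disjoint pair unchanged
  mg <- merge_overlapping_hulls(list(sq(0, 0), sq(10, 10)))
  expect_length(mg$hulls, 2L)
  expect_equal(mg$groups, list(1L, 2L))
  # overlapping pair becomes one hull covering both
  mg2 <- merge_overlapping_hulls(list(sq(0, 0), sq(1, 1)))
  expect_length(mg2$hulls, 1L)
  expect_true(all(sdindex:::points_in_region(c(0.1, 2.9), c(0.1, 2.9),
                                             mg2$hulls[[1]])))
  # chain A-B, B-C with A,C disjoint collapses to a single extent
  mg3 <- merge_overlapping_hulls(list(sq(0, 0), sq(1.5, 0), sq(3, 0)))
  expect_length(mg3$hulls, 1L)
  expect_equal(mg3$groups[[1]], 1:3)
})

test_that("hull merging matches the union-find oracle on random sets", {
  set.seed(123)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    hulls <- lapply(seq_len(n), function(i)
      random_hull(runif(1, 0, 12), runif(1, 0, 12), spread = 2))
    got <- merge_overlapping_hulls(hulls)
    want <- oracle_merge_hulls(hulls)
    expect_equal(got$groups[order(vapply(got$groups, `[`, 0L, 1L))], want)
    # outputs pairwise interior-disjoint
    if (length(got$hulls) > 1L) {
      for (i in seq_len(length(got$hulls) - 1L))
        for (j in (i + 1L):length(got$hulls))
          expect_false(sdindex:::regions_overlap(got$hulls[[i]],
                                                 got$hulls[[j]],
                                                 min_area = 1e-9))
    }
  }
})

test_that("extents clip to the land polygon and offshore extents drop", {
  admin <- list(sdindex:::rect_ring(0, 0, 100, 100))
  inland <- list(sdindex:::rect_ring(10, 10, 30, 30))
  straddle <- list(sdindex:::rect_ring(80, 40, 120, 60))
  offshore <- list(sdindex:::rect_ring(150, 150, 170, 170))
  cl <- clip_extents(list(inland, straddle, offshore), admin)
  expect_equal(cl$kept, c(1L, 2L))
  expect_equal(sdindex:::region_area(cl$extents[[1]]), 400, tolerance = 1e-6)
  expect_equal(sdindex:::region_area(cl$extents[[2]]),
               oracle_intersection_area(straddle, admin), tolerance = 1e-6)
  # water subtraction trims the coastal side
  water <- list(sdindex:::rect_ring(90, 0, 100, 100))
  cl2 <- clip_extents(list(straddle), admin, water)
  expect_equal(sdindex:::region_area(cl2$extents[[1]]), 200, tolerance = 1e-6)
})

test_that("delineation is deterministic and labels extents stably", {
  b <- default_bundle()
  e1 <- delineate_urban_extents(b$smod, b$centres, admin = b$admin,
                                iso3 = "SYN")
  e2 <- delineate_urban_extents(b$smod, b$centres, admin = b$admin,
                                iso3 = "SYN")
  expect_identical(e1$uext_ID, e2$uext_ID)
  expect_identical(e1$geometry, e2$geometry)
  expect_match(e1$uext_ID, "^SYN_\\d{4}$")
  # every extent contains its centre
  for (k in seq_along(e1$uext_ID)) {
    ci <- which(e1$centre_uext == e1$uext_ID[k])
    expect_true(any(sdindex:::points_in_region(e1$centres$x[ci],
                                               e1$centres$y[ci],
                                               e1$geometry[[k]])))
  }
})
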