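crs <- sdi_crs("local", lon0 = 30, lat0 = -10)

test_that("crossing lines subdivide a square extent into four faces", {
  ext <- list(sdindex:::rect_ring(0, 0, 1000, 1000))
  fs <- feature_set(lines = list(list(x = c(500, 500), y = c(-10, 1010)),
                                 list(x = c(-10, 1010), y = c(500, 500))),
                    crs = crs)
  faces <- polygonize_features(fs, ext)
  expect_equal(sdindex:::n_faces(faces), 4L)
  expect_equal(sort(faces$areas), rep(250000, 4))
})

test_that("an extent without features polygonises to itself", {
  ext <- list(sdindex:::rect_ring(0, 0, 300, 200))
  faces <- polygonize_features(feature_set(crs = crs), ext)
  expect_equal(sdindex:::n_faces(faces), 1L)
  expect_equal(faces$areas, 60000)
})

test_that("faces conserve the extent area to below 0.01%", {
  set.seed(5)
  ext <- list(sdindex:::rect_ring(0, 0, 1200, 900))
  lines <- c(
    lapply(runif(4, 100, 1100), function(x) list(x = c(x, x), y = c(-10, 910))),
    lapply(runif(3, 100, 800), function(y) list(x = c(-10, 1210), y = c(y, y))),
    list(list(x = c(-10, 1210), y = c(100, 850))))
  faces <- polygonize_features(feature_set(lines = lines, crs = crs), ext)
  expect_lt(abs(sum(faces$areas) - 1200 * 900) / (1200 * 900), 1e-4)
})

test_that("land-use boundary polygons become standalone faces", {
  ext <- list(sdindex:::rect_ring(0, 0, 600, 600))
  airport <- list(sdindex:::rect_ring(100, 100, 300, 250))
  faces <- polygonize_features(feature_set(boundary = list(airport),
                                           crs = crs), ext)
  expect_equal(sdindex:::n_faces(faces), 2L)
  expect_equal(sort(faces$areas), c(200 * 150, 600 * 600 - 200 * 150))
})

test_that("fringe flagging needs both the area and the boundary condition", {
  ext <- list(sdindex:::rect_ring(0, 0, 1500, 400))
  # three faces: 150,000 m^2 | 150,000 m^2 | 300,000 m^2
  fs <- feature_set(lines = list(list(x = c(375, 375), y = c(-1, 401)),
                                 list(x = c(750, 750), y = c(-1, 401))),
                    crs = crs)
  faces <- polygonize_features(fs, ext)
  expect_equal(sdindex:::n_faces(faces), 3L)
  ord <- order(vapply(faces$regions, function(r)
    sdindex:::region_bbox(r)["xmin"], numeric(1)))
  # BUA boundary crosses only the first face; second face lies strictly
  # inside the BUA; a small face crossing the boundary is below the area bar
  bua <- list(sdindex:::rect_ring(200, -50, 2000, 450))
  flagged <- flag_fringe_polygons(faces, list(bua), 1e5)
  expect_equal(flagged, ord[1])
  small_faces <- polygonize_features(
    feature_set(lines = list(list(x = c(100, 100), y = c(-1, 401))),
                crs = crs),
    list(sdindex:::rect_ring(0, 0, 220, 220)))
  sm_flag <- flag_fringe_polygons(small_faces,
                                  list(list(sdindex:::rect_ring(
                                    150, -50, 400, 300))), 1e5)
  expect_length(sm_flag, 0L)   # 48,400 m^2 max: area condition fails
})

test_that("residential subdivision splits flagged faces and conserves area", {
  face <- list(sdindex:::rect_ring(0, 0, 400, 400))
  inside <- list(sdindex:::rect_ring(100, 100, 250, 250))
  parts <- subdivide_with_residential(face, list(inside))
  expect_length(parts, 2L)
  areas <- vapply(parts, sdindex:::region_area, numeric(1))
  expect_equal(sum(areas), 160000, tolerance = 1e-9)
  expect_equal(sort(areas), c(22500, 137500))
  # non-intersecting residential data leaves the face untouched
  far <- list(sdindex:::rect_ring(900, 900, 950, 950))
  expect_identical(subdivide_with_residential(face, list(far)), list(face))
})

test_that("sub-hectare faces merge into the right neighbour", {
  ext <- list(sdindex:::rect_ring(0, 0, 300, 100))
  # 0.5 ha | 2 ha | 0.5 ha strip layout
  fs <- feature_set(lines = list(list(x = c(50, 50), y = c(-1, 101)),
                                 list(x = c(250, 250), y = c(-1, 101))),
                    crs = crs)
  faces <- polygonize_features(fs, ext)
  merged <- merge_small_units(faces, 1e4)
  expect_equal(sdindex:::n_faces(merged), 1L)
  expect_equal(merged$areas, 30000, tolerance = 1e-9)
  # all faces already over the bar: identity
  big <- polygonize_features(
    feature_set(lines = list(list(x = c(150, 150), y = c(-1, 101))),
                crs = crs), ext)
  kept <- merge_small_units(big, 1e4)
  expect_equal(sdindex:::n_faces(kept), 2L)
  expect_equal(sort(kept$areas), sort(big$areas))
})

test_that("merging prefers the longest shared boundary, then larger area", {
  # sliver (20 x 300) with a 300 m border to its block remainder and to the
  # big face west of it, where the west face is larger: tie on length is
  # broken towards the larger neighbour
  ext <- list(sdindex:::rect_ring(0, 0, 900, 300))
  fs <- feature_set(lines = list(list(x = c(400, 400), y = c(-1, 301)),
                                 list(x = c(420, 420), y = c(-1, 301))),
                    crs = crs)
  faces <- polygonize_features(fs, ext)
  expect_equal(sort(faces$areas), c(6000, 120000, 144000))
  merged <- merge_small_units(faces, 1e4)
  expect_equal(sort(merged$areas), c(120000, 150000), tolerance = 1e-9)
  expect_equal(sum(merged$areas), 270000, tolerance = 1e-9)
})

test_that("an isolated sub-threshold face is retained with a warning", {
  # a face sharing no arrangement edge with any other face cannot be
  # dissolved; it must survive with a warning rather than vanish
  faces <- structure(list(
    regions = list(list(sdindex:::rect_ring(0, 0, 50, 50)),
                   list(sdindex:::rect_ring(100, 0, 300, 200))),
    areas = c(2500, 40000),
    edge_sets = list(1:4, 5:8),
    edges = data.frame(v1 = 1:8, v2 = c(2:4, 1, 6:8, 5),
                       length = rep(50, 8))), class = "sdi_faces")
  expect_warning(merged <- merge_small_units(faces, 1e4), "isolated")
  expect_equal(sdindex:::n_faces(merged), 2L)
  # a single face below the bar simply remains (nothing to merge with)
  ext <- list(sdindex:::rect_ring(0, 0, 50, 50))
  one <- polygonize_features(feature_set(crs = crs), ext)
  expect_equal(sdindex:::n_faces(merge_small_units(one, 1e4)), 1L)
})

test_that("extents below the unit-count threshold are excluded", {
  b <- edge_bundle()
  ext <- delineate_urban_extents(b$smod, b$centres, admin = b$admin,
                                 iso3 = "SYN")
  units <- build_spatial_units(ext, b$features, b$settlements)
  counts <- table(units$uext_ID)
  expect_true(any(counts == 29) && any(counts == 30))
  flt <- suppressMessages(filter_small_extents(units, ext, 30))
  dropped_id <- names(counts)[counts == 29]
  expect_equal(flt$dropped, dropped_id)
  expect_false(dropped_id %in% flt$units$uext_ID)
  expect_true(names(counts)[counts == 30] %in% flt$extents$uext_ID)
  # empty input passes through empty
  empty <- suppressMessages(filter_small_extents(
    sdindex:::subset_units(units, integer(0)), ext, 30))
  expect_length(empty$units$unit_ID, 0L)
})

test_that("units partition each kept extent and respect the area floor", {
  res <- default_result()
  b <- default_bundle()
  for (e in seq_along(res$extents$uext_ID)) {
    id <- res$extents$uext_ID[e]
    idx <- which(res$units$uext_ID == id)
    ext_area <- sdindex:::region_area(res$extents$geometry[[e]])
    expect_lt(abs(sum(res$units$area_m2[idx]) - ext_area) / ext_area, 1e-4)
    expect_true(all(res$units$area_m2[idx] >= 1e4))
    # pairwise interior-disjoint (overlap area at numerical zero)
    g <- res$units$geometry[idx]
    for (i in seq_len(min(length(g), 8) - 1L))
      expect_false(sdindex:::regions_overlap(g[[i]], g[[i + 1L]],
                                             min_area = 1))
  }
})
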