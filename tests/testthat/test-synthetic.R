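test_that("city configs validate their targets", {
  expect_error(city_config(built_prop_field = rep(0.99, 36),
                           density_field = rep(0, 36)),
               "packable limit")
  expect_error(city_config(built_prop_field = rep(-0.1, 36),
                           density_field = rep(0, 36)),
               "packable limit")
  expect_error(city_config(built_prop_field = rep(0.5, 36),
                           density_field = rep(-10, 36)),
               "non-negative")
  expect_error(city_config(block_size = 250), "block_size")
})

test_that("generation is deterministic for a fixed seed", {
  b1 <- generate_city(city_config(seed = 7))
  b2 <- generate_city(city_config(seed = 7))
  expect_identical(b1$footprints, b2$footprints)
  expect_identical(b1$pop$values, b2$pop$values)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_city(city_config(seed = 8))
  expect_false(identical(b1$footprints, b3$footprints))
})

test_that("planted built proportions are realised within half a point", {
  b <- default_bundle()
  cfg <- b$config[[1]]
  crs <- b$crs
  for (blk in c(2, 10, 20, 30)) {
    target <- cfg$built_prop_field[blk]
    reg <- list(sdindex:::block_ring(cfg, blk, c(0, 0)))
    bm <- built_metrics(reg, b$footprints, crs)
    expect_lt(abs(bm$built_prop - target), 0.005)
  }
})

test_that("planted densities are realised exactly by the rasters", {
  b <- default_bundle()
  cfg <- b$config[[1]]
  dens <- density_raster(b$pop, b$surface)
  for (blk in c(2, 5, 17, 33)) {
    target <- cfg$density_field[blk]
    if (is.na(target)) next
    reg <- list(sdindex:::block_ring(cfg, blk, c(0, 0)))
    expect_equal(zonal_mean_density(reg, dens), target, tolerance = 1e-12)
  }
  # the nodata block produces the nodata marker
  nd <- which(is.na(cfg$density_field))[1]
  reg <- list(sdindex:::block_ring(cfg, nd, c(0, 0)))
  expect_equal(zonal_mean_density(reg, dens), -99)
})

test_that("population is only allocated to cells intersecting footprints", {
  b <- default_bundle()
  pos <- which(b$pop$values > 0, arr.ind = TRUE)
  cs <- b$pop$cellsize
  nr <- nrow(b$pop$values)
  foot_bbox <- t(vapply(b$footprints, function(f)
    sdindex:::region_bbox(sdindex:::as_region(f)), numeric(4)))
  for (k in seq_len(nrow(pos))) {
    x0 <- b$pop$xll + (pos[k, 2] - 1) * cs
    y0 <- b$pop$yll + (nr - pos[k, 1]) * cs
    hit <- any(foot_bbox[, 1] < x0 + cs & foot_bbox[, 3] > x0 &
                 foot_bbox[, 2] < y0 + cs & foot_bbox[, 4] > y0)
    expect_true(hit)
  }
})

test_that("street lines polygonise to exactly the planted blocks", {
  b <- default_bundle()
  cfg <- b$config[[1]]
  ext <- list(sdindex:::rect_ring(0, 0, cfg$n_blocks_x * cfg$block_size,
                                  cfg$n_blocks_y * cfg$block_size))
  faces <- polygonize_features(b$features, ext)
  expect_equal(sdindex:::n_faces(faces),
               cfg$n_blocks_x * cfg$n_blocks_y)
  expect_equal(sort(unique(round(faces$areas))), cfg$block_size^2)
})

test_that("the edge-case bundle plants every advertised corner case", {
  b <- edge_bundle()
  cfg <- b$config[[1]]
  # a block with no buildings and no population
  expect_true(any(cfg$built_prop_field == 0 &
                    !is.na(cfg$density_field) & cfg$density_field == 0))
  # a nodata block
  expect_true(any(is.na(cfg$density_field)))
  # truth accounts for the straddling footprint (half of 400 m^2 each side)
  tr <- b$truth[b$truth$city == 1, ]
  expect_equal(sum(abs(tr$BUILT_PROP * cfg$block_size^2 -
                         round(tr$BUILT_PROP * cfg$block_size^2)) > 1e-6), 0)
  expect_equal(sum(tr$BUILT_PROP[c(5, 6)]) * cfg$block_size^2, 400,
               tolerance = 1e-9)
})

test_that("fixtures round-trip through plain-text files", {
  b <- default_bundle()
  dir <- withr::local_tempdir()
  paths <- write_fixture(b, dir)
  expect_true(all(file.exists(paths)))
  pop <- read_raster(file.path(dir, "population.asc"))
  expect_equal(pop$values, b$pop$values)
  cen <- read_vector(file.path(dir, "urban_centres.geojson"))
  expect_equal(cen$data$qa_flag, b$centres$qa_flag)
  foot <- read_vector(file.path(dir, "footprints.geojson"))
  expect_equal(length(foot$geometry), length(b$footprints))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$BUILTscore, b$truth$BUILTscore)
})
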