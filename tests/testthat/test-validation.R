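# Settlement-type classification and score-distribution comparisons.

# index of a compact street-block unit (the first face can be the large
# ring between the city and the extent hull, whose bbox spans everything)
block_unit <- function(res) {
  which(abs(res$records$data$UNIT_AREA - 90000) < 1)[1]
}

test_that("area-overlap classification honours the 50% rule inclusively", {
  res <- default_result()
  g <- res$records$geometry
  u <- block_unit(res)
  # informal polygon covering exactly the left half of a block unit
  bb <- sdindex:::region_bbox(g[[u]])
  half <- list(sdindex:::rect_ring(bb["xmin"], bb["ymin"],
                                   (bb["xmin"] + bb["xmax"]) / 2, bb["ymax"]))
  cm <- assign_by_area_overlap(res$records, list(half))
  expect_equal(cm$class[u], "Informal")     # 50% exactly is informal
  expect_equal(cm$overlap[u], 0.5, tolerance = 1e-6)
  far <- list(sdindex:::rect_ring(bb["xmin"] - 20000, bb["ymin"] - 20000,
                                  bb["xmin"] - 19000, bb["ymin"] - 19000))
  cm0 <- assign_by_area_overlap(res$records, list(far))
  expect_true(all(cm0$class == "Other"))
  expect_true(all(cm0$overlap == 0))
})

test_that("overlap fractions match the clipping oracle on random polygons", {
  res <- default_result()
  set.seed(13)
  g <- res$records$geometry
  for (rep in 1:8) {
    i <- sample(length(g), 1)
    bb <- sdindex:::region_bbox(g[[i]])
    blob <- random_hull(mean(bb[c(1, 3)]), mean(bb[c(2, 4)]),
                        spread = (bb[3] - bb[1]))
    cm <- assign_by_area_overlap(res$records, list(blob))
    want <- oracle_intersection_area(g[[i]], blob) /
      sdindex:::region_area(sdindex:::as_region(g[[i]]))
    expect_equal(cm$overlap[i], want, tolerance = 1e-6)
  }
})

test_that("majority-type classification is modal with ties going to Other", {
  res <- default_result()
  g <- res$records$geometry
  u <- block_unit(res)
  inside_rects <- function(i, n, lab) {
    bb <- sdindex:::region_bbox(g[[i]])
    w <- (bb[3] - bb[1]) / (2 * n + 1)
    list(regions = lapply(seq_len(n), function(k)
      list(sdindex:::rect_ring(bb[1] + (2 * k - 1) * w,
                               (bb[2] + bb[4]) / 2 - 5,
                               bb[1] + 2 * k * w,
                               (bb[2] + bb[4]) / 2 + 5))),
         type = lab)
  }
  all_inf <- inside_rects(u, 3, rep("Informal", 3))
  cm <- assign_by_majority_type(res$records, all_inf)
  expect_equal(cm$class[u], "Informal")
  expect_true(all(cm$class[-u] == "Other"))   # no buildings -> Other
  mixed <- inside_rects(u, 5, c("Informal", "Informal", "Informal",
                                "Other", "Other"))
  expect_equal(assign_by_majority_type(res$records, mixed)$class[u],
               "Informal")
  tie <- inside_rects(u, 4, c("Informal", "Informal", "Other", "Other"))
  expect_message(cmt <- assign_by_majority_type(res$records, tie), "tied")
  expect_equal(cmt$class[u], "Other")
})

test_that("joint score distributions sum to one and match hand counts", {
  res <- default_result()
  n <- nrow(res$records$data)
  cls <- rep(c("Informal", "Other"), length.out = n)
  cm <- data.frame(unit_ID = res$records$unit_ID, class = cls)
  jd <- joint_score_distribution(res$records, cm)
  for (cl in unique(cls))
    expect_equal(sum(jd$proportion[jd$class == cl]), 1)
  # exhaustive hand count on a 10-unit subset
  sub <- res$records
  keep <- which(sub$data$POPscore != -99)[1:10]
  sub$data <- sub$data[keep, ]; sub$geometry <- sub$geometry[keep]
  sub$unit_ID <- sub$unit_ID[keep]
  cm10 <- data.frame(unit_ID = sub$unit_ID,
                     class = rep(c("Informal", "Other"), each = 5))
  jd10 <- joint_score_distribution(sub, cm10)
  for (k in seq_len(nrow(jd10))) {
    idx <- which(cm10$class == jd10$class[k])
    hand <- sum(sub$data$POPscore[idx] == jd10$POPscore[k] &
                  sub$data$BUILTscore[idx] == jd10$BUILTscore[k])
    expect_equal(jd10$n[k], hand)
    expect_equal(jd10$proportion[k], hand / 5)
  }
})

test_that("exceedance proportions match a brute-force count", {
  res <- default_result()
  d <- res$records$data
  ok <- d$POPscore != -99
  cls <- ifelse(seq_len(nrow(d)) %% 3 == 0, "Informal", "Other")
  cm <- data.frame(unit_ID = res$records$unit_ID, class = cls)
  for (thr in c(0, 7, 11)) {
    got <- score_exceedance(res$records, cm, "POPscore", thr)
    for (cl in c("Informal", "Other")) {
      want <- mean(d$POPscore[ok & cls == cl] >= thr)
      expect_equal(got[[cl]], want)
    }
  }
  expect_equal(unname(score_exceedance(res$records, cm, "POPscore", 0)),
               c(1, 1))
  expect_equal(unname(score_exceedance(res$records, cm, "POPscore", 11)),
               c(0, 0))
})

test_that("informal-planted fixtures show higher exceedance than others", {
  # plant the class labels on density: blocks scoring high are 'Informal'
  res <- default_result()
  b <- default_bundle()
  cfg <- b$config[[1]]
  # informal polygons = planted blocks whose density scores >= 7
  tab <- build_threshold_table()
  high <- which(!is.na(cfg$density_field) &
                  classify_pop(cfg$density_field, tab) >= 7)
  polys <- lapply(high, function(blk)
    list(sdindex:::block_ring(cfg, blk, c(0, 0))))
  cm <- assign_by_area_overlap(res$records, polys)
  expect_true(sum(cm$class == "Informal") >= length(high))
  exc <- score_exceedance(res$records, cm, "POPscore", 7)
  expect_gt(exc[["Informal"]], exc[["Other"]])
  tabout <- withr::local_tempfile(fileext = ".tsv")
  write_validation_table(joint_score_distribution(res$records, cm), tabout)
  expect_gt(nrow(utils::read.delim(tabout)), 0)
})
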