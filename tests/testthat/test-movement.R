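test_that("gps_track validates its fixes", {
  expect_error(gps_track("a", data.frame(timestamp = c(0, 0), x = 1:2, y = 1:2)),
               "increasing")
  expect_error(gps_track("a", data.frame(timestamp = c(0, 180), x = c(1, NA),
                                         y = 1:2)), "finite")
})

test_that("point density counts neighbours within the radius, self included", {
  one <- gps_track("a", data.frame(timestamp = 0, x = 5, y = 5))
  expect_equal(point_density(one, 30), 1L)
  co <- gps_track("a", data.frame(timestamp = seq(0, by = 180, length.out = 10),
                                  x = rep(2, 10), y = rep(3, 10)))
  expect_equal(point_density(co, 30), rep(10L, 10))
  # 20 fixes on a 50 m-spaced line, radius 75: interior fixes see 3,
  # verified against exhaustive pairwise distances
  line <- gps_track("a", data.frame(timestamp = seq(0, by = 180, length.out = 20),
                                    x = seq(0, by = 50, length.out = 20), y = 0))
  dens <- point_density(line, 75)
  brute <- vapply(1:20, function(i)
    sum(abs(line$fixes$x - line$fixes$x[i]) <= 75), 0L)
  expect_equal(dens, brute)
  expect_true(all(dens[2:19] == 3L))
  expect_equal(dens[c(1, 20)], c(2L, 2L))
})

test_that("dwell-transit-dwell tracks give exactly two patch-bound clusters", {
  # 500 m between patches so transit fixes stay below the density threshold
  w <- make_two_patch_world(nc = 260, cols_b = 253:258)
  tr <- make_dwell_transit_track(a = c(10, 30), b = c(510, 30))
  dens <- point_density(tr, 30)
  cl <- identify_clusters(tr, dens, 5, w$patches)
  expect_equal(length(cl$patch), 2)
  expect_equal(length(unique(cl$patch)), 2)
  # all-moving track: no clusters
  mv <- gps_track("m", data.frame(timestamp = seq(0, by = 180, length.out = 20),
                                  x = seq(0, by = 60, length.out = 20), y = 30))
  expect_warning(cl0 <- identify_clusters(mv, point_density(mv, 30), 5, w$patches),
                 "min_density")
  expect_equal(length(cl0$patch), 0)
  # one dense dwell: one cluster
  one <- make_dwell_transit_track(a = c(10, 30), b = c(510, 30),
                                  dwell_n = 10, transit_n = 0)
  one$fixes <- one$fixes[1:10, ]
  cl1 <- identify_clusters(one, point_density(one, 30), 5, w$patches)
  expect_equal(length(cl1$patch), 1)
})

test_that("movement segmentation applies the boundary rule and the length metrics", {
  w <- make_two_patch_world(nc = 260, cols_b = 253:258)
  tr <- make_dwell_transit_track(a = c(10, 30), b = c(510, 30),
                                 dwell_n = 10, transit_n = 8, jitter = 0)
  cl <- identify_clusters(tr, point_density(tr, 30), 5, w$patches)
  mv <- segment_movements(tr, cl)
  expect_equal(nrow(mv), 1)
  # first fix = last in-cluster fix (index 10), last = first fix of next
  expect_equal(mv$first_fix, 10)
  expect_equal(mv$last_fix, 19)
  expect_equal(mv$n_locations, 10)
  # 9 intervals x 3 min
  expect_equal(mv$duration_min, 27)
  expect_equal(mv$expected_locations, 9L)
  expect_equal(mv$success_pct, 100)
  # straight-line transit with no jitter: path equals Euclidean
  expect_equal(mv$path_km, mv$euclidean_km, tolerance = 1e-12)
  expect_true(mv$interpatch)
  # fewer than two clusters: empty result
  expect_equal(nrow(segment_movements(tr, structure(
    list(cluster = integer(nrow(tr$fixes)), patch = integer(0)),
    class = "cluster_labeling"))), 0)
})

test_that("movement fix ranges are disjoint save endpoints and respect the triangle inequality", {
  w <- make_two_patch_world(nr = 40, nc = 120, cols_a = 3:8, cols_b = 113:118)
  # three dwells: A, B, then back to A
  set.seed(2)
  seg <- function(n, x, y) cbind(rep(x, n) + runif(n, -1, 1),
                                 rep(y, n) + runif(n, -1, 1))
  pts <- rbind(seg(8, 10, 50), cbind(seq(20, 220, by = 50), 50),
               seg(8, 230, 50), cbind(seq(220, 20, by = -40), 50),
               seg(8, 10, 50))
  tr <- gps_track("a", data.frame(timestamp = seq(0, by = 180,
                                                  length.out = nrow(pts)),
                                  x = pts[, 1], y = pts[, 2]))
  cl <- identify_clusters(tr, point_density(tr, 30), 5, w$patches)
  mv <- segment_movements(tr, cl)
  expect_equal(nrow(mv), 2)
  expect_true(all(mv$path_km >= mv$euclidean_km - 1e-12))
  # interiors belong to no cluster; ranges only share cluster endpoints
  for (k in seq_len(nrow(mv))) {
    interior <- (mv$first_fix[k] + 1):(mv$last_fix[k] - 1)
    expect_true(all(cl$cluster[interior] == 0L))
  }
  expect_true(all(mv$last_fix[-nrow(mv)] <= mv$first_fix[-1]))
})

test_that("expected-locations and success rules reproduce the published table", {
  t3 <- table3_fixture()
  expect_equal(expected_locations(t3$duration_min), t3$expected_locations)
  expect_equal(round(location_success(t3$n_locations, t3$duration_min), 2),
               t3$success_pct)
})

test_that("land-cover use counts are conserved and match areas under the null", {
  rt <- default_resistance_table()
  grid <- matrix(1L, 40, 40)
  grid[, 21:40] <- 2L # half and half
  lc <- lc_raster(grid, 2, c("1" = "Grass", "2" = "Scrub"), origin = c(0, 80))
  set.seed(31)
  n <- 4000
  fixes <- data.frame(x = runif(n, 0, 80), y = runif(n, 0, 80))
  use <- landcover_use(fixes, lc)
  expect_equal(sum(use$observed), n)
  expect_equal(use$expected, c(n / 2, n / 2))
  # uniform points on a 50/50 raster: chi-square should be unremarkable
  gof <- chisq_gof(setNames(use$observed, use$group), use$area_cells)
  expect_gt(gof$p.value, 1e-4)
  # all fixes in one category
  inA <- landcover_use(data.frame(x = runif(50, 0, 38), y = runif(50, 0, 80)), lc)
  expect_equal(inA$observed[inA$group == "Scrub"], 0L)
})

test_that("nearest distances agree with exhaustive search and flag habitat fixes", {
  w <- make_two_patch_world()
  fs <- feature_set(list(
    linear_feature(cbind(c(0, 120), c(50, 50)), "track", 3),
    linear_feature(cbind(c(60, 60), c(0, 40)), "field edge", 4)))
  set.seed(7)
  fixes <- data.frame(x = runif(40, 0, 120), y = runif(40, 0, 60))
  obs <- nearest_distances(fixes, w$patches, fs, w$lc)
  for (i in seq_len(nrow(fixes))) {
    d1 <- brute_dist_to_polyline(fixes$x[i], fixes$y[i], fs$features[[1]]$coords)
    d2 <- brute_dist_to_polyline(fixes$x[i], fixes$y[i], fs$features[[2]]$coords)
    expect_equal(obs$dist_feature_m[i], min(d1, d2), tolerance = 1e-12)
    expect_equal(obs$feature_type[i],
                 if (d1 <= d2) "track" else "field edge")
  }
  # inside-habitat fix: distance 0 and not in matrix
  inside <- nearest_distances(data.frame(x = 10, y = 30), w$patches, fs, w$lc)
  expect_equal(inside$dist_habitat_m, 0)
  expect_false(inside$in_matrix)
  # constructed 30 m offset from the only feature
  one_fs <- feature_set(list(linear_feature(cbind(c(0, 120), c(0, 0)),
                                            "river/stream", 4)))
  off <- nearest_distances(data.frame(x = 60, y = 30), w$patches, one_fs)
  expect_equal(off$dist_feature_m, 30)
  expect_equal(off$feature_type, "river/stream")
  # empty feature set: undefined, not zero
  expect_message(
    na_obs <- nearest_distances(data.frame(x = 60, y = 30), w$patches,
                                feature_set()),
    "undefined")
  expect_true(is.na(na_obs$dist_feature_m))
})
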