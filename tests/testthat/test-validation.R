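test_that("convex polygon wraps the points and is idempotent", {
  sq <- data.frame(x = c(0, 1, 1, 0, 0.5, 0.2), y = c(0, 0, 1, 1, 0.5, 0.7))
  hull <- convex_polygon(sq)
  expect_equal(hull$area, 1)
  expect_equal(nrow(hull$vertices), 4)
  hull2 <- convex_polygon(as.data.frame(hull$vertices))
  expect_equal(hull2$area, hull$area)
  expect_setequal(asplit(hull2$vertices, 1), asplit(hull$vertices, 1))
  # every input point lies inside, verified by exhaustive half-plane checks
  set.seed(12)
  pts <- data.frame(x = rnorm(50), y = rnorm(50))
  h <- convex_polygon(pts)
  v <- h$vertices
  nv <- nrow(v)
  for (i in seq_len(nrow(pts))) {
    inside <- TRUE
    for (e in seq_len(nv)) {
      j <- if (e == nv) 1 else e + 1
      cr <- (v[j, 1] - v[e, 1]) * (pts$y[i] - v[e, 2]) -
        (v[j, 2] - v[e, 2]) * (pts$x[i] - v[e, 1])
      if (cr < -1e-9) inside <- FALSE
    }
    expect_true(inside, info = paste("point", i))
  }
  expect_error(convex_polygon(data.frame(x = c(0, 1), y = c(0, 1))), "3")
  expect_error(convex_polygon(data.frame(x = 0:5, y = 0:5)), "collinear")
})

test_that("comparison statistic reproduces the printed worked examples", {
  lcn <- comparison_statistic(97, 96, "LCN")
  expect_equal(lcn$statistic_2dp, 1.01)
  lcp <- comparison_statistic(42, 81, "LCP")
  expect_equal(lcp$statistic_2dp, 0.51)
  lcc <- comparison_statistic(49, 95, "LCC")
  expect_equal(lcc$statistic_2dp, 0.51)
  expect_equal(lcp$statistic, 42 / 81)
  # saturation: mask covers everything
  expect_equal(comparison_statistic(100, 100)$statistic, 1)
  # no points inside: undefined, not an exception
  expect_message(und <- comparison_statistic(50, 0), "undefined")
  expect_true(und$undefined)
  expect_error(comparison_statistic(101, 50))
})

test_that("mask measurement is translation-invariant and monotone", {
  w <- make_two_patch_world(nr = 60, nc = 100, rows = 28:33,
                            cols_a = 23:28, cols_b = 73:78)
  ps <- w$patches
  ps$visited[] <- TRUE
  set.seed(5)
  pts <- data.frame(x = runif(60, 40, 160), y = runif(60, 40, 80))
  hull <- convex_polygon(pts)
  small <- buffered_least_cost_paths(w$rs, ps, buffer_m = 10)
  big <- buffered_least_cost_paths(w$rs, ps, buffer_m = 40)
  r_small <- compare_model(small, hull, pts)
  r_big <- compare_model(big, hull, pts)
  expect_gte(r_big$area_pct, r_small$area_pct)
  expect_gte(r_big$points_pct, r_small$points_pct)
  # rigid translation of mask grid, polygon and points together
  shift <- c(1000, -500)
  small2 <- small
  small2$origin <- small$origin + shift
  pts2 <- data.frame(x = pts$x + shift[1], y = pts$y + shift[2])
  hull2 <- convex_polygon(pts2)
  r_shift <- compare_model(small2, hull2, pts2)
  expect_equal(r_shift$area_pct, r_small$area_pct)
  expect_equal(r_shift$points_pct, r_small$points_pct)
})

test_that("chi-square goodness of fit matches its closed form and partitions", {
  exact <- chisq_gof(setNames(c(25L, 25L), c("a", "b")), c(0.5, 0.5))
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p.value, 1)
  lop <- chisq_gof(setNames(c(10L, 0L), c("a", "b")), c(0.5, 0.5))
  expect_equal(lop$statistic, 10)
  expect_equal(lop$df, 1)
  # subdivided components are each non-negative 1-df tests
  obs <- setNames(c(40L, 10L, 30L, 20L), letters[1:4])
  g <- chisq_gof(obs, c(1, 1, 1, 1))
  expect_equal(g$df, 3)
  expect_true(all(g$subdivided$chisq >= 0))
  expect_equal(nrow(g$subdivided), 4)
  # full-table statistic is the plain sum((O-E)^2/E), independently recomputed
  E <- sum(obs) / 4
  expect_equal(g$statistic, sum((obs - E)^2 / E))
  expect_warning(chisq_gof(setNames(c(1L, 1L), c("a", "b")), c(0.99, 0.01)),
                 "merging")
})

test_that("the 5% chi-square test holds its size under multinomial nulls", {
  set.seed(99)
  p <- c(0.4, 0.3, 0.2, 0.1)
  reject <- 0
  nrep <- 2000
  for (i in seq_len(nrep)) {
    o <- as.integer(rmultinom(1, 120, p))
    names(o) <- letters[1:4]
    if (chisq_gof(o, p)$p.value < 0.05) reject <- reject + 1
  }
  # binomial(2000, 0.05) three-sigma band around 100
  expect_gt(reject, 100 - 3 * sqrt(2000 * 0.05 * 0.95))
  expect_lt(reject, 100 + 3 * sqrt(2000 * 0.05 * 0.95))
})

test_that("paired t-test reproduces the published path-inflation result", {
  t3 <- table3_fixture()
  res <- paired_t(t3$euclidean_km, t3$actual_km)
  expect_equal(round(res$statistic, 3), -5.104)
  expect_equal(res$df, 9)
  expect_lt(res$p.value, 0.001)
  expect_error(paired_t(1:5, 1:5), "variance")
  # sign convention: a consistently below b gives negative t
  set.seed(3)
  b <- rnorm(500)
  res2 <- paired_t(b - 1 + rnorm(500, 0, 0.1), b)
  expect_lt(res2$statistic, -20)
})

test_that("Mann-Whitney U agrees with exhaustive pair counting", {
  x <- c(1, 5, 9, 13)
  expect_equal(mann_whitney(x, x)$U, length(x)^2 / 2)
  expect_equal(mann_whitney(c(1, 2), c(5, 6, 7))$U, 0)
  set.seed(21)
  a <- round(rnorm(25, 0, 2), 1)
  b <- round(rnorm(30, 1, 2), 1)
  brute <- sum(outer(a, b, function(u, v) (u > v) + 0.5 * (u == v)))
  expect_equal(mann_whitney(a, b)$U, brute)
  expect_lt(mann_whitney(rnorm(80), rnorm(80) + 3)$p.value, 1e-6)
})

test_that("random matrix points are reproducible, matrix-only and uniform", {
  rt <- default_resistance_table()
  grid <- matrix(1L, 40, 40)
  grid[, 1:20] <- 2L
  lc <- lc_raster(grid, 2, c("1" = "Grass", "2" = "Broadleaf"), origin = c(0, 80))
  p1 <- random_matrix_points(lc, rt, 500, seed = 11)
  p2 <- random_matrix_points(lc, rt, 500, seed = 11)
  expect_identical(p1, p2)
  expect_false(identical(p1, random_matrix_points(lc, rt, 500, seed = 12)))
  # all points in the matrix half (x > 40)
  expect_true(all(p1$x > 40))
  expect_equal(nrow(random_matrix_points(lc, rt, 0, seed = 1)), 0)
  hab_only <- lc_raster(matrix(2L, 4, 4), 2, c("2" = "Broadleaf"))
  expect_error(random_matrix_points(hab_only, rt, 5, seed = 1), "matrix")
  # per-cell occupancy roughly uniform over the 800 matrix cells
  big <- random_matrix_points(lc, rt, 10000, seed = 5)
  cellid <- paste(ceiling(big$x / 2 - 20), ceiling((80 - big$y) / 2))
  counts <- table(cellid)
  expect_equal(length(counts), 800)
  expect_gt(suppressWarnings(chisq.test(as.vector(counts))$p.value), 0.01)
})

test_that("breakpoint regression recovers exact and noisy hinges", {
  # noiseless two-segment data joined at x = 25: exact recovery
  x <- c(seq(0, 25, by = 2.5), seq(27.5, 60, by = 2.5))
  y <- ifelse(x <= 25, 2 + 0.8 * x, 2 + 0.8 * 25 - 0.3 * (x - 25))
  fit <- breakpoint_regression(x, y)
  expect_equal(fit$breakpoint_m, 25)
  expect_equal(fit$rss, 0, tolerance = 1e-18)
  expect_equal(fit$left_slope, 0.8, tolerance = 1e-9)
  expect_equal(fit$right_slope, -0.3, tolerance = 1e-9)
  expect_true(fit$supported)
  # perfectly linear data: no supported break
  ylin <- 1 + 0.5 * x
  expect_false(breakpoint_regression(x, ylin)$supported)
  # hinge fit can never beat itself: RSS <= single-line RSS
  set.seed(6)
  xr <- runif(100, 0, 100)
  yr <- rnorm(100)
  f <- breakpoint_regression(xr, yr)
  expect_lte(f$rss, f$rss_line + 1e-9)
  expect_error(breakpoint_regression(rep(2, 20), rnorm(20)), "degenerate")
})

test_that("hinge recovery works at the simulated field conditions", {
  hits <- 0
  for (s in 1:20) {
    d <- simulate_hinge_data(n = 500, breakpoint_m = 40, sigma = 5, seed = s)
    fit <- breakpoint_regression(d$x, d$y)
    if (abs(fit$breakpoint_m - 40) <= 5) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("use ranking orders by observed/expected with stated tie-breaks", {
  obs <- c(woodland = 50, river = 30, track = 20)
  exp_ <- c(woodland = 50, river = 10, track = 20)
  r <- rank_use(obs, exp_)
  expect_equal(r$group, c("river", "track", "woodland"))
  # ties broken alphabetically
  tied <- rank_use(c(b = 10, a = 10), c(b = 10, a = 10))
  expect_equal(tied$group, c("a", "b"))
  # zero expectation with observations ranks first as infinite
  z <- rank_use(c(a = 5, b = 5), c(a = 0, b = 10))
  expect_equal(z$group[1], "a")
  expect_equal(z$ratio[1], Inf)
  # a constructed landscape-use table: river corridor first, habitat edge last
  obs2 <- c("river corridor" = 40, "road/verge" = 30, "track/path" = 20,
            "field edge" = 12, "habitat edge" = 5)
  exp2 <- c("river corridor" = 8, "road/verge" = 12, "track/path" = 10,
            "field edge" = 10, "habitat edge" = 15)
  r2 <- rank_use(obs2, exp2)
  expect_equal(r2$group[1], "river corridor")
  expect_equal(r2$group[5], "habitat edge")
})
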