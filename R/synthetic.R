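# Synthetic landscapes and simulated squirrel tracks with the statistical
# structure the analysis pipeline assumes, plus fixtures of the published
# movement and resistance tables.

#' Synthetic landscape specification
#'
#' Describes a fragmented lowland landscape: woodland patches in an
#' improved/arable matrix, crossed by 4 m field edges, a river corridor
#' with riparian strips, a road with verges, and tracks. The `source` patch
#' (default 10.88 ha) and smaller `release` patch (default 0.45 ha) are
#' placed `release_distance_m` apart (default 500 m), mirroring a
#' translocation study layout.
#'
#' @param extent_m Side of the square landscape in metres.
#' @param cell_size Cell size in metres (default 2, so 4 m features stay at
#'   least 2 cells wide).
#' @param n_patches Total woodland patches including source and release.
#' @param patch_ha Size range (ha) for the additional patches.
#' @param source_ha,release_ha Areas of the two designated patches.
#' @param release_distance_m Source-to-release separation (>= 400).
#' @param n_field_edges,n_tracks Feature counts.
#' @param river,road Include a river corridor / a road with verges?
#' @param habitat_edges Add a habitat-edge strip (fence line, bramble
#'   fringe) around each woodland boundary?
#' @param matrix_category Matrix land-cover label.
#' @param road_resistance Resistance for the "Road" category, which the
#'   bundled table does not carry and must be supplied (default 72, the
#'   sealed-surface value shared with "Urban").
#' @param seed RNG seed.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(extent_m = 1200, cell_size = 2, n_patches = 6,
                           patch_ha = c(0.3, 3), source_ha = 10.88,
                           release_ha = 0.45, release_distance_m = 500,
                           n_field_edges = 6, n_tracks = 2,
                           river = TRUE, road = TRUE, habitat_edges = TRUE,
                           matrix_category = "Improved/Arable/Amenity",
                           road_resistance = 72, seed = 1) {
  stopifnot(extent_m > 0, cell_size > 0, n_patches >= 2,
            release_distance_m >= 400, release_distance_m < extent_m)
  structure(list(extent_m = extent_m, cell_size = cell_size,
                 n_patches = n_patches, patch_ha = patch_ha,
                 source_ha = source_ha, release_ha = release_ha,
                 release_distance_m = release_distance_m,
                 n_field_edges = n_field_edges, n_tracks = n_tracks,
                 river = river, road = road, habitat_edges = habitat_edges,
                 matrix_category = matrix_category,
                 road_resistance = road_resistance, seed = seed),
            class = "landscape_spec")
}

# rectangle (possibly minus a tail of its last row) with exactly n_cells
# cells, as (row, col) offsets from (1, 1)
#' @noRd
patch_cells_exact <- function(n_cells) {
  w <- max(1L, floor(sqrt(n_cells)))
  while (w > 1L && n_cells %% w != 0L && w > 0.6 * sqrt(n_cells)) w <- w - 1L
  if (n_cells %% w == 0L) {
    h <- n_cells %/% w
    cbind(row = rep.int(seq_len(h), w), col = rep(seq_len(w), each = h))
  } else {
    h <- n_cells %/% w + 1L
    full <- cbind(row = rep.int(seq_len(h), w), col = rep(seq_len(w), each = h))
    keep <- full[, 1] < h | full[, 2] <= (n_cells - (h - 1L) * w)
    full[keep, , drop = FALSE]
  }
}

#' Generate a synthetic landscape
#'
#' Places non-overlapping woodland patches (rectangular blocks with exact
#' requested cell counts) in a uniform matrix, then burns linear features
#' at their stated widths: 4 m field edges, a sinuous river (4 m water with
#' 3 m riparian scrub strips either side), a 6 m road flanked by 3 m
#' verges, and 3 m tracks. Reproducible under the spec seed.
#'
#' @param spec A [landscape_spec()].
#' @return List: `lc` ([lc_raster()]), `features` ([feature_set()]),
#'   `patches` (`habitat_patches`), `rt` (the resistance table used,
#'   bundled values plus the spec's road resistance), `release_patch`,
#'   `source_patch` (patch ids), `spec`.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  with_seed(spec$seed, generate_landscape_impl(spec))
}

#' @noRd
generate_landscape_impl <- function(spec) {
  cs <- spec$cell_size
  n <- as.integer(round(spec$extent_m / cs))
  rt <- default_resistance_table()
  if (spec$road) rt <- add_resistance_entry(rt, "Road", spec$road_resistance)
  # codes: position in the resistance table
  categories <- setNames(rt$category, seq_len(nrow(rt)))
  code_of <- function(label) as.integer(names(categories)[match(label, categories)])
  grid <- matrix(code_of(spec$matrix_category), n, n)

  # linear features, burned before the woodland blocks are stamped so that
  # patches stay intact (roads and rivers route around woods, not through)
  ext <- spec$extent_m
  features <- list()
  rand_span <- function() sort(stats::runif(2, 0.05, 0.95)) * ext
  for (k in seq_len(spec$n_field_edges)) {
    horiz <- k %% 2 == 0
    at <- stats::runif(1, 0.1, 0.9) * ext
    sp <- rand_span()
    coords <- if (horiz) cbind(c(sp[1], sp[2]), c(-at, -at) + ext) else
      cbind(c(at, at), c(-sp[1], -sp[2]) + ext)
    features <- c(features, list(linear_feature(coords, "field edge", 4)))
  }
  if (spec$river) {
    xs <- seq(0, ext, length.out = 9)
    ys <- ext * 0.7 + cumsum(c(0, stats::rnorm(8, 0, ext * 0.03)))
    ys <- pmin(pmax(ys, ext * 0.15), ext * 0.9)
    features <- c(features, list(linear_feature(cbind(xs, ys), "river/stream", 4)))
    for (off in c(-4, 4)) {
      features <- c(features,
                    list(linear_feature(cbind(xs, ys + off), "habitat edge", 3)))
    }
  }
  if (spec$road) {
    at <- ext * 0.3
    features <- c(features, list(linear_feature(cbind(c(at, at), c(0, ext)),
                                                "road", 6)))
    for (off in c(-5, 5)) {
      features <- c(features,
                    list(linear_feature(cbind(c(at + off, at + off), c(0, ext)),
                                        "road verge", 3)))
    }
  }
  for (k in seq_len(spec$n_tracks)) {
    sp <- rand_span()
    at <- stats::runif(1, 0.1, 0.9) * ext
    features <- c(features, list(linear_feature(cbind(c(sp[1], sp[2]),
                                                      c(at, at)), "track", 3)))
  }
  woodland <- c("Mixed woodland", "Broadleaf", "Coniferous")
  areas <- c(spec$source_ha, spec$release_ha,
             if (spec$n_patches > 2)
               stats::runif(spec$n_patches - 2, spec$patch_ha[1], spec$patch_ha[2]))
  placed <- vector("list", length(areas))
  occupied <- matrix(FALSE, n, n)
  margin <- max(3L, as.integer(10 / cs))
  centre_rc <- NULL
  for (i in seq_along(areas)) {
    cells <- patch_cells_exact(as.integer(round(areas[i] * 1e4 / cs^2)))
    h <- max(cells[, 1]); w <- max(cells[, 2])
    ok <- FALSE
    for (try in seq_len(400)) {
      if (i == 1) {
        r0 <- as.integer(round(n / 2 - h / 2))
        c0 <- as.integer(round(n / 2 - w / 2))
        if (try > 1) {
          r0 <- r0 + sample.int(21, 1) - 11L
          c0 <- c0 + sample.int(21, 1) - 11L
        }
      } else if (i == 2) {
        ang <- stats::runif(1, 0, 2 * pi)
        dr <- -sin(ang) * spec$release_distance_m / cs
        dc <- cos(ang) * spec$release_distance_m / cs
        r0 <- as.integer(round(centre_rc[1] + dr - h / 2))
        c0 <- as.integer(round(centre_rc[2] + dc - w / 2))
      } else {
        r0 <- sample.int(n - h - 2L * margin, 1) + margin
        c0 <- sample.int(n - w - 2L * margin, 1) + margin
      }
      if (r0 <= margin || c0 <= margin ||
          r0 + h > n - margin || c0 + w > n - margin) next
      rc <- cbind(cells[, 1] + r0 - 1L, cells[, 2] + c0 - 1L)
      # keep a buffer between patches so components stay distinct even
      # after their habitat-edge rings are burned
      pad <- as.integer(ceiling(8 / cs))
      win <- occupied[max(1, r0 - pad):min(n, r0 + h + pad),
                      max(1, c0 - pad):min(n, c0 + w + pad)]
      if (any(win)) next
      occupied[rc] <- TRUE
      placed[[i]] <- list(rc = rc, r0 = r0, c0 = c0, h = h, w = w,
                          code = code_of(woodland[(i - 1L) %% length(woodland) + 1L]))
      if (i == 1) centre_rc <- c(r0 + h / 2, c0 + w / 2)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place patch ", i, " after bounded retries: ",
                  "infeasible packing for this landscape spec")
  }

  # habitat-edge strips just outside each wood boundary: in farmland the
  # wood edge itself (fence line, bramble fringe) is a usable feature
  if (isTRUE(spec$habitat_edges)) for (p in placed) {
    x0 <- (p$c0 - 1) * cs; x1 <- (p$c0 - 1 + p$w) * cs
    ytop <- ext - (p$r0 - 1) * cs; ybot <- ext - (p$r0 - 1 + p$h) * cs
    off <- 3
    ring <- cbind(c(x0 - off, x1 + off, x1 + off, x0 - off, x0 - off),
                  c(ytop + off, ytop + off, ybot - off, ybot - off, ytop + off))
    features <- c(features, list(linear_feature(ring, "habitat edge", 3)))
  }
  fs <- feature_set(features)
  lc <- lc_raster(grid, cs, categories, origin = c(0, ext))
  if (length(features)) lc <- burn_linear_features(lc, fs)
  grid <- lc$grid
  categories <- lc$categories
  # stamp the woodland blocks last so no feature clips a patch cell
  for (p in placed) grid[p$rc] <- p$code
  lc <- lc_raster(grid, cs, categories, origin = c(0, ext))
  patches <- label_habitat_patches(lc, rt)
  find_patch <- function(rc) {
    ids <- patches$labels[rc]
    ids <- ids[ids > 0L]
    as.integer(names(which.max(table(ids))))
  }
  # distance fields used by the walk simulator, computed once per landscape:
  # exact distance to the nearest feature line, and octile grid distance to
  # the habitat set (a <= 8.3 % overestimate of Euclidean distance, ample
  # for a behavioural-bias lookup)
  d <- dim(grid)
  if (length(features)) {
    seg <- feature_segments(fs)
    ctr <- all_cell_centres(d, cs, lc$origin)
    feat_dist <- matrix(pts_to_segments_min(ctr[, 1], ctr[, 2], seg$x0, seg$y0,
                                            seg$x1, seg$y1)$dist, d[1], d[2])
  } else {
    feat_dist <- matrix(Inf, d[1], d[2])
  }
  ones <- resistance_surface(matrix(1, d[1], d[2]), cs, lc$origin)
  hab_dist <- accumulated_cost(ones, patches$labels > 0L)$grid
  list(lc = lc, features = fs, patches = patches, rt = rt,
       source_patch = find_patch(placed[[1]]$rc),
       release_patch = find_patch(placed[[2]]$rc),
       feat_dist = feat_dist, hab_dist = hab_dist, spec = spec)
}

#' Walk specification for the track simulator
#'
#' Parameters of the biased correlated random walk. Step lengths are drawn
#' per nominal fix interval; headings are sampled by softmax over candidate
#' directions scored by directional persistence, goal attraction toward the
#' target patch, attraction to linear features and to habitat, and the
#' resistance of the candidate cell. Fix dropout is category-dependent
#' (dense woodland canopy blocks satellite fixes far more often than open
#' matrix), producing a wide spread of location-success percentages.
#'
#' @param transit_step_m Mean transit step per interval (metres).
#' @param dwell_step_m Mean within-patch dwell step (metres).
#' @param persistence Directional persistence weight (kappa).
#' @param beta_goal Attraction toward the current target patch.
#' @param beta_feat Attraction to linear features (>= 0); the simulated
#'   feature affinity only engages beyond `feature_engage_m` from habitat,
#'   which is what puts a hinge in the distance-to-feature response.
#' @param beta_hab Attraction to habitat within perceptual range (>= 0).
#' @param cost_weight Penalty per unit resistance of the candidate cell.
#' @param feature_scale_m Decay scale of feature attraction.
#' @param feature_engage_m Distance from habitat beyond which feature
#'   attraction engages (default 40).
#' @param perceptual_range_m Habitat detection range (default 300).
#' @param p_miss_canopy,p_miss_open Fix-failure probabilities under
#'   woodland canopy and in the open.
#' @param dwell_mean_min Mean dwell duration in a patch (minutes).
#' @param seed RNG seed for [simulate_track()].
#' @return A `walk_spec` list.
#' @export
walk_spec <- function(transit_step_m = 55, dwell_step_m = 6,
                      persistence = 1.5, beta_goal = 2.5, beta_feat = 6,
                      beta_hab = 1.5, cost_weight = 1.5,
                      feature_scale_m = 25, feature_engage_m = 40,
                      perceptual_range_m = 300,
                      p_miss_canopy = 0.45, p_miss_open = 0.05,
                      dwell_mean_min = 45, seed = 1) {
  stopifnot(p_miss_canopy >= 0, p_miss_canopy <= 1,
            p_miss_open >= 0, p_miss_open <= 1,
            beta_feat >= 0, beta_hab >= 0)
  structure(as.list(environment()), class = "walk_spec")
}

#' Simulate a GPS track over a synthetic landscape
#'
#' Biased correlated random walk alternating dwell (inside a woodland
#' patch) and transit (toward a randomly chosen other patch) behavioural
#' states, one step per nominal fix interval. The full true path is
#' retained; the observed track drops each fix with the
#' category-dependent failure probability.
#'
#' @param landscape Output of [generate_landscape()].
#' @param walk A [walk_spec()].
#' @param duration_h Track duration in hours.
#' @param start_patch Patch id to start in (default the release patch).
#' @param animal_id Identifier for the returned track.
#' @return List: `track` (observed [gps_track()]), `true` (data frame of
#'   all true positions with behavioural state).
#' @export
simulate_track <- function(landscape, walk, duration_h = 24,
                           start_patch = NULL, animal_id = "sim1") {
  stopifnot(inherits(walk, "walk_spec"))
  with_seed(walk$seed,
            simulate_track_impl(landscape, walk, duration_h, start_patch,
                                animal_id))
}

#' @noRd
simulate_track_impl <- function(landscape, walk, duration_h, start_patch,
                                animal_id) {
  lc <- landscape$lc
  patches <- landscape$patches
  rt <- landscape$rt
  cs <- lc$cell_size
  d <- dim(lc$grid)
  ext_x <- c(lc$origin[1], lc$origin[1] + d[2] * cs)
  ext_y <- c(lc$origin[2] - d[1] * cs, lc$origin[2])
  start_patch <- start_patch %||% landscape$release_patch

  rs <- build_resistance_surface(lc, rt)
  feat_dist <- landscape$feat_dist
  hab_dist <- landscape$hab_dist

  lookup <- function(m, x, y) {
    cell <- xy_to_cell(x, y, cs, lc$origin, d)
    ri <- pmin(pmax(cell$row, 1L), d[1])
    ci <- pmin(pmax(cell$col, 1L), d[2])
    ifelse(cell$inside, m[cbind(ri, ci)], NA_real_)
  }
  interval_s <- 180
  n_steps <- as.integer(round(duration_h * 3600 / interval_s))
  patch_ids <- as.integer(names(patches$areas_ha))

  # start at the centre-of-mass cell of the start patch
  rc <- which(patches$labels == start_patch, arr.ind = TRUE)
  ctr0 <- cell_centre_xy(round(mean(rc[, 1])), round(mean(rc[, 2])), cs, lc$origin)
  pos <- c(ctr0[1, 1], ctr0[1, 2])
  heading <- stats::runif(1, 0, 2 * pi)
  state <- "dwell"
  dwell_left <- stats::rgamma(1, shape = 2, rate = 2 / walk$dwell_mean_min)
  target <- NA_integer_
  cand_ang <- seq(0, 2 * pi, length.out = 25)[-25]

  out <- matrix(NA_real_, n_steps + 1L, 2)
  states <- character(n_steps + 1L)
  out[1, ] <- pos
  states[1] <- state
  hab_labels <- habitat_labels(rt)
  for (s in seq_len(n_steps)) {
    here_patch <- patch_at(patches, pos[1], pos[2])
    if (state == "dwell") {
      dwell_left <- dwell_left - interval_s / 60
      if (dwell_left <= 0) {
        state <- "transit"
        choices <- setdiff(patch_ids, here_patch)
        # prefer nearer patches as the next goal
        pc <- t(vapply(choices, function(id) {
          rc <- which(patches$labels == id, arr.ind = TRUE)
          c(mean(rc[, 1]), mean(rc[, 2]))
        }, numeric(2)))
        pxy <- cell_centre_xy(pc[, 1], pc[, 2], cs, lc$origin)
        dd <- sqrt((pxy[, 1] - pos[1])^2 + (pxy[, 2] - pos[2])^2)
        target <- choices[sample.int(length(choices), 1, prob = 1 / (dd + 100)^2)]
      }
    } else if (here_patch > 0L && here_patch != start_patch) {
      state <- "dwell"
      dwell_left <- stats::rgamma(1, shape = 2, rate = 2 / walk$dwell_mean_min)
      start_patch <- here_patch
      target <- NA_integer_
    }
    step <- if (state == "dwell") {
      walk$dwell_step_m * stats::rgamma(1, shape = 2, rate = 2)
    } else {
      walk$transit_step_m * stats::rgamma(1, shape = 4, rate = 4)
    }
    cx <- pos[1] + step * cos(cand_ang)
    cy <- pos[2] + step * sin(cand_ang)
    inb <- cx > ext_x[1] + cs & cx < ext_x[2] - cs &
      cy > ext_y[1] + cs & cy < ext_y[2] - cs
    score <- walk$persistence * cos(cand_ang - heading)
    if (state == "transit") {
      rc <- which(patches$labels == target, arr.ind = TRUE)
      txy <- cell_centre_xy(round(mean(rc[, 1])), round(mean(rc[, 2])), cs, lc$origin)
      goal_ang <- atan2(txy[1, 2] - pos[2], txy[1, 1] - pos[1])
      score <- score + walk$beta_goal * cos(cand_ang - goal_ang)
      fd <- lookup(feat_dist, cx, cy)
      hd <- lookup(hab_dist, cx, cy)
      rv <- lookup(rs$grid, cx, cy)
      here_hd <- lookup(hab_dist, pos[1], pos[2])
      # feature affinity engages once the walker is beyond the engage
      # distance from habitat: nearer habitat the canopy itself is the cue.
      # It combines a descent term (move where the feature distance falls)
      # with an on-feature term (stay on the line once reached).
      fd_here <- lookup(feat_dist, pos[1], pos[2])
      if (walk$beta_feat > 0 && !is.na(here_hd) && is.finite(fd_here) &&
          here_hd > walk$feature_engage_m) {
        drop <- pmax(0, (fd_here - fd)) / max(step, 1)
        score <- score + walk$beta_feat *
          (drop + exp(-fd / walk$feature_scale_m))
      }
      score <- score + walk$beta_hab * exp(-hd / walk$perceptual_range_m)
      score <- score - walk$cost_weight * rv / 40
    } else if (here_patch > 0L) {
      # stay inside the patch while dwelling
      score <- score - 6 * (patch_at(patches, cx, cy) != here_patch)
    }
    score[!inb | is.na(score)] <- -50
    w <- exp(score - max(score))
    k <- sample.int(length(cand_ang), 1, prob = w)
    heading <- cand_ang[k]
    pos <- c(min(max(cx[k], ext_x[1] + cs), ext_x[2] - cs),
             min(max(cy[k], ext_y[1] + cs), ext_y[2] - cs))
    out[s + 1L, ] <- pos
    states[s + 1L] <- state
  }

  times <- seq(0, by = interval_s, length.out = n_steps + 1L)
  true <- data.frame(t = times, x = out[, 1], y = out[, 2], state = states)
  cell <- xy_to_cell(true$x, true$y, cs, lc$origin, d)
  lab <- matrix(category_labels(lc), d[1], d[2])[cbind(cell$row, cell$col)]
  p_miss <- ifelse(lab %in% hab_labels, walk$p_miss_canopy, walk$p_miss_open)
  kept <- stats::runif(nrow(true)) >= p_miss
  kept[1] <- TRUE # release fix always recorded
  obs <- data.frame(timestamp = true$t[kept], x = true$x[kept], y = true$y[kept])
  list(track = gps_track(animal_id, obs), true = true)
}

#' Published movement-table fixture
#'
#' The ten recorded inter-patch movements (squirrel, movement number, fix
#' counts, expected fixes, Euclidean and actual path length in km, duration
#' in minutes, location success %) used by the desk-scale checks.
#'
#' @return Data frame with 10 rows.
#' @export
table3_fixture <- function() {
  data.frame(
    squirrel = c(1, 2, 2, 5, 5, 5, 6, 6, 9, 9),
    movement = c(1, 1, 2, 1, 2, 3, 1, 2, 1, 2),
    n_locations = c(30, 32, 29, 31, 41, 15, 16, 6, 18, 13),
    expected_locations = c(42, 66, 69, 42, 62, 189, 27, 29, 27, 13),
    euclidean_km = c(1.03, 0.86, 0.24, 0.58, 2.26, 1.19, 0.48, 1.05, 0.48, 0.59),
    actual_km = c(1.59, 2.11, 1.79, 2.28, 3.47, 2.14, 0.83, 1.18, 1.24, 0.90),
    duration_min = c(126, 198, 207, 127, 186, 568, 80, 86, 80, 38),
    success_pct = c(71.43, 48.48, 42.03, 73.23, 66.13, 7.92, 60.00, 20.93,
                    67.50, 100.00))
}

#' Published resistance-table fixture
#'
#' The per-land-cover resistance map (woodland habitat = 1 up to
#' Building/Rock = 1000) exactly as published, without the field-edge
#' augmentation used by the default pipeline table.
#'
#' @return A [resistance_table()].
#' @export
table1_fixture <- function() {
  default_resistance_table(field_edge = FALSE)
}

#' Simulate hinge-response data
#'
#' Distance-to-feature responses with a true breakpoint in the
#' distance-to-habitat covariate: rising at `left_slope` up to the hinge,
#' then continuing at `right_slope`, plus Gaussian noise. Used to exercise
#' [breakpoint_regression()] under known truth.
#'
#' @param n Number of points.
#' @param breakpoint_m True hinge location (default 40 m).
#' @param left_slope,right_slope Segment slopes.
#' @param intercept Response at distance 0.
#' @param sigma Noise standard deviation.
#' @param x_max Covariate range upper bound.
#' @param seed RNG seed.
#' @return Data frame with columns `x` (distance to habitat) and `y`
#'   (distance to feature).
#' @export
simulate_hinge_data <- function(n = 500, breakpoint_m = 40, left_slope = 0.8,
                                right_slope = -0.2, intercept = 5, sigma = 5,
                                x_max = 120, seed = 1) {
  with_seed(seed, {
    x <- stats::runif(n, 0, x_max)
    y <- intercept + left_slope * x +
      (right_slope - left_slope) * pmax(0, x - breakpoint_m) +
      stats::rnorm(n, 0, sigma)
    data.frame(x = x, y = y)
  })
}
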