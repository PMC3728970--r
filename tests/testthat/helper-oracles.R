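# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own computational
# paths: shortest paths by Bellman-Ford edge relaxation, geometry by
# exhaustive per-cell / per-pair computation.

# Bellman-Ford single/multi-source shortest path over the 8-neighbour grid
# graph with mean-resistance step costs. O(V^2 E): fine for tiny rasters.
bf_cost <- function(resist, sources, cell_size) {
  nr <- nrow(resist); nc <- ncol(resist)
  cost <- matrix(Inf, nr, nc)
  cost[sources] <- 0
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!is.finite(cost[r, c])) next
      for (m in seq_len(nrow(moves))) {
        rr <- r + moves$dr[m]; cc <- c + moves$dc[m]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        d <- cell_size * if (moves$dr[m] != 0 && moves$dc[m] != 0) sqrt(2) else 1
        nd <- cost[r, c] + (resist[r, c] + resist[rr, cc]) / 2 * d
        if (nd < cost[rr, cc] - 1e-12) {
          cost[rr, cc] <- nd
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  cost
}

# closed-form 8-connectivity (octile) grid distance between cell centres
octile_m <- function(r1, c1, r2, c2, cell_size) {
  dr <- abs(r1 - r2); dc <- abs(c1 - c2)
  cell_size * (max(dr, dc) + (sqrt(2) - 1) * min(dr, dc))
}

# exhaustive point-to-polyline distance
brute_dist_to_polyline <- function(px, py, coords) {
  best <- Inf
  for (s in seq_len(nrow(coords) - 1)) {
    x0 <- coords[s, 1]; y0 <- coords[s, 2]
    x1 <- coords[s + 1, 1]; y1 <- coords[s + 1, 2]
    L2 <- (x1 - x0)^2 + (y1 - y0)^2
    t <- if (L2 == 0) 0 else
      max(0, min(1, ((px - x0) * (x1 - x0) + (py - y0) * (y1 - y0)) / L2))
    d <- sqrt((px - (x0 + t * (x1 - x0)))^2 + (py - (y0 + t * (y1 - y0)))^2)
    best <- min(best, d)
  }
  best
}

# uniform resistance surface fixture
make_uniform_rs <- function(n, value = 1, cell_size = 10) {
  resistance_surface(matrix(value, n, n), cell_size, origin = c(0, n * cell_size))
}

# random resistance surface drawing from the bundled resistance values
make_random_rs <- function(nr, nc, cell_size = 2, seed = 1) {
  vals <- default_resistance_table()$resistance
  set.seed(seed)
  resistance_surface(matrix(sample(vals, nr * nc, replace = TRUE), nr, nc),
                     cell_size, origin = c(0, nr * cell_size))
}

# two-patch world: habitat blocks at given column ranges on a uniform
# matrix, returning lc, rt and labelled patches
make_two_patch_world <- function(nr = 30, nc = 60, cell_size = 2,
                                 rows = 13:18, cols_a = 3:8, cols_b = 53:58,
                                 matrix_label = "Grass") {
  rt <- default_resistance_table()
  grid <- matrix(1L, nr, nc)
  lc <- lc_raster(grid, cell_size,
                  c("1" = matrix_label, "2" = "Broadleaf"),
                  origin = c(0, nr * cell_size))
  lc$grid[rows, cols_a] <- 2L
  lc$grid[rows, cols_b] <- 2L
  patches <- label_habitat_patches(lc, rt)
  list(lc = lc, rt = rt, patches = patches,
       rs = build_resistance_surface(lc, rt))
}

# brute-force point-in-patch membership: test each point against every
# habitat cell's square extent
patch_at_oracle <- function(patches, x, y) {
  cs <- patches$cell_size
  o <- patches$origin
  hab <- which(patches$labels > 0, arr.ind = TRUE)
  vapply(seq_along(x), function(i) {
    for (k in seq_len(nrow(hab))) {
      cx <- o[1] + (hab[k, 2] - 0.5) * cs
      cy <- o[2] - (hab[k, 1] - 0.5) * cs
      if (abs(x[i] - cx) <= cs / 2 && abs(y[i] - cy) <= cs / 2)
        return(patches$labels[hab[k, 1], hab[k, 2]])
    }
    0L
  }, integer(1))
}

# track fixture: dwell at a, transit to b, dwell at b; 3-minute fixes
make_dwell_transit_track <- function(a = c(10, 30), b = c(110, 30),
                                     dwell_n = 10, transit_n = 8,
                                     jitter = 0.5, seed = 1) {
  set.seed(seed)
  n <- dwell_n * 2 + transit_n
  x <- c(rep(a[1], dwell_n),
         seq(a[1], b[1], length.out = transit_n + 2)[-c(1, transit_n + 2)],
         rep(b[1], dwell_n))
  y <- c(rep(a[2], dwell_n),
         seq(a[2], b[2], length.out = transit_n + 2)[-c(1, transit_n + 2)],
         rep(b[2], dwell_n))
  gps_track("t1", data.frame(timestamp = seq(0, by = 180, length.out = n),
                             x = x + runif(n, -jitter, jitter),
                             y = y + runif(n, -jitter, jitter)))
}
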