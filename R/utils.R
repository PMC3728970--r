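# Shared helpers: grid/world coordinate transforms, small geometry kernels,
# local RNG scoping. World coordinates are planar metres, x east / y north;
# grid indices are 1-based (row, col) from the top-left cell and cell (r, c)
# has centre origin + ((c - 0.5) * cell_size, -(r - 0.5) * cell_size).

#' @noRd
cell_centre_xy <- function(row, col, cell_size, origin) {
  cbind(x = origin[1] + (col - 0.5) * cell_size,
        y = origin[2] - (row - 0.5) * cell_size)
}

#' @noRd
xy_to_cell <- function(x, y, cell_size, origin, dim) {
  col <- floor((x - origin[1]) / cell_size) + 1L
  row <- floor((origin[2] - y) / cell_size) + 1L
  inside <- row >= 1L & row <= dim[1] & col >= 1L & col <= dim[2]
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

# Centres of every cell of an nr x nc grid, in column-major order so that
# values line up with as.vector(grid).
#' @noRd
all_cell_centres <- function(dim, cell_size, origin) {
  row <- rep.int(seq_len(dim[1]), dim[2])
  col <- rep(seq_len(dim[2]), each = dim[1])
  cell_centre_xy(row, col, cell_size, origin)
}

# Signed area of a polygon (shoelace); positive when counter-clockwise.
#' @noRd
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# Point-in-convex-polygon by half-plane tests; vertices must be ordered
# counter-clockwise. Boundary points count as inside.
#' @noRd
points_in_convex <- function(px, py, vertices, tol = 1e-9) {
  nv <- nrow(vertices)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    ex <- vertices[j, 1] - vertices[i, 1]
    ey <- vertices[j, 2] - vertices[i, 2]
    cross <- ex * (py - vertices[i, 2]) - ey * (px - vertices[i, 1])
    inside <- inside & cross >= -tol
  }
  inside
}

# Decompose a polyline (n x 2 matrix of vertices) into segment endpoints,
# dropping zero-length segments.
#' @noRd
polyline_segments <- function(coords) {
  n <- nrow(coords)
  s <- list(x0 = coords[-n, 1], y0 = coords[-n, 2],
            x1 = coords[-1, 1], y1 = coords[-1, 2])
  keep <- (s$x0 != s$x1) | (s$y0 != s$y1)
  if (!any(keep) && n >= 2) {
    # degenerate polyline: keep one zero-length segment so the point itself
    # still has a well-defined distance
    keep[1] <- TRUE
  }
  lapply(s, `[`, keep)
}

#' @noRd
polyline_length <- function(coords) {
  if (nrow(coords) < 2) return(0)
  sum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2))
}

# Collect segment endpoints for every feature of a feature set.
#' @noRd
feature_segments <- function(fs) {
  segs <- lapply(seq_along(fs$features), function(i) {
    s <- polyline_segments(fs$features[[i]]$coords)
    data.frame(x0 = s$x0, y0 = s$y0, x1 = s$x1, y1 = s$y1, feature = i)
  })
  do.call(rbind, segs)
}

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Truncate (not round) to the stated number of decimals, matching how the
# source study printed its ratio statistics (42/81 -> 0.51).
#' @noRd
trunc_decimals <- function(x, digits = 2) {
  floor(x * 10^digits + 1e-9) / 10^digits
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
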