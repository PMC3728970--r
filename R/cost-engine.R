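# Accumulated-cost surfaces, least-cost paths and pairwise corridor
# surfaces on the 8-connected grid.
#
# The movement graph connects each cell to its 8 neighbours; a step from
# cell a to adjacent cell b costs mean(r_a, r_b) * d, where d is cell_size
# for rook moves and cell_size * sqrt(2) for diagonal moves. One cost unit
# therefore equals one metre travelled at resistance 1.

#' Accumulated cost from a source set
#'
#' Multi-source Dijkstra over the 8-connected grid. Source cells have cost
#' 0; unreachable cells are `Inf`. Cells at or above the optional barrier
#' resistance are impassable (the default is no barrier: even the most
#' hostile categories remain traversable at extreme cost).
#'
#' @param rs A `resistance_surface`.
#' @param sources Logical matrix of the same shape marking source cells.
#' @param barrier Resistance at or above which a cell is impassable
#'   (default `Inf`, i.e. none).
#' @return An object of class `acc_cost_surface` with fields `grid` (least
#'   accumulated cost, cost units), `pred` (predecessor grid for
#'   backtracing), `sources`, `cell_size`, `origin`.
#' @export
accumulated_cost <- function(rs, sources, barrier = Inf) {
  stopifnot(inherits(rs, "resistance_surface"), is.logical(sources))
  if (!identical(dim(sources), dim(rs$grid)))
    stop("source mask shape does not match the resistance surface")
  if (!any(sources)) stop("source mask is empty")
  res <- grid_dijkstra(rs$grid, sources, rs$cell_size, barrier)
  structure(list(grid = res$cost, pred = res$pred, sources = sources,
                 cell_size = rs$cell_size, origin = rs$origin),
            class = "acc_cost_surface")
}

#' @export
print.acc_cost_surface <- function(x, ...) {
  fin <- x$grid[is.finite(x$grid)]
  cat(sprintf("<acc_cost_surface> %d x %d cells, %d sources, max finite cost %.6g\n",
              nrow(x$grid), ncol(x$grid), sum(x$sources), max(fin)))
  invisible(x)
}

# backtrace a path (end -> source) through the predecessor grid; returns an
# m x 2 (row, col) matrix from the source-side cell to `end`
#' @noRd
backtrace_path <- function(acc, end) {
  nr <- nrow(acc$grid)
  i <- (end[2] - 1L) * nr + end[1]
  cells <- i
  while (acc$pred[i] != 0L) {
    i <- acc$pred[i]
    cells <- c(cells, i)
  }
  cells <- rev(cells)
  cbind(row = ((cells - 1L) %% nr) + 1L, col = ((cells - 1L) %/% nr) + 1L)
}

#' @noRd
path_from_cells <- function(cells, acc, total_cost) {
  vertices <- cell_centre_xy(cells[, 1], cells[, 2], acc$cell_size, acc$origin)
  structure(list(cells = cells, vertices = vertices,
                 total_cost = total_cost,
                 length_m = polyline_length(vertices),
                 found = TRUE,
                 cell_size = acc$cell_size, origin = acc$origin),
            class = "least_cost_path")
}

#' Least-cost path between two cells
#'
#' Runs [accumulated_cost()] sourced at `start` and backtraces the optimal
#' route to `end`. Ties between equal-cost routes are broken
#' deterministically by the engine's fixed neighbour scan order
#' (N, NE, E, SE, S, SW, W, NW).
#'
#' @param rs A `resistance_surface`.
#' @param start,end Length-2 integer (row, col) cells; must differ.
#' @param barrier Passed to [accumulated_cost()].
#' @return An object of class `least_cost_path` with fields `cells`,
#'   `vertices` (cell-centre world coordinates), `total_cost` (cost units),
#'   `length_m` and `found`. When `end` is unreachable, `found` is `FALSE`
#'   and cost/length are `Inf` (an explicit no-path result).
#' @export
least_cost_path <- function(rs, start, end, barrier = Inf) {
  stopifnot(length(start) == 2, length(end) == 2)
  start <- as.integer(start); end <- as.integer(end)
  if (all(start == end)) stop("start and end cells must differ")
  d <- dim(rs$grid)
  if (any(c(start, end) < 1L) || start[1] > d[1] || end[1] > d[1] ||
      start[2] > d[2] || end[2] > d[2])
    stop("start/end cell outside the raster")
  sources <- matrix(FALSE, d[1], d[2])
  sources[start[1], start[2]] <- TRUE
  acc <- accumulated_cost(rs, sources, barrier = barrier)
  total <- acc$grid[end[1], end[2]]
  if (!is.finite(total)) {
    return(structure(list(cells = NULL, vertices = NULL, total_cost = Inf,
                          length_m = Inf, found = FALSE,
                          cell_size = rs$cell_size, origin = rs$origin),
                     class = "least_cost_path"))
  }
  path_from_cells(backtrace_path(acc, end), acc, total)
}

#' @export
print.least_cost_path <- function(x, ...) {
  if (!x$found) cat("<least_cost_path> no path\n")
  else cat(sprintf("<least_cost_path> %d cells, cost %.6g units, length %.6g m\n",
                   nrow(x$cells), x$total_cost, x$length_m))
  invisible(x)
}

#' Pairwise corridor surface
#'
#' The element-wise sum of two accumulated-cost surfaces sourced at patches
#' A and B: `value(x) = cost_from_A(x) + cost_from_B(x)`. Its minimum equals
#' the least-cost path cost between the two source sets, and the sum is
#' symmetric in A and B.
#'
#' @param costA,costB `acc_cost_surface` objects on identical grids.
#' @param pair Optional length-2 identifier for the patch pair.
#' @return An object of class `corridor_surface`.
#' @export
corridor_surface <- function(costA, costB, pair = c(NA, NA)) {
  stopifnot(inherits(costA, "acc_cost_surface"),
            inherits(costB, "acc_cost_surface"))
  if (!identical(dim(costA$grid), dim(costB$grid)) ||
      costA$cell_size != costB$cell_size ||
      !identical(costA$origin, costB$origin))
    stop("corridor surfaces require identically georeferenced cost surfaces")
  structure(list(grid = costA$grid + costB$grid, pair = pair,
                 cell_size = costA$cell_size, origin = costA$origin),
            class = "corridor_surface")
}

#' Least-cost path between two habitat patches
#'
#' The whole patch acts as source and target (cost 0 inside both); the
#' returned path is the minimal-cost traverse between the patch cell sets.
#'
#' @param rs A `resistance_surface`.
#' @param patches A `habitat_patches` object on the same grid.
#' @param from,to Patch ids.
#' @param barrier Passed to [accumulated_cost()].
#' @return A list with the `least_cost_path` (`path`), and the two
#'   `acc_cost_surface`s (`costA`, `costB`) for corridor construction.
#' @export
patch_least_cost_path <- function(rs, patches, from, to, barrier = Inf) {
  stopifnot(from != to)
  srcA <- patches$labels == from
  srcB <- patches$labels == to
  if (!any(srcA)) stop("no cells for patch ", from)
  if (!any(srcB)) stop("no cells for patch ", to)
  costA <- accumulated_cost(rs, srcA, barrier = barrier)
  costB <- accumulated_cost(rs, srcB, barrier = barrier)
  inB <- which(srcB)
  vals <- costA$grid[inB]
  if (!any(is.finite(vals))) {
    path <- structure(list(cells = NULL, vertices = NULL, total_cost = Inf,
                           length_m = Inf, found = FALSE,
                           cell_size = rs$cell_size, origin = rs$origin),
                      class = "least_cost_path")
    return(list(path = path, costA = costA, costB = costB))
  }
  nr <- nrow(rs$grid)
  endi <- inB[which.min(vals)]
  end <- c(((endi - 1L) %% nr) + 1L, ((endi - 1L) %/% nr) + 1L)
  path <- path_from_cells(backtrace_path(costA, end), costA, min(vals, na.rm = TRUE))
  list(path = path, costA = costA, costB = costB)
}
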