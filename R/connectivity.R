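# The three connectivity models as binary landscape masks: least-cost
# network (LCN), buffered least-cost paths (LCP) and least-cost corridor
# (LCC).

#' Corridor margin from a buffer width
#'
#' Converts a buffer distance into cost units through the resistance of the
#' land cover it is meant to span: a 40 m allowance in a matrix of
#' resistance 40 is 40 x 40 = 1600 cost units.
#'
#' @param buffer_m Buffer distance in metres.
#' @param resistance Resistance of the reference land cover.
#' @return Margin in cost units.
#' @export
corridor_margin <- function(buffer_m, resistance) {
  stopifnot(buffer_m >= 0, resistance >= 1)
  buffer_m * resistance
}

#' Least-cost network
#'
#' Habitat plus every matrix cell whose accumulated cost from the habitat
#' cell set is within a dispersal-derived threshold. The threshold is
#' `max_dispersal_m` x 1 (the habitat resistance), i.e. 8000 cost units for
#' the default 8 km maximum dispersal distance: one cost unit is one metre
#' travelled at resistance 1.
#'
#' @param rs A `resistance_surface`.
#' @param patches A `habitat_patches` object on the same grid.
#' @param max_dispersal_m Maximum dispersal distance in metres (default 8000).
#' @param barrier Passed to [accumulated_cost()].
#' @return Object of class `network_mask`: fields `mask` (logical grid),
#'   `max_dispersal_m`, `cost_threshold`, georeferencing.
#' @export
least_cost_network <- function(rs, patches, max_dispersal_m = 8000, barrier = Inf) {
  stopifnot(inherits(rs, "resistance_surface"),
            inherits(patches, "habitat_patches"))
  if (max_dispersal_m <= 0) stop("max_dispersal_m must be positive")
  habitat <- patches$labels > 0L
  if (!any(habitat)) stop("patch set contains no habitat cells")
  threshold <- max_dispersal_m * 1
  acc <- accumulated_cost(rs, habitat, barrier = barrier)
  mask <- habitat | (acc$grid <= threshold)
  structure(list(mask = mask, max_dispersal_m = max_dispersal_m,
                 cost_threshold = threshold,
                 cell_size = rs$cell_size, origin = rs$origin),
            class = c("network_mask", "landscape_mask"))
}

#' Flag patches containing GPS fixes
#'
#' Sets `visited` true exactly for patches that contain at least one fix of
#' any supplied track.
#'
#' @param patches A `habitat_patches` object.
#' @param tracks A `gps_track` or list of them.
#' @return The patch set with updated `visited` flags.
#' @export
select_visited_patches <- function(patches, tracks) {
  if (inherits(tracks, "gps_track")) tracks <- list(tracks)
  visited <- setNames(rep(FALSE, length(patches$areas_ha)), names(patches$areas_ha))
  for (tr in tracks) {
    id <- patch_at(patches, tr$fixes$x, tr$fixes$y)
    hit <- unique(id[id > 0L])
    visited[as.character(hit)] <- TRUE
  }
  patches$visited <- visited
  patches
}

# all unordered pairs of visited patch ids
#' @noRd
visited_pairs <- function(patches) {
  ids <- as.integer(names(patches$visited)[patches$visited])
  if (length(ids) < 2)
    stop("need at least 2 visited patches (got ", length(ids), ")")
  utils::combn(ids, 2, simplify = FALSE)
}

#' Buffered least-cost paths
#'
#' For every unordered pair of visited patches, the least-cost path between
#' the patch cell sets is computed and buffered by `buffer_m` either side;
#' the mask is the union of the buffered paths. Buffering is done in vector
#' space on the path polyline (cells whose centre lies within `buffer_m` of
#' the polyline), so `buffer_m = 0` keeps exactly the path cells.
#' Unreachable pairs are skipped with a warning.
#'
#' @param rs A `resistance_surface`.
#' @param visited A `habitat_patches` object with >= 2 visited patches.
#' @param buffer_m Buffer distance in metres (default 40).
#' @param barrier Passed to [accumulated_cost()].
#' @return Object of class `buffered_path_mask`: fields `mask`, `buffer_m`,
#'   `paths` (list of `least_cost_path`), `skipped_pairs`.
#' @export
buffered_least_cost_paths <- function(rs, visited, buffer_m = 40, barrier = Inf) {
  stopifnot(buffer_m >= 0)
  pairs <- visited_pairs(visited)
  d <- dim(rs$grid)
  mask <- matrix(FALSE, d[1], d[2])
  paths <- list()
  skipped <- list()
  ctr <- NULL
  for (pr in pairs) {
    res <- patch_least_cost_path(rs, visited, pr[1], pr[2], barrier = barrier)
    if (!res$path$found) {
      warning("patch pair ", pr[1], "-", pr[2], " unreachable; skipped")
      skipped <- c(skipped, list(pr))
      next
    }
    paths <- c(paths, list(res$path))
    mask[res$path$cells] <- TRUE
    if (buffer_m > 0) {
      if (is.null(ctr)) ctr <- all_cell_centres(d, rs$cell_size, rs$origin)
      seg <- polyline_segments(res$path$vertices)
      dd <- pts_to_segments_min(ctr[, 1], ctr[, 2],
                                seg$x0, seg$y0, seg$x1, seg$y1)$dist
      mask <- mask | matrix(dd <= buffer_m, d[1], d[2])
    }
  }
  if (!length(paths)) stop("no reachable visited patch pairs")
  structure(list(mask = mask, buffer_m = buffer_m, paths = paths,
                 skipped_pairs = skipped,
                 cell_size = rs$cell_size, origin = rs$origin),
            class = c("buffered_path_mask", "landscape_mask"))
}

#' Least-cost corridor
#'
#' For every unordered pair of visited patches, the corridor surface
#' (cost-from-A + cost-from-B) is thresholded at its own minimum (the pair's
#' least-cost path cost) plus `margin` cost units; the final mask is the
#' union over pairs together with the habitat cells of visited patches.
#' The default margin of 1600 cost units corresponds to a 40 m allowance in
#' the dominant matrix resistance of 40 (see [corridor_margin()]).
#'
#' @param rs A `resistance_surface`.
#' @param visited A `habitat_patches` object with >= 2 visited patches.
#' @param margin Corridor margin in cost units (default 1600, >= 0).
#' @param barrier Passed to [accumulated_cost()].
#' @return Object of class `corridor_mask`: fields `mask`, `margin`,
#'   `pair_surfaces` (list of `corridor_surface`), `skipped_pairs`.
#' @export
least_cost_corridor <- function(rs, visited, margin = 1600, barrier = Inf) {
  stopifnot(margin >= 0)
  pairs <- visited_pairs(visited)
  d <- dim(rs$grid)
  mask <- matrix(FALSE, d[1], d[2])
  surfaces <- list()
  skipped <- list()
  for (pr in pairs) {
    res <- patch_least_cost_path(rs, visited, pr[1], pr[2], barrier = barrier)
    if (!res$path$found) {
      warning("patch pair ", pr[1], "-", pr[2], " unreachable; skipped")
      skipped <- c(skipped, list(pr))
      next
    }
    surf <- corridor_surface(res$costA, res$costB, pair = pr)
    surfaces <- c(surfaces, list(surf))
    lo <- min(surf$grid)
    mask <- mask | (surf$grid <= lo + margin)
  }
  if (!length(surfaces)) stop("no reachable visited patch pairs")
  ids <- as.integer(names(visited$visited)[visited$visited])
  mask <- mask | matrix(visited$labels %in% ids & visited$labels > 0L, d[1], d[2])
  structure(list(mask = mask, margin = margin, pair_surfaces = surfaces,
                 skipped_pairs = skipped,
                 cell_size = rs$cell_size, origin = rs$origin),
            class = c("corridor_mask", "landscape_mask"))
}

#' Lowest-fraction corridor (comparison variant)
#'
#' An alternative corridor rule: per pair surface, keep the cells whose
#' corridor value lies within the lowest `fraction` quantile of finite
#' values (e.g. the lowest 10 % of the cost surface). Provided for
#' comparison with the margin-based rule of [least_cost_corridor()].
#'
#' @param pair_surfaces List of `corridor_surface` objects (or one).
#' @param fraction Quantile in (0, 1].
#' @return Object of class `corridor_mask` (with `fraction` in place of
#'   `margin`).
#' @export
lowest_fraction_corridor <- function(pair_surfaces, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  if (inherits(pair_surfaces, "corridor_surface"))
    pair_surfaces <- list(pair_surfaces)
  stopifnot(length(pair_surfaces) >= 1)
  d <- dim(pair_surfaces[[1]]$grid)
  mask <- matrix(FALSE, d[1], d[2])
  for (surf in pair_surfaces) {
    v <- surf$grid[is.finite(surf$grid)]
    if (length(unique(v)) == 1L) {
      warning("degenerate constant corridor surface; whole surface returned")
      mask <- mask | is.finite(surf$grid)
      next
    }
    k <- max(1L, ceiling(fraction * length(v)))
    thr <- sort(v, partial = k)[k]
    mask <- mask | (is.finite(surf$grid) & surf$grid <= thr)
  }
  structure(list(mask = mask, fraction = fraction,
                 pair_surfaces = pair_surfaces,
                 cell_size = pair_surfaces[[1]]$cell_size,
                 origin = pair_surfaces[[1]]$origin),
            class = c("corridor_mask", "landscape_mask"))
}

#' @export
print.landscape_mask <- function(x, ...) {
  cat(sprintf("<%s> %d x %d cells, %.3g%% inside\n", class(x)[1],
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask)))
  invisible(x)
}
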