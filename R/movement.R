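# GPS fix series: dwell-cluster detection, inter-patch movement
# segmentation, and land-cover / landscape-feature use observations.

#' GPS track
#'
#' Timestamped fixes for one animal. Timestamps must be strictly
#' increasing; coordinates are planar metres in the raster's system.
#'
#' @param animal_id Identifier.
#' @param fixes Data frame with columns `timestamp` (POSIXct or numeric
#'   seconds), `x`, `y`.
#' @param nominal_interval_s Nominal fix interval in seconds (default 180,
#'   i.e. one fix every 3 minutes).
#' @return An object of class `gps_track`.
#' @export
gps_track <- function(animal_id, fixes, nominal_interval_s = 180) {
  stopifnot(is.data.frame(fixes), all(c("timestamp", "x", "y") %in% names(fixes)))
  t <- as.numeric(fixes$timestamp)
  if (nrow(fixes) > 1 && any(diff(t) <= 0))
    stop("fix timestamps must be strictly increasing")
  if (!all(is.finite(fixes$x)) || !all(is.finite(fixes$y)))
    stop("fix coordinates must be finite")
  structure(list(animal_id = animal_id,
                 fixes = fixes[c("timestamp", "x", "y")],
                 nominal_interval_s = nominal_interval_s),
            class = "gps_track")
}

#' @export
print.gps_track <- function(x, ...) {
  cat(sprintf("<gps_track> animal %s, %d fixes, nominal interval %gs\n",
              x$animal_id, nrow(x$fixes), x$nominal_interval_s))
  invisible(x)
}

#' Per-fix point density
#'
#' Number of fixes (including the fix itself) within `radius_m` of each
#' fix. High-density runs mark dwell locations; low density marks transit.
#'
#' @param track A [gps_track()].
#' @param radius_m Search radius in metres (default 30, > 0).
#' @return Integer vector of densities, one per fix.
#' @export
point_density <- function(track, radius_m = 30) {
  stopifnot(inherits(track, "gps_track"), radius_m > 0)
  n <- nrow(track$fixes)
  if (n == 1) return(1L)
  dm <- as.matrix(stats::dist(cbind(track$fixes$x, track$fixes$y)))
  as.integer(rowSums(dm <= radius_m))
}

#' Identify dwell clusters
#'
#' Clusters are maximal runs of consecutive fixes with density >=
#' `min_density` in which a strict majority of the run's fixes fall inside
#' one habitat patch; the cluster is bound to that patch (majority vote, so
#' GPS scatter that places some dwell fixes just outside the patch does not
#' break the binding).
#'
#' @param track A [gps_track()].
#' @param density Per-fix densities from [point_density()].
#' @param min_density Minimum density for a fix to be clustered
#'   (default 5, >= 2).
#' @param patches A `habitat_patches` object.
#' @return Object of class `cluster_labeling`: `cluster` (per-fix id, 0 =
#'   unclustered) and `patch` (named by cluster id).
#' @export
identify_clusters <- function(track, density, min_density = 5, patches) {
  stopifnot(inherits(track, "gps_track"), min_density >= 2,
            length(density) == nrow(track$fixes))
  n <- nrow(track$fixes)
  cluster <- integer(n)
  patch_of <- integer(0)
  dense <- density >= min_density
  if (!any(dense)) {
    warning("no fix reaches min_density; zero clusters")
  } else {
    fix_patch <- patch_at(patches, track$fixes$x, track$fixes$y)
    r <- rle(dense)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- 0L
    for (i in seq_along(r$values)) {
      if (!r$values[i]) next
      run <- starts[i]:ends[i]
      ids <- fix_patch[run]
      tab <- table(ids[ids > 0L])
      if (!length(tab)) next
      top <- as.integer(names(tab)[which.max(tab)])
      if (max(tab) * 2L <= length(run)) next # no strict majority in one patch
      k <- k + 1L
      cluster[run] <- k
      patch_of[k] <- top
    }
    if (k == 0L) warning("no dense run bound to a habitat patch; zero clusters")
  }
  structure(list(cluster = cluster,
                 patch = setNames(patch_of, seq_along(patch_of))),
            class = "cluster_labeling")
}

#' Expected number of fixes over an interval
#'
#' Round-to-nearest of duration divided by the nominal fix interval
#' (e.g. 127 min at 3-min fixes: 42.33 -> 42).
#'
#' @param duration_min Duration in minutes.
#' @param nominal_interval_s Nominal fix interval in seconds (default 180).
#' @return Integer count.
#' @export
expected_locations <- function(duration_min, nominal_interval_s = 180) {
  as.integer(round(duration_min / (nominal_interval_s / 60)))
}

#' Location success percentage
#'
#' `100 * n / (duration / interval)`, capped at 100. The denominator is the
#' unrounded expected fix count; the cap absorbs short intervals in which
#' rounding makes the recorded count exceed the nominal expectation
#' (13 fixes in 38 min reports 100, not 102.63).
#'
#' @param n_locations Recorded fix count.
#' @param duration_min Duration in minutes.
#' @param nominal_interval_s Nominal fix interval in seconds (default 180).
#' @return Percentage in (0, 100].
#' @export
location_success <- function(n_locations, duration_min, nominal_interval_s = 180) {
  pmin(100, 100 * n_locations / (duration_min / (nominal_interval_s / 60)))
}

#' Segment a track into inter-patch movements
#'
#' One movement per consecutive cluster pair: its first fix is the last fix
#' inside the origin cluster and its last fix is the first fix recorded
#' inside the destination cluster. `euclidean_km` is the straight-line
#' distance between those two fixes; `path_km` sums consecutive-fix
#' distances; `expected_locations` and `success_pct` follow
#' [expected_locations()] and [location_success()]. The `interpatch` flag
#' marks movements whose origin and destination clusters are bound to
#' different patches.
#'
#' @param track A [gps_track()].
#' @param clusters A `cluster_labeling` from [identify_clusters()].
#' @return Data frame with one row per movement (empty if < 2 clusters).
#' @export
segment_movements <- function(track, clusters) {
  stopifnot(inherits(track, "gps_track"), inherits(clusters, "cluster_labeling"))
  ncl <- length(clusters$patch)
  cols <- c("animal_id", "movement", "first_fix", "last_fix",
            "origin_cluster", "destination_cluster", "origin_patch",
            "destination_patch", "n_locations", "expected_locations",
            "euclidean_km", "path_km", "duration_min", "success_pct",
            "interpatch")
  if (ncl < 2) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  t <- as.numeric(track$fixes$timestamp)
  x <- track$fixes$x; y <- track$fixes$y
  rows <- vector("list", ncl - 1L)
  for (k in seq_len(ncl - 1L)) {
    first <- max(which(clusters$cluster == k))
    last <- min(which(clusters$cluster == k + 1L))
    idx <- first:last
    dur <- (t[last] - t[first]) / 60
    n <- length(idx)
    path_m <- sum(sqrt(diff(x[idx])^2 + diff(y[idx])^2))
    eu_m <- sqrt((x[last] - x[first])^2 + (y[last] - y[first])^2)
    rows[[k]] <- data.frame(
      animal_id = track$animal_id, movement = k,
      first_fix = first, last_fix = last,
      origin_cluster = k, destination_cluster = k + 1L,
      origin_patch = unname(clusters$patch[k]),
      destination_patch = unname(clusters$patch[k + 1L]),
      n_locations = n,
      expected_locations = expected_locations(dur, track$nominal_interval_s),
      euclidean_km = eu_m / 1000, path_km = path_m / 1000,
      duration_min = dur,
      success_pct = location_success(n, dur, track$nominal_interval_s),
      interpatch = unname(clusters$patch[k] != clusters$patch[k + 1L]))
  }
  do.call(rbind, rows)
}

#' Land-cover use counts
#'
#' Observed fix counts per land-cover group, with expected counts
#' proportional to each group's area share of the analysis region (the
#' whole raster, or an optional logical `region` mask). Fixes outside the
#' raster are excluded with a message.
#'
#' @param fixes Data frame with columns `x`, `y`.
#' @param lc A [lc_raster()].
#' @param groups Optional named character vector, category label -> group
#'   label (categories absent from it keep their own label).
#' @param region Optional logical matrix restricting the area computation.
#' @return Data frame with columns `group`, `observed`, `expected`,
#'   `area_cells`.
#' @export
landcover_use <- function(fixes, lc, groups = NULL, region = NULL) {
  stopifnot(inherits(lc, "lc_raster"))
  cell <- xy_to_cell(fixes$x, fixes$y, lc$cell_size, lc$origin, dim(lc$grid))
  if (any(!cell$inside)) {
    message(sum(!cell$inside), " fix(es) outside the raster excluded")
    cell <- cell[cell$inside, ]
  }
  lab_grid <- matrix(category_labels(lc), nrow(lc$grid), ncol(lc$grid))
  to_group <- function(lab) {
    if (is.null(groups)) return(lab)
    g <- groups[lab]
    ifelse(is.na(g), lab, g)
  }
  fix_lab <- to_group(lab_grid[cbind(cell$row, cell$col)])
  area_lab <- to_group(if (is.null(region)) as.vector(lab_grid) else lab_grid[region])
  all_groups <- sort(unique(c(fix_lab, area_lab)))
  observed <- as.integer(table(factor(fix_lab, levels = all_groups)))
  area <- as.integer(table(factor(area_lab, levels = all_groups)))
  n <- length(fix_lab)
  data.frame(group = all_groups, observed = observed,
             expected = n * area / sum(area), area_cells = area)
}

#' Distances to nearest habitat and nearest feature
#'
#' For each fix: the land-cover category beneath it, whether it lies in the
#' matrix (outside habitat), the Euclidean distance to the nearest habitat
#' cell boundary (0 inside habitat) and the distance and type of the
#' nearest linear feature. With an empty feature set the feature distance
#' is `NA` (undefined, not zero).
#'
#' @param fixes Data frame with columns `x`, `y`.
#' @param patches A `habitat_patches` object.
#' @param fs A [feature_set()] (may be empty).
#' @param lc Optional [lc_raster()] to record the category under each fix.
#' @return Data frame with columns `x`, `y`, `category`, `in_matrix`,
#'   `dist_habitat_m`, `dist_feature_m`, `feature_type`.
#' @export
nearest_distances <- function(fixes, patches, fs, lc = NULL) {
  stopifnot(inherits(patches, "habitat_patches"), inherits(fs, "feature_set"))
  n <- length(fixes$x)
  hab_cells <- which(patches$labels > 0L, arr.ind = TRUE)
  if (!nrow(hab_cells)) stop("patch set contains no habitat cells")
  dh <- pts_to_cells_min(fixes$x, fixes$y,
                         as.integer(hab_cells[, 1]), as.integer(hab_cells[, 2]),
                         patches$cell_size, patches$origin[1], patches$origin[2])
  if (length(fs$features)) {
    seg <- feature_segments(fs)
    near <- pts_to_segments_min(fixes$x, fixes$y, seg$x0, seg$y0, seg$x1, seg$y1)
    df_feat <- near$dist
    type <- vapply(seg$feature[near$which], function(i) fs$features[[i]]$type, "")
  } else {
    message("empty feature set: feature distances undefined")
    df_feat <- rep(NA_real_, n)
    type <- rep(NA_character_, n)
  }
  category <- rep(NA_character_, n)
  if (!is.null(lc)) {
    cell <- xy_to_cell(fixes$x, fixes$y, lc$cell_size, lc$origin, dim(lc$grid))
    lab_grid <- matrix(category_labels(lc), nrow(lc$grid), ncol(lc$grid))
    category[cell$inside] <- lab_grid[cbind(cell$row[cell$inside],
                                            cell$col[cell$inside])]
  }
  data.frame(x = fixes$x, y = fixes$y, category = category,
             in_matrix = patch_at(patches, fixes$x, fixes$y) == 0L,
             dist_habitat_m = dh, dist_feature_m = df_feat,
             feature_type = type, stringsAsFactors = FALSE)
}
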