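# Categorical land-cover rasters, resistance tables and surfaces, linear
# features, and habitat patch labelling.

#' Categorical land-cover raster
#'
#' A thin container for a categorical grid in a planar metric coordinate
#' system. `grid` holds integer category codes; `categories` maps each code
#' to its land-cover label. The grid origin is the outer corner of the
#' top-left cell; x grows east and y grows north, so row indices grow
#' southward.
#'
#' @param grid Integer matrix of category codes (at least 2 x 2).
#' @param cell_size Cell edge length in metres (> 0).
#' @param categories Named character vector mapping code (name) to label.
#' @param origin Numeric length-2, world (x, y) of the top-left outer corner.
#' @return An object of class `lc_raster`.
#' @export
lc_raster <- function(grid, cell_size, categories, origin = c(0, 0)) {
  stopifnot(is.matrix(grid), nrow(grid) >= 2, ncol(grid) >= 2,
            is.numeric(cell_size), length(cell_size) == 1, cell_size > 0,
            length(origin) == 2)
  storage.mode(grid) <- "integer"
  codes <- sort(unique(as.vector(grid)))
  missing <- setdiff(as.character(codes), names(categories))
  if (length(missing)) {
    stop("grid contains codes with no category label: ",
         paste(missing, collapse = ", "))
  }
  structure(list(grid = grid, cell_size = cell_size,
                 origin = as.numeric(origin),
                 categories = categories),
            class = "lc_raster")
}

#' @export
print.lc_raster <- function(x, ...) {
  cat(sprintf("<lc_raster> %d x %d cells, %.6g m cells, %d categories\n",
              nrow(x$grid), ncol(x$grid), x$cell_size,
              length(unique(as.vector(x$grid)))))
  invisible(x)
}

#' @export
dim.lc_raster <- function(x) dim(x$grid)

# label of the category under each cell of the raster (vector parallel to
# as.vector(grid))
#' @noRd
category_labels <- function(lc) unname(lc$categories[as.character(lc$grid)])

#' Resistance table
#'
#' Per-category movement resistance (a dimensionless cost rate: moving d
#' metres through a category accumulates `resistance * d` cost units), and
#' the set of categories classed as habitat. Habitat categories must have
#' resistance 1, the scale's reference value; all resistances must be >= 1.
#'
#' @param df Data frame with columns `category`, `resistance`, `is_habitat`.
#' @return An object of class `resistance_table` (a validated data frame).
#' @export
resistance_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("category", "resistance", "is_habitat") %in% names(df)))
  df$category <- as.character(df$category)
  df$resistance <- as.numeric(df$resistance)
  df$is_habitat <- as.logical(df$is_habitat)
  if (anyDuplicated(df$category))
    stop("duplicated category in resistance table: ",
         paste(unique(df$category[duplicated(df$category)]), collapse = ", "))
  if (any(df$resistance < 1))
    stop("resistance values must be >= 1")
  if (any(df$is_habitat & df$resistance != 1))
    stop("habitat categories must have resistance 1")
  class(df) <- c("resistance_table", "data.frame")
  df
}

#' Bundled gray-squirrel resistance table
#'
#' The expert-derived per-land-cover resistances used throughout the package
#' (woodland habitat = 1 up to Building/Rock = 1000), read from the bundled
#' CSV. `field_edge = TRUE` (default) appends the "Field edge" category at
#' resistance 16 — the same as scrub, coppice and garden — used when burning
#' field-edge features into the map. The table carries no "Road" entry;
#' rasters containing a road category must have its resistance supplied
#' explicitly (see [add_resistance_entry()]).
#'
#' @param field_edge Append the "Field edge" category at resistance 16?
#' @return A [resistance_table()].
#' @export
default_resistance_table <- function(field_edge = TRUE) {
  path <- system.file("extdata", "resistance_table1.csv",
                      package = "corridorcast", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (field_edge) {
    df <- rbind(df, data.frame(category = "Field edge", resistance = 16,
                               is_habitat = FALSE))
  }
  resistance_table(df)
}

#' Add or override an entry of a resistance table
#'
#' @param rt A [resistance_table()].
#' @param category,resistance,is_habitat The entry to add (or replace).
#' @return The updated table.
#' @export
add_resistance_entry <- function(rt, category, resistance, is_habitat = FALSE) {
  df <- as.data.frame(rt)
  df <- df[df$category != category, ]
  df <- rbind(df, data.frame(category = category, resistance = resistance,
                             is_habitat = is_habitat))
  resistance_table(df)
}

#' @noRd
habitat_labels <- function(rt) rt$category[rt$is_habitat]

#' Linear landscape features
#'
#' A set of polyline features (field edges, rivers, roads, verges, tracks,
#' paths, habitat edges), each with a world-coordinate polyline, a type
#' label and a width in metres.
#'
#' @param features List of features as returned by [linear_feature()].
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(features = list()) {
  for (f in features) {
    stopifnot(is.matrix(f$coords), ncol(f$coords) == 2, nrow(f$coords) >= 2,
              is.character(f$type), is.numeric(f$width_m), f$width_m > 0)
  }
  structure(list(features = features), class = "feature_set")
}

#' @rdname feature_set
#' @param coords n x 2 matrix of polyline vertices (world metres, >= 2 rows).
#' @param type Feature type label, e.g. "field edge", "river/stream", "road".
#' @param width_m Feature width in metres (> 0).
#' @export
linear_feature <- function(coords, type, width_m) {
  list(coords = coords, type = type, width_m = width_m)
}

#' @export
length.feature_set <- function(x) length(x$features)

#' Default mapping from feature type to land-cover category
#'
#' Feature types are burned into the land-cover map under these categories:
#' field edges as "Field edge", rivers/streams as "Water", roads as "Road",
#' road verges as "Road verge", tracks as "Track" and paths as "Path".
#'
#' @return Named character vector, feature type -> category label.
#' @export
default_feature_categories <- function() {
  c("field edge" = "Field edge",
    "habitat edge" = "Scrub",
    "path" = "Path",
    "river/stream" = "Water",
    "road" = "Road",
    "road verge" = "Road verge",
    "track" = "Track")
}

#' Burn linear features into a land-cover raster
#'
#' Every cell whose centre lies within `width_m / 2` of a feature's polyline
#' is overwritten with the category mapped to the feature's type; all other
#' cells are unchanged. Features are burned in list order, so later features
#' overwrite earlier ones where they overlap. New category labels are given
#' fresh codes.
#'
#' @param lc A [lc_raster()].
#' @param fs A [feature_set()].
#' @param category_of Named character vector, feature type -> category label
#'   (default [default_feature_categories()]).
#' @return The updated `lc_raster`.
#' @export
burn_linear_features <- function(lc, fs, category_of = default_feature_categories()) {
  stopifnot(inherits(lc, "lc_raster"), inherits(fs, "feature_set"))
  grid <- lc$grid
  categories <- lc$categories
  cs <- lc$cell_size
  nr <- nrow(grid); nc <- ncol(grid)
  xmax <- lc$origin[1] + nc * cs
  ymin <- lc$origin[2] - nr * cs
  for (i in seq_along(fs$features)) {
    f <- fs$features[[i]]
    if (all(f$coords[, 1] == f$coords[1, 1]) &&
        all(f$coords[, 2] == f$coords[1, 2])) {
      stop("feature ", i, " (", f$type, ") has a zero-length polyline")
    }
    type <- f$type
    if (!type %in% names(category_of))
      stop("no category mapping for feature type '", type, "'")
    label <- category_of[[type]]
    if (!label %in% categories) {
      code <- max(as.integer(names(categories))) + 1L
      categories[as.character(code)] <- label
    }
    code <- as.integer(names(categories)[match(label, categories)])
    half <- f$width_m / 2
    bb <- c(min(f$coords[, 1]) - half, max(f$coords[, 1]) + half,
            min(f$coords[, 2]) - half, max(f$coords[, 2]) + half)
    if (bb[2] < lc$origin[1] || bb[1] > xmax || bb[4] < ymin || bb[3] > lc$origin[2]) {
      warning("feature ", i, " (", type, ") lies outside the raster extent; clipped")
      next
    }
    # candidate cell window from the bounding box
    c0 <- max(1L, floor((bb[1] - lc$origin[1]) / cs) + 1L)
    c1 <- min(nc, floor((bb[2] - lc$origin[1]) / cs) + 1L)
    r0 <- max(1L, floor((lc$origin[2] - bb[4]) / cs) + 1L)
    r1 <- min(nr, floor((lc$origin[2] - bb[3]) / cs) + 1L)
    rows <- rep.int(r0:r1, c1 - c0 + 1L)
    cols <- rep(c0:c1, each = r1 - r0 + 1L)
    ctr <- cell_centre_xy(rows, cols, cs, lc$origin)
    seg <- polyline_segments(f$coords)
    d <- pts_to_segments_min(ctr[, 1], ctr[, 2], seg$x0, seg$y0, seg$x1, seg$y1)$dist
    hit <- d <= half
    if (any(hit)) grid[cbind(rows[hit], cols[hit])] <- code
  }
  lc_raster(grid, cs, categories, lc$origin)
}

#' Resistance surface
#'
#' A numeric grid of per-cell movement resistances (all >= 1) with the same
#' georeferencing conventions as [lc_raster()]. Usually built from land
#' cover via [build_resistance_surface()]; this constructor serves direct
#' construction of analytic surfaces.
#'
#' @param grid Numeric matrix of resistances (>= 1).
#' @param cell_size Cell edge length in metres.
#' @param origin World (x, y) of the top-left outer corner.
#' @return An object of class `resistance_surface`.
#' @export
resistance_surface <- function(grid, cell_size, origin = c(0, 0)) {
  stopifnot(is.matrix(grid), is.numeric(grid), all(grid >= 1),
            cell_size > 0, length(origin) == 2)
  structure(list(grid = grid, cell_size = cell_size,
                 origin = as.numeric(origin)),
            class = "resistance_surface")
}

#' Build a resistance surface from land cover
#'
#' Element-wise substitution of category code by its resistance value.
#' A category present in the raster but absent from the table is an error
#' (no silent default), naming the offending category.
#'
#' @param lc A [lc_raster()].
#' @param rt A [resistance_table()].
#' @return An object of class `resistance_surface` with fields `grid`
#'   (numeric matrix), `cell_size`, `origin`.
#' @export
build_resistance_surface <- function(lc, rt) {
  stopifnot(inherits(lc, "lc_raster"), inherits(rt, "resistance_table"))
  labels <- category_labels(lc)
  idx <- match(labels, rt$category)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("no resistance entry for land-cover categor",
         if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "))
  }
  grid <- matrix(rt$resistance[idx], nrow(lc$grid), ncol(lc$grid))
  structure(list(grid = grid, cell_size = lc$cell_size, origin = lc$origin),
            class = "resistance_surface")
}

#' @export
print.resistance_surface <- function(x, ...) {
  cat(sprintf("<resistance_surface> %d x %d cells, %.6g m cells, range [%g, %g]\n",
              nrow(x$grid), ncol(x$grid), x$cell_size,
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Label habitat patches
#'
#' Connected components of habitat cells (categories flagged `is_habitat` in
#' the resistance table). Patch ids are >= 1, with 0 for non-habitat; areas
#' are reported in hectares (cell count x cell_size^2 / 1e4).
#'
#' @param lc A [lc_raster()].
#' @param rt A [resistance_table()].
#' @param connectivity 4 or 8 (default 8, matching the movement model).
#' @return An object of class `habitat_patches` with fields `labels`
#'   (integer matrix), `areas_ha` (named by patch id), `visited` (named
#'   logical, all `FALSE` until [select_visited_patches()]), plus grid
#'   georeferencing.
#' @export
label_habitat_patches <- function(lc, rt, connectivity = 8) {
  stopifnot(inherits(lc, "lc_raster"), inherits(rt, "resistance_table"),
            connectivity %in% c(4, 8))
  hab <- habitat_labels(rt)
  if (!length(hab)) stop("resistance table declares no habitat categories")
  mask <- matrix(category_labels(lc) %in% hab, nrow(lc$grid), ncol(lc$grid))
  if (!any(mask)) {
    warning("no habitat cells in raster; empty patch set")
    labels <- matrix(0L, nrow(lc$grid), ncol(lc$grid))
    areas <- numeric(0)
  } else {
    labels <- grid_components(mask, as.integer(connectivity))
    counts <- tabulate(labels[labels > 0L])
    areas <- counts * lc$cell_size^2 / 1e4
    names(areas) <- seq_along(areas)
  }
  structure(list(labels = labels, areas_ha = areas,
                 visited = setNames(rep(FALSE, length(areas)), names(areas)),
                 cell_size = lc$cell_size, origin = lc$origin),
            class = "habitat_patches")
}

#' @export
print.habitat_patches <- function(x, ...) {
  cat(sprintf("<habitat_patches> %d patches, %.4g ha total, %d visited\n",
              length(x$areas_ha), sum(x$areas_ha), sum(x$visited)))
  invisible(x)
}

# patch id under each point (0 = matrix / outside raster)
#' @noRd
patch_at <- function(patches, x, y) {
  cell <- xy_to_cell(x, y, patches$cell_size, patches$origin, dim(patches$labels))
  id <- integer(length(x))
  ok <- cell$inside
  id[ok] <- patches$labels[cbind(cell$row[ok], cell$col[ok])]
  id
}
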