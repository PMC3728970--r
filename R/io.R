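# Plain-text spatial I/O: ESRI ASCII grids for rasters and masks, GeoJSON
# for linear features and paths, CSV for fixes, resistance tables and
# movement tables.

#' Write a grid as an ESRI ASCII raster
#'
#' Single-band ASCII grid (`ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header). `Inf` and `NA` are written as the NoData value.
#'
#' @param grid Numeric or logical matrix (row 1 = northernmost).
#' @param path Output file.
#' @param cell_size Cell size in metres.
#' @param origin World (x, y) of the top-left outer corner.
#' @param nodata NoData sentinel (default -9999).
#' @export
write_ascii_grid <- function(grid, path, cell_size, origin, nodata = -9999) {
  nr <- nrow(grid); nc <- ncol(grid)
  g <- grid
  storage.mode(g) <- "double"
  g[!is.finite(g)] <- nodata
  hdr <- c(paste("ncols", nc), paste("nrows", nr),
           paste("xllcorner", format(origin[1], scientific = FALSE)),
           paste("yllcorner", format(origin[2] - nr * cell_size, scientific = FALSE)),
           paste("cellsize", format(cell_size, scientific = FALSE)),
           paste("NODATA_value", nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path Input file.
#' @return List: `grid` (numeric matrix, NoData as `NA`), `cell_size`,
#'   `origin` (top-left outer corner).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                  tolower(vapply(kv, `[`, "", 1)))
  n_hdr <- sum(names(hdr) %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                                 "cellsize", "nodata_value"))
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  nr <- hdr[["nrows"]]; nc <- hdr[["ncols"]]
  grid <- matrix(vals, nr, nc, byrow = TRUE)
  if ("nodata_value" %in% names(hdr)) grid[grid == hdr[["nodata_value"]]] <- NA
  list(grid = grid, cell_size = hdr[["cellsize"]],
       origin = c(hdr[["xllcorner"]], hdr[["yllcorner"]] + nr * hdr[["cellsize"]]))
}

#' Write a feature set as GeoJSON
#'
#' LineString features with `type` and `width_m` properties.
#'
#' @param fs A [feature_set()].
#' @param path Output file.
#' @export
write_features_geojson <- function(fs, path) {
  feats <- lapply(fs$features, function(f) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = unname(lapply(seq_len(nrow(f$coords)),
                                                     function(i) unname(f$coords[i, ])))),
         properties = list(type = f$type, width_m = f$width_m))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature set from GeoJSON
#'
#' Accepts LineString and MultiLineString geometries with `type` and
#' `width_m` properties.
#'
#' @param path Input file.
#' @return A [feature_set()].
#' @export
read_features_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  feats <- list()
  for (f in gj$features) {
    prop <- f$properties
    lines <- switch(f$geometry$type,
                    LineString = list(f$geometry$coordinates),
                    MultiLineString = f$geometry$coordinates,
                    stop("unsupported geometry type: ", f$geometry$type))
    for (ln in lines) {
      coords <- do.call(rbind, lapply(ln, function(p) c(p[[1]], p[[2]])))
      feats <- c(feats, list(linear_feature(coords, prop$type, prop$width_m)))
    }
  }
  feature_set(feats)
}

#' Write a least-cost path as GeoJSON
#'
#' @param path_obj A `least_cost_path`.
#' @param path Output file.
#' @export
write_path_geojson <- function(path_obj, path) {
  stopifnot(inherits(path_obj, "least_cost_path"), path_obj$found)
  v <- path_obj$vertices
  feat <- list(type = "Feature",
               geometry = list(type = "LineString",
                               coordinates = unname(lapply(seq_len(nrow(v)),
                                                           function(i) unname(v[i, ])))),
               properties = list(total_cost = path_obj$total_cost,
                                 length_m = path_obj$length_m))
  jsonlite::write_json(list(type = "FeatureCollection", features = list(feat)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GPS fixes from CSV
#'
#' Expects columns `animal_id`, `timestamp`, `x`, `y`; `timestamp` may be
#' ISO-8601 or numeric seconds.
#'
#' @param path Input file.
#' @param nominal_interval_s Nominal fix interval (default 180 s).
#' @return List of [gps_track()], one per animal (in order of appearance).
#' @export
read_fixes_csv <- function(path, nominal_interval_s = 180) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("animal_id", "timestamp", "x", "y") %in% names(df)))
  ts <- suppressWarnings(as.numeric(df$timestamp))
  if (anyNA(ts)) {
    ts <- as.numeric(as.POSIXct(df$timestamp, tz = "UTC",
                                tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                               "%Y-%m-%d %H:%M:%OS",
                                               "%Y-%m-%d")))
  }
  df$timestamp <- ts
  lapply(unique(df$animal_id), function(id) {
    sub <- df[df$animal_id == id, ]
    gps_track(id, sub[c("timestamp", "x", "y")], nominal_interval_s)
  })
}

#' Read a resistance table from CSV
#'
#' Columns `category`, `resistance`, `is_habitat`.
#'
#' @param path Input file.
#' @return A [resistance_table()].
#' @export
read_resistance_csv <- function(path) {
  resistance_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
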