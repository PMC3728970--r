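# Model validation statistics: the area-versus-points comparison statistic,
# goodness-of-fit and distance tests, path-inflation test, random reference
# points, and breakpoint (hinge) regression.

#' Convex polygon around points
#'
#' Convex hull in world coordinates, used as the analysis boundary so that
#' no arbitrary study-area rectangle is needed.
#'
#' @param points Data frame or matrix with x, y columns (>= 3 non-collinear
#'   points).
#' @return Object of class `convex_polygon`: `vertices` (counter-clockwise,
#'   open ring) and `area` (m^2).
#' @export
convex_polygon <- function(points) {
  xy <- if (is.data.frame(points)) {
    cbind(points$x %||% points[[1]], points$y %||% points[[2]])
  } else {
    cbind(points[, 1], points[, 2])
  }
  xy <- unique(xy[stats::complete.cases(xy), , drop = FALSE])
  if (nrow(xy) < 3) stop("need at least 3 distinct points for a convex polygon")
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  v <- xy[idx, , drop = FALSE]
  a <- polygon_signed_area(v)
  if (abs(a) < 1e-12) stop("points are collinear; polygon has zero area")
  if (a < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  colnames(v) <- c("x", "y")
  structure(list(vertices = v, area = abs(a)), class = "convex_polygon")
}

#' @export
print.convex_polygon <- function(x, ...) {
  cat(sprintf("<convex_polygon> %d vertices, area %.6g m^2\n",
              nrow(x$vertices), x$area))
  invisible(x)
}

#' Area/points comparison statistic
#'
#' The model-comparison ratio: percentage of the analysis polygon's area
#' covered by the model mask, divided by the percentage of GPS movement
#' points falling inside the mask. A compact model that still captures the
#' points scores low, which is preferred. `statistic_2dp` truncates to the
#' two decimals of the conventional printed form (42/81 prints as 0.51).
#'
#' @param area_pct Percentage of polygon area inside the mask (0-100).
#' @param points_pct Percentage of points inside the mask (0-100).
#' @param model_name Optional label (e.g. "LCN", "LCP", "LCC").
#' @return Object of class `comparison_result` with `area_pct`,
#'   `points_pct`, `statistic`, `statistic_2dp`, `undefined`.
#' @export
comparison_statistic <- function(area_pct, points_pct, model_name = NA_character_) {
  stopifnot(area_pct >= 0, area_pct <= 100, points_pct >= 0, points_pct <= 100)
  if (points_pct == 0) {
    message("no points inside the mask: statistic undefined")
    stat <- NA_real_
  } else {
    stat <- area_pct / points_pct
  }
  structure(list(model_name = model_name, area_pct = area_pct,
                 points_pct = points_pct, statistic = stat,
                 statistic_2dp = if (is.na(stat)) NA_real_ else trunc_decimals(stat, 2),
                 undefined = is.na(stat)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: area %.4g%%, points %.4g%%, statistic %s\n",
              x$model_name, x$area_pct, x$points_pct,
              if (x$undefined) "undefined" else sprintf("%.2f", x$statistic_2dp)))
  invisible(x)
}

#' Compare a connectivity model mask against GPS points
#'
#' Measures, on the mask's grid, the percentage of the polygon's area
#' covered by the mask (cells whose centre falls in the polygon) and the
#' percentage of points inside the mask, and forms the comparison
#' statistic.
#'
#' @param mask A `landscape_mask` (network, buffered-path or corridor).
#' @param polygon A [convex_polygon()].
#' @param points Data frame with columns `x`, `y` (the movement fixes).
#' @param model_name Optional label; defaults to the mask class.
#' @return A `comparison_result`.
#' @export
compare_model <- function(mask, polygon, points, model_name = NULL) {
  stopifnot(inherits(mask, "landscape_mask"), inherits(polygon, "convex_polygon"))
  if (is.null(model_name))
    model_name <- switch(class(mask)[1], network_mask = "LCN",
                         buffered_path_mask = "LCP", corridor_mask = "LCC",
                         class(mask)[1])
  d <- dim(mask$mask)
  ctr <- all_cell_centres(d, mask$cell_size, mask$origin)
  inpoly <- points_in_convex(ctr[, 1], ctr[, 2], polygon$vertices)
  if (!any(inpoly)) stop("polygon covers no raster cells")
  area_pct <- 100 * sum(mask$mask[inpoly]) / sum(inpoly)
  cell <- xy_to_cell(points$x, points$y, mask$cell_size, mask$origin, d)
  if (any(!cell$inside)) {
    message(sum(!cell$inside), " point(s) outside the raster excluded")
    cell <- cell[cell$inside, ]
  }
  if (!nrow(cell)) stop("no points inside the raster")
  points_pct <- 100 * mean(mask$mask[cbind(cell$row, cell$col)])
  comparison_statistic(area_pct, points_pct, model_name)
}

#' Chi-square goodness of fit with subdivided per-group tests
#'
#' Full-table test of observed counts against expectations proportional to
#' `expected_weights`, plus the 1-df subdivided partition testing each
#' group against the pooled remainder.
#'
#' @param observed Named integer vector of counts.
#' @param expected_weights Positive weights (areas, availabilities), same
#'   groups.
#' @return List: `statistic`, `df`, `p.value`, `expected`, and `subdivided`
#'   (data frame with one 1-df test per group).
#' @export
chisq_gof <- function(observed, expected_weights) {
  stopifnot(length(observed) == length(expected_weights),
            sum(observed) >= 1, all(expected_weights > 0))
  p <- expected_weights / sum(expected_weights)
  expected <- sum(observed) * p
  if (any(expected < 1))
    warning("expected count below 1 in some group; consider merging groups")
  full <- suppressWarnings(stats::chisq.test(observed, p = p))
  n <- sum(observed)
  sub <- lapply(seq_along(observed), function(i) {
    t1 <- suppressWarnings(stats::chisq.test(c(observed[i], n - observed[i]),
                                             p = c(p[i], 1 - p[i])))
    data.frame(group = names(observed)[i] %||% as.character(i),
               observed = observed[i], expected = expected[i],
               chisq = unname(t1$statistic), p.value = t1$p.value)
  })
  list(statistic = unname(full$statistic), df = unname(full$parameter),
       p.value = full$p.value, expected = expected,
       subdivided = do.call(rbind, sub))
}

#' Paired t-test (difference a - b)
#'
#' Two-sided paired t-test on `series_a - series_b`. With the Euclidean
#' distances as `series_a` and the actual path lengths as `series_b`, path
#' inflation shows as a negative t.
#'
#' @param series_a,series_b Equal-length numeric vectors (n >= 2).
#' @return List: `statistic`, `df`, `p.value`, `mean_difference`.
#' @export
paired_t <- function(series_a, series_b) {
  stopifnot(length(series_a) == length(series_b), length(series_a) >= 2)
  d <- series_a - series_b
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t-test undefined")
  tt <- stats::t.test(series_a, series_b, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_difference = mean(d))
}

#' Mann-Whitney U test
#'
#' U for the first sample with midrank tie handling; p by the normal
#' approximation with tie correction.
#'
#' @param sample_obs,sample_ref Non-empty numeric vectors.
#' @return List: `U`, `p.value`.
#' @export
mann_whitney <- function(sample_obs, sample_ref) {
  stopifnot(length(sample_obs) >= 1, length(sample_ref) >= 1)
  wt <- suppressWarnings(stats::wilcox.test(sample_obs, sample_ref,
                                            exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value)
}

#' Random points in the landscape matrix
#'
#' `n` points drawn uniformly over non-habitat cells (uniform cell choice
#' plus uniform jitter within the cell), reproducible under `seed`. These
#' serve as the chance reference for distance-to-habitat and
#' distance-to-feature tests.
#'
#' @param lc A [lc_raster()].
#' @param rt A [resistance_table()] (defines the habitat categories).
#' @param n Number of points (>= 0).
#' @param seed Optional RNG seed.
#' @return Data frame with columns `x`, `y`.
#' @export
random_matrix_points <- function(lc, rt, n, seed = NULL) {
  stopifnot(inherits(lc, "lc_raster"), inherits(rt, "resistance_table"), n >= 0)
  hab <- habitat_labels(rt)
  matrix_cells <- which(!(category_labels(lc) %in% hab))
  if (!length(matrix_cells)) stop("raster contains no matrix (non-habitat) cells")
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  with_seed(seed, {
    nr <- nrow(lc$grid)
    i <- matrix_cells[sample.int(length(matrix_cells), n, replace = TRUE)]
    row <- ((i - 1L) %% nr) + 1L
    col <- ((i - 1L) %/% nr) + 1L
    ctr <- cell_centre_xy(row, col, lc$cell_size, lc$origin)
    jit <- lc$cell_size * (matrix(stats::runif(2 * n), n, 2) - 0.5)
    data.frame(x = ctr[, 1] + jit[, 1], y = ctr[, 2] + jit[, 2])
  })
}

#' Breakpoint (hinge) regression
#'
#' Two-segment continuous piecewise-linear least squares:
#' `y = b0 + b1 x + b2 max(0, x - psi)`, with the breakpoint `psi` chosen
#' by exhaustive search over the interior unique x values (smallest RSS;
#' ties go to the smaller psi). Used to locate the distance from habitat
#' beyond which animals re-orientate towards landscape features.
#'
#' @param x,y Numeric vectors (n >= 8, x spanning >= 3 distinct values).
#' @return Object of class `segmented_fit`: `breakpoint_m`, `left_slope`,
#'   `left_intercept`, `right_slope`, `right_intercept`, `rss`, `rss_line`
#'   (single-line fit), `p.value` (F test of the 2 extra parameters) and
#'   `supported` (FALSE when the break adds nothing over a single line).
#' @export
breakpoint_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 8) stop("need at least 8 points")
  ux <- sort(unique(x))
  if (length(ux) < 3) stop("x is degenerate: fewer than 3 distinct values")
  candidates <- ux[-c(1, length(ux))]
  line <- stats::lm.fit(cbind(1, x), y)
  rss_line <- sum(line$residuals^2)
  best <- NULL
  for (psi in candidates) {
    fit <- stats::lm.fit(cbind(1, x, pmax(0, x - psi)), y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(psi = psi, rss = rss, coef = fit$coefficients)
    }
  }
  b <- unname(best$coef)
  b[is.na(b)] <- 0
  if (rss_line < 1e-10 * max(1, sum(y^2)) || best$rss >= rss_line - 1e-12) {
    p <- 1
  } else {
    fstat <- ((rss_line - best$rss) / 2) / (best$rss / (n - 4))
    p <- stats::pf(fstat, 2, n - 4, lower.tail = FALSE)
  }
  structure(list(breakpoint_m = best$psi,
                 left_slope = b[2], left_intercept = b[1],
                 right_slope = b[2] + b[3],
                 right_intercept = b[1] - b[3] * best$psi,
                 rss = best$rss, rss_line = rss_line,
                 p.value = p,
                 supported = p < 0.05 && best$rss < rss_line * (1 - 1e-6)),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("<segmented_fit> breakpoint %.4g m (%s), slopes %.4g -> %.4g, RSS %.6g\n",
              x$breakpoint_m, if (x$supported) "supported" else "unsupported",
              x$left_slope, x$right_slope, x$rss))
  invisible(x)
}

#' Rank land-cover / feature use
#'
#' Groups ordered by observed/expected ratio (descending); ties broken
#' alphabetically. A group with observations but zero expectation gets an
#' infinite ratio and ranks first.
#'
#' @param observed,expected Named numeric vectors over the same groups.
#' @return Data frame `group`, `observed`, `expected`, `ratio`, `rank`.
#' @export
rank_use <- function(observed, expected) {
  stopifnot(!is.null(names(observed)),
            setequal(names(observed), names(expected)))
  expected <- expected[names(observed)]
  ratio <- ifelse(expected == 0 & observed > 0, Inf, observed / expected)
  ord <- order(-ratio, names(observed))
  out <- data.frame(group = names(observed)[ord],
                    observed = unname(observed)[ord],
                    expected = unname(expected)[ord],
                    ratio = unname(ratio)[ord])
  out$rank <- seq_len(nrow(out))
  out
}
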