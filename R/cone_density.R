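
#' Construct a calibrated foveal cone mosaic
#'
#' A cone mosaic is the set of cone-center coordinates identified inside a
#' calibrated region of interest (ROI) centered on the fovea, nominally
#' 300 x 300 micrometres. Coordinates are micrometres from the ROI's top-left
#' corner, x increasing rightward and y downward.
#'
#' @param coords two-column matrix or data frame of cone centers
#'   (`x_um`, `y_um`).
#' @param roi_width_um,roi_height_um ROI extent in micrometres.
#' @param participant_id optional label carried through the pipeline.
#' @param min_separation_um coordinates closer than this raise a warning
#'   (default 0.5); exact duplicates are an error.
#' @return an object of class `cone_mosaic`.
#' @export
cone_mosaic <- function(coords, roi_width_um = 300, roi_height_um = 300,
                        participant_id = NA_character_,
                        min_separation_um = 0.5) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x_um", "y_um")
  check_positive(roi_width_um, "roi_width_um")
  check_positive(roi_height_um, "roi_height_um")
  if (nrow(coords) == 0L) stop_fovea("cone mosaic is empty")
  if (anyNA(coords)) stop_fovea("cone coordinates contain missing values")
  if (any(coords[, 1] < 0 | coords[, 1] > roi_width_um |
          coords[, 2] < 0 | coords[, 2] > roi_height_um))
    stop_fovea("cone coordinates fall outside the %g x %g um ROI",
               roi_width_um, roi_height_um)
  if (anyDuplicated(coords))
    stop_fovea("duplicate cone coordinates present")
  # near-duplicates: check only when feasible without an O(n^2) blowup
  if (nrow(coords) <= 5000L && min_separation_um > 0) {
    d <- stats::dist(coords)
    if (any(d < min_separation_um))
      warn_fovea("%d cone pair(s) closer than %g um",
                 sum(d < min_separation_um), min_separation_um)
  }
  structure(list(coords = coords, roi_width_um = roi_width_um,
                 roi_height_um = roi_height_um,
                 participant_id = participant_id),
            class = "cone_mosaic")
}

#' @export
print.cone_mosaic <- function(x, ...) {
  cat(sprintf("<cone_mosaic> %d cones in %g x %g um ROI (participant %s)\n",
              nrow(x$coords), x$roi_width_um, x$roi_height_um,
              x$participant_id))
  invisible(x)
}

#' Read cone coordinates from CSV
#'
#' Expects a header `x_um,y_um` (an optional `participant_id` column is
#' ignored in favour of the argument).
#'
#' @inheritParams cone_mosaic
#' @param path CSV file path.
#' @return a [cone_mosaic()].
#' @export
read_cone_coords <- function(path, roi_width_um = 300, roi_height_um = 300,
                             participant_id = NA_character_) {
  df <- read.csv(path, check.names = FALSE)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop_fovea("'%s' must have columns x_um,y_um (found: %s)", path,
               paste(names(df), collapse = ","))
  cone_mosaic(df[, c("x_um", "y_um")], roi_width_um, roi_height_um,
              participant_id)
}

#' Write cone coordinates to CSV
#'
#' @param mosaic a [cone_mosaic()].
#' @param path output CSV path.
#' @export
write_cone_coords <- function(mosaic, path) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  write.csv(as.data.frame(mosaic$coords), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Sliding-window cone density map
#'
#' Computes cone density (cones/mm^2) on a regular grid of window centers. At
#' each grid node whose square window lies fully inside the ROI, density is
#' the number of cones inside the half-open window
#' `[cx - w/2, cx + w/2) x [cy - w/2, cy + w/2)` divided by the window area,
#' so every cone is counted by a well-defined set of windows. Windows partially
#' outside the ROI are not evaluated (no partial-window renormalization).
#'
#' @param mosaic a [cone_mosaic()].
#' @param window_side_um side of the square counting window (default 50).
#' @param grid_step_um spacing of window centers (default 1). When
#'   `window_side_um` is an integer multiple of `grid_step_um` the counts are
#'   computed exactly via a summed-area table; otherwise each node is counted
#'   directly.
#' @param density_ceiling maximum physically plausible density (cones/mm^2);
#'   values above it trigger a warning (default 4e5).
#' @return an object of class `density_map` with fields `grid` (rows = y,
#'   cols = x, cones/mm^2), `grid_step_um`, `window_side_um`, `origin_um`
#'   (physical x, y of grid node \[1,1\]) and ROI metadata.
#' @export
density_map <- function(mosaic, window_side_um = 50, grid_step_um = 1,
                        density_ceiling = 4e5) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  w <- window_side_um
  step <- grid_step_um
  check_positive(w, "window_side_um")
  check_positive(step, "grid_step_um")
  if (w >= min(mosaic$roi_width_um, mosaic$roi_height_um))
    stop_fovea("window (%g um) must be smaller than the ROI (%g x %g um)",
               w, mosaic$roi_width_um, mosaic$roi_height_um)
  if (step > w) stop_fovea("grid_step_um must not exceed window_side_um")
  xc <- seq(w / 2, mosaic$roi_width_um - w / 2, by = step)
  yc <- seq(w / 2, mosaic$roi_height_um - w / 2, by = step)
  x <- mosaic$coords[, 1]
  y <- mosaic$coords[, 2]
  m <- w / step
  if (abs(m - round(m)) < 1e-9) {
    counts <- .window_counts_sat(x, y, length(xc), length(yc), step,
                                 as.integer(round(m)))
  } else {
    counts <- matrix(0L, length(yc), length(xc))
    for (j in seq_along(xc)) {
      inx <- x >= xc[j] - w / 2 & x < xc[j] + w / 2
      ys <- y[inx]
      for (i in seq_along(yc))
        counts[i, j] <- sum(ys >= yc[i] - w / 2 & ys < yc[i] + w / 2)
    }
  }
  grid <- counts / (w / 1000)^2
  if (any(grid > density_ceiling))
    warn_fovea("density map exceeds the physical ceiling of %g cones/mm^2",
               density_ceiling)
  structure(list(grid = grid, grid_step_um = step, window_side_um = w,
                 origin_um = c(x = xc[1], y = yc[1]),
                 roi_width_um = mosaic$roi_width_um,
                 roi_height_um = mosaic$roi_height_um,
                 participant_id = mosaic$participant_id),
            class = "density_map")
}

# exact window counts via a summed-area table over step-sized bins.
# Node k (0-based) has window [k*step, k*step + m*step): bins k .. k+m-1.
.window_counts_sat <- function(x, y, nx, ny, step, m) {
  nbx <- nx + m - 1L
  nby <- ny + m - 1L
  bx <- floor(x / step)
  by <- floor(y / step)
  keep <- bx < nbx & by < nby
  tab <- matrix(0, nby, nbx)
  if (any(keep)) {
    idx <- by[keep] + nby * bx[keep] + 1
    cnt <- tabulate(idx, nbins = nby * nbx)
    tab <- matrix(cnt, nby, nbx)
  }
  # summed-area table padded with a leading zero row/col
  S <- matrix(0, nby + 1L, nbx + 1L)
  S[-1, -1] <- tab
  for (j in 2:(nbx + 1L)) S[, j] <- S[, j] + S[, j - 1L]
  for (i in 2:(nby + 1L)) S[i, ] <- S[i, ] + S[i - 1L, ]
  ky <- seq_len(ny)
  kx <- seq_len(nx)
  S[ky + m, kx + m, drop = FALSE] - S[ky, kx + m, drop = FALSE] -
    S[ky + m, kx, drop = FALSE] + S[ky, kx, drop = FALSE]
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map> %d x %d nodes, step %g um, window %g um, max %.0f cones/mm^2\n",
    nrow(x$grid), ncol(x$grid), x$grid_step_um, x$window_side_um, max(x$grid)))
  invisible(x)
}

# physical positions of grid nodes
.map_node_x <- function(map) map$origin_um["x"] + (seq_len(ncol(map$grid)) - 1) * map$grid_step_um
.map_node_y <- function(map) map$origin_um["y"] + (seq_len(nrow(map$grid)) - 1) * map$grid_step_um

#' Peak cone density of a density map
#'
#' The peak cone density (PCD) is the maximum of the sliding-window density
#' map. Ties (common with integer window counts) are broken by the node
#' closest to the ROI center, then by row-major order.
#'
#' @param map a [density_map()].
#' @return list with `pcd` (cones/mm^2), `location_um` (x, y of the winning
#'   node) and `index` (row, col).
#' @export
peak_cone_density <- function(map) {
  stopifnot(inherits(map, "density_map"))
  g <- map$grid
  mx <- max(g)
  idx <- which(g == mx, arr.ind = TRUE)
  xs <- .map_node_x(map)[idx[, 2]]
  ys <- .map_node_y(map)[idx[, 1]]
  cx <- map$roi_width_um / 2
  cy <- map$roi_height_um / 2
  d2 <- (xs - cx)^2 + (ys - cy)^2
  # row-major order among equidistant ties: order by row then column
  best <- order(d2, idx[, 1], idx[, 2])[1]
  list(pcd = mx,
       location_um = c(x = unname(xs[best]), y = unname(ys[best])),
       index = c(row = unname(idx[best, 1]), col = unname(idx[best, 2])))
}

#' Cone density centroid from an isodensity contour
#'
#' Thresholds the density map at `fraction` of the peak cone density, keeps
#' the 8-connected supra-threshold component containing the PCD node, and
#' returns the (density-weighted, by default) centroid of that component as
#' the cone density centroid (CDC) — a stabler foveal landmark than the PCD
#' pixel itself. The density at the CDC is read off the map by bilinear
#' interpolation.
#'
#' @param map a [density_map()].
#' @param fraction isodensity level as a fraction of PCD (default 0.8).
#' @param weighted use density-weighted centroid (default) or the unweighted
#'   centroid of the component's node positions.
#' @return an object of class `density_metrics`: `pcd`, `pcd_location_um`,
#'   `cdc_location_um`, `cdc_density`, `contour_mask` (logical grid),
#'   `threshold`, `fraction`.
#' @export
cdc <- function(map, fraction = 0.8, weighted = TRUE) {
  stopifnot(inherits(map, "density_map"))
  if (fraction <= 0 || fraction >= 1)
    stop_fovea("'fraction' must be in (0, 1)")
  pk <- peak_cone_density(map)
  threshold <- fraction * pk$pcd
  mask <- map$grid >= threshold
  lab <- label_components(mask, connectivity = 8L)
  keep <- lab == lab[pk$index["row"], pk$index["col"]]
  if (sum(keep) == 1L)
    warn_fovea("degenerate isodensity contour: single supra-threshold node")
  xs <- .map_node_x(map)
  ys <- .map_node_y(map)
  wgt <- if (weighted) map$grid[keep] else rep(1, sum(keep))
  idx <- which(keep, arr.ind = TRUE)
  cdc_x <- sum(xs[idx[, 2]] * wgt) / sum(wgt)
  cdc_y <- sum(ys[idx[, 1]] * wgt) / sum(wgt)
  cdc_density <- interp_grid(map$grid, cdc_x - map$origin_um["x"],
                             cdc_y - map$origin_um["y"],
                             map$grid_step_um, map$grid_step_um)
  structure(list(pcd = pk$pcd, pcd_location_um = pk$location_um,
                 cdc_location_um = c(x = cdc_x, y = cdc_y),
                 cdc_density = unname(cdc_density),
                 contour_mask = keep, threshold = threshold,
                 fraction = fraction,
                 participant_id = map$participant_id),
            class = "density_metrics")
}

#' @export
print.density_metrics <- function(x, ...) {
  cat(sprintf(
    "<density_metrics> PCD %.0f at (%.1f, %.1f) um; CDC (%.1f, %.1f) um, density %.0f\n",
    x$pcd, x$pcd_location_um["x"], x$pcd_location_um["y"],
    x$cdc_location_um["x"], x$cdc_location_um["y"], x$cdc_density))
  invisible(x)
}

#' Areal foveal cone density over the cohort-common region
#'
#' Aligns all density maps at their CDC and finds the largest half-width `h`
#' such that every map still covers `[CDC - h, CDC + h]` along both axes (the
#' common square). For each map, density is sampled by bilinear interpolation
#' along the horizontal row through the CDC over `[CDC_x - h, CDC_x + h]` at
#' the map's grid step and averaged.
#'
#' @param maps list of [density_map()] objects (one per participant).
#' @param metrics optional list of matching [cdc()] results; computed when
#'   omitted.
#' @param fraction passed to [cdc()] when metrics are computed here.
#' @return list with `common_width_um` (2h), `common_halfwidth_um` (h) and a
#'   data frame `areal` with `participant_id` and `areal_density` (cones/mm^2).
#' @export
areal_foveal_density <- function(maps, metrics = NULL, fraction = 0.8) {
  if (inherits(maps, "density_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1, all(vapply(maps, inherits, TRUE, "density_map")))
  if (is.null(metrics)) metrics <- lapply(maps, cdc, fraction = fraction)
  margins <- mapply(function(map, met) {
    xs <- .map_node_x(map); ys <- .map_node_y(map)
    cx <- met$cdc_location_um["x"]; cy <- met$cdc_location_um["y"]
    min(cx - xs[1], xs[length(xs)] - cx, cy - ys[1], ys[length(ys)] - cy)
  }, maps, metrics)
  if (any(margins <= 0))
    stop_fovea("CDC on the grid edge for participant(s): %s",
               paste(vapply(maps[margins <= 0],
                            function(m) as.character(m$participant_id),
                            ""), collapse = ", "))
  h <- min(margins)
  areal <- mapply(function(map, met) {
    cx <- met$cdc_location_um["x"]; cy <- met$cdc_location_um["y"]
    xq <- seq(cx - h, cx + h, by = map$grid_step_um)
    if (xq[length(xq)] < cx + h - 1e-9) xq <- c(xq, cx + h)
    vals <- interp_grid(map$grid, xq - map$origin_um["x"],
                        cy - map$origin_um["y"],
                        map$grid_step_um, map$grid_step_um)
    mean(vals)
  }, maps, metrics)
  list(common_width_um = 2 * h, common_halfwidth_um = h,
       areal = data.frame(
         participant_id = vapply(maps, function(m)
           as.character(m$participant_id), ""),
         areal_density = unname(areal)))
}
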