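
#' Construct a retinal thickness map
#'
#' Gridded ILM-RPE thickness in micrometres, with per-axis lateral sampling
#' (the source volumes are anisotropic: nominally 512 x 128 samples over a
#' 6 x 6 mm corrected extent). The top-left pixel center is the physical
#' origin; x increases along columns, y along rows.
#'
#' @param grid numeric matrix of thickness values (micrometres), all > 0.
#' @param x_um_per_px,y_um_per_px lateral sampling along columns / rows.
#' @param participant_id optional label.
#' @return object of class `thickness_map`.
#' @export
thickness_map <- function(grid, x_um_per_px, y_um_per_px,
                          participant_id = NA_character_) {
  grid <- as.matrix(grid)
  check_positive(x_um_per_px, "x_um_per_px")
  check_positive(y_um_per_px, "y_um_per_px")
  if (anyNA(grid) || any(grid <= 0))
    stop_fovea("thickness map must be strictly positive and complete")
  structure(list(grid = grid, x_um_per_px = x_um_per_px,
                 y_um_per_px = y_um_per_px, participant_id = participant_id),
            class = "thickness_map")
}

.map_extent_um <- function(map)
  c(x = (ncol(map$grid) - 1) * map$x_um_per_px,
    y = (nrow(map$grid) - 1) * map$y_um_per_px)

#' Locate the foveal pit center on a thickness map
#'
#' Minimum thickness within `search_radius_um` of the map's geometric center,
#' after light box smoothing (the pit bottom is locally flat, so a raw pixel
#' minimum wanders under measurement noise), refined to sub-pixel precision by
#' a separable quadratic fit around the minimum. Ties resolve to the candidate
#' nearest the geometric center.
#'
#' @param map a [thickness_map()].
#' @param search_radius_um search radius around the geometric center
#'   (default 750).
#' @param smooth_halfwidth_um half-width of the presmoothing box per axis,
#'   micrometres (default 50; 0 disables smoothing).
#' @return named vector `c(x, y)` in micrometres.
#' @export
find_pit_center <- function(map, search_radius_um = 750,
                            smooth_halfwidth_um = 50) {
  stopifnot(inherits(map, "thickness_map"))
  if (smooth_halfwidth_um > 0)
    map <- thickness_map(pmax(box_smooth(map$grid,
                                         round(smooth_halfwidth_um /
                                                 map$x_um_per_px),
                                         round(smooth_halfwidth_um /
                                                 map$y_um_per_px)),
                              .Machine$double.eps),
                         map$x_um_per_px, map$y_um_per_px,
                         map$participant_id)
  ext <- .map_extent_um(map)
  gc <- ext / 2
  xs <- (seq_len(ncol(map$grid)) - 1) * map$x_um_per_px
  ys <- (seq_len(nrow(map$grid)) - 1) * map$y_um_per_px
  d2 <- outer((ys - gc["y"])^2, (xs - gc["x"])^2, `+`)
  inside <- d2 <= search_radius_um^2
  if (!any(inside)) stop_fovea("search region lies outside the map")
  vals <- map$grid
  vals[!inside] <- Inf
  mn <- min(vals)
  tie <- which(vals <= mn + 1e-9, arr.ind = TRUE)
  if (nrow(tie) > 0.05 * sum(inside))
    warn_fovea("thickness map is (near-)flat over the search region")
  best <- tie[order(d2[tie]), , drop = FALSE][1, ]
  r <- best[1]; c <- best[2]
  # warn when the minimum sits on the search boundary
  ring <- sqrt(d2[r, c]) > search_radius_um - max(map$x_um_per_px,
                                                  map$y_um_per_px)
  if (ring) warn_fovea("pit minimum on the search boundary (decentered map?)")
  x <- xs[c]; y <- ys[r]
  if (c > 1 && c < ncol(vals) && all(is.finite(map$grid[r, c + c(-1, 1)]))) {
    q <- quadratic_refine(map$grid[r, c - 1], map$grid[r, c],
                          map$grid[r, c + 1])
    x <- x + q$offset * map$x_um_per_px
  }
  if (r > 1 && r < nrow(vals)) {
    q <- quadratic_refine(map$grid[r - 1, c], map$grid[r, c],
                          map$grid[r + 1, c])
    y <- y + q$offset * map$y_um_per_px
  }
  c(x = unname(x), y = unname(y))
}

#' Radial thickness profiles around the pit center
#'
#' Samples the map by bilinear interpolation along `n_angles` equally spaced
#' rays in physical micrometre coordinates (per-axis pixel scales handle the
#' grid anisotropy). Radii beyond the map bounds are `NA`.
#'
#' @param map a [thickness_map()].
#' @param center pit center `c(x, y)` in micrometres.
#' @param n_angles number of rays over `[0, 2*pi)` (default 180, must be even
#'   for diameter pairing).
#' @param radial_step_um radial sampling step (default 10).
#' @param max_radius_um maximum radius (default 3000).
#' @return list with `angles` (radians), `radii_um` and `values` (matrix,
#'   rows = angles, cols = radii).
#' @export
radial_profiles <- function(map, center, n_angles = 180, radial_step_um = 10,
                            max_radius_um = 3000) {
  stopifnot(inherits(map, "thickness_map"), n_angles >= 4)
  angles <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  radii <- seq(0, max_radius_um, by = radial_step_um)
  xq <- outer(cos(angles), radii) + center["x"]
  yq <- outer(sin(angles), radii) + center["y"]
  vals <- interp_grid(map$grid, as.vector(xq), as.vector(yq),
                      map$x_um_per_px, map$y_um_per_px)
  list(angles = angles, radii_um = radii,
       values = matrix(vals, n_angles, length(radii)))
}

#' Detect the pit rim on a radial thickness profile
#'
#' After moving-average smoothing, the rim is the first local maximum (moving
#' outward from the center) whose topographic prominence reaches
#' `prominence_um`; when none exists the global maximum is used and flagged.
#' Radius and height are refined by a quadratic fit around the peak.
#'
#' @param values thickness along one ray (micrometres), `NA` beyond the map.
#' @param radii_um radial positions matching `values`.
#' @param smooth_halfwidth half-width of the moving-average window, in samples
#'   (default 2).
#' @param prominence_um minimum peak prominence (default 2).
#' @return list `rim_radius_um`, `rim_height_um`, `fallback` (TRUE when the
#'   global-maximum fallback was used).
#' @export
detect_rim <- function(values, radii_um, smooth_halfwidth = 2,
                       prominence_um = 2) {
  ok <- is.finite(values)
  if (sum(ok) < 5) stop_fovea("radial profile has fewer than 5 valid samples")
  v <- values[ok]
  r <- radii_um[ok]
  s <- moving_average(v, smooth_halfwidth)
  peaks <- local_maxima(s)
  peaks <- peaks[peaks > 1]
  k <- NA_integer_
  for (p in peaks) {
    if (peak_prominence(s, p) >= prominence_um) { k <- p; break }
  }
  fallback <- is.na(k)
  if (fallback) k <- which.max(s)
  if (k > 1 && k < length(s)) {
    q <- quadratic_refine(s[k - 1], s[k], s[k + 1])
    step <- r[min(k + 1, length(r))] - r[k]
    list(rim_radius_um = r[k] + q$offset * step, rim_height_um = q$value,
         fallback = fallback)
  } else {
    list(rim_radius_um = r[k], rim_height_um = s[k], fallback = TRUE)
  }
}

# rim detection on every ray; returns data.frame(angle, radius, height, valid)
pit_rims <- function(profiles, smooth_halfwidth = 2, prominence_um = 2) {
  n <- length(profiles$angles)
  out <- data.frame(angle = profiles$angles,
                    rim_radius_um = NA_real_, rim_height_um = NA_real_,
                    valid = FALSE, fallback = FALSE)
  for (i in seq_len(n)) {
    res <- tryCatch(detect_rim(profiles$values[i, ], profiles$radii_um,
                               smooth_halfwidth, prominence_um),
                    error = function(e) NULL)
    if (!is.null(res)) {
      out$rim_radius_um[i] <- res$rim_radius_um
      out$rim_height_um[i] <- res$rim_height_um
      out$valid[i] <- TRUE
      out$fallback[i] <- res$fallback
    }
  }
  out
}

#' Foveal pit diameter from per-angle rim radii
#'
#' Mean rim-to-rim extent: the average over opposed ray pairs of
#' `rim_radius(theta) + rim_radius(theta + pi)`, in millimetres. Pairs with a
#' missing rim on either side are excluded.
#'
#' @param rims data frame from the rim-detection stage (angles equally spaced
#'   over `[0, 2*pi)`, even count).
#' @return list `diameter_mm`, `n_valid_pairs`, `n_excluded_pairs`.
#' @export
pit_diameter <- function(rims) {
  n <- nrow(rims)
  if (n %% 2 != 0) stop_fovea("diameter pairing requires an even angle count")
  half <- n / 2
  r1 <- rims$rim_radius_um[seq_len(half)]
  r2 <- rims$rim_radius_um[seq_len(half) + half]
  ok <- rims$valid[seq_len(half)] & rims$valid[seq_len(half) + half] &
    is.finite(r1) & is.finite(r2)
  if (sum(ok) < 2) stop_fovea("fewer than 2 valid opposed rim pairs")
  list(diameter_mm = mean(r1[ok] + r2[ok]) / 1000,
       n_valid_pairs = sum(ok), n_excluded_pairs = sum(!ok))
}

#' Foveal pit volume under the rim surface
#'
#' Integrates `max(0, rim_height(theta) - thickness)` over all map pixels
#' inside the rim (pixel radius less than the periodically interpolated rim
#' radius at the pixel's angle), in cubic millimetres. Pixels above the rim
#' surface contribute nothing, so the volume is non-negative by construction.
#'
#' @param map a [thickness_map()].
#' @param center pit center `c(x, y)` in micrometres.
#' @param rims per-angle rim table (see [pit_diameter()]).
#' @return volume in mm^3.
#' @export
pit_volume <- function(map, center, rims) {
  stopifnot(inherits(map, "thickness_map"))
  ok <- rims$valid & is.finite(rims$rim_radius_um)
  if (sum(ok) < 3) stop_fovea("too few valid rim angles for volume")
  ang <- rims$angle[ok]
  rr <- rims$rim_radius_um[ok]
  hh <- rims$rim_height_um[ok]
  # periodic linear interpolation over angle
  ang2 <- c(ang, ang[1] + 2 * pi)
  rr2 <- c(rr, rr[1])
  hh2 <- c(hh, hh[1])
  xs <- (seq_len(ncol(map$grid)) - 1) * map$x_um_per_px - center["x"]
  ys <- (seq_len(nrow(map$grid)) - 1) * map$y_um_per_px - center["y"]
  dx <- matrix(xs, nrow(map$grid), ncol(map$grid), byrow = TRUE)
  dy <- matrix(ys, nrow(map$grid), ncol(map$grid))
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) %% (2 * pi)
  theta <- pmin(pmax(theta, ang2[1]), ang2[length(ang2)])
  rim_r <- approx(ang2, rr2, xout = theta)$y
  rim_h <- approx(ang2, hh2, xout = theta)$y
  inside <- r < rim_r
  depth_um <- pmax(0, rim_h - map$grid)
  sum(depth_um[inside]) * 1e-3 * (map$x_um_per_px * map$y_um_per_px) * 1e-6
}

#' Foveal pit diameter, volume and depth from a thickness map
#'
#' Composition of the radial rim-detection pipeline: locate the pit center,
#' sample radial profiles, detect the rim on each ray, then compute the mean
#' rim-to-rim diameter, the rim-capped volume integral, and the pit depth
#' (mean rim height minus thickness at the center).
#'
#' @inheritParams radial_profiles
#' @inheritParams detect_rim
#' @param search_radius_um passed to [find_pit_center()].
#' @return object of class `pit_metrics`: `center_um`, `rims`, `diameter_mm`,
#'   `volume_mm3`, `depth_um`, `n_valid_angles`.
#' @export
pit_metrics <- function(map, n_angles = 180, radial_step_um = 10,
                        max_radius_um = 3000, smooth_halfwidth = 2,
                        prominence_um = 2, search_radius_um = 750) {
  center <- find_pit_center(map, search_radius_um)
  prof <- radial_profiles(map, center, n_angles, radial_step_um,
                          max_radius_um)
  rims <- pit_rims(prof, smooth_halfwidth, prominence_um)
  dia <- pit_diameter(rims)
  vol <- pit_volume(map, center, rims)
  t_center <- interp_grid(map$grid, center["x"], center["y"],
                          map$x_um_per_px, map$y_um_per_px)
  structure(list(center_um = center, rims = rims,
                 diameter_mm = dia$diameter_mm,
                 volume_mm3 = vol,
                 depth_um = mean(rims$rim_height_um[rims$valid]) -
                   unname(t_center),
                 n_valid_angles = sum(rims$valid),
                 participant_id = map$participant_id),
            class = "pit_metrics")
}

#' @export
print.pit_metrics <- function(x, ...) {
  cat(sprintf(
    "<pit_metrics> diameter %.2f mm, volume %.3f mm^3, depth %.0f um (%d/%d rays)\n",
    x$diameter_mm, x$volume_mm3, x$depth_um, x$n_valid_angles, nrow(x$rims)))
  invisible(x)
}
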