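
# evaluate code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Dart throwing undershoots the nominal density because random sequential
# packing saturates below the hexagonal-lattice density implied by the local
# spacing. The proposal density is inflated by this factor (measured once on
# uniform fields at the default inhibition of 0.8) so realized density tracks
# the requested one.
.dart_density_compensation <- 1.111

#' Synthetic foveal cone mosaic with known density profile
#'
#' Places cones by variable-radius dart throwing: uniform candidate positions
#' are accepted when no prior cone lies within `inhibition` times the local
#' hexagonal-lattice pitch `s = sqrt(2 / (sqrt(3) D))` of the target density
#' `D(x, y) = base + (peak - base) exp(-|r - r_peak|^2 / (2 sigma^2))`.
#' Proposals continue until 200 times the expected count of cumulative
#' rejections, i.e. effectively to packing saturation. The generator verifies
#' its own output: the realized density in a 50-micrometre window at the true
#' peak must be within 10% of `peak_density`.
#'
#' @param peak_density cones/mm^2 at the profile maximum (default 2e5).
#' @param base_density cones/mm^2 far from the peak (default 5e4).
#' @param sigma_um Gaussian fall-off scale (default 100).
#' @param peak_offset_um `c(x, y)` displacement of the true peak from the ROI
#'   center (default none).
#' @param roi_width_um,roi_height_um ROI extent (default 300 x 300).
#' @param inhibition spacing inhibition factor (default 0.8).
#' @param participant_id optional label.
#' @param seed RNG seed (the generator is seed-deterministic).
#' @return list with `mosaic` (a [cone_mosaic()]) and `truth`: the model
#'   parameters, the true peak location (`peak_um`), and `density_fun(x, y)`
#'   returning the target density (cones/mm^2).
#' @export
synth_mosaic <- function(peak_density = 2e5, base_density = 5e4,
                         sigma_um = 100, peak_offset_um = c(0, 0),
                         roi_width_um = 300, roi_height_um = 300,
                         inhibition = 0.8, participant_id = NA_character_,
                         seed = NULL) {
  stopifnot(peak_density > base_density, base_density >= 0, sigma_um > 0)
  cx <- roi_width_um / 2 + peak_offset_um[1]
  cy <- roi_height_um / 2 + peak_offset_um[2]
  # densities in cones/um^2 for the sampler, inflated for packing shortfall
  comp <- .dart_density_compensation
  peak_c <- peak_density * 1e-6 * comp
  base_c <- base_density * 1e-6 * comp
  s_min <- sqrt(2 / (sqrt(3) * peak_c))
  if (inhibition * s_min < 1)
    stop_fovea("infeasible model: minimal spacing below 1 um")
  dens_fun <- function(x, y)
    base_density + (peak_density - base_density) *
      exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma_um^2))
  # expected count from the target density integrated over the ROI
  nx <- 60
  gx <- seq(0, roi_width_um, length.out = nx)
  gy <- seq(0, roi_height_um, length.out = nx)
  mean_d <- mean(outer(gy, gx, function(y, x) dens_fun(x, y)))
  expected <- mean_d * 1e-6 * roi_width_um * roi_height_um
  pts <- with_seed(seed, cpp_dart_throw(roi_width_um, roi_height_um,
                                        peak_c, base_c, sigma_um, cx, cy,
                                        inhibition, 200 * expected))
  mosaic <- cone_mosaic(pts, roi_width_um, roi_height_um, participant_id,
                        min_separation_um = 0)
  # self-check: realized density in a 50 um window at the true peak
  w <- 50
  n_in <- sum(pts[, 1] >= cx - w / 2 & pts[, 1] < cx + w / 2 &
              pts[, 2] >= cy - w / 2 & pts[, 2] < cy + w / 2)
  realized <- n_in / (w / 1000)^2
  if (abs(realized - peak_density) > 0.10 * peak_density)
    stop_fovea("generator self-check failed: realized peak density %.0f vs target %.0f",
               realized, peak_density)
  list(mosaic = mosaic,
       truth = list(peak_density = peak_density, base_density = base_density,
                    sigma_um = sigma_um, peak_um = c(x = cx, y = cy),
                    realized_peak_density = realized,
                    density_fun = dens_fun))
}

#' Synthetic directional-OCT boundary segmentation with analytic ONL profile
#'
#' Builds five ordered boundaries from an analytic layered model whose ONL
#' thickness is `ONL(e) = base + (peak - base) exp(-e^2 / (2 sigma^2))`
#' (e = eccentricity from the foveal center, micrometres) and whose total
#' retinal thickness has a Gaussian pit, then samples `knot_count` evenly
#' spaced knots per boundary, optionally with Gaussian z noise. Noisy knots
#' are clipped to preserve the depth ordering of the boundaries.
#'
#' @param onl_base_um,onl_peak_um,onl_sigma_um ONL profile parameters
#'   (defaults 60, 100, 600).
#' @param t_center_um,t_rim_um,pit_sigma_um total retinal thickness at the
#'   foveal center / away from it, and the pit's Gaussian scale (defaults
#'   220, 320, 400).
#' @param elm_rpe_um ELM-to-RPE offset (default 15).
#' @param hfl_um OPL/HFL to HFL/ONL offset (default 30).
#' @param scan_width_um lateral scan extent (default 6000).
#' @param center_offset_um pit center displacement from the scan middle
#'   (default 0).
#' @param axial_um_per_px,lateral_um_per_px pixel scales (defaults 1.95, 6).
#' @param rpe_z_px RPE depth in pixels (default 400).
#' @param knot_count segmentation points per boundary (default 30).
#' @param z_noise_px Gaussian sd of knot depth noise, pixels (default 0).
#' @param seed RNG seed.
#' @return list with `seg` (a [boundary_segmentation()]) and `truth`:
#'   `center_x_um`, `onl_fun(ecc_um)`, `max_onl_um`, and
#'   `central_onl_fun(width_um)` giving the analytic mean ONL over a centered
#'   interval.
#' @export
synth_segmentation <- function(onl_base_um = 60, onl_peak_um = 100,
                               onl_sigma_um = 600, t_center_um = 220,
                               t_rim_um = 320, pit_sigma_um = 400,
                               elm_rpe_um = 15, hfl_um = 30,
                               scan_width_um = 6000, center_offset_um = 0,
                               axial_um_per_px = 1.95, lateral_um_per_px = 6,
                               rpe_z_px = 400, knot_count = 30,
                               z_noise_px = 0, seed = NULL) {
  stopifnot(onl_peak_um >= onl_base_um, onl_base_um > 0,
            t_rim_um > t_center_um, knot_count >= 2)
  center <- scan_width_um / 2 + center_offset_um
  onl_fun <- function(e)
    onl_base_um + (onl_peak_um - onl_base_um) * exp(-e^2 / (2 * onl_sigma_um^2))
  thick_fun <- function(e)
    t_rim_um - (t_rim_um - t_center_um) * exp(-e^2 / (2 * pit_sigma_um^2))
  # inner retina must not collapse: ILM above OPL/HFL everywhere
  ecc_chk <- seq(-scan_width_um, scan_width_um, by = 10)
  if (any(thick_fun(ecc_chk) < onl_fun(ecc_chk) + elm_rpe_um + hfl_um + 5))
    stop_fovea("layer model infeasible: retinal thickness thinner than outer layers")
  # knots evenly spaced across the scan, anchored so one knot sits exactly at
  # the scan center (graders anchor a point at the foveal center); spacing is
  # scan_width / knot_count so the span stays inside the scan
  spacing <- scan_width_um / knot_count
  offs <- (seq_len(knot_count) - 1 - floor((knot_count - 1) / 2)) * spacing
  x_px <- (scan_width_um / 2 + offs) / lateral_um_per_px
  ecc <- x_px * lateral_um_per_px - center
  z <- list(
    ILM = rpe_z_px - thick_fun(ecc) / axial_um_per_px,
    OPL_HFL = rpe_z_px - (elm_rpe_um + onl_fun(ecc) + hfl_um) / axial_um_per_px,
    HFL_ONL = rpe_z_px - (elm_rpe_um + onl_fun(ecc)) / axial_um_per_px,
    ELM = rpe_z_px - elm_rpe_um / axial_um_per_px,
    RPE = rep(rpe_z_px, knot_count))
  z$ELM <- rep(z$ELM, length.out = knot_count)
  if (z_noise_px > 0) {
    z <- with_seed(seed, lapply(z, function(v)
      v + rnorm(knot_count, 0, z_noise_px)))
    # restore depth ordering where noise inverted adjacent boundaries
    for (i in 2:5)
      z[[i]] <- pmax(z[[i]], z[[i - 1]] + 0.05)
  }
  boundaries <- lapply(z, function(v) cbind(x_px = x_px, z_px = v))
  seg <- boundary_segmentation(boundaries, axial_um_per_px, lateral_um_per_px)
  central_onl_fun <- function(width_um) {
    h <- width_um / 2
    integrate(onl_fun, -h, h, rel.tol = 1e-10)$value / width_um
  }
  list(seg = seg,
       truth = list(center_x_um = center, onl_fun = onl_fun,
                    max_onl_um = onl_peak_um,
                    central_onl_fun = central_onl_fun,
                    thick_fun = thick_fun))
}

# analytic pit surface; onset of the outer quadratic fall-off sits inside the
# rim so the profile has a true local maximum that can be placed exactly
.pit_surface <- function(r, t_center, t_rim, r0, slope, onset)
  t_rim - (t_rim - t_center) * exp(-(r / r0)^2) -
    slope * pmax(0, r - onset)^2

# dense 1-D search for the rim (argmax) of the analytic profile
.pit_rim_search <- function(t_center, t_rim, r0, slope, onset, r_max) {
  r <- seq(0, r_max, by = 0.25)
  v <- .pit_surface(r, t_center, t_rim, r0, slope, onset)
  r[which.max(v)]
}

#' Synthetic retinal thickness map with an analytically known pit
#'
#' Radially symmetric surface
#' `T(r) = t_rim - (t_rim - t_center) exp(-(r/r0)^2) - slope * max(0, r - onset)^2`
#' sampled on an anisotropic grid. The Gaussian scale `r0` is solved
#' numerically so that the densely located rim (profile maximum) sits at
#' `rim_radius_um`. Ground truth (rim radius, rim height, and the rim-capped
#' pit volume by fine polar quadrature) is returned alongside.
#'
#' @param t_center_um,t_rim_um thickness at the pit center / rim (defaults
#'   220, 330).
#' @param rim_radius_um target rim radius (default 950).
#' @param outer_slope quadratic fall-off beyond the rim, micrometres of
#'   thickness per square micrometre (default 1e-5).
#' @param onset_fraction where the outer fall-off begins, as a fraction of
#'   `rim_radius_um` (default 0.7).
#' @param n_x,n_y grid samples (defaults 512, 128).
#' @param extent_um physical map extent per axis (default 6000).
#' @param center_offset_um pit center `c(x, y)` displacement from the map
#'   center (default none).
#' @param noise_sd_um Gaussian pixel noise (default 0).
#' @param seed RNG seed.
#' @return list with `map` (a [thickness_map()]) and `truth`: `center_um`,
#'   `rim_radius_um` (numerically located), `rim_height_um`,
#'   `volume_mm3` (fine quadrature), `diameter_mm`, `profile_fun(r)`.
#' @export
synth_thickness_map <- function(t_center_um = 220, t_rim_um = 330,
                                rim_radius_um = 950, outer_slope = 1e-5,
                                onset_fraction = 0.7, n_x = 512, n_y = 128,
                                extent_um = 6000, center_offset_um = c(0, 0),
                                noise_sd_um = 0, seed = NULL) {
  stopifnot(t_rim_um > t_center_um, t_center_um > 0, rim_radius_um > 0)
  onset <- onset_fraction * rim_radius_um
  r_max <- 2.5 * rim_radius_um
  g <- function(r0) .pit_rim_search(t_center_um, t_rim_um, r0, outer_slope,
                                    onset, r_max) - rim_radius_um
  r0 <- uniroot(g, c(0.05 * rim_radius_um, 2.5 * rim_radius_um),
                tol = 1e-3)$root
  profile_fun <- function(r) .pit_surface(r, t_center_um, t_rim_um, r0,
                                          outer_slope, onset)
  rim_r <- .pit_rim_search(t_center_um, t_rim_um, r0, outer_slope, onset,
                           r_max)
  rim_h <- profile_fun(rim_r)
  # rim-capped volume by fine radial quadrature (radially symmetric)
  rq <- seq(0, rim_r, length.out = 20001)
  vol <- 2 * pi * pracma::trapz(rq, rq * pmax(0, rim_h - profile_fun(rq))) * 1e-9
  sx <- extent_um / n_x
  sy <- extent_um / n_y
  cx <- (n_x - 1) / 2 * sx + center_offset_um[1]
  cy <- (n_y - 1) / 2 * sy + center_offset_um[2]
  xs <- (seq_len(n_x) - 1) * sx
  ys <- (seq_len(n_y) - 1) * sy
  r <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  grid <- profile_fun(r)
  if (noise_sd_um > 0)
    grid <- grid + with_seed(seed, matrix(rnorm(length(grid), 0, noise_sd_um),
                                          nrow(grid), ncol(grid)))
  grid <- pmax(grid, 1)
  list(map = thickness_map(grid, sx, sy),
       truth = list(center_um = c(x = cx, y = cy), rim_radius_um = rim_r,
                    rim_height_um = rim_h, volume_mm3 = vol,
                    diameter_mm = 2 * rim_r / 1000, r0_um = r0,
                    profile_fun = profile_fun))
}

# plus-shaped binary dilation by n pixels
.dilate_plus <- function(m, n) {
  for (i in seq_len(n)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
    m <- m | up | dn | lf | rt
  }
  m
}

#' Synthetic vessel mask with a known enclosed avascular area
#'
#' Draws a capillary bed as the Voronoi-cell walls of Poisson-sampled seed
#' points surrounding a circular foveal avascular zone of radius
#' `faz_radius_um`, with the FAZ boundary itself a closed vessel loop.
#' Optionally a vertical capillary traverses the FAZ, splitting it into two
#' fragments with approximately the requested area proportions. The true
#' pixel-counted enclosed area(s) of the final mask are returned.
#'
#' @param faz_radius_um radius of the circular avascular zone (default 300).
#' @param capillary_spacing_um typical seed spacing of the surrounding bed
#'   (default 150).
#' @param vessel_width_px capillary wall width in pixels (default 2).
#' @param split_proportions `NULL` (intact FAZ) or two proportions summing to
#'   1 (e.g. `c(0.6, 0.4)`) for a traversing capillary.
#' @param n_px image side in pixels (default 304).
#' @param um_per_px isotropic scale (default 9.868, a 3 x 3 mm scan at 304
#'   samples).
#' @param seed RNG seed.
#' @return list with `vm` (a [vessel_mask()]) and `truth`: `faz_area_mm2`
#'   (largest enclosed fragment), `total_enclosed_mm2`, `fragment_areas_mm2`,
#'   `fragmented`.
#' @export
synth_vessel_mask <- function(faz_radius_um = 300, capillary_spacing_um = 150,
                              vessel_width_px = 2, split_proportions = NULL,
                              n_px = 304, um_per_px = 9.868, seed = NULL) {
  stopifnot(faz_radius_um > 0, capillary_spacing_um > 0, vessel_width_px >= 1)
  if (!is.null(split_proportions))
    stopifnot(length(split_proportions) == 2,
              abs(sum(split_proportions) - 1) < 1e-9)
  ext <- (n_px - 1) * um_per_px
  cx <- ext / 2; cy <- ext / 2
  xs <- (seq_len(n_px) - 1) * um_per_px
  px_x <- matrix(xs, n_px, n_px, byrow = TRUE)
  px_y <- matrix(xs, n_px, n_px)
  r2 <- (px_x - cx)^2 + (px_y - cy)^2
  res <- with_seed(seed, {
    margin <- capillary_spacing_um / 2
    n_seeds <- max(8, round((ext^2 - pi * faz_radius_um^2) /
                              capillary_spacing_um^2))
    sx <- numeric(0); sy <- numeric(0)
    while (length(sx) < n_seeds) {
      m <- 2 * n_seeds
      candx <- runif(m, 0, ext); candy <- runif(m, 0, ext)
      keep <- (candx - cx)^2 + (candy - cy)^2 > (faz_radius_um + margin)^2
      sx <- c(sx, candx[keep]); sy <- c(sy, candy[keep])
    }
    list(sx = sx[seq_len(n_seeds)], sy = sy[seq_len(n_seeds)])
  })
  # nearest-seed label per pixel (running minimum over seeds)
  best_d <- matrix(Inf, n_px, n_px)
  lab <- matrix(0L, n_px, n_px)
  for (i in seq_along(res$sx)) {
    d <- (px_x - res$sx[i])^2 + (px_y - res$sy[i])^2
    closer <- d < best_d
    best_d[closer] <- d[closer]
    lab[closer] <- i
  }
  lab[r2 <= faz_radius_um^2] <- 0L  # FAZ interior is its own cell
  # walls between different cells
  vess <- matrix(FALSE, n_px, n_px)
  vess[, -n_px] <- vess[, -n_px] | (lab[, -n_px] != lab[, -1])
  vess[-n_px, ] <- vess[-n_px, ] | (lab[-n_px, ] != lab[-1, ])
  vess <- .dilate_plus(vess, vessel_width_px - 1)
  # the FAZ boundary loop grows outward only: the enclosed open area is the
  # full pixel-counted disk of radius faz_radius_um
  ring_w <- vessel_width_px * um_per_px
  vess[r2 >= faz_radius_um^2 & r2 < (faz_radius_um + ring_w)^2] <- TRUE
  vess[r2 < faz_radius_um^2] <- FALSE
  faz_px <- lab == 0L & !vess
  if (!is.null(split_proportions)) {
    col_counts <- colSums(faz_px)
    cum <- cumsum(col_counts) / sum(col_counts)
    c_star <- which(cum >= split_proportions[1])[1]
    rows_in <- r2[, c_star] <= (faz_radius_um + 2 * um_per_px)^2
    cols <- c_star:min(n_px, c_star + vessel_width_px - 1)
    vess[rows_in, cols] <- TRUE
    faz_px <- lab == 0L & !vess
    left <- sum(faz_px[, seq_len(c_star - 1)])
    right <- sum(faz_px[, -(seq_len(max(cols)))])
    frag <- sort(c(left, right), decreasing = TRUE) * (um_per_px / 1000)^2
  } else {
    frag <- sum(faz_px) * (um_per_px / 1000)^2
  }
  vm <- vessel_mask(vess, um_per_px)
  list(vm = vm,
       truth = list(faz_area_mm2 = frag[1],
                    total_enclosed_mm2 = sum(faz_px) * (um_per_px / 1000)^2,
                    fragment_areas_mm2 = frag,
                    fragmented = !is.null(split_proportions),
                    faz_radius_um = faz_radius_um))
}

#' Synthetic grayscale angiogram from a vessel mask
#'
#' Assigns distinct intensity levels to vessel and background pixels and adds
#' Gaussian noise, for exercising the binarization stage.
#'
#' @param vm a [vessel_mask()].
#' @param vessel_intensity,background_intensity mean levels (defaults 200, 20).
#' @param noise_sd Gaussian noise sd (default 0).
#' @param seed RNG seed.
#' @return numeric matrix.
#' @export
synth_angiogram <- function(vm, vessel_intensity = 200,
                            background_intensity = 20, noise_sd = 0,
                            seed = NULL) {
  stopifnot(inherits(vm, "vessel_mask"))
  img <- matrix(background_intensity, nrow(vm$mask), ncol(vm$mask))
  img[vm$mask] <- vessel_intensity
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(rnorm(length(img), 0, noise_sd),
                                        nrow(img), ncol(img)))
  img
}

#' Default cohort metric margins
#'
#' Scaled-Beta marginal specifications (minimum, median, maximum and a
#' concentration parameter) for each cohort metric, calibrated to the ranges
#' reported for healthy adult foveae.
#'
#' @return named list of margin specifications.
#' @export
default_cohort_margins <- function() {
  ranges <- list(
    pcd            = c(141067, 191211, 251214),
    cdc_density    = c(135948, 182097, 244368),
    areal_density  = c(116956, 153808, 198577),
    max_onl_um     = c(74.13, 97.63, 131.60),
    central_onl_um = c(74.30, 98.30, 128.37),
    pit_diameter_mm = c(1.48, 1.91, 2.64),
    pit_volume_mm3 = c(0.02, 0.09, 0.19),
    faz_area_mm2   = c(0.04, 0.27, 0.51))
  lapply(ranges, function(v)
    list(min = v[1], median = v[2], max = v[3], concentration = 5))
}

#' Default target Spearman correlation matrix for synthetic cohorts
#'
#' Pairwise rank correlations among the eight cohort metrics, using reported
#' cohort correlations where available and plausible values for pairs of the
#' same modality (e.g. the three cone-density metrics are strongly mutually
#' correlated); repaired to the nearest positive semi-definite correlation
#' matrix if needed.
#'
#' @return 8 x 8 correlation matrix with dimnames.
#' @export
default_target_spearman <- function() {
  m <- c("pcd", "cdc_density", "areal_density", "max_onl_um",
         "central_onl_um", "pit_diameter_mm", "pit_volume_mm3",
         "faz_area_mm2")
  R <- diag(8)
  dimnames(R) <- list(m, m)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("pcd", "cdc_density", 0.90)
  set_r("pcd", "areal_density", 0.85)
  set_r("cdc_density", "areal_density", 0.90)
  set_r("max_onl_um", "central_onl_um", 0.90)
  set_r("max_onl_um", "pcd", 0.23)
  set_r("max_onl_um", "cdc_density", 0.22)
  set_r("max_onl_um", "areal_density", 0.26)
  set_r("central_onl_um", "pcd", 0.25)
  set_r("central_onl_um", "cdc_density", 0.24)
  set_r("central_onl_um", "areal_density", 0.28)
  set_r("pit_diameter_mm", "pcd", -0.54)
  set_r("pit_diameter_mm", "cdc_density", -0.46)
  set_r("pit_diameter_mm", "areal_density", -0.50)
  set_r("pit_volume_mm3", "pcd", -0.39)
  set_r("pit_volume_mm3", "cdc_density", -0.32)
  set_r("pit_volume_mm3", "areal_density", -0.37)
  set_r("pit_diameter_mm", "pit_volume_mm3", 0.65)
  set_r("faz_area_mm2", "pit_diameter_mm", 0.64)
  set_r("faz_area_mm2", "pit_volume_mm3", 0.67)
  set_r("faz_area_mm2", "pcd", -0.35)
  set_r("faz_area_mm2", "cdc_density", -0.30)
  set_r("faz_area_mm2", "areal_density", -0.33)
  set_r("faz_area_mm2", "max_onl_um", -0.05)
  set_r("faz_area_mm2", "central_onl_um", -0.05)
  set_r("pit_diameter_mm", "max_onl_um", -0.10)
  set_r("pit_diameter_mm", "central_onl_um", -0.10)
  set_r("pit_volume_mm3", "max_onl_um", -0.10)
  set_r("pit_volume_mm3", "central_onl_um", -0.10)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 0)
    R <- nearest_psd_correlation(R)
  R
}

# beta shapes with a given median on [0, 1] and total concentration a + b
.beta_shapes <- function(median01, concentration) {
  f <- function(a) suppressWarnings(qbeta(0.5, a, concentration - a)) - median01
  a <- uniroot(f, c(1e-3, concentration - 1e-3), tol = 1e-10)$root
  c(a = a, b = concentration - a)
}

#' Synthetic cohort table by Gaussian copula
#'
#' Draws a multivariate normal sample whose correlation matrix is the target
#' Spearman matrix converted through `rho_pearson = 2 sin(pi rho_s / 6)`,
#' then maps each margin through a scaled-Beta quantile function calibrated
#' to the metric's minimum / median / maximum. Metric values therefore respect
#' the configured bounds exactly, and the sample rank correlations converge to
#' the targets. Adds a fragmented-FAZ flag, age and sex columns.
#'
#' @param n participants (default 68).
#' @param target_spearman target rank-correlation matrix (default
#'   [default_target_spearman()]).
#' @param margins named margin list (default [default_cohort_margins()]).
#' @param fragmented_rate probability of a fragmented FAZ (default 6/68).
#' @param seed RNG seed.
#' @return list with `table` (data frame, one row per participant) and the
#'   `target_spearman` / `margins` actually used.
#' @export
synth_cohort <- function(n = 68, target_spearman = default_target_spearman(),
                         margins = default_cohort_margins(),
                         fragmented_rate = 6 / 68, seed = NULL) {
  stopifnot(n >= 4, nrow(target_spearman) == length(margins))
  metrics <- names(margins)
  pearson <- 2 * sin(pi * target_spearman / 6)
  diag(pearson) <- 1
  ev <- eigen(pearson, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    warn_fovea("converted correlation matrix not PSD; nearest-PSD repair applied")
    pearson <- nearest_psd_correlation(pearson)
  }
  tab <- with_seed(seed, {
    z <- MASS::mvrnorm(n, mu = rep(0, length(metrics)), Sigma = pearson)
    u <- pnorm(z)
    vals <- lapply(seq_along(metrics), function(j) {
      mg <- margins[[j]]
      sh <- .beta_shapes((mg$median - mg$min) / (mg$max - mg$min),
                         mg$concentration)
      mg$min + (mg$max - mg$min) * qbeta(u[, j], sh["a"], sh["b"])
    })
    names(vals) <- metrics
    df <- as.data.frame(vals)
    df$fragmented <- runif(n) < fragmented_rate
    df$age_years <- round(runif(n, 12, 64))
    df$sex <- ifelse(runif(n) < 0.72, "F", "M")
    df
  })
  tab <- cbind(participant_id = sprintf("S%03d", seq_len(n)), tab)
  list(table = tab, target_spearman = target_spearman, margins = margins)
}
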