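
BOUNDARY_NAMES <- c("ILM", "OPL_HFL", "HFL_ONL", "ELM", "RPE")

#' Construct a B-scan image
#'
#' @param pixels numeric matrix of intensities (rows = depth, increasing
#'   downward; cols = lateral position).
#' @param axial_um_per_px depth sampling (micrometres per pixel).
#' @param lateral_um_per_px corrected lateral sampling (micrometres per pixel).
#' @return object of class `bscan_image`.
#' @export
bscan_image <- function(pixels, axial_um_per_px, lateral_um_per_px) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0 || ncol(pixels) == 0) stop_fovea("empty B-scan")
  check_positive(axial_um_per_px, "axial_um_per_px")
  check_positive(lateral_um_per_px, "lateral_um_per_px")
  structure(list(pixels = pixels, axial_um_per_px = axial_um_per_px,
                 lateral_um_per_px = lateral_um_per_px),
            class = "bscan_image")
}

# integer translation with zero fill; shift = c(rows down, cols right)
shift_image <- function(m, shift) {
  out <- matrix(0, nrow(m), ncol(m))
  sr <- shift[1]; sc <- shift[2]
  src_r <- seq_len(nrow(m)) - sr
  src_c <- seq_len(ncol(m)) - sc
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# integer shift of b maximizing cross-correlation with a (FFT, zero-padded)
.best_shift <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  pr <- stats::nextn(2L * nr, c(2, 3, 5))
  pc <- stats::nextn(2L * nc, c(2, 3, 5))
  ap <- matrix(0, pr, pc); bp <- matrix(0, pr, pc)
  ap[1:nr, 1:nc] <- a - mean(a)
  bp[1:nr, 1:nc] <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(ap) * Conj(stats::fft(bp)), inverse = TRUE))
  k <- which.max(cc)
  kr <- (k - 1) %% pr
  kc <- (k - 1) %/% pr
  c(if (kr <= pr / 2) kr else kr - pr,
    if (kc <= pc / 2) kc else kc - pc)
}

#' Align a directional-OCT triad by integer translation
#'
#' Each off-axis B-scan is shifted by the integer 2-D translation that
#' maximizes its cross-correlation with the central (first) scan. The
#' normalized cross-correlation (Pearson correlation of overlapping pixels) at
#' the chosen shift is reported per scan; scans scoring below `ncc_threshold`
#' are flagged as poorly aligned, mirroring the manual quality gate applied to
#' directional-OCT triads before merging.
#'
#' @param scans list of 2 or 3 [bscan_image()] objects with identical
#'   dimensions and scales; the first is the central-pupil-entry reference.
#' @param ncc_threshold flag scans with alignment NCC below this (default 0.5).
#' @return list with `scans` (aligned copies), `shifts` (one row per scan:
#'   rows, cols), `ncc` and `flagged`.
#' @export
align_doct <- function(scans, ncc_threshold = 0.5) {
  stopifnot(length(scans) >= 2, length(scans) <= 3,
            all(vapply(scans, inherits, TRUE, "bscan_image")))
  dims <- vapply(scans, function(s) dim(s$pixels), integer(2))
  if (any(dims != dims[, 1]))
    stop_fovea("all scans must have identical dimensions")
  ref <- scans[[1]]$pixels
  shifts <- matrix(0L, length(scans), 2,
                   dimnames = list(NULL, c("rows", "cols")))
  ncc <- numeric(length(scans))
  out <- scans
  for (i in seq_along(scans)) {
    if (i == 1L) {
      sh <- c(0L, 0L)
    } else {
      sh <- .best_shift(ref, scans[[i]]$pixels)
    }
    shifted <- shift_image(scans[[i]]$pixels, sh)
    # NCC on the overlap region actually covered by the shifted scan
    rr <- max(1, 1 + sh[1]):min(nrow(ref), nrow(ref) + sh[1])
    cc <- max(1, 1 + sh[2]):min(ncol(ref), ncol(ref) + sh[2])
    ncc[i] <- suppressWarnings(cor(as.vector(ref[rr, cc]),
                                   as.vector(shifted[rr, cc])))
    if (is.na(ncc[i])) ncc[i] <- 0
    shifts[i, ] <- sh
    out[[i]] <- bscan_image(shifted, scans[[i]]$axial_um_per_px,
                            scans[[i]]$lateral_um_per_px)
  }
  flagged <- ncc < ncc_threshold
  if (any(flagged))
    warn_fovea("scan(s) %s poorly aligned (NCC < %g)",
               paste(which(flagged), collapse = ", "), ncc_threshold)
  list(scans = out, shifts = shifts, ncc = ncc, flagged = flagged)
}

#' Merge aligned directional-OCT scans by pixelwise maximum
#'
#' Maximum-intensity projection across the aligned triad (or pair), which
#' renders the Henle fiber layer / outer nuclear layer boundary visible
#' regardless of pupil entry position.
#'
#' @param aligned list of 2 or 3 aligned [bscan_image()] objects of identical
#'   dimensions.
#' @return merged [bscan_image()].
#' @export
merge_doct <- function(aligned) {
  if (!is.null(aligned$scans)) aligned <- aligned$scans
  stopifnot(all(vapply(aligned, inherits, TRUE, "bscan_image")))
  if (length(aligned) < 2) stop_fovea("merge requires at least 2 scans")
  dims <- vapply(aligned, function(s) dim(s$pixels), integer(2))
  if (any(dims != dims[, 1]))
    stop_fovea("all scans must have identical dimensions")
  merged <- Reduce(pmax, lapply(aligned, `[[`, "pixels"))
  bscan_image(merged, aligned[[1]]$axial_um_per_px,
              aligned[[1]]$lateral_um_per_px)
}

#' Construct a boundary segmentation
#'
#' Ordered manual segmentation points for up to five retinal boundaries (ILM,
#' OPL/HFL, HFL/ONL, ELM, RPE), nominally 30 points per boundary, with the
#' axial and (axial-length-corrected) lateral pixel scales.
#'
#' @param boundaries named list; each element a two-column matrix or data
#'   frame `(x_px, z_px)` with strictly increasing x. Names must be among
#'   `ILM, OPL_HFL, HFL_ONL, ELM, RPE`.
#' @param axial_um_per_px,lateral_um_per_px pixel scales (micrometres).
#' @return object of class `boundary_segmentation`.
#' @export
boundary_segmentation <- function(boundaries, axial_um_per_px,
                                  lateral_um_per_px) {
  check_positive(axial_um_per_px, "axial_um_per_px")
  check_positive(lateral_um_per_px, "lateral_um_per_px")
  if (is.null(names(boundaries)) ||
      !all(names(boundaries) %in% BOUNDARY_NAMES))
    stop_fovea("boundary names must be among: %s",
               paste(BOUNDARY_NAMES, collapse = ", "))
  boundaries <- lapply(boundaries, function(b) {
    b <- as.matrix(as.data.frame(b)[, 1:2])
    colnames(b) <- c("x_px", "z_px")
    if (nrow(b) < 2) stop_fovea("each boundary needs >= 2 points")
    if (any(diff(b[, 1]) <= 0))
      stop_fovea("boundary x coordinates must be strictly increasing")
    b
  })
  # depth ordering on the common overlap of all present boundaries
  present <- BOUNDARY_NAMES[BOUNDARY_NAMES %in% names(boundaries)]
  if (length(present) >= 2) {
    lo <- max(vapply(boundaries[present], function(b) b[1, 1], 0))
    hi <- min(vapply(boundaries[present], function(b) b[nrow(b), 1], 0))
    if (hi > lo) {
      xq <- seq(lo, hi, length.out = 101)
      z <- vapply(present, function(nm)
        interpolate_boundary(boundaries[[nm]], xq), numeric(101))
      if (any(apply(z, 1, function(r) any(diff(r) < -1e-9))))
        stop_fovea("boundary depth ordering violated (ILM..RPE must be non-decreasing in z)")
    }
  }
  structure(list(boundaries = boundaries, axial_um_per_px = axial_um_per_px,
                 lateral_um_per_px = lateral_um_per_px),
            class = "boundary_segmentation")
}

#' Piecewise-linear interpolation of a segmented boundary
#'
#' Exact at the manual points; queries outside the knot span are an error
#' (manual points bound the trusted region — no extrapolation).
#'
#' @param points two-column matrix `(x, z)` with strictly increasing x.
#' @param x_grid query positions.
#' @return interpolated z at `x_grid`.
#' @export
interpolate_boundary <- function(points, x_grid) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop_fovea("need >= 2 boundary points")
  if (any(diff(points[, 1]) <= 0))
    stop_fovea("boundary x coordinates must be strictly increasing")
  lo <- points[1, 1]; hi <- points[nrow(points), 1]
  if (any(x_grid < lo - 1e-9 | x_grid > hi + 1e-9))
    stop_fovea("query outside boundary span [%g, %g] (no extrapolation)",
               lo, hi)
  approx(points[, 1], points[, 2], xout = pmin(pmax(x_grid, lo), hi),
         method = "linear", ties = "ordered")$y
}

#' Outer nuclear layer thickness profile
#'
#' True ONL thickness is the axial distance between the HFL/ONL boundary and
#' the external limiting membrane, evaluated on the overlap of the two
#' boundaries' lateral spans.
#'
#' @param seg a [boundary_segmentation()] containing `HFL_ONL` and `ELM`.
#' @param x_step_um lateral evaluation step (default 5).
#' @return list with `x_um` (lateral position in scan coordinates) and
#'   `thickness_um`.
#' @export
onl_thickness_profile <- function(seg, x_step_um = 5) {
  stopifnot(inherits(seg, "boundary_segmentation"))
  if (!all(c("HFL_ONL", "ELM") %in% names(seg$boundaries)))
    stop_fovea("segmentation must contain HFL_ONL and ELM boundaries")
  hfl <- seg$boundaries$HFL_ONL
  elm <- seg$boundaries$ELM
  lat <- seg$lateral_um_per_px
  lo_um <- max(hfl[1, 1], elm[1, 1]) * lat
  hi_um <- min(hfl[nrow(hfl), 1], elm[nrow(elm), 1]) * lat
  if (hi_um <= lo_um) stop_fovea("HFL_ONL and ELM spans do not overlap")
  x_um <- seq(lo_um, hi_um, by = x_step_um)
  z_hfl <- interpolate_boundary(hfl, x_um / lat)
  z_elm <- interpolate_boundary(elm, x_um / lat)
  thickness <- (z_elm - z_hfl) * seg$axial_um_per_px
  if (any(thickness < 0))
    stop_fovea("negative ONL thickness (boundary ordering violation) at x = %s um",
               paste(signif(x_um[thickness < 0][1:min(5, sum(thickness < 0))], 5),
                     collapse = ", "))
  list(x_um = x_um, thickness_um = thickness)
}

#' Locate the foveal center on a segmented B-scan
#'
#' The foveal center is taken as the lateral position minimizing total retinal
#' thickness (RPE minus ILM), evaluated on a 1-micrometre grid within a search
#' window centered on the scan middle. Exact ties resolve to the midpoint of
#' the tying interval; a minimum on the window edge raises a warning
#' (possible decentered scan).
#'
#' @param seg a [boundary_segmentation()] containing `ILM` and `RPE`.
#' @param search_halfwidth_um half-width of the central search window
#'   (default 750).
#' @return foveal center x (micrometres, scan coordinates).
#' @export
locate_foveal_center <- function(seg, search_halfwidth_um = 750) {
  stopifnot(inherits(seg, "boundary_segmentation"))
  if (!all(c("ILM", "RPE") %in% names(seg$boundaries)))
    stop_fovea("segmentation must contain ILM and RPE boundaries")
  ilm <- seg$boundaries$ILM
  rpe <- seg$boundaries$RPE
  lat <- seg$lateral_um_per_px
  lo_um <- max(ilm[1, 1], rpe[1, 1]) * lat
  hi_um <- min(ilm[nrow(ilm), 1], rpe[nrow(rpe), 1]) * lat
  mid <- (lo_um + hi_um) / 2
  lo <- max(lo_um, mid - search_halfwidth_um)
  hi <- min(hi_um, mid + search_halfwidth_um)
  x <- seq(lo, hi, by = 1)
  thick <- (interpolate_boundary(rpe, x / lat) -
            interpolate_boundary(ilm, x / lat)) * seg$axial_um_per_px
  mn <- min(thick)
  tie <- which(thick <= mn + 1e-9)
  center <- (x[tie[1]] + x[tie[length(tie)]]) / 2
  if (tie[1] == 1L || tie[length(tie)] == length(x))
    warn_fovea("retinal thickness minimum on the search-window edge (decentered scan?)")
  center
}

#' Maximum and central foveal ONL thickness
#'
#' The maximum is taken over a window around the foveal center; the central
#' value is the trapezoidal mean of the profile over the cohort-common central
#' interval (default full width 227 micrometres, i.e. center +/- 113.5).
#'
#' @param profile result of [onl_thickness_profile()].
#' @param center_x_um foveal center from [locate_foveal_center()].
#' @param central_width_um full width of the central averaging interval
#'   (default 227).
#' @param max_search_halfwidth_um half-width of the max-ONL search window
#'   (default 500).
#' @return list with `max_onl_um`, `max_onl_x_um` (scan coordinates) and
#'   `central_onl_um`.
#' @export
onl_summaries <- function(profile, center_x_um, central_width_um = 227,
                          max_search_halfwidth_um = 500) {
  need <- max(central_width_um / 2, max_search_halfwidth_um)
  lo <- center_x_um - need
  hi <- center_x_um + need
  if (profile$x_um[1] > lo + 1e-9 ||
      profile$x_um[length(profile$x_um)] < hi - 1e-9)
    stop_fovea("profile must cover [%g, %g] um around the foveal center",
               lo, hi)
  in_max <- abs(profile$x_um - center_x_um) <= max_search_halfwidth_um + 1e-9
  k <- which(in_max)[which.max(profile$thickness_um[in_max])]
  half <- central_width_um / 2
  xs <- profile$x_um[profile$x_um > center_x_um - half &
                     profile$x_um < center_x_um + half]
  xs <- c(center_x_um - half, xs, center_x_um + half)
  ys <- approx(profile$x_um, profile$thickness_um, xout = xs)$y
  list(max_onl_um = profile$thickness_um[k],
       max_onl_x_um = profile$x_um[k],
       central_onl_um = trapz_mean(xs, ys))
}

#' Full ONL profile metrics from a boundary segmentation
#'
#' Convenience composition: interpolates the boundaries, locates the foveal
#' center, and extracts the thickness profile (re-expressed as signed
#' eccentricity from the center) with its maximum and central summaries.
#'
#' @inheritParams onl_thickness_profile
#' @inheritParams onl_summaries
#' @inheritParams locate_foveal_center
#' @return object of class `onl_profile` with fields `x_um` (eccentricity from
#'   the foveal center), `thickness_um`, `foveal_center_x_um`, `max_onl_um`,
#'   `max_onl_x_um` (eccentricity), `central_onl_um`, `central_width_um`.
#' @export
onl_metrics <- function(seg, x_step_um = 5, central_width_um = 227,
                        max_search_halfwidth_um = 500,
                        search_halfwidth_um = 750) {
  profile <- onl_thickness_profile(seg, x_step_um)
  center <- locate_foveal_center(seg, search_halfwidth_um)
  s <- onl_summaries(profile, center, central_width_um,
                     max_search_halfwidth_um)
  structure(list(x_um = profile$x_um - center,
                 thickness_um = profile$thickness_um,
                 foveal_center_x_um = center,
                 max_onl_um = s$max_onl_um,
                 max_onl_x_um = s$max_onl_x_um - center,
                 central_onl_um = s$central_onl_um,
                 central_width_um = central_width_um),
            class = "onl_profile")
}

#' @export
print.onl_profile <- function(x, ...) {
  cat(sprintf(
    "<onl_profile> max ONL %.1f um at %.0f um; central (%g um) ONL %.1f um\n",
    x$max_onl_um, x$max_onl_x_um, x$central_width_um, x$central_onl_um))
  invisible(x)
}

#' Average two graders' measurements
#'
#' Elementwise arithmetic mean of paired measurements (per participant, per
#' metric).
#'
#' @param grader1,grader2 paired numeric vectors of equal length.
#' @return elementwise mean.
#' @export
grader_average <- function(grader1, grader2) {
  if (length(grader1) != length(grader2))
    stop_fovea("grader vectors must be paired (lengths %d and %d)",
               length(grader1), length(grader2))
  if (any(is.na(grader1) != is.na(grader2)))
    stop_fovea("grader measurements unpaired: missingness differs")
  (grader1 + grader2) / 2
}
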