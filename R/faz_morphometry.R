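
#' Construct a binary vessel mask
#'
#' @param mask logical matrix, `TRUE` = vessel.
#' @param um_per_px isotropic lateral scale (micrometres per pixel).
#' @param center_um assumed foveal center `c(x, y)` in micrometres; defaults
#'   to the image center.
#' @param participant_id optional label.
#' @return object of class `vessel_mask`.
#' @export
vessel_mask <- function(mask, um_per_px, center_um = NULL,
                        participant_id = NA_character_) {
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop_fovea("numeric mask must be 0/1")
    mask <- mask > 0
  }
  stopifnot(is.logical(mask), is.matrix(mask))
  check_positive(um_per_px, "um_per_px")
  if (!any(mask) || all(mask))
    stop_fovea("mask must contain both vessel and non-vessel pixels")
  if (is.null(center_um))
    center_um <- c(x = (ncol(mask) - 1) / 2 * um_per_px,
                   y = (nrow(mask) - 1) / 2 * um_per_px)
  structure(list(mask = mask, um_per_px = um_per_px, center_um = center_um,
                 participant_id = participant_id),
            class = "vessel_mask")
}

#' Average repeated angiograms
#'
#' Pixelwise arithmetic mean of aligned grayscale angiogram acquisitions
#' (2 to 10 per eye), producing the single image analysed per participant.
#'
#' @param images list of numeric matrices with identical dimensions.
#' @return numeric matrix.
#' @export
average_angiograms <- function(images) {
  stopifnot(is.list(images))
  if (length(images) < 2 || length(images) > 10)
    stop_fovea("expected 2 to 10 angiograms (got %d)", length(images))
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop_fovea("all angiograms must have identical dimensions")
  Reduce(`+`, images) / length(images)
}

#' Binarize an angiogram into a vessel mask
#'
#' Otsu's threshold by default; already-binary input passes through unchanged.
#'
#' @param image numeric matrix (grayscale, any range) or 0/1 matrix.
#' @param um_per_px isotropic lateral scale.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold when `method = "fixed"` (vessel = pixel above).
#' @param ... passed to [vessel_mask()].
#' @return a [vessel_mask()].
#' @export
binarize_vessels <- function(image, um_per_px, method = c("otsu", "fixed"),
                             threshold = NULL, ...) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), is.numeric(image))
  if (all(image %in% c(0, 1)))
    return(vessel_mask(image > 0, um_per_px, ...))
  if (method == "otsu") {
    rng <- range(image)
    if (diff(rng) == 0)
      stop_fovea("constant image: Otsu undefined, use method = 'fixed'")
    thr <- EBImage::otsu(EBImage::Image((image - rng[1]) / diff(rng)),
                         range = c(0, 1))
    thr <- rng[1] + thr * diff(rng)
  } else {
    if (is.null(threshold)) stop_fovea("method = 'fixed' needs 'threshold'")
    thr <- threshold
  }
  vessel_mask(image > thr, um_per_px, ...)
}

#' Identify parafoveal intercapillary areas (PICAs)
#'
#' PICAs are the 4-connected components of non-vessel pixels (so diagonal
#' gaps in 8-connected capillary walls do not merge neighbouring regions).
#' Regions touching the image border are kept but flagged: they are unbounded
#' intercapillary space and never FAZ candidates.
#'
#' @param vm a [vessel_mask()].
#' @return object of class `pica_set` with a data frame `regions` (`label`,
#'   `area_mm2`, `centroid_x_um`, `centroid_y_um`, `touches_border`) and the
#'   label image.
#' @export
label_picas <- function(vm) {
  stopifnot(inherits(vm, "vessel_mask"))
  lab <- label_components(!vm$mask, connectivity = 4L)
  n <- max(lab)
  if (n == 0) stop_fovea("no candidate PICA: mask is all vessel")
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  area_px <- tabulate(labs, n)
  cx <- tapply((idx[, 2] - 1) * vm$um_per_px, labs, mean)
  cy <- tapply((idx[, 1] - 1) * vm$um_per_px, labs, mean)
  border <- logical(n)
  edge <- unique(labs[idx[, 1] == 1 | idx[, 1] == nrow(lab) |
                      idx[, 2] == 1 | idx[, 2] == ncol(lab)])
  border[edge] <- TRUE
  if (all(border))
    stop_fovea("no candidate PICA: every avascular region touches the border")
  regions <- data.frame(label = seq_len(n),
                        area_mm2 = area_px * (vm$um_per_px / 1000)^2,
                        centroid_x_um = as.numeric(cx),
                        centroid_y_um = as.numeric(cy),
                        touches_border = border)
  structure(list(regions = regions, labels = lab, um_per_px = vm$um_per_px,
                 center_um = vm$center_um,
                 participant_id = vm$participant_id),
            class = "pica_set")
}

#' Assign the FAZ and classify fragmentation
#'
#' Central PICAs are the non-border regions whose centroid lies within
#' `central_radius_um` of the assumed foveal center. The largest central PICA
#' is assigned as the foveal avascular zone (FAZ); each central PICA's area
#' ratio to the largest is computed, and the FAZ is classified as fragmented
#' when two or more ratios exceed `ratio_threshold` (strict comparison). The
#' FAZ area is the largest central area regardless of fragmentation.
#'
#' @param picas a `pica_set` from [label_picas()].
#' @param central_radius_um radius of the central region (default 500).
#' @param ratio_threshold fragmentation ratio threshold (default 0.3).
#' @return the `pica_set`, completed with `faz_label`, `faz_area_mm2`,
#'   `ratios`, `fragmented`, `n_central_picas`; `regions` gains a `central`
#'   column.
#' @export
assign_faz <- function(picas, central_radius_um = 500, ratio_threshold = 0.3) {
  stopifnot(inherits(picas, "pica_set"))
  reg <- picas$regions
  d <- sqrt((reg$centroid_x_um - picas$center_um["x"])^2 +
            (reg$centroid_y_um - picas$center_um["y"])^2)
  reg$central <- !reg$touches_border & d <= central_radius_um
  if (!any(reg$central))
    stop_fovea("no central PICA within %g um of the assumed foveal center",
               central_radius_um)
  central <- reg[reg$central, ]
  faz_area <- max(central$area_mm2)
  ratios <- central$area_mm2 / faz_area
  names(ratios) <- central$label
  picas$regions <- reg
  picas$faz_label <- central$label[which.max(central$area_mm2)]
  picas$faz_area_mm2 <- faz_area
  picas$ratios <- ratios
  picas$fragmented <- sum(ratios > ratio_threshold) >= 2
  picas$n_central_picas <- nrow(central)
  picas
}

#' @export
print.pica_set <- function(x, ...) {
  cat(sprintf("<pica_set> %d regions", nrow(x$regions)))
  if (!is.null(x$faz_area_mm2))
    cat(sprintf("; FAZ %.3f mm^2 (%s, %d central)", x$faz_area_mm2,
                if (x$fragmented) "fragmented" else "single",
                x$n_central_picas))
  cat("\n")
  invisible(x)
}

#' FAZ area and fragmentation from a vessel mask
#'
#' Composition of [label_picas()] and [assign_faz()].
#'
#' @param vm a [vessel_mask()].
#' @inheritParams assign_faz
#' @return list `faz_area_mm2`, `fragmented`, `n_central_picas`, `ratios`.
#' @export
faz_area <- function(vm, central_radius_um = 500, ratio_threshold = 0.3) {
  p <- assign_faz(label_picas(vm), central_radius_um, ratio_threshold)
  list(faz_area_mm2 = p$faz_area_mm2, fragmented = p$fragmented,
       n_central_picas = p$n_central_picas, ratios = p$ratios)
}
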