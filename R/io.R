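
# sidecar path convention: same basename, .json extension
.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

.read_sidecar <- function(path, sidecar) {
  if (is.null(sidecar)) sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar)) return(NULL)
  jsonlite::read_json(sidecar, simplifyVector = TRUE)
}

# corrected lateral scale from sidecar metadata: explicit um/px is treated as
# the device-nominal value and rescaled when an axial length is supplied
.lateral_from_meta <- function(meta) {
  if (is.null(meta$lateral_um_per_px))
    stop_fovea("sidecar missing 'lateral_um_per_px'")
  lat <- meta$lateral_um_per_px
  if (!is.null(meta$axial_length_mm) && !is.null(meta$nominal_length_mm)) {
    corr <- correct_lateral_scale(meta$nominal_length_mm,
                                  meta$axial_length_mm,
                                  meta$device_assumed_axial_mm %||% 24.46)
    lat <- lat * corr / meta$nominal_length_mm
  }
  lat
}

#' Read a boundary segmentation from CSV (+ JSON sidecar)
#'
#' The CSV must have columns `boundary,x_px,z_px` with boundary names among
#' `ILM, OPL_HFL, HFL_ONL, ELM, RPE`. Scales come from the JSON sidecar
#' (`axial_um_per_px`, `lateral_um_per_px`, optionally `nominal_length_mm` and
#' `axial_length_mm` for axial-length correction of the lateral scale) or from
#' the explicit arguments, which take precedence.
#'
#' @param path CSV path.
#' @param sidecar JSON sidecar path (default: same basename, `.json`).
#' @param axial_um_per_px,lateral_um_per_px explicit scales (override sidecar).
#' @return a [boundary_segmentation()].
#' @export
read_segmentation <- function(path, sidecar = NULL, axial_um_per_px = NULL,
                              lateral_um_per_px = NULL) {
  df <- read.csv(path)
  need <- c("boundary", "x_px", "z_px")
  if (!all(need %in% names(df)))
    stop_fovea("'%s' must have columns %s", path, paste(need, collapse = ","))
  meta <- .read_sidecar(path, sidecar)
  if (is.null(axial_um_per_px)) {
    if (is.null(meta$axial_um_per_px))
      stop_fovea("no axial scale: supply 'axial_um_per_px' or a sidecar")
    axial_um_per_px <- meta$axial_um_per_px
  }
  if (is.null(lateral_um_per_px)) {
    if (is.null(meta)) stop_fovea("no lateral scale: supply 'lateral_um_per_px' or a sidecar")
    lateral_um_per_px <- .lateral_from_meta(meta)
  }
  boundaries <- split(df[, c("x_px", "z_px")], df$boundary)
  boundary_segmentation(boundaries, axial_um_per_px, lateral_um_per_px)
}

#' Write a boundary segmentation to CSV (+ JSON sidecar)
#'
#' @param seg a [boundary_segmentation()].
#' @param path CSV output path; the sidecar goes to the same basename `.json`.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "boundary_segmentation"))
  df <- do.call(rbind, lapply(names(seg$boundaries), function(nm)
    data.frame(boundary = nm, x_px = seg$boundaries[[nm]][, 1],
               z_px = seg$boundaries[[nm]][, 2])))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(axial_um_per_px = seg$axial_um_per_px,
                            lateral_um_per_px = seg$lateral_um_per_px),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a density map to 32-bit float TIFF (+ JSON sidecar)
#'
#' The sidecar records `grid_step_um`, `window_side_um` and `origin_um` so the
#' map can be re-read with its geometry intact.
#'
#' @param map a [density_map()].
#' @param path `.tif`/`.tiff` output path.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  # float TIFF samples must lie in [0, 1]: store in 1e6 cones/mm^2 and record
  # the factor in the sidecar
  scale <- 1e6
  tiff::writeTIFF(map$grid / scale, path, bits.per.sample = 32,
                  reduce = FALSE)
  jsonlite::write_json(list(grid_step_um = map$grid_step_um,
                            window_side_um = map$window_side_um,
                            origin_um = as.list(map$origin_um),
                            roi_width_um = map$roi_width_um,
                            roi_height_um = map$roi_height_um,
                            scale_to_cones_mm2 = scale),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a density map written by [write_density_map()]
#'
#' @param path `.tif`/`.tiff` path with its JSON sidecar alongside.
#' @param participant_id optional label.
#' @return a [density_map()] object.
#' @export
read_density_map <- function(path, participant_id = NA_character_) {
  meta <- .read_sidecar(path, NULL)
  if (is.null(meta$grid_step_um))
    stop_fovea("missing sidecar with grid geometry for '%s'", path)
  grid <- tiff::readTIFF(path, as.is = FALSE) *
    (meta$scale_to_cones_mm2 %||% 1)
  dimnames(grid) <- NULL
  structure(list(grid = grid, grid_step_um = meta$grid_step_um,
                 window_side_um = meta$window_side_um,
                 origin_um = c(x = meta$origin_um$x, y = meta$origin_um$y),
                 roi_width_um = meta$roi_width_um,
                 roi_height_um = meta$roi_height_um,
                 participant_id = participant_id),
            class = "density_map")
}

#' Read a grayscale B-scan image (TIFF or PNG)
#'
#' @param path image path; multi-channel images are reduced to their first
#'   channel.
#' @param axial_um_per_px,lateral_um_per_px pixel scales (micrometres).
#' @return a [bscan_image()].
#' @export
read_bscan <- function(path, axial_um_per_px, lateral_um_per_px) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_fovea("unsupported B-scan format: .%s", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  dimnames(img) <- NULL
  bscan_image(img, axial_um_per_px, lateral_um_per_px)
}

#' Read a retinal thickness map (CSV grid or TIFF + JSON sidecar)
#'
#' @param path `.csv` (numeric grid, no header) or `.tif`/`.tiff` (32-bit
#'   float, micrometres).
#' @param sidecar JSON sidecar path (default: same basename, `.json`) with
#'   `x_um_per_px`, `y_um_per_px` (and optional axial-length fields, applied
#'   to both).
#' @param x_um_per_px,y_um_per_px explicit scales (override sidecar).
#' @param participant_id optional label.
#' @return a [thickness_map()].
#' @export
read_thickness_map <- function(path, sidecar = NULL, x_um_per_px = NULL,
                               y_um_per_px = NULL,
                               participant_id = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  grid <- switch(ext,
    csv = as.matrix(read.csv(path, header = FALSE)),
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    stop_fovea("unsupported thickness map format: .%s", ext))
  storage.mode(grid) <- "double"
  dimnames(grid) <- NULL
  meta <- .read_sidecar(path, sidecar)
  ratio <- 1
  if (!is.null(meta$axial_length_mm) && !is.null(meta$nominal_length_mm))
    ratio <- correct_lateral_scale(meta$nominal_length_mm,
                                   meta$axial_length_mm,
                                   meta$device_assumed_axial_mm %||% 24.46) /
      meta$nominal_length_mm
  if (is.null(x_um_per_px)) {
    if (is.null(meta$x_um_per_px)) stop_fovea("no x scale for '%s'", path)
    x_um_per_px <- meta$x_um_per_px * ratio
  }
  if (is.null(y_um_per_px)) {
    if (is.null(meta$y_um_per_px)) stop_fovea("no y scale for '%s'", path)
    y_um_per_px <- meta$y_um_per_px * ratio
  }
  thickness_map(grid, x_um_per_px, y_um_per_px, participant_id)
}

#' Write a retinal thickness map (CSV grid + JSON sidecar)
#'
#' @param map a [thickness_map()].
#' @param path `.csv` output path; sidecar goes to the same basename `.json`.
#' @export
write_thickness_map <- function(map, path) {
  stopifnot(inherits(map, "thickness_map"))
  write.table(map$grid, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(x_um_per_px = map$x_um_per_px,
                            y_um_per_px = map$y_um_per_px),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binary vessel mask (PNG, TIFF or CSV)
#'
#' Grayscale images are accepted when already binary (two levels); otherwise
#' use [binarize_vessels()] on the raw image.
#'
#' @param path `.png`, `.tif`/`.tiff` or `.csv` (0/1 grid, no header).
#' @param um_per_px isotropic scale; read from the JSON sidecar when omitted.
#' @param sidecar sidecar path (default: same basename, `.json`).
#' @param participant_id optional label.
#' @return a [vessel_mask()].
#' @export
read_vessel_mask <- function(path, um_per_px = NULL, sidecar = NULL,
                             participant_id = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    csv = as.matrix(read.csv(path, header = FALSE)),
    stop_fovea("unsupported mask format: .%s", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  dimnames(img) <- NULL
  lv <- sort(unique(as.vector(img)))
  if (length(lv) > 2)
    stop_fovea("'%s' is not binary (%d gray levels); binarize first",
               path, length(lv))
  mask <- img == max(lv)
  if (is.null(um_per_px)) {
    meta <- .read_sidecar(path, sidecar)
    if (is.null(meta$um_per_px))
      stop_fovea("no scale for '%s': supply 'um_per_px' or a sidecar", path)
    um_per_px <- meta$um_per_px
  }
  vessel_mask(mask, um_per_px, participant_id = participant_id)
}

#' Write a vessel mask to PNG (+ JSON sidecar)
#'
#' @param vm a [vessel_mask()].
#' @param path `.png` output path.
#' @export
write_vessel_mask <- function(vm, path) {
  stopifnot(inherits(vm, "vessel_mask"))
  png::writePNG(vm$mask * 1, path)
  jsonlite::write_json(list(um_per_px = vm$um_per_px), .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
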