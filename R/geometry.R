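
#' Correct a nominal lateral scan length for ocular axial length
#'
#' OCT devices convert scan angle to lateral distance assuming a fixed ocular
#' axial length (24.46 mm for the Cirrus HD-OCT). The true lateral extent of a
#' scan scales linearly with the participant's measured axial length, so the
#' corrected length is the nominal length multiplied by the ratio of measured
#' to assumed axial length.
#'
#' @param nominal_length_mm nominal scan length reported by the device (mm).
#' @param axial_length_mm participant's measured axial length (mm).
#' @param device_assumed_axial_mm axial length assumed by the device (mm);
#'   default 24.46 (Cirrus HD-OCT).
#' @param axial_length_window_mm two-element plausibility window for
#'   `axial_length_mm`; values outside it are rejected to catch unit errors.
#' @return corrected scan length (mm).
#' @examples
#' correct_lateral_scale(6, 24.46)          # 6: ratio is 1
#' correct_lateral_scale(9, 27.49)          # a long eye stretches the scan
#' @export
correct_lateral_scale <- function(nominal_length_mm, axial_length_mm,
                                  device_assumed_axial_mm = 24.46,
                                  axial_length_window_mm = c(18, 32)) {
  check_positive(nominal_length_mm, "nominal_length_mm")
  check_positive(device_assumed_axial_mm, "device_assumed_axial_mm")
  if (!is.numeric(axial_length_mm) || length(axial_length_mm) != 1L ||
      !is.finite(axial_length_mm) || axial_length_mm <= 0)
    stop_fovea("'axial_length_mm' must be a single positive number (got %s)",
               format(axial_length_mm))
  if (axial_length_mm < axial_length_window_mm[1] ||
      axial_length_mm > axial_length_window_mm[2])
    stop_fovea(paste0("axial_length_mm = %g is outside the plausibility ",
                      "window [%g, %g] mm; check units"),
               axial_length_mm, axial_length_window_mm[1],
               axial_length_window_mm[2])
  nominal_length_mm * axial_length_mm / device_assumed_axial_mm
}

#' Lateral sampling in micrometres per pixel
#'
#' @param corrected_length_mm true (axial-length-corrected) scan length (mm).
#' @param n_pixels number of samples along the scan (>= 2).
#' @return sampling in micrometres per pixel.
#' @examples
#' um_per_pixel(6, 512)
#' @export
um_per_pixel <- function(corrected_length_mm, n_pixels) {
  check_positive(corrected_length_mm, "corrected_length_mm")
  if (!is.numeric(n_pixels) || length(n_pixels) != 1L || n_pixels < 2 ||
      n_pixels != round(n_pixels))
    stop_fovea("'n_pixels' must be an integer >= 2 (got %s)", format(n_pixels))
  1000 * corrected_length_mm / n_pixels
}
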