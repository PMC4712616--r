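#' Per-axis apparent diffusion coefficient map
#'
#' Mono-exponential Stejskal-Tanner inversion of a b0/b1000 pair:
#' ADC = ln(S0 / Sb) / b (mm^2/s) wherever both signals are positive inside
#' the brain mask; other voxels are 0. Voxels where Sb > S0 would yield a
#' negative ADC; they are clamped to 0, counted, and flagged invalid so the
#' reporting layer can exclude them from region statistics.
#'
#' @param s0 `volume_image`, b = 0 s/mm^2 acquisition.
#' @param s_b `volume_image`, diffusion-weighted acquisition along one axis.
#' @param b_value diffusion weighting, s/mm^2 (> 0).
#' @param brain_mask binary `volume_image`.
#' @return `volume_image` of ADC in mm^2/s, with attributes
#'   `n_clamped` (count of negative-ADC voxels clamped to 0) and
#'   `valid_mask` (logical array: voxels carrying a usable ADC).
#' @export
adc_axis_map <- function(s0, s_b, b_value, brain_mask) {
  if (!is.finite(b_value) || b_value <= 0)
    stop("b_value must be > 0", call. = FALSE)
  stop_if_grid_mismatch(s0, s_b, "DWI volumes")
  stop_if_grid_mismatch(s0, brain_mask, "DWI volume and brain mask")
  inmask <- brain_mask$data != 0
  pos <- inmask & s0$data > 0 & s_b$data > 0
  adc <- array(0, dim(s0$data))
  adc[pos] <- log(s0$data[pos] / s_b$data[pos]) / b_value
  neg <- adc < 0
  n_clamped <- sum(neg)
  adc[neg] <- 0
  out <- volume_image(adc, s0$voxel_mm, s0$affine, s0$space)
  attr(out, "n_clamped") <- n_clamped
  attr(out, "valid_mask") <- pos & !neg
  out
}

#' Average ADC map over the three Cartesian axes
#'
#' Voxelwise arithmetic mean of the per-axis ADC maps. The valid mask of
#' the result is the intersection of the inputs' valid masks (a voxel mean
#' is only meaningful where every axis produced a usable ADC).
#'
#' @param adc_x,adc_y,adc_z per-axis ADC `volume_image`s from
#'   [adc_axis_map()] (plain volumes are accepted; missing valid masks are
#'   treated as all-valid).
#' @return mean ADC `volume_image` with a combined `valid_mask` attribute.
#' @export
mean_adc_map <- function(adc_x, adc_y, adc_z) {
  stop_if_grid_mismatch(adc_x, adc_y, "ADC maps")
  stop_if_grid_mismatch(adc_x, adc_z, "ADC maps")
  m <- (adc_x$data + adc_y$data + adc_z$data) / 3
  out <- volume_image(m, adc_x$voxel_mm, adc_x$affine, adc_x$space)
  vm <- function(a) attr(a, "valid_mask") %||% array(TRUE, dim(a$data))
  attr(out, "valid_mask") <- vm(adc_x) & vm(adc_y) & vm(adc_z)
  out
}
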