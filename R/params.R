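# Detector parameter presets.
#
# The published reconstruction presets use fixed discretization steps
# (theta 0.5 deg on [-90, 89.5]; rho 6 px; circle radius step 0.4 px for
# real data) and peak parameters printed as a (value at 5% density, value
# at 100% density) pair; between those endpoints we interpolate linearly
# in density.

interp_density <- function(v5, v100, density) {
  d <- min(max(density, 0.05), 1)
  v5 + (v100 - v5) * (d - 0.05) / 0.95
}

#' Hough detector parameter presets
#'
#' Returns the peak-detection parameter set for [detect_lines()] /
#' [detect_circles()] at a given data density: discretization steps theta
#' 0.5 degrees on `[-90, 89.5]` and rho 6 px, and density-dependent peak
#' parameters that vary linearly from their 5%-density to their
#' 100%-density preset value (line peak threshold 0.23-0.26 of the
#' accumulator maximum, minimum line length 126-168 px, maximum gap
#' 47.5-33.6 px; circle peak threshold 0.53-0.63, minimum spatial peak
#' separation 55 px, minimum radius separation 71-75 px).
#'
#' `peak_separation = NULL` (line default) selects a non-maximum
#' suppression neighborhood of `floor(dim(accumulator) / 50)` bins per
#' axis at detection time. This rejects the duplicate ridge peaks that a
#' single structure spreads over neighbouring bins; workflows that must
#' resolve closely spaced parallel lines should set it explicitly to a
#' small value such as `c(2, 2)` (bins in rho and theta).
#'
#' @param shape `"line"` or `"circle"`.
#' @param density data density in `(0, 1]` used for the interpolated values.
#' @param r_range,r_step circle radius search range and step, pixels. The
#'   real-data preset is step 0.4 on `[10, 120] * scale / pixelsize`
#'   (~1.6-19 px at scale 25 and 158 nm pixels); the default here suits the
#'   640 px simulation masks.
#' @param nm_per_px physical size of one analysis pixel in nm (for circle
#'   diameters; `158/25` for the real-data grid, 1 for simulation masks).
#' @param ... overrides for any returned field.
#' @return a named list of detector parameters.
#' @export
hough_params <- function(shape = c("line", "circle"), density = 1,
                         r_range = c(15, 70), r_step = 1,
                         nm_per_px = 1, ...) {
  shape <- match.arg(shape)
  p <- if (shape == "line") {
    list(theta_step = 0.5, theta_range = c(-90, 89.5), rho_step = 6,
         max_peaks = 5000,
         peak_threshold_frac = interp_density(0.23, 0.26, density),
         peak_separation = NULL,     # auto: floor(dim(H) / 50) bins
         min_line_length = interp_density(126, 168, density),
         max_gap = interp_density(47.5, 33.6, density),
         support_residual = NULL)    # default rho_step / 2
  } else {
    list(r_range = r_range, r_step = r_step, max_peaks = 200,
         peak_threshold_frac = interp_density(0.53, 0.63, density),
         min_spatial_sep = 55,
         min_radius_sep = interp_density(71, 75, density),
         log_sigma = 4, unsharp_amount = 0.2, nm_per_px = nm_per_px)
  }
  modifyList(p, list(...))
}
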