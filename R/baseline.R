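#' Render localizations to an intensity image
#'
#' Blob detection operates on intensity images, so localization points are
#' splatted as unit impulses onto the pixel grid and smoothed with a small
#' Gaussian.
#'
#' @param locs a [localization_set()] or points matrix/data frame.
#' @param width,height image size in pixels.
#' @param sigma Gaussian smoothing sd in pixels (0 disables smoothing).
#' @return a `height` x `width` numeric matrix.
#' @export
render_points_image <- function(locs, width, height, sigma = 2) {
  pts <- round(as_points(locs))
  keep <- pts[, 1] >= 0 & pts[, 1] < width & pts[, 2] >= 0 & pts[, 2] < height
  pts <- pts[keep, , drop = FALSE]
  img <- matrix(0, height, width)
  if (nrow(pts) > 0) {
    idx <- pts[, 2] + 1 + height * pts[, 1]  # row y+1, col x+1
    tab <- table(idx)
    img[as.integer(names(tab))] <- as.integer(tab)
  }
  if (sigma > 0) img <- conv2_fft(img, gaussian_kernel(sigma))
  img
}

#' Multi-scale Laplacian-of-Gaussian blob detection
#'
#' The comparison baseline for circular features: scale-normalized LoG
#' responses \eqn{\sigma^2 |\nabla^2 G_\sigma * I|} are computed over a
#' geometric grid of scales and local maxima across space and scale above
#' `threshold * max(response)` are returned as blobs with radius
#' \eqn{r = \sigma\sqrt{2}}. Being multi-scale, a single feature may yield
#' several blobs of different radii; use [size_filter()] to remove the
#' small ones.
#'
#' @param image intensity image (e.g. from [render_points_image()]).
#' @param radius_range length-2 radius search range in pixels; alternatively
#'   give `kernel_range_frac`.
#' @param kernel_range_frac optional length-2 fraction of the image size
#'   taken as the LoG kernel size range (kernel size ~ 6 sigma, radius
#'   `sigma * sqrt(2)`); overrides `radius_range`.
#' @param n_scales number of scales on the geometric grid.
#' @param threshold relative response threshold in `(0, 1)`.
#' @return a data frame of blobs: `x, y, radius, scale, response`, strongest
#'   first. Empty for a blank image.
#' @export
blob_detect_log <- function(image, radius_range = c(5, 70),
                            kernel_range_frac = NULL, n_scales = 12,
                            threshold = 0.2) {
  if (!is.null(kernel_range_frac)) {
    sz <- kernel_range_frac * max(dim(image))
    radius_range <- (sz / 6) * sqrt(2)
  }
  if (all(image == 0))
    return(data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                      scale = numeric(0), response = numeric(0)))
  sigmas <- exp(seq(log(radius_range[1] / sqrt(2)),
                    log(radius_range[2] / sqrt(2)), length.out = n_scales))
  h <- nrow(image); w <- ncol(image)
  stack <- array(0, dim = c(h, w, n_scales))
  for (i in seq_len(n_scales)) {
    k <- log_kernel(sigmas[i], min(2 * ceiling(3 * sigmas[i]) + 1,
                                   2 * floor((min(h, w) - 1) / 2) + 1))
    # bright blobs on dark background give negative LoG response: negate
    stack[, , i] <- -sigmas[i]^2 * conv2_fft(image, k)
  }
  thr <- threshold * max(stack)
  if (thr <= 0) thr <- .Machine$double.eps
  cand <- cpp_local_maxima3(as.numeric(stack), h, w, n_scales, thr)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                      scale = numeric(0), response = numeric(0)))
  out <- data.frame(x = cand[, "j"] - 1, y = cand[, "i"] - 1,
                    radius = sigmas[cand[, "k"]] * sqrt(2),
                    scale = sigmas[cand[, "k"]],
                    response = cand[, "value"])
  out[order(-out$response), , drop = FALSE]
}

#' Size-filter detected blobs
#'
#' Removes blobs whose radius is below `min_radius`, the aggressive filter
#' needed because multi-scale detection emits several concentric circles
#' per feature (e.g. a 6 px cutoff at 25x scale and 158 nm camera pixels
#' removes features below ~38 nm).
#'
#' @param blobs data frame from [blob_detect_log()].
#' @param min_radius minimum retained radius, pixels (>= 0).
#' @return the filtered data frame.
#' @export
size_filter <- function(blobs, min_radius) {
  if (min_radius < 0) stop("min_radius must be >= 0")
  blobs[blobs$radius >= min_radius, , drop = FALSE]
}
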