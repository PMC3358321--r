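#' Circle Hough transform
#'
#' Votes each localization into the 3-d \eqn{(a, b, r)} parameter space of
#' the circle equation \eqn{(x-a)^2 + (y-b)^2 = r^2}. For every radius bin
#' the point increments all centre cells on the circle of that radius around
#' itself (the cone surface of the accumulator), so points generated by one
#' circle intersect at its true centre: the \eqn{(a, b, r)} cell receives
#' one vote per input point. Centre circles are rasterized with the same
#' midpoint algorithm used for the ground-truth masks; because the midpoint
#' offset set is symmetric under negation, a point on a rasterized circle
#' always votes for that circle's exact centre cell.
#'
#' @param points a [localization_set()] or matrix/data frame with `x`, `y`;
#'   coordinates are rounded to integer pixels.
#' @param dims accumulator spatial size `c(width, height)` (the image size).
#' @param r_axis radius bin centres in pixels (e.g. `seq(15, 70, by = 1)`).
#' @return an object of class `circle_accumulator`: integer vote array of
#'   dim `c(width, height, length(r_axis))` (`votes[a+1, b+1, k]` for centre
#'   `(a, b)`, 0-based) plus axes.
#' @seealso [smooth_circle_accumulator()], [detect_circles()], [hough_fit()]
#' @export
circle_transform <- function(points, dims, r_axis) {
  pts <- as_points(points)
  if (nrow(pts) == 0) stop("empty point set")
  if (any(r_axis <= 0)) stop("radius range must be positive")
  width <- as.integer(dims[1]); height <- as.integer(dims[2])
  est_bytes <- 4 * as.double(width) * height * length(r_axis)
  if (est_bytes > getOption("smlmhough.max_accumulator_bytes", 2e9))
    stop("circle accumulator would exceed the memory cap (",
         round(est_bytes / 1e9, 2), " GB); restrict the radius range or ",
         "raise options(smlmhough.max_accumulator_bytes = )")
  v <- cpp_circle_vote(pts[, 1], pts[, 2], width, height, r_axis)
  structure(list(votes = array(v, dim = c(width, height, length(r_axis))),
                 r = r_axis, dims = c(width, height)),
            class = "circle_accumulator")
}

#' @export
print.circle_accumulator <- function(x, ...) {
  cat(sprintf("circle_accumulator: %d x %d x %d bins (r %g..%g), max votes %d\n",
              dim(x$votes)[1], dim(x$votes)[2], dim(x$votes)[3],
              min(x$r), max(x$r), max(x$votes)))
  invisible(x)
}

#' Smooth the 3-d circle accumulator
#'
#' Consolidates the spread-out votes of noisy localizations by convolving
#' each radius slice with a (negated, peak-enhancing) Laplacian-of-Gaussian
#' kernel, followed by a 3x3 unsharp contrast-enhancement filter with
#' amount `unsharp_amount` (default 0.2). Slice-wise 2-d filtering is the
#' default; `volumetric = TRUE` first applies a normalized Gaussian filter
#' of standard deviation `r_sigma` bins along the radius axis, pooling the
#' votes that position noise spreads across neighbouring radius slices
#' (a point at noisy distance d from a centre votes near that centre in
#' the slices around r = d).
#'
#' @param acc a `circle_accumulator`.
#' @param log_sigma standard deviation of the LoG kernel in accumulator
#'   pixels. The default 4 is calibrated on synthetic circle data so the
#'   kernel spans the blob over which position noise spreads a circle's
#'   centre votes (roughly twice the per-axis noise sd at the study's
#'   5 px FWHM).
#' @param log_size odd kernel size (default `2*ceiling(3*log_sigma) + 1`).
#' @param unsharp_amount unsharp filter amount.
#' @param volumetric also couple neighbouring radius slices.
#' @param r_sigma standard deviation (in radius bins) of the Gaussian
#'   pooling along the radius axis when `volumetric = TRUE`.
#' @return a `circle_accumulator` with numeric filtered votes; the input is
#'   unchanged.
#' @export
smooth_circle_accumulator <- function(acc, log_sigma = 4, log_size = NULL,
                                      unsharp_amount = 0.2,
                                      volumetric = FALSE, r_sigma = 2) {
  stopifnot(inherits(acc, "circle_accumulator"))
  log_size <- log_size %||% (2 * ceiling(3 * log_sigma) + 1)
  if (log_size > min(dim(acc$votes)[1:2]))
    stop("LoG kernel larger than the accumulator plane")
  k <- -log_kernel(log_sigma, log_size)
  u <- unsharp_kernel(unsharp_amount)
  # single combined kernel: LoG then unsharp
  kp <- matrix(0, nrow(k) + 2, ncol(k) + 2)
  kp[1 + seq_len(nrow(k)), 1 + seq_len(ncol(k))] <- k
  k2 <- conv2_fft(kp, u)
  nr <- dim(acc$votes)[3]
  out <- acc
  vol <- acc$votes + 0
  if (volumetric && nr > 1) {
    kk <- min(nr - 1, ceiling(2 * r_sigma))
    w <- exp(-(-kk:kk)^2 / (2 * r_sigma^2))
    band <- matrix(0, nr, nr)
    for (i in seq_len(nr)) {
      j <- max(1, i - kk):min(nr, i + kk)
      wi <- w[j - i + kk + 1]
      band[j, i] <- wi / sum(wi)
    }
    dim(vol) <- c(prod(dim(acc$votes)[1:2]), nr)
    vol <- vol %*% band
    dim(vol) <- dim(acc$votes)
  }
  out$votes <- conv_slices(vol, k2)
  out$smoothed <- TRUE
  out
}

#' Extract circles from a circle accumulator
#'
#' Candidate peaks are local maxima at or above
#' `peak_threshold_frac * max(votes)`, accepted greedily in descending vote
#' order (ties broken by lower `(a, b, r)` bin index). A candidate is
#' suppressed when it lies within `min_spatial_sep` (Euclidean distance in
#' the centre plane) AND within `min_radius_sep` of an already accepted
#' peak; with the published presets the radius separation exceeds the whole
#' radius search range, so suppression is effectively spatial — one circle
#' per location.
#'
#' @param acc a (raw or smoothed) `circle_accumulator`.
#' @param cfg parameter list from [hough_params()] (`shape = "circle"`).
#' @return a data frame of detected circles: `a, b, r, votes, diameter_nm`
#'   with `diameter_nm = 2 r * nm_per_px`. Empty when no peak reaches the
#'   threshold.
#' @export
detect_circles <- function(acc, cfg = hough_params("circle")) {
  stopifnot(inherits(acc, "circle_accumulator"))
  empty <- data.frame(a = numeric(0), b = numeric(0), r = numeric(0),
                      votes = numeric(0), diameter_nm = numeric(0))
  vmax <- max(acc$votes)
  if (vmax <= 0) return(empty)
  thr <- cfg$peak_threshold_frac * vmax
  d <- dim(acc$votes)
  cand <- cpp_local_maxima3(as.numeric(acc$votes), d[1], d[2], d[3], thr)
  if (nrow(cand) == 0) return(empty)
  ord <- order(-cand[, "value"], cand[, "i"], cand[, "j"], cand[, "k"])
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(numeric(0), 0, 4)
  for (t in seq_len(nrow(cand))) {
    a <- cand[t, "i"] - 1; b <- cand[t, "j"] - 1
    r <- acc$r[cand[t, "k"]]
    if (nrow(keep) > 0) {
      ds <- sqrt((keep[, 1] - a)^2 + (keep[, 2] - b)^2)
      if (any(ds < cfg$min_spatial_sep & abs(keep[, 3] - r) < cfg$min_radius_sep))
        next
    }
    keep <- rbind(keep, c(a, b, r, cand[t, "value"]))
    if (nrow(keep) >= cfg$max_peaks) break
  }
  nmpp <- cfg$nm_per_px %||% 1
  data.frame(a = keep[, 1], b = keep[, 2], r = keep[, 3], votes = keep[, 4],
             diameter_nm = 2 * keep[, 3] * nmpp)
}

#' Export an accumulator as a TIFF stack
#'
#' Writes the vote array (one slice per radius for circles, a single slice
#' for lines) as a 32-bit float TIFF for inspection in image viewers.
#'
#' @param acc a `line_accumulator` or `circle_accumulator`.
#' @param path output TIFF path.
#' @return invisibly, `path`.
#' @export
write_accumulator_tiff <- function(acc, path) {
  v <- acc$votes
  if (inherits(acc, "line_accumulator")) {
    img <- list(v / max(max(v), 1))
  } else {
    img <- lapply(seq_len(dim(v)[3]), function(i) t(v[, , i]) / max(max(v), 1))
  }
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  invisible(path)
}
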