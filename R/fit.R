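#' Fit parametric structures to localization data by Hough voting
#'
#' The central model-fitting function of the package. Treats the Hough
#' transform as a generative model for single-molecule localization data:
#' each point votes for every line (\eqn{\rho = x\cos\theta + y\sin\theta})
#' or circle (\eqn{(x-a)^2 + (y-b)^2 = r^2}) that could have generated it,
#' and the consensus structures are read off as accumulator peaks. The
#' pipeline is transform, optional accumulator smoothing (2-d median filter
#' for lines, Laplacian-of-Gaussian plus unsharp masking for circles), and
#' peak extraction with non-maximum suppression.
#'
#' @param x a [localization_set()], a matrix/data frame of points with
#'   columns `x`, `y`, or a [structure_mask()] (fit to all active pixels).
#' @param shape `"line"` or `"circle"`.
#' @param dims image `c(width, height)` in pixels; inferred from a mask
#'   input, otherwise from the point extent.
#' @param params detector parameters from [hough_params()]; defaults to the
#'   preset for `shape` at `density`.
#' @param density data density used to select density-dependent preset
#'   values (only used when `params` is `NULL`).
#' @param smooth apply accumulator smoothing before peak extraction.
#'   Default (`NULL`): on for circles, where the Laplacian-of-Gaussian
#'   filter consolidates votes that position noise spreads over
#'   neighbouring centre/radius bins, and off for lines, where on sparse
#'   accumulators the median window can erase the single-bin ridge of a
#'   short filament along with the spurious peaks.
#' @param keep_accumulator retain the (raw) accumulator in the fit object.
#' @return an object of class `smlm_hough` with methods [print()],
#'   [summary()], [coef()] (shape parameter matrix), [plot()],
#'   [residuals()] (distance of each point to the nearest fitted shape),
#'   [predict()] (nearest-shape assignment for new points), [fitted()]
#'   (rendered reconstruction image) and [simulate()] (new localization
#'   sets sampled from the fitted structures).
#' @examples
#' mask <- make_line_mask(256, 256, n_lines = 3, seed = 1)
#' locs <- sample_localizations(mask, density = 0.3, seed = 2)
#' fit <- hough_fit(locs, "line", dims = c(256, 256))
#' coef(fit)
#' @export
hough_fit <- function(x, shape = c("line", "circle"), dims = NULL,
                      params = NULL, density = 1, smooth = NULL,
                      keep_accumulator = FALSE) {
  shape <- match.arg(shape)
  smooth <- smooth %||% (shape == "circle")
  if (inherits(x, "structure_mask")) {
    dims <- c(x$width, x$height)
    pts <- as_points(data.frame(x = as.numeric(x$active[, 1]),
                                y = as.numeric(x$active[, 2])))
  } else {
    pts <- as_points(x)
  }
  if (is.null(dims)) dims <- c(ceiling(max(pts[, 1])) + 1,
                               ceiling(max(pts[, 2])) + 1)
  params <- params %||% hough_params(shape, density = density)
  if (shape == "line") {
    theta_axis <- seq(params$theta_range[1], params$theta_range[2],
                      by = params$theta_step)
    acc <- line_transform(pts, theta_axis, params$rho_step, dims = dims)
    det_acc <- if (smooth) smooth_line_accumulator(acc) else acc
    detections <- detect_lines(det_acc, pts, params)
  } else {
    r_axis <- seq(params$r_range[1], params$r_range[2], by = params$r_step)
    acc <- circle_transform(pts, dims, r_axis)
    det_acc <- if (smooth) {
      smooth_circle_accumulator(acc, log_sigma = params$log_sigma,
                                unsharp_amount = params$unsharp_amount)
    } else acc
    detections <- detect_circles(det_acc, params)
  }
  structure(list(call = match.call(), shape = shape, points = pts,
                 dims = dims, params = params, smooth = smooth,
                 detections = detections,
                 accumulator_max = max(acc$votes),
                 accumulator = if (keep_accumulator) acc else NULL),
            class = "smlm_hough")
}

#' @export
print.smlm_hough <- function(x, ...) {
  cat(sprintf("Hough %s fit: %d points (%d x %d px) -> %d %s(s)\n",
              x$shape, nrow(x$points), x$dims[1], x$dims[2],
              nrow(x$detections), x$shape))
  invisible(x)
}

#' @export
summary.smlm_hough <- function(object, ...) {
  structure(list(fit = object), class = "summary.smlm_hough")
}

#' @export
print.summary.smlm_hough <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  raw accumulator maximum: %d votes\n", f$accumulator_max))
  cat(sprintf("  smoothing: %s\n", if (f$smooth) "on" else "off"))
  if (nrow(f$detections) > 0) {
    cat("  detections:\n")
    print(f$detections, digits = 4)
    res <- residuals(f)
    cat(sprintf("  point-to-structure residuals: median %.2f px, 90%% %.2f px\n",
                median(res), quantile(res, 0.9)))
  }
  invisible(x)
}

#' @export
coef.smlm_hough <- function(object, ...) {
  d <- object$detections
  if (object$shape == "line")
    as.matrix(d[, c("rho", "theta")])
  else
    as.matrix(d[, c("a", "b", "r")])
}

#' @export
residuals.smlm_hough <- function(object, ...) {
  shape_distances(object$points, object$detections, object$shape, min = TRUE)
}

#' @export
predict.smlm_hough <- function(object, newdata = NULL, ...) {
  pts <- if (is.null(newdata)) object$points else as_points(newdata)
  d <- shape_distances(pts, object$detections, object$shape, min = FALSE)
  if (ncol(d) == 0)
    return(data.frame(shape = rep(NA_integer_, nrow(pts)),
                      distance = rep(NA_real_, nrow(pts))))
  data.frame(shape = max.col(-d, ties.method = "first"),
             distance = apply(d, 1, min))
}

# distances of points to each detected shape; min = TRUE collapses to the
# nearest-shape distance (Inf when there are no detections)
shape_distances <- function(pts, det, shape, min = TRUE) {
  n <- nrow(pts)
  if (nrow(det) == 0) {
    d <- matrix(numeric(0), n, 0)
    return(if (min) rep(Inf, n) else d)
  }
  d <- matrix(0, n, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (shape == "line") {
      th <- det$theta[i] * pi / 180
      d[, i] <- abs(pts[, 1] * cos(th) + pts[, 2] * sin(th) - det$rho[i])
    } else {
      d[, i] <- abs(sqrt((pts[, 1] - det$a[i])^2 + (pts[, 2] - det$b[i])^2) -
                      det$r[i])
    }
  }
  if (min) apply(d, 1, min) else d
}

#' @export
fitted.smlm_hough <- function(object, ...) {
  render_shapes(detections_to_shapes(object$detections, object$shape),
                object$dims[1], object$dims[2], clip = TRUE)
}

#' @export
plot.smlm_hough <- function(x, ...) {
  plot(x$points[, 1], x$dims[2] - 1 - x$points[, 2], pch = ".", cex = 2,
       col = "grey40", asp = 1, xlab = "x (px)", ylab = "y (px)",
       xlim = c(0, x$dims[1]), ylim = c(0, x$dims[2]), ...)
  d <- x$detections
  if (nrow(d) == 0) return(invisible(x))
  if (x$shape == "line") {
    segments(d$x1, x$dims[2] - 1 - d$y1, d$x2, x$dims[2] - 1 - d$y2,
             col = "red", lwd = 2)
  } else {
    symbols(d$a, x$dims[2] - 1 - d$b, circles = d$r, inches = FALSE,
            add = TRUE, fg = "red", lwd = 2)
  }
  invisible(x)
}

#' @export
simulate.smlm_hough <- function(object, nsim = 1, seed = NULL,
                                density = NULL, position_fwhm = 0, ...) {
  shapes <- detections_to_shapes(object$detections, object$shape)
  mask <- structure_mask(object$dims[1], object$dims[2], shapes)
  if (is.null(density))
    density <- min(1, nrow(object$points) / max(1, nrow(mask$active)))
  base <- if (is.null(seed)) NULL else as.integer(seed)
  out <- lapply(seq_len(nsim), function(i) {
    s <- if (is.null(base)) NULL else base + i - 1
    locs <- sample_localizations(mask, density, seed = s)
    if (position_fwhm > 0)
      locs <- apply_position_noise(locs, position_fwhm,
                                   seed = if (is.null(s)) NULL else s + 777)
    locs
  })
  if (nsim == 1) out[[1]] else out
}

# Convert a detections data frame back to a shape list for rendering.
detections_to_shapes <- function(det, shape) {
  if (nrow(det) == 0) return(list())
  lapply(seq_len(nrow(det)), function(i) {
    if (shape == "line")
      line_shape(det$x1[i], det$y1[i], det$x2[i], det$y2[i])
    else
      circle_shape(det$a[i], det$b[i], det$r[i])
  })
}

#' Write detected shapes as CSV
#'
#' Lines are written as `x1,y1,x2,y2,rho,theta_deg,votes`; circles as
#' `a,b,r,votes,diameter_nm`.
#'
#' @param fit an `smlm_hough` fit (or a detections data frame).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_detections_csv <- function(fit, path) {
  d <- if (inherits(fit, "smlm_hough")) fit$detections else fit
  if ("theta" %in% names(d)) {
    d <- d[, c("x1", "y1", "x2", "y2", "rho", "theta", "votes")]
    names(d)[6] <- "theta_deg"
  }
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
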