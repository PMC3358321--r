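#' Render parametric shapes to a binary image
#'
#' Rasterizes a shape list with the same Bresenham/midpoint rasterizer used
#' for the ground-truth masks, so a rendering of a mask's own shapes
#' reproduces its active set exactly. Used to compare reconstructions to
#' masks via [cw_ssim()].
#'
#' @param shapes list of [line_shape()] / [circle_shape()] descriptors, or
#'   an `smlm_hough` fit whose detections are rendered.
#' @param width,height output image size in pixels.
#' @param clip rasterize out-of-frame shapes by clipping their pixels to the
#'   frame instead of raising an error.
#' @return a `height` x `width` 0/1 matrix (element `[y+1, x+1]`).
#' @export
render_shapes <- function(shapes, width, height, clip = FALSE) {
  if (inherits(shapes, "smlm_hough"))
    shapes <- detections_to_shapes(shapes$detections, shapes$shape)
  for (s in if (clip) list() else shapes) {
    if (s$kind == "circle" &&
        (s$a - s$r < -0.5 || s$a + s$r > width - 0.5 ||
         s$b - s$r < -0.5 || s$b + s$r > height - 0.5))
      stop("shape extends outside the frame")
    if (s$kind == "line" &&
        any(c(s$x1, s$x2) < -0.5 | c(s$x1, s$x2) > width - 0.5 |
            c(s$y1, s$y2) < -0.5 | c(s$y1, s$y2) > height - 0.5))
      stop("shape extends outside the frame")
  }
  act <- rasterize_shapes(shapes, width, height)
  img <- matrix(0, height, width)
  if (nrow(act) > 0) img[cbind(act[, 2] + 1, act[, 1] + 1)] <- 1
  img
}

#' Reconstruction resolution from parallel-line detections
#'
#' The resolution of a parallel-line reconstruction is the smallest pairwise
#' distance between the detected lines: for pairs with (near-)equal
#' \eqn{\theta} this is \eqn{|\Delta\rho|}; in general the perpendicular
#' distance from each segment's midpoint to the other segment's supporting
#' line, minimized over the pair.
#'
#' @param segments a detections data frame from [detect_lines()] (or an
#'   `smlm_hough` line fit).
#' @return the minimum inter-line distance in pixels, or `NA` (not
#'   applicable) with fewer than two segments.
#' @export
resolution <- function(segments) {
  if (inherits(segments, "smlm_hough")) segments <- segments$detections
  n <- nrow(segments)
  if (n < 2) return(NA_real_)
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- segments$theta[i] * pi / 180
      tj <- segments$theta[j] * pi / 180
      mi <- c((segments$x1[i] + segments$x2[i]) / 2,
              (segments$y1[i] + segments$y2[i]) / 2)
      mj <- c((segments$x1[j] + segments$x2[j]) / 2,
              (segments$y1[j] + segments$y2[j]) / 2)
      dij <- abs(mi[1] * cos(tj) + mi[2] * sin(tj) - segments$rho[j])
      dji <- abs(mj[1] * cos(ti) + mj[2] * sin(ti) - segments$rho[i])
      best <- min(best, dij, dji)
    }
  }
  best
}

#' Replicate statistics of extracted biological features
#'
#' For each replicate sampling, computes the mean and median filament
#' orientation angle over detected line segments (normal angle
#' \eqn{\theta + 90} mapped to `[0, 180)` degrees) and the mean and median
#' circle diameter in nm (\eqn{D = 2 r \times} nm per pixel, with
#' `nm_per_px = camera_pixel_size / scale` for real data), then the mean
#' \eqn{\mu} and standard deviation \eqn{\sigma} of each statistic across
#' replicates. Replicates with zero detections are excluded with a warning.
#'
#' @param line_fits list (one per replicate) of line detections data frames
#'   or `smlm_hough` fits; may be `NULL`.
#' @param circle_fits list of circle detections or fits; may be `NULL`.
#' @param camera_pixel_size camera pixel size in nm.
#' @param scale analysis rescale factor.
#' @return an object of class `feature_stats`: data frame `per_replicate`
#'   and data frame `summary` with columns `statistic`, `mu`, `sigma`,
#'   plus counts of excluded replicates.
#' @export
feature_statistics <- function(line_fits = NULL, circle_fits = NULL,
                               camera_pixel_size = 1, scale = 1) {
  nm_per_px <- camera_pixel_size / scale
  nrep <- max(length(line_fits), length(circle_fits))
  if (nrep == 0) stop("at least one replicate is required")
  rows <- list()
  excluded <- 0
  for (i in seq_len(nrep)) {
    row <- data.frame(replicate = i, theta_average = NA_real_,
                      theta_median = NA_real_, d_average = NA_real_,
                      d_median = NA_real_)
    got <- FALSE
    if (!is.null(line_fits) && i <= length(line_fits)) {
      d <- line_fits[[i]]
      if (inherits(d, "smlm_hough")) d <- d$detections
      if (nrow(d) > 0) {
        ori <- orientation_angle(d$theta)
        row$theta_average <- mean(ori); row$theta_median <- median(ori)
        got <- TRUE
      }
    }
    if (!is.null(circle_fits) && i <= length(circle_fits)) {
      d <- circle_fits[[i]]
      if (inherits(d, "smlm_hough")) d <- d$detections
      if (nrow(d) > 0) {
        D <- 2 * d$r * nm_per_px
        row$d_average <- mean(D); row$d_median <- median(D)
        got <- TRUE
      }
    }
    if (!got) excluded <- excluded + 1 else rows[[length(rows) + 1]] <- row
  }
  if (excluded > 0)
    warning(excluded, " replicate(s) with zero detections excluded")
  per <- do.call(rbind, rows)
  stats <- c("theta_average", "theta_median", "d_average", "d_median")
  summ <- data.frame(
    statistic = stats,
    mu = vapply(stats, function(s) mean(per[[s]], na.rm = TRUE), 0),
    sigma = vapply(stats, function(s) {
      v <- per[[s]][!is.na(per[[s]])]
      if (length(v) <= 1) 0 else sd(v)
    }, 0), row.names = NULL)
  structure(list(per_replicate = per, summary = summ,
                 n_replicates = nrep, n_excluded = excluded,
                 nm_per_px = nm_per_px),
            class = "feature_stats")
}

# line normal angle (degrees, [-90, 90)) -> orientation angle in [0, 180)
orientation_angle <- function(theta) {
  o <- theta + 90
  o[o >= 180] <- o[o >= 180] - 180
  o[o < 0] <- o[o < 0] + 180
  o
}

#' @export
print.feature_stats <- function(x, ...) {
  cat(sprintf("feature_stats over %d replicate(s) (%d excluded):\n",
              x$n_replicates, x$n_excluded))
  print(x$summary, digits = 5, row.names = FALSE)
  invisible(x)
}

#' Density sweep: reconstruction quality vs data density
#'
#' Emulates the study protocol: for each data density and noise
#' configuration, repeatedly samples the mask, applies position and outlier
#' noise, fits structures by Hough voting, renders the detections and
#' scores them against the ground-truth mask rendering with [cw_ssim()].
#' Feature statistics and (for parallel-line masks) the resolution are
#' collected per replicate. Replicates in which nothing is detected score 0
#' so that very low densities are penalized rather than silently dropped.
#'
#' @param mask a [structure_mask()].
#' @param shape `"line"` or `"circle"`.
#' @param densities vector of data densities in `(0, 1]`.
#' @param noise_cfgs list of noise configurations, each a list with
#'   `position_fwhm` (pixels) and `outlier_density` (fraction).
#' @param n_replicates random samplings per condition.
#' @param seed_base integer; replicate `r` of condition `k` derives its
#'   seeds from `seed_base`, `k` and `r` so the whole sweep is reproducible.
#' @param params detector parameters; `NULL` selects the density-dependent
#'   preset per condition.
#' @param smooth passed to [hough_fit()].
#' @param reference compare reconstructions against the rendered mask
#'   (`"mask"`, default) or against a rendering of the noise-free sampled
#'   data points (`"data"`).
#' @param cwssim_args extra arguments for [cw_ssim()].
#' @return an object of class `density_sweep`: `results` (one row per
#'   replicate: density, noise, CW-SSIM score, detection count, feature
#'   statistics, resolution) and `summary` (mean and sd of CW-SSIM per
#'   condition).
#' @export
density_sweep <- function(mask, shape = c("line", "circle"),
                          densities = seq(0.05, 1, by = 0.05),
                          noise_cfgs = list(list(position_fwhm = 0,
                                                 outlier_density = 0)),
                          n_replicates = 100, seed_base = 1,
                          params = NULL, smooth = NULL,
                          reference = c("mask", "data"),
                          cwssim_args = list()) {
  shape <- match.arg(shape)
  reference <- match.arg(reference)
  stopifnot(all(densities > 0 & densities <= 1), n_replicates >= 1)
  ref_img <- render_shapes(mask$shapes, mask$width, mask$height)
  is_parallel <- shape == "line" &&
    length(unique(round(vapply(mask$shapes, `[[`, 0, "theta"), 4))) == 1 &&
    length(mask$shapes) > 1
  rows <- list()
  cond <- 0
  for (dens in densities) {
    for (nc in noise_cfgs) {
      cond <- cond + 1
      p <- params %||% hough_params(shape, density = dens)
      for (r in seq_len(n_replicates)) {
        s <- seed_base + 7919L * (cond - 1L) + 3L * (r - 1L)
        locs <- sample_localizations(mask, dens, seed = s)
        if (nc$position_fwhm > 0)
          locs <- apply_position_noise(locs, nc$position_fwhm, seed = s + 1L)
        if (nc$outlier_density > 0)
          locs <- add_outlier_noise(locs, mask, nc$outlier_density,
                                    seed = s + 2L)
        fit <- hough_fit(locs, shape, dims = c(mask$width, mask$height),
                         params = p, smooth = smooth)
        if (reference == "data") {
          ref_img <- matrix(0, mask$height, mask$width)
          pr <- round(as_points(sample_localizations(mask, dens, seed = s)))
          ref_img[cbind(pmin(pmax(pr[, 2], 0), mask$height - 1) + 1,
                        pmin(pmax(pr[, 1], 0), mask$width - 1) + 1)] <- 1
        }
        score <- 0
        if (nrow(fit$detections) > 0) {
          rec <- fitted(fit)
          if (any(rec > 0))
            score <- as.numeric(do.call(cw_ssim, c(list(rec, ref_img),
                                                   cwssim_args)))
        }
        row <- data.frame(density = dens,
                          position_fwhm = nc$position_fwhm,
                          outlier_density = nc$outlier_density,
                          replicate = r, cwssim = score,
                          n_detected = nrow(fit$detections),
                          theta_average = NA_real_, theta_median = NA_real_,
                          d_average = NA_real_, d_median = NA_real_,
                          resolution = NA_real_)
        if (nrow(fit$detections) > 0) {
          if (shape == "line") {
            ori <- orientation_angle(fit$detections$theta)
            row$theta_average <- mean(ori)
            row$theta_median <- median(ori)
            if (is_parallel) row$resolution <- resolution(fit$detections)
          } else {
            D <- fit$detections$diameter_nm
            row$d_average <- mean(D)
            row$d_median <- median(D)
          }
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  results <- do.call(rbind, rows)
  key <- interaction(results$density, results$position_fwhm,
                     results$outlier_density, drop = TRUE)
  summ <- do.call(rbind, lapply(split(results, key), function(g)
    data.frame(density = g$density[1], position_fwhm = g$position_fwhm[1],
               outlier_density = g$outlier_density[1],
               mean_cwssim = mean(g$cwssim), sd_cwssim = sd(g$cwssim),
               mean_resolution = mean(g$resolution, na.rm = TRUE),
               n_replicates = nrow(g))))
  summ <- summ[order(summ$position_fwhm, summ$outlier_density, summ$density), ]
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ, shape = shape,
                 n_replicates = n_replicates, is_parallel = is_parallel),
            class = "density_sweep")
}

#' @export
print.density_sweep <- function(x, ...) {
  cat(sprintf("density_sweep (%s, %d replicates/condition):\n", x$shape,
              x$n_replicates))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.density_sweep <- function(x, ...) {
  s <- x$summary
  grp <- interaction(s$position_fwhm, s$outlier_density, drop = TRUE)
  cols <- seq_len(nlevels(grp))
  plot(NA, xlim = range(s$density), ylim = c(0, 1),
       xlab = "data density", ylab = "CW-SSIM", ...)
  for (k in seq_len(nlevels(grp))) {
    g <- s[grp == levels(grp)[k], ]
    lines(g$density, g$mean_cwssim, col = cols[k], lwd = 2)
    points(g$density, g$mean_cwssim, col = cols[k], pch = 16)
    up <- which(g$sd_cwssim > 0)
    if (length(up) > 0)
      arrows(g$density[up], g$mean_cwssim[up] - g$sd_cwssim[up],
             g$density[up], g$mean_cwssim[up] + g$sd_cwssim[up],
             angle = 90, code = 3, length = 0.02, col = cols[k])
  }
  legend("bottomright", legend = paste0("fwhm=", sub("\\.", " out=", levels(grp))),
         col = cols, lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Export a density sweep as CSV + JSON summary
#'
#' @param sweep a `density_sweep`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_sweep <- function(sweep, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(sweep$results, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(sweep$summary, json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  invisible(c(csv = csv_path, json = json_path))
}
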