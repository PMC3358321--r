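#' Localization sets
#'
#' A `localization_set` holds the continuous 2-d molecular positions that are
#' the raw data of localization microscopy, together with coordinate
#' metadata: the units of the coordinates, the analysis rescale factor and
#' the physical camera pixel size.
#'
#' @param points data frame with numeric columns `x` and `y` (optionally
#'   `channel`).
#' @param units one of `"mask-pixel"`, `"camera-pixel"`, `"nm"`.
#' @param scale dimensionless rescale factor applied for analysis (> 0).
#' @param camera_pixel_size camera pixel size in nm (e.g. 158), or `NULL`.
#' @param channel optional channel label for the whole set.
#' @return an object of class `localization_set`.
#' @export
localization_set <- function(points, units = "mask-pixel", scale = 1,
                             camera_pixel_size = NULL, channel = NULL) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (!all(is.finite(points$x)) || !all(is.finite(points$y)))
    stop("localization coordinates must be finite")
  if (scale <= 0) stop("scale must be positive")
  units <- match.arg(units, c("mask-pixel", "camera-pixel", "nm"))
  structure(list(points = points, units = units, scale = scale,
                 camera_pixel_size = camera_pixel_size, channel = channel),
            class = "localization_set")
}

#' @export
print.localization_set <- function(x, ...) {
  cat(sprintf("localization_set: %d points [%s]", nrow(x$points), x$units))
  if (!is.null(x$channel)) cat(sprintf(", channel %s", x$channel))
  if (!is.null(x$camera_pixel_size))
    cat(sprintf(", camera px %g nm, scale %g", x$camera_pixel_size, x$scale))
  cat("\n")
  invisible(x)
}

n_points <- function(locs) nrow(locs$points)

#' Stochastic-activation sampling of a structure mask
#'
#' Emulates the serial acquisition of PALM/STORM imaging: active pixels of
#' the ground-truth mask are drawn uniformly at random without replacement,
#' so shortened acquisitions preserve the relative molecular density of all
#' regions (no spatial bias).
#'
#' @param mask a [structure_mask()].
#' @param density fraction of active pixels to sample, in `(0, 1]`. The data
#'   density of the paper-style sweeps; `density = 1` returns every active
#'   pixel exactly once.
#' @param seed integer seed.
#' @return a [localization_set()] in mask-pixel units; exactly
#'   `round(density * n_active)` points, all members of the active set.
#' @export
sample_localizations <- function(mask, density, seed = NULL) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop("density must be in (0, 1]")
  na <- nrow(mask$active)
  n <- round(density * na)
  idx <- with_seed(seed, sample.int(na, n, replace = FALSE))
  localization_set(data.frame(x = as.numeric(mask$active[idx, 1]),
                              y = as.numeric(mask$active[idx, 2])),
                   units = "mask-pixel")
}

#' Gaussian position noise
#'
#' Displaces each localization independently by isotropic Gaussian noise,
#' modelling the finite localization accuracy of single-molecule fitting.
#' The spread is parameterized by its full width at half maximum;
#' `sigma = position_fwhm / (2 sqrt(2 log 2))` per axis.
#'
#' @param locs a [localization_set()].
#' @param position_fwhm FWHM of the Gaussian spread, pixels (>= 0; 0 leaves
#'   the set unchanged).
#' @param seed integer seed.
#' @return a [localization_set()] with the same number of points.
#' @export
apply_position_noise <- function(locs, position_fwhm, seed = NULL) {
  stopifnot(inherits(locs, "localization_set"))
  if (!is.numeric(position_fwhm) || position_fwhm < 0)
    stop("position_fwhm must be >= 0")
  if (position_fwhm == 0) return(locs)
  sigma <- position_fwhm / (2 * sqrt(2 * log(2)))
  n <- n_points(locs)
  out <- locs
  noise <- with_seed(seed, matrix(rnorm(2 * n, 0, sigma), n, 2))
  out$points$x <- locs$points$x + noise[, 1]
  out$points$y <- locs$points$y + noise[, 2]
  out
}

#' Salt-and-pepper outlier noise
#'
#' Appends spurious localizations (background signal, nonspecific binding)
#' drawn uniformly without replacement from pixels NOT on the structure.
#' `outlier_density` is the fraction of off-mask pixels converted to
#' localizations; the study grid is 0, 0.002, 0.005, 0.01, 0.02 and 0.05.
#'
#' @param locs a [localization_set()].
#' @param mask the [structure_mask()] defining on/off-structure pixels.
#' @param outlier_density fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return a [localization_set()] with `round(outlier_density * n_off)`
#'   points appended; the original points are unchanged.
#' @export
add_outlier_noise <- function(locs, mask, outlier_density, seed = NULL) {
  stopifnot(inherits(locs, "localization_set"), inherits(mask, "structure_mask"))
  if (!is.numeric(outlier_density) || outlier_density < 0 || outlier_density > 1)
    stop("outlier_density must be in [0, 1]")
  if (outlier_density == 0) return(locs)
  npix <- mask$width * mask$height
  active_key <- mask$active[, 1] + mask$width * mask$active[, 2]
  off <- setdiff(0:(npix - 1), active_key)
  n_out <- round(outlier_density * length(off))
  keys <- with_seed(seed, sample(off, n_out, replace = FALSE))
  out <- locs
  extra <- data.frame(x = as.numeric(keys %% mask$width),
                      y = as.numeric(keys %/% mask$width))
  for (nm in setdiff(names(locs$points), c("x", "y"))) extra[[nm]] <- NA
  out$points <- rbind(locs$points, extra[names(locs$points)])
  out
}

#' Read a molecular position table
#'
#' Reads a delimited text localization table (one row per localized
#' molecule). Column names are mapped through `column_map`, accommodating
#' the heterogeneous schemas of published STORM tables.
#'
#' @param path CSV file path.
#' @param column_map named list mapping the fields `x`, `y` and optionally
#'   `channel` to column names in the file.
#' @param units,scale,camera_pixel_size coordinate metadata, see
#'   [localization_set()].
#' @param sep field separator.
#' @return a [localization_set()]. Rows with non-numeric coordinates are
#'   dropped with a warning reporting their count.
#' @export
read_localizations <- function(path, column_map = list(x = "x", y = "y"),
                               units = "camera-pixel", scale = 1,
                               camera_pixel_size = NULL, sep = ",") {
  tab <- read.csv(path, sep = sep, check.names = FALSE)
  need <- unlist(column_map[c("x", "y")])
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("localization table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  pts <- data.frame(x = suppressWarnings(as.numeric(tab[[column_map$x]])),
                    y = suppressWarnings(as.numeric(tab[[column_map$y]])))
  if (!is.null(column_map$channel)) {
    if (!column_map$channel %in% names(tab))
      stop("localization table is missing column(s): ", column_map$channel)
    pts$channel <- tab[[column_map$channel]]
  }
  bad <- !is.finite(pts$x) | !is.finite(pts$y)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-numeric coordinates dropped")
    pts <- pts[!bad, , drop = FALSE]
  }
  localization_set(pts, units = units, scale = scale,
                   camera_pixel_size = camera_pixel_size)
}

#' @rdname read_localizations
#' @param locs a [localization_set()] to write.
#' @export
write_localizations <- function(locs, path) {
  write.csv(locs$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset a two-color set by channel
#'
#' @param locs a [localization_set()] whose points carry a `channel` column.
#' @param channel channel label to keep.
#' @return a [localization_set()] restricted to that channel.
#' @export
filter_channel <- function(locs, channel) {
  stopifnot(inherits(locs, "localization_set"))
  if (!"channel" %in% names(locs$points)) stop("no channel column present")
  out <- locs
  out$points <- locs$points[locs$points$channel == channel, , drop = FALSE]
  out$channel <- channel
  out
}

#' Rescale and discretize coordinates onto the analysis grid
#'
#' Multiplies coordinates by `scale` and rounds to integer analysis pixels,
#' the preparation step used for real camera-coordinate tables (default
#' scale 25 turns 158 nm camera pixels into ~6.3 nm analysis pixels, which
#' retains most close points without binning them into the same pixel).
#' Points that collapse onto the same analysis pixel are merged; the number
#' of merged duplicates is reported in attribute `n_duplicates`.
#'
#' @param locs a [localization_set()].
#' @param scale rescale factor (> 0).
#' @return a [localization_set()] on the integer analysis grid.
#' @export
rescale_discretize <- function(locs, scale = 25) {
  stopifnot(inherits(locs, "localization_set"))
  if (scale <= 0) stop("scale must be positive")
  pts <- locs$points
  pts$x <- round(pts$x * scale)
  pts$y <- round(pts$y * scale)
  dup <- duplicated(pts[c("x", "y")])
  out <- locs
  out$points <- pts[!dup, , drop = FALSE]
  rownames(out$points) <- NULL
  out$scale <- scale
  attr(out, "n_duplicates") <- sum(dup)
  out
}
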