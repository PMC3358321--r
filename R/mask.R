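#' Ground-truth structure masks
#'
#' A `structure_mask` is a binary ground-truth image on an integer pixel grid
#' together with the parametric shapes that generated it. Masks emulate the
#' targets of localization microscopy experiments: thin filaments (actin,
#' microtubules) as 1-pixel line segments and vesicle-like features
#' (clathrin-coated pits, endosomes) as 1-pixel circle perimeters. The default
#' scale is 1 nm per mask pixel, so a 640x640 mask represents a 640 nm x
#' 640 nm region of a cell.
#'
#' Coordinates are 0-based with the origin at the top-left corner, x running
#' right and y running down. Lines are rasterized with Bresenham's algorithm,
#' circles with the midpoint algorithm; both strokes are one pixel wide.
#'
#' @param width,height mask dimensions in pixels (>= 2).
#' @param shapes list of shape descriptors, see [line_shape()] and
#'   [circle_shape()].
#' @param pixel_scale physical size of one mask pixel in nm.
#' @return an object of class `structure_mask` with fields `width`, `height`,
#'   `active` (n x 2 integer matrix of active pixel coordinates), `shapes`
#'   and `pixel_scale`.
#' @seealso [make_line_mask()], [make_circle_mask()],
#'   [make_parallel_line_mask()], [render_shapes()]
#' @export
structure_mask <- function(width, height, shapes = list(), pixel_scale = 1) {
  if (!is.numeric(width) || !is.numeric(height) || width < 2 || height < 2)
    stop("mask dimensions must be numeric and >= 2")
  active <- rasterize_shapes(shapes, width, height)
  structure(list(width = as.integer(width), height = as.integer(height),
                 active = active, shapes = shapes,
                 pixel_scale = pixel_scale),
            class = "structure_mask")
}

#' Parametric shape descriptors
#'
#' Shapes are stored with their defining parameters plus, for lines, the
#' normal-form parameters \eqn{\rho = x\cos\theta + y\sin\theta} (\eqn{\rho}
#' the signed perpendicular distance of the line from the origin in pixels,
#' \eqn{\theta} the angle of its normal in degrees, in \eqn{[-90, 90)}).
#'
#' @param x1,y1,x2,y2 line segment endpoints, pixels.
#' @param a,b,r circle centre and radius, pixels (radius positive).
#' @return a list describing the shape (`kind` is `"line"` or `"circle"`).
#' @export
line_shape <- function(x1, y1, x2, y2) {
  if (x1 == x2 && y1 == y2) stop("degenerate line: endpoints coincide")
  nf <- line_normal_form(x1, y1, x2, y2)
  list(kind = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2,
       rho = nf$rho, theta = nf$theta)
}

#' @rdname line_shape
#' @export
circle_shape <- function(a, b, r) {
  if (r <= 0) stop("circle radius must be positive")
  list(kind = "circle", a = a, b = b, r = r)
}

# (rho, theta in degrees, theta in [-90, 90)) of the line through two points.
line_normal_form <- function(x1, y1, x2, y2) {
  theta <- atan2(y2 - y1, x2 - x1) * 180 / pi + 90  # normal angle
  rho <- NA_real_
  while (theta >= 90) theta <- theta - 180
  while (theta < -90) theta <- theta + 180
  th <- theta * pi / 180
  rho <- x1 * cos(th) + y1 * sin(th)
  list(rho = rho, theta = theta)
}

# Shared rasterizer: unique active pixels of a shape list, clipped to frame.
rasterize_shapes <- function(shapes, width, height) {
  if (length(shapes) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  px <- lapply(shapes, function(s) {
    if (s$kind == "line") {
      cpp_line_pixels(round(s$x1), round(s$y1), round(s$x2), round(s$y2))
    } else if (s$kind == "circle") {
      cpp_circle_pixels(round(s$a), round(s$b), round(s$r))
    } else stop("unknown shape kind: ", s$kind)
  })
  m <- unique(do.call(rbind, px))
  keep <- m[, 1] >= 0 & m[, 1] < width & m[, 2] >= 0 & m[, 2] < height
  m <- m[keep, , drop = FALSE]
  colnames(m) <- c("x", "y")
  m
}

#' @export
print.structure_mask <- function(x, ...) {
  kinds <- vapply(x$shapes, `[[`, "", "kind")
  cat(sprintf("structure_mask: %d x %d px (%g nm/px)\n", x$width, x$height,
              x$pixel_scale))
  cat(sprintf("  shapes: %d line(s), %d circle(s); active pixels: %d\n",
              sum(kinds == "line"), sum(kinds == "circle"), nrow(x$active)))
  invisible(x)
}

#' Simulated filament mask
#'
#' Generates a mask of `n_lines` straight filaments. Each filament is a random
#' chord of the frame (both endpoints on the image boundary), resampled until
#' it is at least `min_length` pixels long, mimicking filamentous structures
#' such as actin fibers or microtubules crossing the field of view.
#'
#' @inheritParams structure_mask
#' @param n_lines number of filaments (>= 1).
#' @param seed integer seed for reproducible generation.
#' @param min_length minimum chord length in pixels.
#' @param endpoints optional n x 4 matrix `(x1, y1, x2, y2)` of explicit
#'   endpoints overriding random generation.
#' @return a [structure_mask()].
#' @export
make_line_mask <- function(width = 640, height = 640, n_lines = 12,
                           seed = NULL, min_length = 0.5 * min(width, height),
                           endpoints = NULL, pixel_scale = 1) {
  if (width < 2 || height < 2) stop("mask dimensions must be >= 2")
  if (is.null(endpoints) && n_lines < 1) stop("n_lines must be >= 1")
  if (is.null(endpoints)) {
    endpoints <- with_seed(seed, {
      out <- matrix(0, n_lines, 4)
      for (i in seq_len(n_lines)) {
        repeat {
          p <- boundary_points(width, height, 2)
          len <- sqrt(sum((p[1, ] - p[2, ])^2))
          if (len >= min_length) break
        }
        out[i, ] <- c(p[1, ], p[2, ])
      }
      out
    })
  }
  shapes <- lapply(seq_len(nrow(endpoints)), function(i)
    do.call(line_shape, as.list(endpoints[i, 1:4])))
  structure_mask(width, height, shapes, pixel_scale)
}

# n random points on the rectangle boundary (0-based, inclusive of edges)
boundary_points <- function(width, height, n) {
  per <- 2 * (width - 1) + 2 * (height - 1)
  t <- runif(n, 0, per)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    s <- t[i]
    if (s < width - 1) out[i, ] <- c(s, 0)
    else if (s < width - 1 + height - 1) out[i, ] <- c(width - 1, s - (width - 1))
    else if (s < 2 * (width - 1) + height - 1)
      out[i, ] <- c(s - (width - 1) - (height - 1), height - 1)
    else out[i, ] <- c(0, s - 2 * (width - 1) - (height - 1))
  }
  round(out)
}

#' Simulated vesicle (circle) mask
#'
#' Generates `n_circles` circle perimeters mimicking circular structures such
#' as clathrin-coated pits or endosomes; the default radius range 30-60 px
#' corresponds to the ~60-120 nm diameters of clathrin-coated pits and
#' vesicles at the 1 nm/px mask scale. Circles lie fully inside the frame;
#' random placement enforces a minimum centre separation of
#' `r_i + r_j + 10` pixels so features do not merge.
#'
#' @inheritParams make_line_mask
#' @param n_circles number of circles (0 allowed, giving an empty mask).
#' @param radius_range length-2 range of radii in pixels.
#' @param circles optional n x 3 matrix `(a, b, r)` of explicit circles
#'   overriding random placement.
#' @return a [structure_mask()].
#' @export
make_circle_mask <- function(width = 640, height = 640, n_circles = 9,
                             radius_range = c(30, 60), seed = NULL,
                             circles = NULL, pixel_scale = 1) {
  if (width < 2 || height < 2) stop("mask dimensions must be >= 2")
  if (is.null(circles)) {
    if (max(radius_range) * 2 + 2 > min(width, height))
      stop("radius_range too large for the frame")
    circles <- with_seed(seed, {
      out <- matrix(0, 0, 3)
      tries <- 0
      while (nrow(out) < n_circles && tries < 5000 * max(1, n_circles)) {
        tries <- tries + 1
        r <- round(runif(1, radius_range[1], radius_range[2]))
        a <- round(runif(1, r + 1, width - r - 2))
        b <- round(runif(1, r + 1, height - r - 2))
        if (nrow(out) == 0 ||
            all(sqrt((out[, 1] - a)^2 + (out[, 2] - b)^2) >= out[, 3] + r + 10))
          out <- rbind(out, c(a, b, r))
      }
      if (nrow(out) < n_circles)
        stop("could not place ", n_circles, " non-overlapping circles")
      out
    })
  } else if (nrow(circles) > 0) {
    if (any(circles[, 1] - circles[, 3] < 0 | circles[, 1] + circles[, 3] >= width |
            circles[, 2] - circles[, 3] < 0 | circles[, 2] + circles[, 3] >= height))
      stop("circle extends outside the frame")
  }
  shapes <- lapply(seq_len(nrow(circles)), function(i)
    circle_shape(circles[i, 1], circles[i, 2], circles[i, 3]))
  structure_mask(width, height, shapes, pixel_scale)
}

#' Parallel-line resolution target
#'
#' Generates `n_lines` parallel filaments with common orientation and
#' perpendicular spacing `spacing` pixels, the target used to measure
#' reconstruction resolution as the minimum inter-line distance.
#'
#' @inheritParams make_line_mask
#' @param spacing perpendicular distance between consecutive lines, pixels
#'   (>= 1).
#' @param theta common normal angle in degrees (in `[-90, 90)`); randomly
#'   drawn when `NULL`.
#' @return a [structure_mask()] whose line shapes share `theta` and have
#'   `rho` values spaced by `spacing`.
#' @export
make_parallel_line_mask <- function(width = 640, height = 640, n_lines = 2,
                                    spacing = 20, seed = NULL, theta = NULL,
                                    pixel_scale = 1) {
  if (spacing < 1) stop("spacing must be >= 1 pixel")
  if (n_lines < 1) stop("n_lines must be >= 1")
  theta <- with_seed(seed, theta %||% runif(1, -90, 90))
  th <- theta * pi / 180
  # centre the family on the image midpoint
  rho_mid <- (width / 2) * cos(th) + (height / 2) * sin(th)
  rhos <- rho_mid + (seq_len(n_lines) - (n_lines + 1) / 2) * spacing
  shapes <- lapply(rhos, function(r) {
    ep <- clip_line_to_rect(r, theta, width, height)
    if (is.null(ep)) stop("parallel lines exceed the frame at this spacing")
    s <- line_shape(ep[1], ep[2], ep[3], ep[4])
    s$rho <- r; s$theta <- theta   # exact family parameters
    s
  })
  structure_mask(width, height, shapes, pixel_scale)
}

# Clip the infinite line rho = x cos(theta) + y sin(theta) to the pixel frame
# [0, w-1] x [0, h-1]; returns c(x1, y1, x2, y2) or NULL if no intersection.
clip_line_to_rect <- function(rho, theta_deg, width, height) {
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  pts <- list()
  if (abs(st) > 1e-12) {
    for (x in c(0, width - 1)) {
      y <- (rho - x * ct) / st
      if (y >= -1e-9 && y <= height - 1 + 1e-9) pts <- c(pts, list(c(x, y)))
    }
  }
  if (abs(ct) > 1e-12) {
    for (y in c(0, height - 1)) {
      x <- (rho - y * st) / ct
      if (x >= -1e-9 && x <= width - 1 + 1e-9) pts <- c(pts, list(c(x, y)))
    }
  }
  if (length(pts) < 2) return(NULL)
  m <- unique(round(do.call(rbind, pts), 6))
  if (nrow(m) < 2) return(NULL)
  d <- as.matrix(dist(m))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  c(m[ij[1], ], m[ij[2], ])
}

#' Equispaced points on a discrete circle perimeter
#'
#' Returns `n` angularly equispaced pixels of the midpoint-rasterized
#' circle, the sampling used in the worked voting examples: because such
#' points lie exactly on the discrete perimeter, each one votes for the
#' true `(a, b, r)` accumulator cell and the consensus maximum equals `n`.
#'
#' @param a,b,r circle centre and radius in pixels.
#' @param n number of points.
#' @return an `n` x 2 integer matrix of `(x, y)` pixel coordinates.
#' @export
circle_points <- function(a, b, r, n) {
  per <- cpp_circle_pixels(round(a), round(b), round(r))
  ang <- atan2(per[, 2] - b, per[, 1] - a)
  per <- per[order(ang), , drop = FALSE]
  idx <- round(seq(1, nrow(per), length.out = n + 1))[seq_len(n)]
  out <- per[idx, , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Mask as a binary image matrix
#'
#' @param mask a [structure_mask()].
#' @return a `height` x `width` 0/1 matrix; element `[y + 1, x + 1]` is the
#'   pixel at 0-based coordinate `(x, y)`.
#' @export
mask_image <- function(mask) {
  img <- matrix(0, mask$height, mask$width)
  if (nrow(mask$active) > 0)
    img[cbind(mask$active[, 2] + 1, mask$active[, 1] + 1)] <- 1
  img
}

#' Export a mask as PNG plus a JSON shape sidecar
#'
#' @param mask a [structure_mask()].
#' @param path output PNG path; the shape list is written next to it with a
#'   `.json` extension.
#' @return invisibly, the two paths written.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask_image(mask), path)
  jpath <- sub("\\.png$", ".json", path)
  if (identical(jpath, path)) jpath <- paste0(path, ".json")
  jsonlite::write_json(mask$shapes, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(png = path, json = jpath))
}
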